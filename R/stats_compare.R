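# QA/QC statistics (RSD, identification efficiency, false-positive rates),
# group differential analysis, and the acquisition-mode comparison report.

# round-half-up at `digits` decimals (R's round() is round-half-even)
.round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Relative standard deviation of replicate intensities
#'
#' 100 * sample standard deviation / mean, reported to one decimal.
#'
#' @param intensities Replicate values (>= 2, positive mean).
#' @return RSD in percent.
#' @examples
#' rsd(c(90, 100, 110))  # 10.0
#' @export
rsd <- function(intensities) {
  if (length(intensities) < 2)
    stop("RSD requires at least 2 replicate values")
  m <- mean(intensities)
  if (m <= 0) stop("RSD undefined for non-positive mean intensity")
  .round_half_up(100 * stats::sd(intensities) / m, 1)
}

#' False positive rate in percent
#'
#' 100 * n_false / n_total, rounded half-up. Labelled-standard rates are
#' conventionally reported to one decimal (`digits = 1`); feature-level rates
#' to the nearest integer (`digits = 0`).
#'
#' @param n_false Number of false positives (0 <= n_false <= n_total).
#' @param n_total Total count (> 0).
#' @param digits Decimals to report (default 1).
#' @return Percent value.
#' @examples
#' false_positive_rate(3, 14)              # 21.4
#' false_positive_rate(114, 132, digits = 0)  # 86
#' @export
false_positive_rate <- function(n_false, n_total, digits = 1) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_false < 0 || n_false > n_total)
    stop("n_false must lie in [0, n_total]")
  .round_half_up(100 * n_false / n_total, digits)
}

#' Identification efficiency of spiked labelled standards
#'
#' The fraction of spiked standards recovered by the screen; identified
#' labelled features that were never spiked are counted separately as false
#' positives (with the false-positive rate computed over the number of
#' spiked standards, matching the labelled-standard QC convention).
#'
#' @param spiked Character vector of spiked standard names (or a standards
#'   data.frame with a `name` column).
#' @param identified Character vector of identified names.
#' @return A list: `per_standard` (data.frame `name`/`identified`),
#'   `n_spiked`, `n_identified`, `efficiency` (fraction),
#'   `n_false_positive`, `false_positive_rate` (percent, one decimal).
#' @export
identification_efficiency <- function(spiked, identified) {
  if (is.data.frame(spiked)) spiked <- spiked$name
  if (!length(spiked)) stop("spiked standard list must be non-empty")
  spiked <- unique(spiked)
  identified <- unique(identified)
  found <- spiked %in% identified
  extras <- setdiff(identified, spiked)
  list(
    per_standard = data.frame(name = spiked, identified = found,
                              stringsAsFactors = FALSE),
    n_spiked = length(spiked),
    n_identified = sum(found),
    efficiency = sum(found) / length(spiked),
    n_false_positive = length(extras),
    false_positive_rate = false_positive_rate(length(extras), length(spiked))
  )
}

#' Measure a feature intensity matrix across runs
#'
#' For every feature (m/z, RT) the maximum MS1 EIC intensity within
#' `rt_window_min` of the feature RT is taken per run.
#'
#' @param runs Named list of [acquisition_run()]s (one column per run).
#' @param features A data.frame with columns `mz` and `rt_min`.
#' @param tol_ppm EIC tolerance, ppm.
#' @param rt_window_min RT half-window, minutes.
#' @return A numeric matrix (features x runs).
#' @export
measure_feature_matrix <- function(runs, features, tol_ppm = 5,
                                   rt_window_min = 0.2) {
  out <- vapply(runs, function(run) {
    vapply(seq_len(nrow(features)), function(i) {
      tr <- extract_eic(run, features$mz[i], tol_ppm, ms_level = 1L)
      sel <- abs(tr$rt_min - features$rt_min[i]) <= rt_window_min
      if (any(sel)) max(tr$intensity[sel]) else 0
    }, numeric(1))
  }, numeric(nrow(features)))
  rownames(out) <- rownames(features)
  out
}

#' Group differential analysis of a feature matrix
#'
#' Fold change is the ratio of raw-intensity group means (`mean_b / mean_a`);
#' significance is a two-sided t-test on log10-transformed intensities.
#' The default pools the group variances (`var_equal = TRUE`): replicate
#' injections of the same pooled extract share their technical variance, and
#' the pooled test has exact size under that model at n = 3, where the
#' Welch-Satterthwaite approximation is measurably conservative (empirical
#' size near 0.03 at alpha 0.05). Set `var_equal = FALSE` for Welch.
#' Labels: `up` if fold > `fold_threshold` and p < `alpha`; `down` if fold <
#' `1/fold_threshold` and p < `alpha`; else `unchanged`. Zero/NA intensities
#' count as missing; features present in only one group get an infinite (or
#' zero) fold and are labelled only when the present group's minimum
#' replicate exceeds `detection_floor` (no p-value is fabricated). When both
#' groups are replicate-degenerate (zero variance), p is 1 for equal means
#' and 0 otherwise. No multiple-testing correction by default
#' (`p_adjust = "BH"` enables Benjamini-Hochberg).
#'
#' @param intensities Numeric matrix, features x samples.
#' @param groups Character/factor of group labels per column.
#' @param group_a,group_b The two groups to compare (fold = b over a).
#' @param fold_threshold Fold-change threshold (default 2).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param var_equal Pool the group variances (default `TRUE`).
#' @param detection_floor Intensity floor for one-group-only calls.
#' @return A data.frame: `mean_a`, `mean_b`, `fold_change`, `p_value`,
#'   `label`.
#' @export
differential_analysis <- function(intensities, groups, group_a, group_b,
                                  fold_threshold = 2, alpha = 0.05,
                                  p_adjust = c("none", "BH"),
                                  detection_floor = 0, var_equal = TRUE) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(ncol(intensities) == length(groups))
  a_cols <- which(groups == group_a)
  b_cols <- which(groups == group_b)
  if (length(a_cols) < 2 || length(b_cols) < 2)
    stop("both groups need >= 2 replicates")
  res <- lapply(seq_len(nrow(intensities)), function(i) {
    a <- intensities[i, a_cols]
    b <- intensities[i, b_cols]
    a <- a[!is.na(a) & a > 0]
    b <- b[!is.na(b) & b > 0]
    if (length(a) == 0 && length(b) == 0)
      return(data.frame(mean_a = NA_real_, mean_b = NA_real_,
                        fold_change = NA_real_, p_value = NA_real_,
                        label = "unchanged"))
    if (length(a) == 0 || length(b) == 0) {
      present <- if (length(a)) a else b
      lbl <- if (min(present) > detection_floor) {
        if (length(b)) "up" else "down"
      } else "unchanged"
      return(data.frame(mean_a = if (length(a)) mean(a) else 0,
                        mean_b = if (length(b)) mean(b) else 0,
                        fold_change = if (length(b)) Inf else 0,
                        p_value = NA_real_, label = lbl))
    }
    fold <- mean(b) / mean(a)
    la <- log10(a)
    lb <- log10(b)
    p <- if (length(a) < 2 || length(b) < 2) {
      NA_real_
    } else if (stats::var(la) == 0 && stats::var(lb) == 0) {
      if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0
    } else {
      stats::t.test(lb, la, var.equal = var_equal)$p.value
    }
    data.frame(mean_a = mean(a), mean_b = mean(b), fold_change = fold,
               p_value = p, label = "unchanged")
  })
  out <- do.call(rbind, res)
  if (p_adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  decided <- !is.na(out$p_value) & out$p_value < alpha
  out$label[decided & out$fold_change > fold_threshold] <- "up"
  out$label[decided & out$fold_change < 1 / fold_threshold] <- "down"
  rownames(out) <- rownames(intensities)
  out
}

#' Assemble the acquisition-mode comparison report
#'
#' One row per analyzed (mode, sample) pair with the count chain
#' `n_precursor_ions >= n_candidate_ions >= n_level1 + n_level2 + n_level3`
#' asserted (a violated chain is an internal bug, not a data property).
#'
#' @param sets A list of analysis sets; each element is a list with `mode`,
#'   `sample_id`, `candidates` (candidate table; precursor ions = rows that
#'   passed the composition filters) and optionally `annotations`
#'   (from [assign_level()]).
#' @return A `comparison_report` data.frame: `mode`, `sample_id`,
#'   `n_precursor_ions`, `n_candidate_ions`, `n_false_positive`, `n_level1`,
#'   `n_level2`, `n_level3`.
#' @export
build_comparison_report <- function(sets) {
  if (!length(sets)) stop("at least one analyzed set is required")
  rows <- lapply(sets, function(s) {
    cand <- s$candidates
    surv <- cand[!cand$status %in% "filtered", , drop = FALSE]
    ann <- s$annotations
    lv <- function(k) if (is.null(ann)) 0L else sum(ann$level == k,
                                                    na.rm = TRUE)
    data.frame(
      mode = s$mode, sample_id = s$sample_id,
      n_precursor_ions = nrow(surv),
      n_candidate_ions = sum(surv$status == "candidate"),
      n_false_positive = sum(surv$status == "false_positive"),
      n_level1 = lv(1L), n_level2 = lv(2L), n_level3 = lv(3L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  bad <- out$n_candidate_ions > out$n_precursor_ions |
    (out$n_level1 + out$n_level2 + out$n_level3) > out$n_candidate_ions
  if (any(bad))
    stop("count chain violated (precursor >= candidate >= sum of levels) ",
         "for row(s) ", paste(which(bad), collapse = ", "),
         "; this indicates an internal inconsistency")
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Acquisition-mode comparison\n")
  cat(sprintf("%-5s %-12s %10s %10s %8s %7s %7s %7s\n", "mode", "sample",
              "precursor", "candidate", "false+", "level1", "level2",
              "level3"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-5s %-12s %10d %10d %8d %7d %7d %7d\n", x$mode[i],
                x$sample_id[i], x$n_precursor_ions[i], x$n_candidate_ions[i],
                x$n_false_positive[i], x$n_level1[i], x$n_level2[i],
                x$n_level3[i]))
  }
  invisible(x)
}
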