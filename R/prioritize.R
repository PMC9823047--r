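# Precursor prioritization under the diagnostic-fragment-ion rules, for both
# DIA (in-source CE channels) and DDA (ddMS2) acquisitions: EIC screening,
# intensity threshold, elemental-composition filtering, the two-of-three
# diagnostic-ion candidacy rule, procedural-blank comparison, and the
# targeted-MS/MS inclusion list. Every filtered ion carries a single
# machine-readable reason so that filter counts reconcile.

#' Filter thresholds of the screening workflow
#'
#' @param tic_intensity_threshold Minimum full-scan (CE=0 / MS1) centroid
#'   intensity for a nominated ion, counts. Default 5e5 — five times the
#'   typical S/N in spiked samples.
#' @param dda_match_tol_ppm Fragment/precursor matching tolerance, ppm.
#' @param blank_ratio Sample/blank intensity ratio required to keep a
#'   feature (default 3).
#' @param require_two_of_three Enforce the >= 2-of-3 diagnostic-ion rule at
#'   MS/MS confirmation.
#' @return A `filter_config` list.
#' @export
filter_config <- function(tic_intensity_threshold = 5e5,
                          dda_match_tol_ppm = 5,
                          blank_ratio = 3,
                          require_two_of_three = TRUE) {
  stopifnot(tic_intensity_threshold > 0, dda_match_tol_ppm > 0,
            blank_ratio > 0)
  structure(
    list(tic_intensity_threshold = tic_intensity_threshold,
         dda_match_tol_ppm = dda_match_tol_ppm, blank_ratio = blank_ratio,
         require_two_of_three = require_two_of_three),
    class = "filter_config"
  )
}

#' Match diagnostic ions in a fragment spectrum
#'
#' For each diagnostic ion, the most intense centroid within `tol_ppm` (if
#' any) is reported.
#'
#' @param spectrum A [spectrum_record()] (MS2, or a scan from an in-source
#'   fragmentation channel).
#' @param ions Numeric vector of diagnostic ion m/z values (e.g. the native
#'   trio of [diagnostic_ion_set()]).
#' @param tol_ppm Matching tolerance in ppm (closed window).
#' @return A data.frame with one row per matched ion: `ion_mz`,
#'   `observed_mz`, `intensity`.
#' @export
diagnostic_ion_match <- function(spectrum, ions, tol_ppm = 5) {
  hits <- lapply(ions, function(target) {
    half <- tol_ppm * target / 1e6
    sel <- spectrum$mz >= target - half & spectrum$mz <= target + half
    if (!any(sel)) return(NULL)
    i <- which(sel)[which.max(spectrum$intensity[sel])]
    data.frame(ion_mz = target, observed_mz = spectrum$mz[i],
               intensity = spectrum$intensity[i])
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(ion_mz = numeric(0), observed_mz = numeric(0),
                      intensity = numeric(0))
  out
}

.empty_candidates <- function() {
  data.frame(
    mz = numeric(0), rt_min = numeric(0), intensity = numeric(0),
    n_diagnostic_ions = integer(0), matched_ions = character(0),
    supplementary_ion = logical(0), top_formula = character(0),
    formula_ppm = numeric(0), n_formulas = integer(0),
    mode = character(0), sample_id = character(0), status = character(0),
    reason = character(0), stringsAsFactors = FALSE
  )
}

.merge_duplicate_precursors <- function(cand, rt_tol = 0.1, ppm_tol = 5) {
  if (nrow(cand) <= 1) return(cand)
  # chain along m/z (ppm gaps), then along RT within each m/z chain:
  # repeated ddMS2 selections of one eluting precursor sit a cycle or two
  # apart and must collapse to a single feature
  o <- order(cand$mz, cand$rt_min)
  cand <- cand[o, , drop = FALSE]
  mz_gap <- diff(cand$mz) > ppm_tol * cand$mz[-nrow(cand)] / 1e6
  mz_grp <- cumsum(c(1L, as.integer(mz_gap)))
  grp <- integer(nrow(cand))
  gid <- 0L
  for (g in split(seq_len(nrow(cand)), mz_grp)) {
    idx <- g[order(cand$rt_min[g])]
    sub <- cumsum(c(1L, as.integer(diff(cand$rt_min[idx]) > rt_tol)))
    grp[idx] <- gid + sub
    gid <- gid + max(sub)
  }
  merged <- lapply(split(cand, grp), function(g) {
    best <- g[which.max(g$intensity), , drop = FALSE]
    ions <- sort(unique(unlist(strsplit(g$matched_ions[g$matched_ions != ""],
                                        ";"))))
    best$matched_ions <- paste(ions, collapse = ";")
    best$n_diagnostic_ions <- length(ions)
    best$supplementary_ion <- any(g$supplementary_ion)
    best
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$rt_min, out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# intensity threshold + formula enumeration; fills status/reason in place
.apply_composition_filters <- function(cand, constraints, filters) {
  if (nrow(cand) == 0) return(cand)
  cand$top_formula <- NA_character_
  cand$formula_ppm <- NA_real_
  cand$n_formulas <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand$intensity[i] < filters$tic_intensity_threshold) {
      cand$status[i] <- "filtered"
      cand$reason[i] <- "intensity_threshold"
      next
    }
    fs <- enumerate_formulas(cand$mz[i], constraints)
    if (nrow(fs) == 0) {
      cand$status[i] <- "filtered"
      cand$reason[i] <- "no_formula"
    } else {
      cand$top_formula[i] <- fs$formula[1]
      cand$formula_ppm[i] <- fs$ppm_error[1]
      cand$n_formulas[i] <- nrow(fs)
    }
  }
  cand
}

#' Prioritize precursor candidates from DIA channel runs
#'
#' Implements the in-source-fragmentation screening path: (1) EICs of each
#' native diagnostic ion in each fragment channel; (2) peak detection;
#' (3) cross-channel alignment to consensus retention times; (4) at each
#' consensus RT, centroids of the nearest CE=0 full scan are nominated and
#' the 5e5-count intensity threshold applied; (5) formula enumeration under
#' the elemental composition restrictions. Surviving ions are *provisional*
#' (`status = "provisional"`): the two-of-three diagnostic-ion rule is only
#' decided on acquired MS/MS spectra ([confirm_candidates()]). Channel
#' co-elution is carried as provisional evidence (`n_diagnostic_ions`,
#' `matched_ions`).
#'
#' @param ce0_run The CE = 0 V DIA channel ([acquisition_run()], MS1 only).
#' @param fragment_channel_runs List of fragment channel runs (CE 20/40 V).
#' @param diag A [diagnostic_ion_set()].
#' @param constraints A [composition_constraints()].
#' @param filters A [filter_config()].
#' @param rt_align_tol_min Cross-channel apex alignment tolerance, minutes.
#' @param dia_min_coeluting_ions Minimum number of distinct diagnostic-ion
#'   EIC peaks that must co-elute before the consensus RT is considered
#'   (default 1).
#' @param sample_id Label carried into the candidate table.
#' @return A candidate data.frame (one row per nominated ion) with columns
#'   `mz`, `rt_min`, `intensity`, `n_diagnostic_ions`, `matched_ions`,
#'   `supplementary_ion`, `top_formula`, `formula_ppm`, `n_formulas`, `mode`,
#'   `sample_id`, `status` (`provisional`/`filtered`), `reason`.
#' @export
prioritize_dia <- function(ce0_run, fragment_channel_runs,
                           diag = diagnostic_ion_set(),
                           constraints = composition_constraints(),
                           filters = filter_config(),
                           rt_align_tol_min = 0.1,
                           dia_min_coeluting_ions = 1,
                           sample_id = "sample") {
  if (is.null(ce0_run) || !inherits(ce0_run, "acquisition_run"))
    stop("a CE = 0 V channel run is required")
  if (!length(fragment_channel_runs))
    stop("at least one fragment channel run (CE > 0) is required")
  ions <- c(diag$native_trio, diag$supplementary)
  peak_tabs <- list()
  for (run in fragment_channel_runs) {
    for (ion in ions) {
      tr <- extract_eic(run, ion, diag$match_tol_ppm, ms_level = 1L)
      pk <- detect_peaks(tr, snr_min = constraints$snr_min)
      if (nrow(pk)) {
        pk$ion_mz <- ion
        pk$ce_v <- if (!is.na(run$channel_ce_v)) run$channel_ce_v else NA_real_
        peak_tabs[[length(peak_tabs) + 1]] <- pk
      }
    }
  }
  if (!length(peak_tabs)) return(.empty_candidates())
  peak_table <- do.call(rbind, peak_tabs)
  # supplementary ion never counts toward co-elution of the trio
  trio_peaks <- peak_table[peak_table$ion_mz %in% diag$native_trio, ,
                           drop = FALSE]
  if (nrow(trio_peaks) == 0) return(.empty_candidates())
  ali <- align_across_channels(trio_peaks, rt_align_tol_min)
  groups <- ali$groups[ali$groups$n_distinct_diagnostic_ions >=
                         dia_min_coeluting_ions, , drop = FALSE]
  if (nrow(groups) == 0) return(.empty_candidates())
  ms1_rts <- vapply(ce0_run$spectra, `[[`, numeric(1), "rt_min")
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    rtc <- groups$consensus_rt_min[g]
    si <- which.min(abs(ms1_rts - rtc))
    sp <- ce0_run$spectra[[si]]
    if (!length(sp$mz)) next
    memb <- ali$members[ali$members$group_id == groups$group_id[g], ,
                        drop = FALSE]
    ion_set <- sort(unique(memb$ion_mz))
    supp <- any(abs(peak_table$ion_mz - diag$supplementary) < 1e-6 &
                  abs(peak_table$apex_rt_min - rtc) <= rt_align_tol_min)
    rows[[length(rows) + 1]] <- data.frame(
      mz = sp$mz, rt_min = rtc, intensity = sp$intensity,
      n_diagnostic_ions = length(ion_set),
      matched_ions = paste(sprintf("%.4f", ion_set), collapse = ";"),
      supplementary_ion = supp, top_formula = NA_character_,
      formula_ppm = NA_real_, n_formulas = 0L,
      mode = "DIA", sample_id = sample_id, status = "provisional",
      reason = NA_character_, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(.empty_candidates())
  cand <- do.call(rbind, rows)
  cand <- .merge_duplicate_precursors(cand, rt_tol = rt_align_tol_min,
                                      ppm_tol = filters$dda_match_tol_ppm)
  cand <- .apply_composition_filters(cand, constraints, filters)
  rownames(cand) <- NULL
  cand
}

#' Prioritize precursor candidates from a DDA run
#'
#' Precursor ions are taken directly from the EIC MS/MS evidence: every MS2
#' scan is matched against the native diagnostic trio (plus the supplementary
#' ion); scans with at least one match nominate their precursor. Duplicate
#' nominations within `rt_tol`/`ppm_tol` are merged (maximum intensity
#' retained, matched-ion sets pooled). The intensity threshold and elemental
#' composition restrictions are then applied, and — since the MS/MS spectra
#' are already in hand — the two-of-three rule immediately sets
#' `status = "candidate"` or `"false_positive"`.
#'
#' @param run A DDA [acquisition_run()] (interleaved MS1 + ddMS2).
#' @inheritParams prioritize_dia
#' @param ion_trio Which trio to screen: `"native"` (default) or `"labelled"`
#'   (isotope-labelled internal standards).
#' @return A candidate data.frame as in [prioritize_dia()], with `status`
#'   in `candidate`/`false_positive`/`filtered`.
#' @export
prioritize_dda <- function(run, diag = diagnostic_ion_set(),
                           constraints = composition_constraints(),
                           filters = filter_config(),
                           sample_id = "sample",
                           ion_trio = c("native", "labelled")) {
  ion_trio <- match.arg(ion_trio)
  trio <- if (ion_trio == "native") diag$native_trio else diag$labelled_trio
  ms2 <- Filter(function(s) s$ms_level == 2L, run$spectra)
  if (!length(ms2)) stop("run contains no MS2 scans; not a DDA acquisition")
  ms1 <- Filter(function(s) s$ms_level == 1L, run$spectra)
  ms1_rts <- vapply(ms1, `[[`, numeric(1), "rt_min")
  rows <- list()
  for (sp in ms2) {
    m <- diagnostic_ion_match(sp, trio, diag$match_tol_ppm)
    if (nrow(m) == 0) next
    supp <- nrow(diagnostic_ion_match(sp, diag$supplementary,
                                      diag$match_tol_ppm)) > 0
    # MS1 intensity of the nominated precursor: nearest preceding full scan
    intens <- sp$precursor_intensity
    if (length(ms1)) {
      si <- which.min(abs(ms1_rts - sp$rt_min))
      half <- filters$dda_match_tol_ppm * sp$precursor_mz / 1e6
      sel <- ms1[[si]]$mz >= sp$precursor_mz - half &
        ms1[[si]]$mz <= sp$precursor_mz + half
      if (any(sel)) intens <- max(ms1[[si]]$intensity[sel])
    }
    if (is.na(intens)) intens <- 0
    rows[[length(rows) + 1]] <- data.frame(
      mz = sp$precursor_mz, rt_min = sp$rt_min, intensity = intens,
      n_diagnostic_ions = nrow(m),
      matched_ions = paste(sprintf("%.4f", sort(m$ion_mz)), collapse = ";"),
      supplementary_ion = supp, top_formula = NA_character_,
      formula_ppm = NA_real_, n_formulas = 0L,
      mode = "DDA", sample_id = sample_id, status = "nominated",
      reason = NA_character_, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(.empty_candidates())
  cand <- do.call(rbind, rows)
  cand <- .merge_duplicate_precursors(cand, rt_tol = 0.1,
                                      ppm_tol = filters$dda_match_tol_ppm)
  cand <- .apply_composition_filters(cand, constraints, filters)
  pending <- cand$status == "nominated"
  two_of_three <- cand$n_diagnostic_ions >= 2L
  cand$status[pending & (two_of_three | !filters$require_two_of_three)] <-
    "candidate"
  cand$status[pending & !two_of_three & filters$require_two_of_three] <-
    "false_positive"
  cand$reason[cand$status == "false_positive"] <- "lt2_diagnostic_ions"
  rownames(cand) <- NULL
  cand
}

#' Confirm provisional DIA candidates against targeted MS/MS spectra
#'
#' Applies the two-of-three diagnostic-ion rule to the MS2 spectra acquired
#' in the targeted follow-up run. Matched ions are pooled over all MS2 scans
#' whose isolated precursor is within `ppm_tol` and `rt_window_min` of the
#' provisional ion. Provisional ions with no acquired MS2 stay provisional
#' (with a warning).
#'
#' @param candidates A candidate table from [prioritize_dia()].
#' @param targeted_run A ddMS2 [acquisition_run()] acquired with the
#'   inclusion list.
#' @param diag A [diagnostic_ion_set()].
#' @param ppm_tol Precursor matching tolerance, ppm.
#' @param rt_window_min RT window around the provisional RT, minutes.
#' @param ion_trio `"native"` or `"labelled"` trio for the rule.
#' @return The candidate table with `status` updated to
#'   `candidate`/`false_positive` (or left `provisional`).
#' @export
confirm_candidates <- function(candidates, targeted_run,
                               diag = diagnostic_ion_set(),
                               ppm_tol = 5, rt_window_min = 0.5,
                               ion_trio = c("native", "labelled")) {
  ion_trio <- match.arg(ion_trio)
  trio <- if (ion_trio == "native") diag$native_trio else diag$labelled_trio
  ms2 <- Filter(function(s) s$ms_level == 2L, targeted_run$spectra)
  unconfirmed <- 0L
  for (i in seq_len(nrow(candidates))) {
    if (candidates$status[i] != "provisional") next
    half <- ppm_tol * candidates$mz[i] / 1e6
    sel <- Filter(function(s) abs(s$precursor_mz - candidates$mz[i]) <= half &&
                    abs(s$rt_min - candidates$rt_min[i]) <= rt_window_min, ms2)
    if (!length(sel)) {
      unconfirmed <- unconfirmed + 1L
      next
    }
    matched <- unique(unlist(lapply(sel, function(s)
      diagnostic_ion_match(s, trio, diag$match_tol_ppm)$ion_mz)))
    candidates$n_diagnostic_ions[i] <- length(matched)
    candidates$matched_ions[i] <-
      paste(sprintf("%.4f", sort(matched)), collapse = ";")
    if (length(matched) >= 2L) {
      candidates$status[i] <- "candidate"
    } else {
      candidates$status[i] <- "false_positive"
      candidates$reason[i] <- "lt2_diagnostic_ions"
    }
  }
  if (unconfirmed > 0)
    warning(unconfirmed, " provisional ion(s) had no targeted MS2 acquired; ",
            "left provisional")
  candidates
}

#' Procedural-blank rule for a single feature
#'
#' A feature is kept iff its intensity is at least `ratio` times the mean of
#' the blank replicate intensities; a feature absent from all blanks is kept.
#'
#' @param feature_intensity Feature intensity in the sample.
#' @param blank_intensities Intensities of the same feature in the blank
#'   replicates (NA/0 = absent).
#' @param ratio Required sample/blank ratio (default 3).
#' @param aggregate Aggregation over blank replicates: `"mean"` (default) or
#'   `"max"`.
#' @return `TRUE` (keep) or `FALSE` (drop).
#' @export
blank_filter <- function(feature_intensity, blank_intensities, ratio = 3,
                         aggregate = c("mean", "max")) {
  stopifnot(ratio > 0)
  aggregate <- match.arg(aggregate)
  b <- blank_intensities[!is.na(blank_intensities)]
  if (!length(b) || all(b == 0)) return(TRUE)
  ref <- if (aggregate == "mean") mean(b) else max(b)
  feature_intensity >= ratio * ref
}

#' Apply the blank rule to a candidate table
#'
#' Blank intensities are measured per candidate as the maximum MS1 EIC
#' intensity within `rt_window_min` of the candidate RT in each blank run.
#'
#' @param candidates A candidate table.
#' @param blank_runs List of procedural-blank [acquisition_run()]s.
#' @param filters A [filter_config()] (supplies `blank_ratio` and the ppm
#'   tolerance).
#' @param rt_window_min RT window for the blank EIC, minutes.
#' @return The table with failing rows set to `status = "filtered"`,
#'   `reason = "blank_ratio"`.
#' @export
apply_blank_filter <- function(candidates, blank_runs,
                               filters = filter_config(),
                               rt_window_min = 0.2) {
  for (i in seq_len(nrow(candidates))) {
    if (!candidates$status[i] %in% c("candidate", "provisional")) next
    blank_int <- vapply(blank_runs, function(run) {
      tr <- extract_eic(run, candidates$mz[i], filters$dda_match_tol_ppm,
                        ms_level = 1L)
      sel <- abs(tr$rt_min - candidates$rt_min[i]) <= rt_window_min
      if (any(sel)) max(tr$intensity[sel]) else 0
    }, numeric(1))
    if (!blank_filter(candidates$intensity[i], blank_int,
                      filters$blank_ratio)) {
      candidates$status[i] <- "filtered"
      candidates$reason[i] <- "blank_ratio"
    }
  }
  candidates
}

#' Export the targeted-MS/MS inclusion list
#'
#' One row per surviving (provisional or candidate) ion, ordered by RT, in
#' the vendor-style layout: Mass, Formula, Species ([M-H]-), CS (charge
#' state), Polarity, Start/End RT (apex +/- `rt_pad_min`, clipped at 0).
#'
#' @param candidates A candidate table.
#' @param path Optional CSV output path.
#' @param rt_pad_min Half-width of the RT window, minutes (default 0.5).
#' @return The inclusion-list data.frame (invisibly written to `path` when
#'   given). Zero candidates give a header-only table/file.
#' @export
export_inclusion_list <- function(candidates, path = NULL, rt_pad_min = 0.5) {
  keep <- candidates[candidates$status %in% c("provisional", "candidate"), ,
                     drop = FALSE]
  keep <- keep[order(keep$rt_min), , drop = FALSE]
  out <- data.frame(
    Mass = keep$mz,
    Formula = keep$top_formula,
    Species = rep("[M-H]-", nrow(keep)),
    CS = rep(1L, nrow(keep)),
    Polarity = rep("Negative", nrow(keep)),
    Start = pmax(0, keep$rt_min - rt_pad_min),
    End = keep$rt_min + rt_pad_min,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Tally of filter reasons in a candidate table
#'
#' @param candidates A candidate table.
#' @return A data.frame `reason`/`n`; reasons sum to the number of
#'   non-surviving rows.
#' @export
filter_audit <- function(candidates) {
  dropped <- candidates$reason[!is.na(candidates$reason)]
  as.data.frame(table(reason = dropped), responseName = "n",
                stringsAsFactors = FALSE)
}
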