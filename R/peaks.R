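# Chromatographic peak detection on EIC traces and co-elution grouping of
# diagnostic-ion peaks across DIA collision-energy channels.
#
# The detector is deliberately simple and deterministic: 3-point moving
# average smoothing, local maxima extended to valley bounds, noise estimated
# as the MAD (sigma-scaled) of the trace outside detected peaks with a floor
# of 1 count, S/N = raw apex / noise.

#' Detect chromatographic peaks on an EIC trace
#'
#' @param trace An `eic_trace` (from [extract_eic()] or [tic()]) with at
#'   least 5 points.
#' @param min_intensity Minimum raw apex intensity.
#' @param snr_min Minimum signal-to-noise ratio (chromatographic S/N
#'   threshold; default 3).
#' @return A data.frame with columns `apex_rt_min`, `apex_intensity`, `area`
#'   (trapezoidal, counts*min), `left_rt`, `right_rt`, `snr`, sorted by RT.
#'   Traces shorter than 5 points give an empty table with a warning.
#' @export
detect_peaks <- function(trace, min_intensity = 0, snr_min = 3) {
  empty <- data.frame(apex_rt_min = numeric(0), apex_intensity = numeric(0),
                      area = numeric(0), left_rt = numeric(0),
                      right_rt = numeric(0), snr = numeric(0))
  x <- trace$intensity
  rt <- trace$rt_min
  n <- length(x)
  if (n < 5) {
    warning("trace has fewer than 5 points; no peaks detected")
    return(empty)
  }
  # 3-point moving average; end points keep their raw value
  s <- x
  s[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  # local maxima of the smoothed trace (plateaus: keep the first point)
  is_max <- s > 0 &
    s >= c(Inf, s[-n]) & s > c(s[-1], Inf)
  apexes <- which(is_max)
  if (!length(apexes)) return(empty)
  # extend each apex to valley bounds on the smoothed trace
  bounds <- t(vapply(apexes, function(i) {
    l <- i
    while (l > 1 && s[l - 1] < s[l] && x[l - 1] > 0) l <- l - 1
    if (l > 1 && s[l - 1] <= s[l]) l <- l - 1   # include the valley point
    r <- i
    while (r < n && s[r + 1] < s[r] && x[r + 1] > 0) r <- r + 1
    if (r < n && s[r + 1] <= s[r]) r <- r + 1
    c(l, r)
  }, numeric(2)))
  in_peak <- logical(n)
  for (k in seq_along(apexes)) in_peak[bounds[k, 1]:bounds[k, 2]] <- TRUE
  outside <- x[!in_peak]
  noise <- if (length(outside) >= 3) max(stats::mad(outside), 1) else 1
  # apex re-localized on the raw trace inside the bounds
  peaks <- lapply(seq_along(apexes), function(k) {
    idx <- bounds[k, 1]:bounds[k, 2]
    ai <- idx[which.max(x[idx])]
    area <- if (length(idx) > 1)
      sum(diff(rt[idx]) * (x[idx[-length(idx)]] + x[idx[-1]]) / 2) else 0
    data.frame(apex_rt_min = rt[ai], apex_intensity = x[ai], area = area,
               left_rt = rt[bounds[k, 1]], right_rt = rt[bounds[k, 2]],
               snr = x[ai] / noise)
  })
  out <- do.call(rbind, peaks)
  out <- out[out$apex_intensity > 0 & out$apex_intensity >= min_intensity &
               out$snr >= snr_min, , drop = FALSE]
  # merge duplicate apexes (same raw apex claimed by two smoothed maxima)
  out <- out[!duplicated(out$apex_rt_min), , drop = FALSE]
  out <- out[order(out$apex_rt_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group co-eluting diagnostic-ion peaks across CE channels
#'
#' Single-linkage grouping of peak apexes along retention time: sorted apexes
#' are chained while consecutive gaps are `<= rt_align_tol_min`. The consensus
#' RT of a group is the intensity-weighted mean of member apexes; the number
#' of distinct diagnostic ions represented is counted per group.
#'
#' @param peak_table A data.frame of detected peaks across ions and channels
#'   with columns `ion_mz`, `ce_v`, `apex_rt_min`, `apex_intensity` (extra
#'   columns are carried through to `members`).
#' @param rt_align_tol_min Chaining tolerance in minutes (default 0.1).
#' @return A list with `groups` (data.frame: `group_id`, `consensus_rt_min`,
#'   `n_distinct_diagnostic_ions`, `n_members`, `max_intensity`) and
#'   `members` (the input table with a `group_id` column).
#' @export
align_across_channels <- function(peak_table, rt_align_tol_min = 0.1) {
  stopifnot(all(c("ion_mz", "ce_v", "apex_rt_min", "apex_intensity") %in%
                  names(peak_table)))
  if (nrow(peak_table) == 0) {
    return(list(
      groups = data.frame(group_id = integer(0), consensus_rt_min = numeric(0),
                          n_distinct_diagnostic_ions = integer(0),
                          n_members = integer(0), max_intensity = numeric(0)),
      members = cbind(peak_table, group_id = integer(0))
    ))
  }
  o <- order(peak_table$apex_rt_min)
  tab <- peak_table[o, , drop = FALSE]
  gaps <- diff(tab$apex_rt_min)
  tab$group_id <- cumsum(c(1L, as.integer(gaps > rt_align_tol_min)))
  groups <- do.call(rbind, lapply(split(tab, tab$group_id), function(g) {
    data.frame(
      group_id = g$group_id[1],
      consensus_rt_min = sum(g$apex_rt_min * g$apex_intensity) /
        sum(g$apex_intensity),
      n_distinct_diagnostic_ions = length(unique(g$ion_mz)),
      n_members = nrow(g),
      max_intensity = max(g$apex_intensity)
    )
  }))
  rownames(groups) <- NULL
  list(groups = groups, members = tab)
}
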