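# Acquisition-run model and mzML I/O (via Bioconductor mzR), plus TIC and
# extracted-ion-chromatogram traces. Retention times are minutes end-to-end;
# mzML seconds are converted on read.

#' A single centroided spectrum
#'
#' @param scan_index Ordinal scan number within the run.
#' @param rt_min Retention time, minutes.
#' @param ms_level 1 or 2.
#' @param mz,intensity Centroid arrays (sorted ascending by m/z;
#'   intensities >= 0).
#' @param in_source_ce_v In-source collision energy in volts (DIA channels:
#'   0/20/40; DDA MS1: 0).
#' @param nce Normalized collision energies for MS2 (e.g. `c(15, 35, 50)`).
#' @param precursor_mz Isolated precursor m/z (MS2 only).
#' @param precursor_intensity MS1 intensity of the isolated precursor
#'   (MS2 only).
#' @param isolation_width_mz Isolation window width in m/z (MS2 only).
#' @return A `spectrum_record` object.
#' @export
spectrum_record <- function(scan_index, rt_min, ms_level, mz, intensity,
                            in_source_ce_v = 0, nce = NULL,
                            precursor_mz = NA_real_,
                            precursor_intensity = NA_real_,
                            isolation_width_mz = NA_real_) {
  stopifnot(rt_min >= 0, ms_level %in% c(1L, 2L),
            length(mz) == length(intensity))
  if (length(intensity) && any(intensity < 0))
    stop("centroid intensities must be >= 0")
  if (is.unsorted(mz)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
  }
  if (ms_level == 2L && is.na(precursor_mz))
    stop("MS2 spectra require precursor_mz")
  structure(
    list(scan_index = as.integer(scan_index), rt_min = rt_min,
         ms_level = as.integer(ms_level), mz = as.numeric(mz),
         intensity = as.numeric(intensity), in_source_ce_v = in_source_ce_v,
         nce = nce, precursor_mz = precursor_mz,
         precursor_intensity = precursor_intensity,
         isolation_width_mz = isolation_width_mz, polarity = "negative"),
    class = "spectrum_record"
  )
}

#' An ordered LC-MS acquisition
#'
#' @param spectra A list of [spectrum_record()]s, strictly RT-ordered.
#' @param mode `"DIA_channel"` (full-scan run at one in-source CE; MS1 only)
#'   or `"DDA"` (interleaved MS1 + ddMS2).
#' @param channel_ce_v In-source CE of a DIA channel, volts.
#' @param scan_range `(low, high)` m/z scan range of the MS1 scans.
#' @param metadata Free-form instrument settings (resolution, AGC, IT, ...);
#'   informational only.
#' @return An `acquisition_run` object.
#' @export
acquisition_run <- function(spectra, mode = c("DIA_channel", "DDA"),
                            channel_ce_v = NA_real_,
                            scan_range = c(150, 1000), metadata = list()) {
  mode <- match.arg(mode)
  rts <- vapply(spectra, `[[`, numeric(1), "rt_min")
  if (length(rts) > 1 && any(diff(rts) <= 0))
    stop("spectra must be strictly RT-ordered")
  levels <- vapply(spectra, `[[`, integer(1), "ms_level")
  if (mode == "DIA_channel" && any(levels != 1L))
    stop("DIA channel runs contain only MS1 spectra")
  structure(
    list(spectra = spectra, mode = mode, channel_ce_v = channel_ce_v,
         scan_range = scan_range, metadata = metadata),
    class = "acquisition_run"
  )
}

#' @export
print.acquisition_run <- function(x, ...) {
  lv <- vapply(x$spectra, `[[`, integer(1), "ms_level")
  cat("<acquisition_run> mode=", x$mode,
      if (!is.na(x$channel_ce_v)) paste0(" (CE ", x$channel_ce_v, " V)"),
      ": ", length(x$spectra), " spectra (", sum(lv == 1L), " MS1, ",
      sum(lv == 2L), " MS2), scan range ", x$scan_range[1], "-",
      x$scan_range[2], " m/z\n", sep = "")
  invisible(x)
}

#' Number of spectra in a run
#' @param run An [acquisition_run()].
#' @export
n_spectra <- function(run) length(run$spectra)

#' Read a centroided mzML file
#'
#' Profile-mode spectra are rejected. The acquisition mode is inferred from
#' the presence of MS2 scans unless overridden; the in-source CE of a DIA
#' channel is not representable in plain mzML for MS1 scans, so supply it via
#' `channel_ce_v` (a `_ce<NN>` suffix in the file name, as written by
#' [write_mzml()], is recognized automatically).
#'
#' @param path Path to an mzML file (indexed or plain; gzip accepted).
#' @param mode Override the inferred mode (`"DIA_channel"` or `"DDA"`).
#' @param channel_ce_v In-source CE for a DIA channel run, volts.
#' @return An [acquisition_run()].
#' @export
read_mzml <- function(path, mode = NULL, channel_ce_v = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("malformed mzML '", path, "': ",
                                          conditionMessage(e)))
  on.exit(mzR::close(ms))
  n <- mzR::runInfo(ms)$scanCount
  if (is.null(n) || n == 0) {
    return(acquisition_run(list(),
                           mode = if (is.null(mode)) "DIA_channel" else mode,
                           channel_ce_v = channel_ce_v))
  }
  hdr <- mzR::header(ms)
  pk <- mzR::peaks(ms)
  if (n == 1) pk <- list(pk)
  if (any(!is.na(hdr$centroided) & !hdr$centroided))
    stop("profile-mode spectra are not supported (scan ",
         which(!is.na(hdr$centroided) & !hdr$centroided)[1], "); centroid first")
  spectra <- lapply(seq_len(n), function(i) {
    spectrum_record(
      scan_index = i, rt_min = hdr$retentionTime[i] / 60,
      ms_level = hdr$msLevel[i],
      mz = pk[[i]][, 1], intensity = pk[[i]][, 2],
      in_source_ce_v = 0,
      nce = if (hdr$msLevel[i] == 2L && !is.na(hdr$collisionEnergy[i]))
        hdr$collisionEnergy[i],
      precursor_mz = if (hdr$msLevel[i] == 2L) hdr$precursorMZ[i] else NA_real_,
      precursor_intensity = if (hdr$msLevel[i] == 2L)
        hdr$precursorIntensity[i] else NA_real_,
      isolation_width_mz = if (hdr$msLevel[i] == 2L &&
                               !is.na(hdr$isolationWindowLowerOffset[i]))
        hdr$isolationWindowLowerOffset[i] + hdr$isolationWindowUpperOffset[i]
      else NA_real_
    )
  })
  has_ms2 <- any(hdr$msLevel == 2L)
  if (is.null(mode)) mode <- if (has_ms2) "DDA" else "DIA_channel"
  if (mode == "DIA_channel" && is.na(channel_ce_v)) {
    m <- regmatches(basename(path), regexec("_ce([0-9]+)\\.mzML(\\.gz)?$",
                                            basename(path)))[[1]]
    if (length(m)) channel_ce_v <- as.numeric(m[2])
  }
  if (mode == "DIA_channel" && !is.na(channel_ce_v)) {
    spectra <- lapply(spectra, function(s) {
      s$in_source_ce_v <- channel_ce_v
      s
    })
  }
  sr <- c(min(hdr$scanWindowLowerLimit[hdr$msLevel == 1L], na.rm = TRUE),
          max(hdr$scanWindowUpperLimit[hdr$msLevel == 1L], na.rm = TRUE))
  if (any(!is.finite(sr))) sr <- c(150, 1000)
  acquisition_run(spectra, mode = mode, channel_ce_v = channel_ce_v,
                  scan_range = sr)
}

#' Write a run as mzML 1.1
#'
#' @param run An [acquisition_run()].
#' @param path Output path (`.mzML`). For DIA channels a `_ce<NN>` suffix in
#'   the name lets [read_mzml()] recover the channel CE.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  spectra <- run$spectra
  n <- length(spectra)
  if (n == 0) stop("cannot write an empty run as mzML")
  pks <- lapply(spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
  num <- function(fld, default = NA_real_) {
    vapply(spectra, function(s) {
      v <- s[[fld]]
      if (is.null(v) || !length(v)) default else mean(v)
    }, numeric(1))
  }
  lv <- vapply(spectra, `[[`, integer(1), "ms_level")
  npk <- vapply(pks, nrow, integer(1))
  tot <- vapply(spectra, function(s) sum(s$intensity), numeric(1))
  bp <- vapply(spectra, function(s) {
    if (!length(s$mz)) c(0, 0) else {
      i <- which.max(s$intensity)
      c(s$mz[i], s$intensity[i])
    }
  }, numeric(2))
  iso_half <- ifelse(lv == 2L, num("isolation_width_mz") / 2, NA_real_)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lv,
    polarity = 0L, peaksCount = npk, totIonCurrent = tot,
    retentionTime = vapply(spectra, `[[`, numeric(1), "rt_min") * 60,
    basePeakMZ = bp[1, ], basePeakIntensity = bp[2, ],
    collisionEnergy = ifelse(lv == 2L, num("nce"), num("in_source_ce_v", 0)),
    ionisationEnergy = 0,
    lowMZ = vapply(pks, function(p) if (nrow(p)) min(p[, 1]) else 0, numeric(1)),
    highMZ = vapply(pks, function(p) if (nrow(p)) max(p[, 1]) else 0, numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = ifelse(lv == 2L, num("precursor_mz"), 0),
    precursorCharge = ifelse(lv == 2L, 1L, 0L),
    precursorIntensity = ifelse(lv == 2L, num("precursor_intensity"), 0),
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(lv == 2L, num("precursor_mz"), NA_real_),
    isolationWindowLowerOffset = iso_half,
    isolationWindowUpperOffset = iso_half,
    scanWindowLowerLimit = run$scan_range[1],
    scanWindowUpperLimit = run$scan_range[2],
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

.eic_trace <- function(rt_min, intensity, target_mz = NA_real_,
                       tol_ppm = NA_real_, ms_level = 1L) {
  structure(
    list(target_mz = target_mz, tol_ppm = tol_ppm, ms_level = ms_level,
         rt_min = rt_min, intensity = intensity),
    class = "eic_trace"
  )
}

#' @export
print.eic_trace <- function(x, ...) {
  lbl <- if (is.na(x$target_mz)) "TIC" else
    sprintf("EIC m/z %.4f (+/- %g ppm, MS%d)", x$target_mz, x$tol_ppm,
            x$ms_level)
  cat("<eic_trace> ", lbl, ": ", length(x$rt_min), " points, max intensity ",
      format(if (length(x$intensity)) max(x$intensity) else 0), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.eic_trace <- function(x, ...) {
  data.frame(rt_min = x$rt_min, intensity = x$intensity)
}

#' Total ion chromatogram
#'
#' Per-MS1-spectrum sum of all centroid intensities.
#'
#' @param run An [acquisition_run()].
#' @return An `eic_trace` (with `target_mz = NA`).
#' @export
tic <- function(run) {
  ms1 <- Filter(function(s) s$ms_level == 1L, run$spectra)
  .eic_trace(
    rt_min = vapply(ms1, `[[`, numeric(1), "rt_min"),
    intensity = vapply(ms1, function(s) sum(s$intensity), numeric(1))
  )
}

#' Extracted ion chromatogram
#'
#' Per-spectrum sum of centroid intensities within a closed ppm window
#' `|mz - target| <= tol_ppm * target / 1e6`; multiple centroids inside the
#' window in one spectrum are summed. For `ms_level = 2` only MS2 scans
#' contribute (the "EIC MS/MS" of DDA data).
#'
#' @param run An [acquisition_run()].
#' @param target_mz Target m/z.
#' @param tol_ppm Window half-width in ppm.
#' @param ms_level MS level to extract from (1 or 2).
#' @return An `eic_trace`.
#' @export
extract_eic <- function(run, target_mz, tol_ppm = 5, ms_level = 1L) {
  sp <- Filter(function(s) s$ms_level == ms_level, run$spectra)
  if (ms_level == 1L && length(run$scan_range) == 2 &&
      (target_mz < run$scan_range[1] || target_mz > run$scan_range[2]))
    warning(sprintf("target m/z %.4f outside scan range [%g, %g]; trace is zero",
                    target_mz, run$scan_range[1], run$scan_range[2]))
  half <- tol_ppm * target_mz / 1e6
  lo <- target_mz - half
  hi <- target_mz + half
  ints <- vapply(sp, function(s) {
    i1 <- findInterval(lo, s$mz, left.open = TRUE) + 1
    i2 <- findInterval(hi, s$mz)
    if (i2 < i1) 0 else sum(s$intensity[i1:i2])
  }, numeric(1))
  .eic_trace(rt_min = vapply(sp, `[[`, numeric(1), "rt_min"),
             intensity = ints, target_mz = target_mz, tol_ppm = tol_ppm,
             ms_level = as.integer(ms_level))
}

#' Export a trace as a two-column CSV
#' @param trace An `eic_trace`.
#' @param path Output CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
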