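# Deterministic Q-Exactive-style acquisition simulator: DIA in-source CE
# channels and TopN ddMS2 DDA runs of a configurable monophthalate panel
# with isotope-labelled standards, single-diagnostic-ion decoys, procedural
# blanks and a sparse noise floor. Provides ground truth for every other
# module. All randomness flows from the config seed.

.mass_co2 <- 43.98982923912

#' Define one simulated analyte
#'
#' @param name Compound name.
#' @param formula Neutral formula string (CHO, without the 13C substitutions
#'   — give those via `n_carbon13`).
#' @param rt_min Elution apex, minutes.
#' @param apex_intensity MS1 apex intensity, counts.
#' @param sigma_min Gaussian peak width (sigma), minutes.
#' @param labelled Isotope-labelled internal standard?
#' @param n_carbon13 Number of 13C substitutions (labelled standards).
#' @param is_decoy Decoy interferent emitting exactly one native diagnostic
#'   ion.
#' @param pure_alkyl Pure-alkyl-chain monophthalate (adds the supplementary
#'   m/z 134.0377 fragment channel).
#' @param frag_mz,frag_rel Fragmentation template: fragment m/z values and
#'   relative intensities in `[0, 1]` summing to 1 (defaults are built from
#'   the class flags; labelled analytes fragment into the labelled trio).
#' @return A one-row data.frame (list columns for the template) that can be
#'   `rbind`ed into a panel.
#' @export
simulated_analyte <- function(name, formula, rt_min, apex_intensity,
                              sigma_min = 0.05, labelled = FALSE,
                              n_carbon13 = 0L, is_decoy = FALSE,
                              pure_alkyl = FALSE,
                              frag_mz = NULL, frag_rel = NULL) {
  fo <- parse_formula(formula)
  ion <- formula_cho(fo$n_carbon, fo$n_hydrogen - 1L, fo$n_oxygen,
                     as.integer(n_carbon13))
  mz <- anion_mz(ion)
  diag <- diagnostic_ion_set()
  if (is.null(frag_mz)) {
    if (is_decoy) {
      stop("decoys must specify frag_mz/frag_rel explicitly ",
           "(exactly one native-trio ion)")
    } else if (labelled) {
      frag_mz <- c(diag$labelled_trio, mz - .mass_co2)
      frag_rel <- c(0.45, 0.25, 0.15, 0.15)
    } else if (pure_alkyl) {
      frag_mz <- c(diag$native_trio, diag$supplementary, mz - .mass_co2)
      frag_rel <- c(0.40, 0.22, 0.13, 0.10, 0.15)
    } else {
      frag_mz <- c(diag$native_trio, mz - .mass_co2)
      frag_rel <- c(0.45, 0.25, 0.15, 0.15)
    }
  }
  stopifnot(length(frag_mz) == length(frag_rel),
            all(frag_rel >= 0), all(frag_rel <= 1))
  if (abs(sum(frag_rel) - 1) > 1e-9)
    stop("fragmentation template must sum to 1")
  if (is_decoy) {
    half <- 5 * diag$native_trio / 1e6
    n_trio <- sum(vapply(diag$native_trio, function(d)
      any(abs(frag_mz - d) <= 5 * d / 1e6 & frag_rel > 0), logical(1)))
    if (n_trio != 1L)
      stop("decoys must emit exactly one native-trio diagnostic ion")
  }
  out <- data.frame(name = name, formula = formula, mz = mz,
                    rt_min = rt_min, sigma_min = sigma_min,
                    apex_intensity = apex_intensity, labelled = labelled,
                    n_carbon13 = as.integer(n_carbon13),
                    is_decoy = is_decoy, pure_alkyl = pure_alkyl,
                    stringsAsFactors = FALSE)
  out$frag_mz <- list(frag_mz)
  out$frag_rel <- list(frag_rel)
  out
}

#' The default simulated monophthalate panel
#'
#' 10 native monophthalates (pure-alkyl and oxidized chains; monoethyl
#' phthalate sits at the 6.78 min standard RT), 5 decoy interferents that
#' emit exactly one native diagnostic ion each, and 14 ring-13C4 labelled
#' internal standards. All apexes are above both the 5e5-count prioritization
#' threshold and the 2e5-count DDA trigger.
#'
#' @return A panel data.frame (one row per analyte).
#' @export
default_panel <- function() {
  d121 <- 121.0295
  d147 <- 147.0088
  d165 <- 165.0193
  native <- rbind(
    simulated_analyte("mono-methyl phthalate", "C9H8O4", 5.88, 2.0e6,
                      pure_alkyl = TRUE),
    simulated_analyte("mono-ethyl phthalate", "C10H10O4", 6.78, 5.0e7,
                      pure_alkyl = TRUE),
    simulated_analyte("mono-n-butyl phthalate", "C12H14O4", 8.58, 3.0e7,
                      pure_alkyl = TRUE),
    simulated_analyte("mono-benzyl phthalate", "C15H12O4", 10.55, 1.5e7),
    simulated_analyte("mono-5-hydroxyhexyl phthalate", "C14H18O5", 8.20,
                      2.5e7),
    simulated_analyte("mono-5-oxohexyl phthalate", "C14H16O5", 9.40, 1.2e7),
    simulated_analyte("mono-2-ethyl-5-hydroxyhexyl phthalate", "C16H22O5",
                      11.05, 4.0e7),
    simulated_analyte("mono-2-ethyl-5-oxohexyl phthalate", "C16H20O5",
                      12.00, 3.0e7),
    simulated_analyte("mono-2-ethylhexyl phthalate", "C16H22O4", 12.55,
                      2.0e7, pure_alkyl = TRUE),
    simulated_analyte("mono-3-carboxypropyl phthalate", "C12H12O6", 5.00,
                      8.0e5)
  )
  decoy <- function(name, formula, rt, apex, ion) {
    mz <- anion_mz(with(parse_formula(formula),
                        formula_cho(n_carbon, n_hydrogen - 1L, n_oxygen)))
    simulated_analyte(name, formula, rt, apex, is_decoy = TRUE,
                      frag_mz = c(ion, mz - 46.00547930),
                      frag_rel = c(0.6, 0.4))
  }
  decoys <- rbind(
    decoy("decoy interferent 1", "C13H16O4", 7.30, 3.0e6, d121),
    decoy("decoy interferent 2", "C11H12O5", 9.00, 2.0e6, d147),
    decoy("decoy interferent 3", "C15H20O4", 10.10, 5.0e6, d165),
    decoy("decoy interferent 4", "C10H10O6", 6.20, 1.0e6, d121),
    decoy("decoy interferent 5", "C14H16O5", 11.50, 1.5e6, d147)
  )
  lab <- function(name, formula, rt) {
    simulated_analyte(paste0("[13C4]-", name), formula, rt, 2.0e6,
                      labelled = TRUE, n_carbon13 = 4L)
  }
  labelled <- rbind(
    lab("mono-methyl phthalate", "C9H8O4", 5.88),
    lab("mono-ethyl phthalate", "C10H10O4", 6.78),
    lab("mono-n-propyl phthalate", "C11H12O4", 7.68),
    lab("mono-n-butyl phthalate", "C12H14O4", 8.58),
    lab("mono-n-pentyl phthalate", "C13H16O4", 9.48),
    lab("mono-n-hexyl phthalate", "C14H18O4", 10.38),
    lab("mono-n-heptyl phthalate", "C15H20O4", 11.28),
    lab("mono-n-octyl phthalate", "C16H22O4", 12.40),
    lab("mono-benzyl phthalate", "C15H12O4", 10.55),
    lab("mono-cyclohexyl phthalate", "C14H16O4", 9.90),
    lab("mono-2-ethylhexyl phthalate", "C16H22O4", 12.55),
    lab("mono-isononyl phthalate", "C17H24O4", 13.50),
    lab("mono-2-ethyl-5-carboxypentyl phthalate", "C16H20O6", 9.70),
    lab("mono-5-carboxypentyl phthalate", "C14H16O6", 8.60)
  )
  rbind(native, decoys, labelled)
}

#' Simulation configuration
#'
#' Defaults mirror the acquisition settings of the emulated instrument
#' method: DIA as full-scan runs at in-source CE 0/20/40 V (scan range
#' 150-1000 m/z at CE 0, 50-500 in the fragment channels); DDA as TopN-5
#' ddMS2 with a 2e5-count trigger, 3.0 s dynamic exclusion, 1.5 m/z
#' isolation and NCE 15/35/50 (MS1 range 150-800). The fraction of each
#' analyte fragmented in a DIA channel is CE/40, saturating at 40 V.
#'
#' @param panel Analyte panel ([default_panel()]).
#' @param run_length_min Run length, minutes.
#' @param scan_interval_s Full-scan (cycle) interval, seconds.
#' @param noise_floor Sparse-noise centroid intensity scale, counts.
#' @param noise_peaks_per_scan Number of random noise centroids per scan.
#' @param n_interferents Number of random non-fragmenting matrix features.
#' @param blank_contamination_fraction Per-analyte carryover fraction into
#'   procedural blanks (must stay below 1/blank_ratio for the 3x rule to
#'   remove it).
#' @param replicate_cv Log-normal coefficient of variation across replicate
#'   injections.
#' @param replicates Replicates per group and per blank.
#' @param fold_changes Named vector of group-B/group-A intensity folds
#'   planted on native analytes.
#' @param seed Mandatory RNG seed; identical config + seed gives identical
#'   output.
#' @param dda,dia Acquisition sub-settings (see Details above).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(panel = default_panel(),
                              run_length_min = 16,
                              scan_interval_s = 2,
                              noise_floor = 1e3,
                              noise_peaks_per_scan = 15,
                              n_interferents = 8,
                              blank_contamination_fraction = 0.05,
                              replicate_cv = 0.05,
                              replicates = 3,
                              fold_changes = c(
                                "mono-ethyl phthalate" = 25,
                                "mono-n-butyl phthalate" = 2.5,
                                "mono-2-ethyl-5-hydroxyhexyl phthalate" = 2.5,
                                "mono-2-ethylhexyl phthalate" = 2.5),
                              seed = 20221108,
                              dda = list(top_n = 5, trigger_threshold = 2e5,
                                         dynamic_exclusion_s = 3.0,
                                         isolation_width_mz = 1.5,
                                         nce_levels = c(15, 35, 50),
                                         scan_range_ms1 = c(150, 800),
                                         scan_range_ms2 = c(50, 500)),
                              dia = list(ce_levels_v = c(0, 20, 40),
                                         scan_range_ce0 = c(150, 1000),
                                         scan_range_frag = c(50, 500))) {
  stopifnot(!is.null(seed), dda$top_n >= 1, dda$dynamic_exclusion_s >= 0,
            scan_interval_s > 0, run_length_min > 0)
  structure(
    list(panel = panel, run_length_min = run_length_min,
         scan_interval_s = scan_interval_s, noise_floor = noise_floor,
         noise_peaks_per_scan = noise_peaks_per_scan,
         n_interferents = n_interferents,
         blank_contamination_fraction = blank_contamination_fraction,
         replicate_cv = replicate_cv, replicates = replicates,
         fold_changes = fold_changes, seed = as.integer(seed),
         dda = dda, dia = dia),
    class = "simulation_config"
  )
}

.scan_rts <- function(config) {
  seq(0, config$run_length_min, by = config$scan_interval_s / 60)
}

# analyte x scan matrix of Gaussian elution intensities (values < 1 count
# truncated to 0 to keep spectra sparse)
.elution_matrix <- function(panel, rts) {
  m <- vapply(seq_along(rts), function(si) {
    v <- panel$apex_intensity *
      exp(-(rts[si] - panel$rt_min)^2 / (2 * panel$sigma_min^2))
    v[v < 1] <- 0
    v
  }, numeric(nrow(panel)))
  if (nrow(panel) == 1) m <- matrix(m, nrow = 1)
  m
}

# random matrix interferents; drawn from a private RNG stream so they are
# identical across channels/replicate runs of the same config
.make_interferents <- function(config) {
  if (config$n_interferents == 0)
    return(data.frame(mz = numeric(0), rt_min = numeric(0),
                      apex_intensity = numeric(0), sigma_min = numeric(0)))
  rs <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv()))
  set.seed(config$seed + 7L)
  n <- config$n_interferents
  data.frame(
    mz = stats::runif(n, 160, 480),
    rt_min = stats::runif(n, 1, config$run_length_min - 1),
    apex_intensity = stats::runif(n, 2e4, 3e5),
    sigma_min = rep(0.05, n)
  )
}

.noise_centroids <- function(config, range) {
  n <- config$noise_peaks_per_scan
  if (n == 0) return(list(mz = numeric(0), intensity = numeric(0)))
  list(mz = stats::runif(n, range[1], range[2]),
       intensity = config$noise_floor * stats::runif(n, 0.5, 2))
}

.assemble_spectrum <- function(scan_index, rt, mz, intensity, range,
                               ce_v = 0, ...) {
  keep <- mz >= range[1] & mz <= range[2] & intensity > 0
  spectrum_record(scan_index, rt, 1L, mz[keep], intensity[keep],
                  in_source_ce_v = ce_v, ...)
}

#' Simulate the DIA channel set
#'
#' One full-scan run per in-source CE level. At CE = 0 every analyte appears
#' as its intact [M-H]- Gaussian elution profile; at CE > 0 a fraction
#' CE/40 (saturating at 1) of each analyte's intensity is redistributed over
#' its fragmentation template (fragments clipped to the fragment scan
#' range), the remainder staying on the precursor. Matrix interferents do
#' not fragment; sparse noise is added everywhere. Intact + fragment
#' intensities conserve the CE = 0 intensity exactly (before noise).
#'
#' @param config A [simulation_config()].
#' @return A named list of [acquisition_run()]s (`"ce0"`, `"ce20"`, ...).
#' @export
simulate_dia <- function(config) {
  rts <- .scan_rts(config)
  interf <- .make_interferents(config)
  panel <- config$panel
  out_of_range <- panel$mz < config$dia$scan_range_ce0[1] |
    panel$mz > config$dia$scan_range_ce0[2]
  if (any(out_of_range))
    warning("analyte(s) outside the CE=0 scan range skipped: ",
            paste(panel$name[out_of_range], collapse = ", "))
  panel <- panel[!out_of_range, , drop = FALSE]
  elu <- .elution_matrix(panel, rts)
  elu_int <- if (nrow(interf)) .elution_matrix(
    data.frame(apex_intensity = interf$apex_intensity, rt_min = interf$rt_min,
               sigma_min = interf$sigma_min), rts) else
                 matrix(0, 0, length(rts))
  runs <- list()
  for (k in seq_along(config$dia$ce_levels_v)) {
    ce <- config$dia$ce_levels_v[k]
    range <- if (ce == 0) config$dia$scan_range_ce0 else
      config$dia$scan_range_frag
    frac <- min(ce / 40, 1)
    set.seed(config$seed + k)
    spectra <- vector("list", length(rts))
    for (si in seq_along(rts)) {
      mzv <- numeric(0)
      iv <- numeric(0)
      act <- which(elu[, si] > 0)
      for (a in act) {
        I <- elu[a, si]
        if (frac > 0) {
          fm <- panel$frag_mz[[a]]
          fr <- panel$frag_rel[[a]]
          mzv <- c(mzv, panel$mz[a], fm)
          iv <- c(iv, (1 - frac) * I, frac * I * fr)
        } else {
          mzv <- c(mzv, panel$mz[a])
          iv <- c(iv, I)
        }
      }
      ia <- which(elu_int[, si] > 0)
      if (length(ia)) {
        mzv <- c(mzv, interf$mz[ia])
        iv <- c(iv, elu_int[ia, si])
      }
      nz <- .noise_centroids(config, range)
      spectra[[si]] <- .assemble_spectrum(si, rts[si], c(mzv, nz$mz),
                                          c(iv, nz$intensity), range,
                                          ce_v = ce)
    }
    runs[[paste0("ce", ce)]] <- acquisition_run(
      spectra, mode = "DIA_channel", channel_ce_v = ce, scan_range = range,
      metadata = list(resolution = if (ce == 0) 7e4 else 3.5e4,
                      agc_target = 5e5)
    )
  }
  runs
}

#' Simulate a TopN ddMS2 (DDA) run
#'
#' MS1 full scans every `scan_interval_s`; after each, up to `top_n` MS2
#' scans on the most intense MS1 centroids above `trigger_threshold` that
#' are not dynamically excluded (and, for a targeted re-run, that match the
#' inclusion list). An isolated precursor's MS2 spectrum is the summed
#' fragmentation template of every panel analyte inside the isolation
#' window, averaged over the NCE levels. Selected precursors are excluded
#' for `dynamic_exclusion_s`. The selection event log is attached as
#' `attr(run, "event_log")`.
#'
#' @param config A [simulation_config()].
#' @param inclusion_mz Optional numeric vector of precursor m/z values: when
#'   given, only matching precursors (5 ppm) are selected (the targeted
#'   MS/MS re-run driven by an inclusion list).
#' @return A DDA [acquisition_run()] with interleaved MS1/MS2 scans.
#' @export
simulate_dda <- function(config, inclusion_mz = NULL) {
  rts <- .scan_rts(config)
  interf <- .make_interferents(config)
  panel <- config$panel
  elu <- .elution_matrix(panel, rts)
  elu_int <- if (nrow(interf)) .elution_matrix(
    data.frame(apex_intensity = interf$apex_intensity, rt_min = interf$rt_min,
               sigma_min = interf$sigma_min), rts) else
                 matrix(0, 0, length(rts))
  set.seed(config$seed + 101L)
  iso_half <- config$dda$isolation_width_mz / 2
  excl_s <- config$dda$dynamic_exclusion_s
  spectra <- list()
  log_rows <- list()
  exc_mz <- numeric(0)
  exc_until <- numeric(0)
  scan_i <- 0L
  for (si in seq_along(rts)) {
    t <- rts[si]
    act <- which(elu[, si] > 0)
    ia <- which(elu_int[, si] > 0)
    mzv <- c(panel$mz[act], interf$mz[ia])
    iv <- c(elu[act, si], elu_int[ia, si])
    nz <- .noise_centroids(config, config$dda$scan_range_ms1)
    scan_i <- scan_i + 1L
    spectra[[length(spectra) + 1]] <-
      .assemble_spectrum(scan_i, t, c(mzv, nz$mz), c(iv, nz$intensity),
                         config$dda$scan_range_ms1, ce_v = 0)
    # precursor selection on the analyte/interferent centroids; species
    # closer than the mass accuracy are one observed peak, so merge them
    if (length(mzv) > 1) {
      o <- order(mzv)
      mzs <- mzv[o]
      ivs <- iv[o]
      pg <- cumsum(c(1L, as.integer(diff(mzs) > 5 * mzs[-length(mzs)] / 1e6)))
      mzv <- vapply(split(seq_along(mzs), pg), function(ii)
        mzs[ii][which.max(ivs[ii])], numeric(1))
      iv <- vapply(split(ivs, pg), sum, numeric(1))
    }
    eligible <- which(iv >= config$dda$trigger_threshold &
                        mzv >= config$dda$scan_range_ms1[1] &
                        mzv <= config$dda$scan_range_ms1[2])
    if (length(exc_mz)) {
      live <- exc_until > t
      exc_mz <- exc_mz[live]
      exc_until <- exc_until[live]
    }
    if (length(eligible) && length(exc_mz)) {
      blocked <- vapply(eligible, function(j)
        any(abs(mzv[j] - exc_mz) <= 5 * mzv[j] / 1e6), logical(1))
      eligible <- eligible[!blocked]
    }
    if (length(eligible) && !is.null(inclusion_mz)) {
      on_list <- vapply(eligible, function(j)
        any(abs(mzv[j] - inclusion_mz) <= 5 * mzv[j] / 1e6), logical(1))
      eligible <- eligible[on_list]
    }
    if (!length(eligible)) next
    sel <- eligible[order(iv[eligible], decreasing = TRUE)]
    sel <- sel[seq_len(min(config$dda$top_n, length(sel)))]
    for (k in seq_along(sel)) {
      j <- sel[k]
      p <- mzv[j]
      ms2_rt <- t + k * (config$scan_interval_s / 60) /
        (config$dda$top_n + 1)
      co <- which(abs(panel$mz - p) <= iso_half & elu[, si] > 0)
      fmz <- unlist(lapply(co, function(a) panel$frag_mz[[a]]))
      fiv <- unlist(lapply(co, function(a)
        panel$frag_rel[[a]] * elu[a, si]))
      if (is.null(fmz)) {
        fmz <- numeric(0)
        fiv <- numeric(0)
      }
      nz2 <- .noise_centroids(config, config$dda$scan_range_ms2)
      fmz <- c(fmz, nz2$mz)
      fiv <- c(fiv, 0.1 * nz2$intensity)
      keep <- fmz >= config$dda$scan_range_ms2[1] &
        fmz <= config$dda$scan_range_ms2[2] & fiv > 0
      scan_i <- scan_i + 1L
      spectra[[length(spectra) + 1]] <- spectrum_record(
        scan_i, ms2_rt, 2L, fmz[keep], fiv[keep],
        nce = config$dda$nce_levels, precursor_mz = p,
        precursor_intensity = iv[j],
        isolation_width_mz = config$dda$isolation_width_mz
      )
      exc_mz <- c(exc_mz, p)
      exc_until <- c(exc_until, t + excl_s / 60)
      log_rows[[length(log_rows) + 1]] <- data.frame(
        cycle = si, rt_min = t, precursor_mz = p, ms1_intensity = iv[j],
        excluded_until_min = t + excl_s / 60
      )
    }
  }
  run <- acquisition_run(spectra, mode = "DDA",
                         scan_range = config$dda$scan_range_ms1,
                         metadata = list(resolution_ms1 = 7e4,
                                         resolution_ms2 = 1.75e4,
                                         top_n = config$dda$top_n))
  attr(run, "event_log") <- if (length(log_rows)) do.call(rbind, log_rows)
  else data.frame(cycle = integer(0), rt_min = numeric(0),
                  precursor_mz = numeric(0), ms1_intensity = numeric(0),
                  excluded_until_min = numeric(0))
  run
}

# scale panel apexes by a per-analyte multiplier vector
.scale_panel <- function(panel, mult) {
  panel$apex_intensity <- panel$apex_intensity * mult
  panel
}

#' Generate the replicate study fixture
#'
#' Builds the full replicate structure around one panel: three group-A
#' ("fertile") and three group-B ("infertile") DDA runs with the configured
#' fold changes planted on group B, three procedural blanks (per-analyte
#' carryover at `blank_contamination_fraction`, no labelled standards),
#' one pooled spiked-QC DDA run, and a DIA channel set of the pooled QC
#' sample. Labelled standards are spiked into all non-blank runs. Replicate
#' variation is log-normal at `replicate_cv`. Ground-truth tables (analytes,
#' true per-replicate intensities, expected differential labels) accompany
#' the runs.
#'
#' The targeted MS/MS follow-up of DIA prioritization is generated on demand
#' with `simulate_dda(fixture$sample_configs$qc_spiked, inclusion_mz = ...)`
#' because its inclusion list is an output of the screen.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory: runs are written as mzML and the truth
#'   tables as CSV.
#' @return A list: `dda_runs` (named list incl. blanks and QC), `dia_runs`
#'   (CE channel set of the QC sample), `blank_runs`, `sample_configs`
#'   (per-sample [simulation_config()]s), `truth` (list of data.frames
#'   `analytes`, `intensities`, `differential`), `config`.
#' @export
make_study_fixture <- function(config = simulation_config(), out_dir = NULL) {
  set.seed(config$seed)
  panel <- config$panel
  n <- nrow(panel)
  sdlog <- sqrt(log(1 + config$replicate_cv^2))
  groups <- c(rep("fertile", config$replicates),
              rep("infertile", config$replicates))
  sample_ids <- c(paste0("fertile_", seq_len(config$replicates)),
                  paste0("infertile_", seq_len(config$replicates)))
  fold_vec <- rep(1, n)
  names(fold_vec) <- panel$name
  planted <- intersect(names(config$fold_changes), panel$name)
  fold_vec[planted] <- config$fold_changes[planted]
  # per-sample true intensity multipliers (replicate noise x group fold)
  mult <- matrix(stats::rlnorm(n * length(sample_ids),
                               meanlog = -sdlog^2 / 2, sdlog = sdlog),
                 nrow = n)
  for (j in which(groups == "infertile")) mult[, j] <- mult[, j] * fold_vec
  qc_mult <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  colnames(mult) <- sample_ids
  sample_configs <- list()
  for (j in seq_along(sample_ids)) {
    cfg <- config
    cfg$panel <- .scale_panel(panel, mult[, j])
    cfg$seed <- config$seed + 37L * j
    sample_configs[[sample_ids[j]]] <- cfg
  }
  qc_cfg <- config
  qc_cfg$panel <- .scale_panel(panel, qc_mult)
  qc_cfg$seed <- config$seed + 37L * (length(sample_ids) + 1L)
  sample_configs[["qc_spiked"]] <- qc_cfg
  blank_ids <- paste0("blank_", seq_len(config$replicates))
  for (r in seq_along(blank_ids)) {
    cfg <- config
    bp <- panel[!panel$labelled, , drop = FALSE]
    bmult <- stats::rlnorm(nrow(bp), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    cfg$panel <- .scale_panel(bp, config$blank_contamination_fraction * bmult)
    cfg$seed <- config$seed + 37L * (length(sample_ids) + 1L + r)
    sample_configs[[blank_ids[r]]] <- cfg
  }
  dda_runs <- lapply(sample_configs, simulate_dda)
  dia_runs <- simulate_dia(qc_cfg)
  truth_analytes <- data.frame(
    name = panel$name, formula = panel$formula, mz = panel$mz,
    rt_min = panel$rt_min, apex_intensity = panel$apex_intensity,
    labelled = panel$labelled, is_decoy = panel$is_decoy,
    pure_alkyl = panel$pure_alkyl, fold_change = unname(fold_vec),
    stringsAsFactors = FALSE
  )
  truth_intensities <- data.frame(
    name = panel$name, panel$apex_intensity * mult,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  truth_diff <- data.frame(
    name = panel$name[!panel$labelled & !panel$is_decoy],
    fold_change = unname(fold_vec[!panel$labelled & !panel$is_decoy]),
    stringsAsFactors = FALSE
  )
  truth_diff$label <- ifelse(truth_diff$fold_change > 2, "up", "unchanged")
  fixture <- list(
    dda_runs = dda_runs, dia_runs = dia_runs,
    blank_runs = dda_runs[blank_ids],
    sample_ids = sample_ids, groups = groups,
    sample_configs = sample_configs,
    truth = list(analytes = truth_analytes, intensities = truth_intensities,
                 differential = truth_diff),
    config = config
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(dda_runs))
      write_mzml(dda_runs[[id]], file.path(out_dir,
                                           paste0("dda_", id, ".mzML")))
    for (ch in names(dia_runs))
      write_mzml(dia_runs[[ch]], file.path(out_dir,
                                           paste0("dia_qc_", ch, ".mzML")))
    utils::write.csv(truth_analytes,
                     file.path(out_dir, "truth_analytes.csv"),
                     row.names = FALSE)
    utils::write.csv(truth_intensities,
                     file.path(out_dir, "truth_intensities.csv"),
                     row.names = FALSE)
    utils::write.csv(truth_diff,
                     file.path(out_dir, "truth_differential.csv"),
                     row.names = FALSE)
  }
  fixture
}

#' Simulate a replicate feature matrix (no chromatography)
#'
#' Log-normal replicate intensities around per-feature base means, with a
#' configurable true fold change between two groups — the matrix-level Monte
#' Carlo used to calibrate the differential test (type-I error, fold
#' recovery) independently of the acquisition simulators.
#'
#' @param n_features Number of features.
#' @param fold True group-B/group-A fold change (scalar or per-feature).
#' @param n_per_group Replicates per group.
#' @param cv Log-normal coefficient of variation.
#' @param seed RNG seed.
#' @return A list: `intensities` (matrix), `groups`, `true_fold`.
#' @export
simulate_feature_matrix <- function(n_features = 2000, fold = 1,
                                    n_per_group = 3, cv = 0.05,
                                    seed = 20221108) {
  set.seed(seed)
  fold <- rep_len(fold, n_features)
  sdlog <- sqrt(log(1 + cv^2))
  base <- stats::rlnorm(n_features, meanlog = log(1e6), sdlog = 1)
  a <- matrix(stats::rlnorm(n_features * n_per_group, sdlog = sdlog),
              ncol = n_per_group) * base
  b <- matrix(stats::rlnorm(n_features * n_per_group, sdlog = sdlog),
              ncol = n_per_group) * base * fold
  intens <- cbind(a, b)
  colnames(intens) <- c(paste0("a_", seq_len(n_per_group)),
                        paste0("b_", seq_len(n_per_group)))
  list(intensities = intens,
       groups = rep(c("a", "b"), each = n_per_group),
       true_fold = fold)
}
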