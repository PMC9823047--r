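# Shared test fixtures, built in code. The default study fixture is cached
# per test session (it is deterministic given its seed).

.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$fx))
    .fixture_cache$fx <- make_study_fixture(simulation_config())
  .fixture_cache$fx
}

# a short two-analyte configuration for fast simulator tests
small_config <- function(panel = NULL, n_interferents = 2, ...) {
  if (is.null(panel))
    panel <- rbind(
      simulated_analyte("mono-ethyl phthalate", "C10H10O4", 1.5, 2e6,
                        pure_alkyl = TRUE),
      simulated_analyte("mono-n-butyl phthalate", "C12H14O4", 2.5, 1e6)
    )
  simulation_config(panel = panel, run_length_min = 4,
                    n_interferents = n_interferents, ...)
}

# an MS2 spectrum with the given fragment m/z values
ms2_spectrum <- function(frag_mz, frag_int = NULL, precursor_mz = 277.1445,
                        rt_min = 1, scan_index = 1) {
  if (is.null(frag_int)) frag_int <- rep(1e5, length(frag_mz))
  spectrum_record(scan_index, rt_min, 2L, frag_mz, frag_int,
                  precursor_mz = precursor_mz, precursor_intensity = 1e6,
                  isolation_width_mz = 1.5)
}

# an EIC-shaped trace from explicit vectors
make_trace <- function(rt_min, intensity, target_mz = 121.0295) {
  structure(list(target_mz = target_mz, tol_ppm = 5, ms_level = 1L,
                 rt_min = rt_min, intensity = intensity),
            class = "eic_trace")
}

# gaussian elution profile on a regular RT grid
gaussian_trace <- function(apex, rt0, sigma = 0.05, from = 0, to = 4,
                           by = 1 / 30, baseline = 0) {
  rt <- seq(from, to, by = by)
  make_trace(rt, apex * exp(-(rt - rt0)^2 / (2 * sigma^2)) + baseline)
}

# native-panel subset of the fixture truth table
native_truth <- function(fx) {
  tr <- fx$truth$analytes
  tr[!tr$labelled & !tr$is_decoy, , drop = FALSE]
}

# which rows of a candidate table match a truth analyte (5 ppm, 0.2 min)
matches_truth <- function(cand, truth_row) {
  any(abs(cand$mz - truth_row$mz) / truth_row$mz * 1e6 <= 5 &
        abs(cand$rt_min - truth_row$rt_min) <= 0.2)
}
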