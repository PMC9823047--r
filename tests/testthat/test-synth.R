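test_that("simulation is deterministic given config and seed", {
  cfg <- small_config(seed = 21)
  a <- simulate_dda(cfg)
  b <- simulate_dda(cfg)
  expect_identical(lapply(a$spectra, `[[`, "mz"),
                   lapply(b$spectra, `[[`, "mz"))
  expect_identical(lapply(a$spectra, `[[`, "intensity"),
                   lapply(b$spectra, `[[`, "intensity"))
  d1 <- simulate_dia(cfg)
  d2 <- simulate_dia(cfg)
  expect_identical(lapply(d1$ce20$spectra, `[[`, "intensity"),
                   lapply(d2$ce20$spectra, `[[`, "intensity"))
})

test_that("an empty panel with zero noise gives an all-zero TIC", {
  cfg <- simulation_config(panel = default_panel()[0, ], run_length_min = 2,
                           noise_peaks_per_scan = 0, n_interferents = 0)
  dia <- simulate_dia(cfg)
  expect_true(all(tic(dia$ce0)$intensity == 0))
})

test_that("DIA channels conserve analyte ion current before noise", {
  cfg <- small_config(seed = 21, noise_peaks_per_scan = 0,
                      n_interferents = 0)
  dia <- simulate_dia(cfg)
  s0 <- tic(dia$ce0)
  for (ch in c("ce20", "ce40")) {
    s <- tic(dia[[ch]])
    expect_equal(s$intensity, s0$intensity, tolerance = 1e-6)
  }
})

test_that("labelled analytes shift precursors and fragment channels", {
  panel <- default_panel()
  lab <- panel[panel$labelled, ][1, ]
  nat <- panel[panel$name == sub("^\\[13C4\\]-", "", lab$name), ]
  expect_equal(lab$mz - nat$mz, 4 * (13.00335483507 - 12), tolerance = 1e-9)
  expect_true(all(c(124.0397, 151.0223, 169.0329) %in% lab$frag_mz[[1]]))
  expect_false(any(c(121.0295, 147.0088, 165.0193) %in% lab$frag_mz[[1]]))
})

test_that("the DDA trigger threshold gates fragmentation", {
  dim_panel <- simulated_analyte("dim", "C12H14O4", 1.5, 1.5e5,
                                 pure_alkyl = TRUE)
  run <- simulate_dda(small_config(panel = dim_panel, seed = 3))
  ev <- attr(run, "event_log")
  expect_equal(nrow(ev), 0)
  # and a single analyte above the trigger is picked on its first eligible
  # cycle
  bright <- simulated_analyte("bright", "C12H14O4", 1.5, 5e6,
                              pure_alkyl = TRUE)
  cfg <- small_config(panel = bright, seed = 3)
  run2 <- simulate_dda(cfg)
  ev2 <- attr(run2, "event_log")
  expect_gt(nrow(ev2), 0)
  elig <- cfg$panel$rt_min - cfg$panel$sigma_min *
    sqrt(2 * log(cfg$panel$apex_intensity / cfg$dda$trigger_threshold))
  first_cycle_rt <- min(ev2$rt_min)
  expect_lte(first_cycle_rt, elig + cfg$scan_interval_s / 60 + 1e-9)
})

test_that("TopN and dynamic exclusion are honored in the event log", {
  # seven co-eluting precursors above the trigger, far enough apart in m/z
  # not to co-isolate
  panel <- do.call(rbind, lapply(0:6, function(k)
    simulated_analyte(paste0("co_", k), sprintf("C%dH%dO4", 12 + k,
                                                14 + 2 * k),
                      2.0, 3e6, pure_alkyl = (k %% 2 == 0))))
  cfg <- small_config(panel = panel, seed = 13)
  run <- simulate_dda(cfg)
  ev <- attr(run, "event_log")
  # never more than TopN selections per cycle
  expect_lte(max(table(ev$cycle)), cfg$dda$top_n)
  # all seven are eventually fragmented
  for (i in seq_len(nrow(panel)))
    expect_true(any(abs(ev$precursor_mz - panel$mz[i]) / panel$mz[i] * 1e6 <=
                      5))
  # the same precursor is never re-selected inside the exclusion window
  for (i in seq_len(nrow(panel))) {
    sel <- sort(ev$rt_min[abs(ev$precursor_mz - panel$mz[i]) /
                            panel$mz[i] * 1e6 <= 5])
    if (length(sel) > 1)
      expect_true(all(diff(sel) > cfg$dda$dynamic_exclusion_s / 60 - 1e-9))
  }
  # every selection satisfied the intensity trigger
  expect_true(all(ev$ms1_intensity >= cfg$dda$trigger_threshold))
})

test_that("blanks carry only the configured contamination", {
  cfg <- simulation_config(blank_contamination_fraction = 0)
  fx <- make_study_fixture(cfg)
  blank <- fx$blank_runs[[1]]
  nat <- native_truth(fx)
  for (i in seq_len(nrow(nat))) {
    tr <- extract_eic(blank, nat$mz[i], 5)
    expect_lt(max(tr$intensity), 3 * cfg$noise_floor)
  }
})

test_that("the study fixture has the documented replicate structure", {
  fx <- default_fixture()
  expect_equal(length(fx$dda_runs), 10)  # 3 + 3 groups, QC, 3 blanks
  expect_equal(length(fx$dia_runs), 3)
  expect_equal(names(fx$dia_runs), c("ce0", "ce20", "ce40"))
  expect_equal(nrow(fx$truth$analytes), nrow(default_panel()))
  expect_equal(sum(fx$truth$differential$label == "up"), 4)
  expect_setequal(fx$groups, c("fertile", "infertile"))
  # truth intensities: group B carries the planted folds
  ti <- fx$truth$intensities
  fold25 <- ti[ti$name == "mono-ethyl phthalate", ]
  ratio <- mean(as.numeric(fold25[paste0("infertile_", 1:3)])) /
    mean(as.numeric(fold25[paste0("fertile_", 1:3)]))
  expect_equal(ratio, 25, tolerance = 0.15)
})

test_that("fixture runs written as mzML read back faithfully", {
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- small_config(seed = 33)
  cfg$replicates <- 1
  fx <- make_study_fixture(cfg, out_dir = dir)
  files <- list.files(dir)
  expect_true("truth_analytes.csv" %in% files)
  expect_true(any(grepl("^dda_.*\\.mzML$", files)))
  expect_true(all(paste0("dia_qc_ce", c(0, 20, 40), ".mzML") %in% files))
  back <- read_mzml(file.path(dir, "dia_qc_ce20.mzML"))
  expect_equal(back$channel_ce_v, 20)
  expect_equal(n_spectra(back), n_spectra(fx$dia_runs$ce20))
})
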