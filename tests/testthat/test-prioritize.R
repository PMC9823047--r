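test_that("diagnostic ions match the most intense centroid in window", {
  diag <- diagnostic_ion_set()
  sp <- ms2_spectrum(c(121.0295, 121.0297, 165.0193), c(1e5, 3e5, 2e5))
  m <- diagnostic_ion_match(sp, diag$native_trio, 5)
  expect_equal(nrow(m), 2)
  expect_equal(m$observed_mz[m$ion_mz == 121.0295], 121.0297)
  expect_equal(m$intensity[m$ion_mz == 121.0295], 3e5)
  # empty spectrum: no matches
  empty <- spectrum_record(1, 1, 2L, numeric(0), numeric(0),
                           precursor_mz = 200)
  expect_equal(nrow(diagnostic_ion_match(empty, diag$native_trio, 5)), 0)
})

test_that("the two-of-three rule decides DDA candidacy", {
  ms1 <- spectrum_record(1, 0.99, 1L, 277.1445, 2e6)
  two <- ms2_spectrum(c(121.0295, 147.0088), scan_index = 2)
  run2 <- acquisition_run(list(ms1, two), mode = "DDA")
  cand <- prioritize_dda(run2)
  expect_equal(cand$status, "candidate")
  expect_equal(cand$n_diagnostic_ions, 2)
  # a single diagnostic ion is a false positive
  one <- ms2_spectrum(121.0296, scan_index = 2)
  cand1 <- prioritize_dda(acquisition_run(list(ms1, one), mode = "DDA"))
  expect_equal(cand1$status, "false_positive")
  expect_equal(cand1$reason, "lt2_diagnostic_ions")
  # the supplementary ion flags the subclass but never counts to the rule
  supp <- ms2_spectrum(c(121.0295, 134.0377), scan_index = 2)
  cands <- prioritize_dda(acquisition_run(list(ms1, supp), mode = "DDA"))
  expect_equal(cands$status, "false_positive")
  expect_true(cands$supplementary_ion)
  # no candidate ever has fewer than two native-trio matches
  expect_true(all(cands$n_diagnostic_ions[cands$status == "candidate"] >= 2))
  expect_error(prioritize_dda(acquisition_run(list(ms1), mode = "DDA")),
               "no MS2")
})

test_that("sub-threshold precursors are filtered with a recorded reason", {
  panel <- simulated_analyte("dim analyte", "C12H14O4", 1.5, 4e5,
                             pure_alkyl = TRUE)
  cfg <- small_config(panel = panel, seed = 5)
  cand <- prioritize_dda(simulate_dda(cfg))
  expect_true(all(cand$status == "filtered"))
  expect_true("intensity_threshold" %in% cand$reason)
  # audit reasons account for every dropped ion
  audit <- filter_audit(cand)
  expect_equal(sum(audit$n), sum(!is.na(cand$reason)))
})

test_that("DIA prioritization recovers planted analytes as provisional", {
  cfg <- small_config(seed = 5)
  dia <- simulate_dia(cfg)
  prov <- prioritize_dia(dia$ce0, dia[c("ce20", "ce40")])
  surv <- prov[prov$status == "provisional", ]
  for (i in seq_len(nrow(cfg$panel)))
    expect_true(matches_truth(surv, cfg$panel[i, ]))
  expect_true(all(surv$n_formulas >= 1))
  expect_error(prioritize_dia(NULL, dia["ce20"]), "CE = 0")
})

test_that("targeted MS2 confirmation applies the two-of-three rule", {
  prov <- data.frame(
    mz = c(277.1445, 235.0976), rt_min = c(1.0, 2.0),
    intensity = c(2e6, 1e6), n_diagnostic_ions = c(3L, 1L),
    matched_ions = c("", ""), supplementary_ion = FALSE,
    top_formula = c("C16H21O4", "C13H15O4"), formula_ppm = 0,
    n_formulas = 1L, mode = "DIA", sample_id = "s",
    status = "provisional", reason = NA_character_,
    stringsAsFactors = FALSE
  )
  targ <- acquisition_run(list(
    spectrum_record(1, 0.98, 1L, c(235.0976, 277.1445), c(1e6, 2e6)),
    ms2_spectrum(c(121.0295, 147.0088), precursor_mz = 277.1445,
                 rt_min = 1.0, scan_index = 2),
    ms2_spectrum(121.0295, precursor_mz = 235.0976, rt_min = 2.0,
                 scan_index = 3)
  ), mode = "DDA")
  conf <- confirm_candidates(prov, targ)
  expect_equal(conf$status, c("candidate", "false_positive"))
  # an ion with no acquired MS2 stays provisional, with a warning
  prov3 <- prov[1, ]
  prov3$mz <- 400.123
  expect_warning(conf3 <- confirm_candidates(prov3, targ), "provisional")
  expect_equal(conf3$status, "provisional")
})

test_that("the blank rule keeps >= 3x features and blank-absent features", {
  expect_true(blank_filter(3.0e6, c(1.1e6, 0.9e6, 1.0e6), 3))   # boundary
  expect_false(blank_filter(2.9e6, c(1.1e6, 0.9e6, 1.0e6), 3))
  expect_true(blank_filter(1e4, c(0, 0, 0), 3))
  expect_true(blank_filter(1e4, c(NA, NA), 3))
  # max aggregation is stricter than mean
  expect_false(blank_filter(3.4e6, c(0.9e6, 1.2e6), 3, aggregate = "max"))
})

test_that("blank-contaminated features survive at the 3x default carryover", {
  fx <- default_fixture()
  cand <- prioritize_dda(fx$dda_runs$qc_spiked)
  cand2 <- apply_blank_filter(cand, fx$blank_runs)
  # 5% carryover gives a 20x sample/blank ratio; nothing should be dropped
  expect_equal(sum(cand2$status == "candidate"),
               sum(cand$status == "candidate"))
})

test_that("the inclusion list has vendor columns and padded RT windows", {
  cand <- data.frame(
    mz = 321.1709, rt_min = 12.66, intensity = 1e6, n_diagnostic_ions = 3L,
    matched_ions = "", supplementary_ion = FALSE, top_formula = "C18H25O5",
    formula_ppm = -0.5, n_formulas = 1L, mode = "DIA", sample_id = "s",
    status = "provisional", reason = NA_character_, stringsAsFactors = FALSE
  )
  incl <- export_inclusion_list(cand)
  expect_equal(nrow(incl), 1)
  expect_equal(incl$Start, 12.16)
  expect_equal(incl$End, 13.16)
  expect_equal(incl$Species, "[M-H]-")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  export_inclusion_list(cand[0, ], path)
  empty <- utils::read.csv(path)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("Mass", "Formula", "Start", "End") %in% names(empty)))
})
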