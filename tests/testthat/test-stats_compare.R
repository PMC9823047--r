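test_that("rsd matches the replicate definition and scales out", {
  expect_equal(rsd(c(100, 100, 100)), 0.0)
  expect_equal(rsd(c(90, 100, 110)), 10.0)
  expect_equal(rsd(c(90, 100, 110) * 1e4), 10.0)
  expect_error(rsd(1), "at least 2")
  expect_error(rsd(c(-1, 1)), "non-positive mean")
})

test_that("false positive rates reproduce the printed QC arithmetic", {
  expect_equal(false_positive_rate(3, 14), 21.4)
  expect_equal(false_positive_rate(2, 14), 14.3)
  expect_equal(false_positive_rate(1, 14), 7.1)
  expect_equal(false_positive_rate(114, 132, digits = 0), 86)
  for (n in c(1, 5, 14)) {
    expect_equal(false_positive_rate(0, n), 0)
    expect_equal(false_positive_rate(n, n), 100)
  }
  expect_error(false_positive_rate(1, 0), "positive")
  expect_error(false_positive_rate(5, 4), "n_false")
})

test_that("identification efficiency separates recovery from extras", {
  spiked <- sprintf("std_%02d", 1:14)
  all_found <- identification_efficiency(spiked, spiked)
  expect_equal(all_found$efficiency, 1)
  expect_equal(all_found$false_positive_rate, 0)
  part <- identification_efficiency(spiked,
                                    c(spiked[1:10], "ghost_a", "ghost_b",
                                      "ghost_c"))
  expect_equal(part$n_identified, 10)
  expect_equal(part$efficiency, 10 / 14)
  expect_equal(part$n_false_positive, 3)
  expect_equal(part$false_positive_rate, 21.4)
})

test_that("differential analysis recovers planted folds and labels", {
  sim <- simulate_feature_matrix(n_features = 60,
                                 fold = rep(c(25, 1), each = 30),
                                 cv = 0.05, seed = 99)
  res <- differential_analysis(sim$intensities, sim$groups, "a", "b")
  up <- res$fold_change[1:30]
  expect_true(all(abs(up / 25 - 1) < 0.25))
  expect_true(all(res$label[1:30] == "up"))
  # identical groups: fold 1, unchanged
  m <- matrix(rep(c(10, 11, 12), 2), nrow = 1)
  r1 <- differential_analysis(m, rep(c("a", "b"), each = 3), "a", "b")
  expect_equal(r1$fold_change, 1)
  expect_equal(r1$label, "unchanged")
  # degenerate variance with equal means: p = 1 by convention
  md <- matrix(rep(5, 6), nrow = 1)
  expect_equal(differential_analysis(md, rep(c("a", "b"), each = 3),
                                     "a", "b")$p_value, 1)
})

test_that("differential labels are antisymmetric under group swap", {
  sim <- simulate_feature_matrix(n_features = 40,
                                 fold = rep(c(5, 0.2, 1, 1), 10),
                                 cv = 0.05, seed = 17)
  ab <- differential_analysis(sim$intensities, sim$groups, "a", "b")
  ba <- differential_analysis(sim$intensities, sim$groups, "b", "a")
  swap <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_identical(unname(swap[ab$label]), ba$label)
  expect_equal(ab$fold_change, 1 / ba$fold_change, tolerance = 1e-12)
})

test_that("features present in only one group are handled without fake p", {
  m <- matrix(c(NA, NA, NA, 1e6, 1.1e6, 0.9e6), nrow = 1)
  r <- differential_analysis(m, rep(c("a", "b"), each = 3), "a", "b",
                             detection_floor = 1e3)
  expect_equal(r$label, "up")
  expect_true(is.infinite(r$fold_change))
  expect_true(is.na(r$p_value))
})

test_that("the comparison report enforces its count chain", {
  fx <- default_fixture()
  cand <- prioritize_dda(fx$dda_runs$qc_spiked)
  std <- read_standards()
  ml <- read_mass_list()
  ann <- assign_level(cand, std, ml, make_rt_predictor(std))
  rep2 <- build_comparison_report(list(
    list(mode = "DDA", sample_id = "qc", candidates = cand,
         annotations = ann),
    list(mode = "DIA", sample_id = "qc", candidates = cand[0, ])
  ))
  expect_equal(nrow(rep2), 2)
  expect_true(all(rep2$n_candidate_ions <= rep2$n_precursor_ions))
  expect_true(all(rep2$n_level1 + rep2$n_level2 + rep2$n_level3 <=
                    rep2$n_candidate_ions))
  # a corrupted annotation set (more levels than candidates) trips the trap
  bad_ann <- rbind(ann, ann)
  bad_ann$level <- 1L
  expect_error(build_comparison_report(list(
    list(mode = "DDA", sample_id = "qc", candidates = cand,
         annotations = bad_ann))), "count chain")
  expect_error(build_comparison_report(list()), "at least one")
})
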