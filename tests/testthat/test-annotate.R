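test_that("mass-list screening matches by accurate neutral mass", {
  ml <- read_mass_list()
  mbp <- ml[ml$name == "mono-n-butyl phthalate", ]
  feats <- data.frame(mz = mbp$anion_mz, rt_min = 8.6)
  hits <- screen_mass_list(feats, ml, 5)
  expect_true("mono-n-butyl phthalate" %in% hits$proposed_name)
  # isomers all report: C12H14O4 occurs twice (n-butyl and isobutyl)
  expect_equal(sum(hits$feature_id == 1), 2)
  # 50 ppm off everything: no hit
  none <- screen_mass_list(data.frame(mz = mbp$anion_mz * (1 + 5e-5)), ml, 5)
  expect_equal(nrow(none), 0)
  expect_error(screen_mass_list(feats, ml[0, ], 5), "empty")
})

test_that("ppm matching is symmetric around the list mass", {
  ml <- read_mass_list()
  m0 <- ml$anion_mz[ml$name == "mono-n-hexyl phthalate"][1]
  up <- screen_mass_list(data.frame(mz = m0 * (1 + 4e-6)), ml, 5)
  dn <- screen_mass_list(data.frame(mz = m0 * (1 - 4e-6)), ml, 5)
  expect_setequal(up$proposed_name, dn$proposed_name)
})

test_that("replicate retention times collapse to unique compounds", {
  ann <- data.frame(
    proposed_name = c(rep("mono-5-hydroxyhexyl phthalate", 9), "a", "b", "c"),
    rt_min = c(seq(5, 9, length.out = 9), 1, 2, 3),
    stringsAsFactors = FALSE
  )
  coll <- collapse_replicate_rts(ann)
  expect_equal(nrow(coll), 4)
  expect_equal(coll$n_rts[coll$proposed_name ==
                            "mono-5-hydroxyhexyl phthalate"], 9)
  expect_equal(nrow(collapse_replicate_rts(ann[10:12, ])), 3)
})

test_that("the RT surrogate is exact on standards and monotone in chain", {
  std <- read_standards()
  pred <- make_rt_predictor(std)
  train <- std[!std$labelled, ]
  expect_equal(predict_rt(pred, train$name), train$rt_min)
  # homologous monoalkyl series: predicted RT increases with chain length
  homologs <- sprintf("C%dH%dO4", 8 + 1:12, 6 + 2 * (1:12))
  p <- predict_rt(pred, rep("unknown", 12), homologs)
  expect_true(all(diff(p) > 0))
  # no descriptors, no prediction
  expect_true(is.na(predict_rt(pred, "unknown", NA_character_)))
})

.cand_row <- function(mz, rt, formula) {
  data.frame(mz = mz, rt_min = rt, intensity = 1e6, n_diagnostic_ions = 2L,
             matched_ions = "", supplementary_ion = FALSE,
             top_formula = formula, formula_ppm = 0, n_formulas = 1L,
             mode = "DDA", sample_id = "s", status = "candidate",
             reason = NA_character_, stringsAsFactors = FALSE)
}

test_that("confidence levels follow the evidence ladder", {
  std <- read_standards()
  ml <- read_mass_list()
  pred <- make_rt_predictor(std)
  mbz <- std[std$name == "mono-benzyl phthalate", ]
  # standard match in mass and RT: level 1
  c1 <- .cand_row(mbz$anion_mz, mbz$rt_min + 0.05, "C15H11O4")
  a1 <- assign_level(c1, std, ml, pred)
  expect_equal(a1$level, 1L)
  expect_equal(a1$proposed_name, "mono-benzyl phthalate")
  # no standard, single structure with predicted RT inside 0.2 min: level 2
  mehhp <- ml[ml$name == "mono-2-ethyl-5-hydroxyhexyl phthalate", ]
  p2 <- predict_rt(pred, mehhp$name, mehhp$formula)
  c2 <- .cand_row(mehhp$anion_mz, p2 + 0.1, mehhp$formula)
  a2 <- assign_level(c2, std, ml, pred)
  expect_equal(a2$level, 2L)
  expect_equal(a2$proposed_name, mehhp$name)
  # same structure observed >0.2 min away from the prediction: level 3
  c3 <- .cand_row(mehhp$anion_mz, p2 + 1.0, mehhp$formula)
  a3 <- assign_level(c3, std, ml, pred)
  expect_equal(a3$level, 3L)
})

test_that("level assignment is monotone in evidence", {
  std <- read_standards()
  ml <- read_mass_list()
  pred <- make_rt_predictor(std)
  mbz <- std[std$name == "mono-benzyl phthalate", ]
  cand <- .cand_row(mbz$anion_mz, mbz$rt_min, "C15H11O4")
  with_std <- assign_level(cand, std, ml, pred)
  without_std <- assign_level(cand, std[std$name != "mono-benzyl phthalate", ],
                              ml, pred)
  expect_lte(with_std$level, without_std$level)
  # removing the predictor never raises a level
  expect_warning(no_pred <- assign_level(cand[, ],
                                         std[std$name != "mono-benzyl phthalate", ],
                                         ml, NULL),
                 "capped at 3")
  expect_gte(no_pred$level, without_std$level)
  expect_equal(no_pred$level, 3L)
})

test_that("two isomers inside the prediction window stay ambiguous level 3", {
  ml <- data.frame(name = c("isomer A", "isomer B"),
                   formula = c("C12H14O4", "C12H14O4"),
                   stringsAsFactors = FALSE)
  ml$neutral_mass <- vapply(ml$formula, monoisotopic_mass, numeric(1))
  std <- data.frame(name = "far standard", formula = "C9H8O4", rt_min = 2,
                    labelled = FALSE, anion_mz = anion_mz("C9H7O4"),
                    stringsAsFactors = FALSE)
  # external predictions put both isomers within 0.2 min of the observation
  pred <- c("isomer A" = 8.50, "isomer B" = 8.60)
  cand <- .cand_row(anion_mz("C12H13O4"), 8.55, "C12H13O4")
  a <- assign_level(cand, std, ml, pred)
  expect_equal(a$level, 3L)
  expect_true(a$ambiguous_isomers)
})
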