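# Structure annotation: suspect-mass-list screening, replicate-RT collapse,
# retention-time prediction (pluggable surrogate), and Schymanski-style
# confidence levels:
#   level 1 — exact mass + RT match to a reference standard, >= 2 diagnostic
#             ions;
#   level 2 — probable structure: >= 2 diagnostic ions and predicted RT
#             within 0.2 min of the observed RT;
#   level 3 — tentative candidate (formula + diagnostic evidence, isomer
#             unresolved).

#' Read a standards library CSV
#'
#' Expected columns: `name`, `formula` (neutral, Hill notation, 13C as
#' `[13C]n`), `rt_min`, `labelled` (logical). The shipped
#' `standards_library_synthetic.csv` is a synthetic reconstruction (24 native
#' + 14 ring-13C4 labelled monophthalate standards), not measured data.
#'
#' @param path CSV path; defaults to the shipped synthetic library.
#' @return A data.frame with an added `anion_mz` column ([M-H]- of the
#'   neutral formula).
#' @export
read_standards <- function(path = system.file("extdata",
                                              "standards_library_synthetic.csv",
                                              package = "phthalscreen")) {
  std <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "formula", "rt_min", "labelled") %in% names(std)))
  if (any(std$rt_min <= 0)) stop("standard retention times must be positive")
  std$labelled <- as.logical(std$labelled)
  std$anion_mz <- vapply(std$formula, function(f) {
    fo <- parse_formula(f)
    anion_mz(formula_cho(fo$n_carbon, fo$n_hydrogen - 1L, fo$n_oxygen,
                         fo$n_carbon13))
  }, numeric(1), USE.NAMES = FALSE)
  std
}

#' Read a suspect mass list CSV
#'
#' Expected columns: `name`, `formula` (neutral); a `neutral_mass` column is
#' recomputed from the formula and must agree to 1e-4 Da if present. The
#' shipped `mass_list_synthetic_75.csv` is a 75-entry reconstruction of
#' common monophthalates and their oxidized metabolites.
#'
#' @param path CSV path; defaults to the shipped synthetic list.
#' @return A data.frame with columns `name`, `formula`, `neutral_mass`,
#'   `anion_mz`.
#' @export
read_mass_list <- function(path = system.file("extdata",
                                              "mass_list_synthetic_75.csv",
                                              package = "phthalscreen")) {
  ml <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "formula") %in% names(ml)))
  calc <- vapply(ml$formula, function(f) monoisotopic_mass(parse_formula(f)),
                 numeric(1), USE.NAMES = FALSE)
  if ("neutral_mass" %in% names(ml) &&
      any(abs(ml$neutral_mass - calc) > 1e-4))
    stop("mass list neutral_mass disagrees with formula by > 1e-4 Da")
  ml$neutral_mass <- calc
  ml$anion_mz <- vapply(ml$formula, function(f) {
    fo <- parse_formula(f)
    anion_mz(formula_cho(fo$n_carbon, fo$n_hydrogen - 1L, fo$n_oxygen))
  }, numeric(1), USE.NAMES = FALSE)
  ml
}

#' Screen features against a suspect mass list
#'
#' Database-style annotation by accurate mass alone: every mass-list entry
#' whose neutral mass lies within `tol_ppm` of the feature's neutral mass
#' (reconstructed from the [M-H]- m/z) is reported. One feature may hit
#' several isomers (all reported) and one compound may hit at several
#' retention times.
#'
#' @param features A data.frame with columns `mz` (and optionally `rt_min`).
#' @param mass_list A mass list from [read_mass_list()].
#' @param tol_ppm Matching tolerance, ppm.
#' @return A data.frame of hits: `feature_id` (row of `features`), `mz`,
#'   `rt_min`, `proposed_name`, `formula`, `theoretical_mass`, `ppm_error`.
#' @export
screen_mass_list <- function(features, mass_list, tol_ppm = 5) {
  if (is.null(mass_list) || nrow(mass_list) == 0)
    stop("mass list is empty; configuration error")
  hits <- lapply(seq_len(nrow(features)), function(i) {
    nm <- neutral_mass_from_mz(features$mz[i])
    ppm <- (nm - mass_list$neutral_mass) / mass_list$neutral_mass * 1e6
    sel <- which(abs(ppm) <= tol_ppm)
    if (!length(sel)) return(NULL)
    data.frame(
      feature_id = i, mz = features$mz[i],
      rt_min = if ("rt_min" %in% names(features)) features$rt_min[i]
      else NA_real_,
      proposed_name = mass_list$name[sel], formula = mass_list$formula[sel],
      theoretical_mass = mass_list$neutral_mass[sel], ppm_error = ppm[sel],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(feature_id = integer(0), mz = numeric(0),
                      rt_min = numeric(0), proposed_name = character(0),
                      formula = character(0), theoretical_mass = numeric(0),
                      ppm_error = numeric(0), stringsAsFactors = FALSE)
  out
}

#' Collapse annotations that repeat at several retention times
#'
#' Mass-only screening annotates the same compound name at multiple RTs
#' (isomers, in-source artifacts). This reports one row per unique proposed
#' name with its RT list, so "n annotations" becomes "n unique compounds".
#'
#' @param annotations A data.frame with `proposed_name` and `rt_min`.
#' @return A data.frame: `proposed_name`, `n_rts`, `rt_list` (semicolon
#'   separated, sorted).
#' @export
collapse_replicate_rts <- function(annotations) {
  if (nrow(annotations) == 0)
    return(data.frame(proposed_name = character(0), n_rts = integer(0),
                      rt_list = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(annotations, annotations$proposed_name),
                               function(g) {
    rts <- sort(g$rt_min)
    data.frame(proposed_name = g$proposed_name[1], n_rts = length(rts),
               rt_list = paste(sprintf("%.2f", rts), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$proposed_name), , drop = FALSE]
}

#' Fit the surrogate retention-time predictor
#'
#' The in-house multi-descriptor RT regression used with real data is not
#' public; this surrogate regresses standard RTs on a single logP-like
#' hydrophobicity proxy computed from the neutral CHO formula
#' (`(C - 8) - 1.2 * (O - 4)`: side-chain carbons increase retention, polar
#' oxygens beyond the phthalate ester core decrease it). Structures present
#' in the training standards are returned at their library RT (exact on
#' training points); unknown structures fall back to the linear fit. The
#' `predict_rt()` interface also accepts externally supplied predictions, so
#' a full descriptor model can be plugged in.
#'
#' @param standards A standards table from [read_standards()] (labelled
#'   entries are excluded from the fit).
#' @return An `rt_predictor` object.
#' @export
make_rt_predictor <- function(standards) {
  train <- standards[!standards$labelled, , drop = FALSE]
  if (nrow(train) < 2) stop("need at least 2 native standards to fit")
  d <- vapply(train$formula, .hydrophobicity_proxy, numeric(1),
              USE.NAMES = FALSE)
  fit <- stats::lm(rt_min ~ d, data = data.frame(rt_min = train$rt_min, d = d))
  structure(
    list(lookup = stats::setNames(train$rt_min, train$name),
         coef = stats::coef(fit)),
    class = "rt_predictor"
  )
}

.hydrophobicity_proxy <- function(formula) {
  f <- parse_formula(formula)
  (f$n_carbon - 8) - 1.2 * (f$n_oxygen - 4)
}

#' Predict retention time for proposed structures
#'
#' @param predictor An `rt_predictor` from [make_rt_predictor()], or a named
#'   numeric vector of externally supplied predictions (minutes), or `NULL`
#'   (no predictor: all predictions `NA`, levels cap at 3).
#' @param names Structure names (used for exact training-point lookup and
#'   for externally supplied predictions).
#' @param formulas Neutral formulas (used for the descriptor fallback);
#'   `NA`/unparseable formulas give `NA` (no prediction).
#' @return Predicted RTs in minutes (NA where no prediction is possible).
#' @export
predict_rt <- function(predictor, names = NULL, formulas = NULL) {
  n <- max(length(names), length(formulas))
  if (is.null(predictor)) return(rep(NA_real_, n))
  if (is.numeric(predictor))
    return(unname(predictor[names]))
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.null(names) && !is.na(names[i]) &&
        names[i] %in% names(predictor$lookup)) {
      out[i] <- predictor$lookup[[names[i]]]
    } else if (!is.null(formulas) && !is.na(formulas[i])) {
      d <- tryCatch(.hydrophobicity_proxy(formulas[i]),
                    error = function(e) NA_real_)
      if (!is.na(d)) out[i] <- predictor$coef[[1]] + predictor$coef[[2]] * d
    }
  }
  out
}

#' Assign identification confidence levels to confirmed candidates
#'
#' For each row with `status == "candidate"` (i.e. >= 2 diagnostic ions):
#' level 1 when a standard matches in accurate mass (`tol_ppm`) and RT
#' (`|dRT| <= rt_match_tol_min`); otherwise level 2 when exactly one
#' mass-list structure has `|predicted RT - observed RT| < rt_pred_tol_min`;
#' otherwise level 3 (two or more isomers inside the prediction window are
#' reported as ambiguous and stay level 3). Without an RT predictor levels
#' are capped at 3 (with a warning).
#'
#' @param candidates A candidate table ([prioritize_dda()] /
#'   [confirm_candidates()]).
#' @param standards A standards table from [read_standards()].
#' @param mass_list A mass list from [read_mass_list()] (proposed
#'   structures).
#' @param rt_predictor An `rt_predictor`, external prediction vector, or
#'   `NULL`.
#' @param rt_match_tol_min Standard RT tolerance for level 1 (default 0.1).
#' @param rt_pred_tol_min Predicted-RT tolerance for level 2 (default 0.2).
#' @param tol_ppm Accurate-mass tolerance, ppm.
#' @return An annotation data.frame: candidate columns plus `proposed_name`,
#'   `level`, `standard_name`, `standard_rt_delta_min`, `predicted_rt_min`,
#'   `predicted_rt_delta_min`, `mass_list_hit`, `ambiguous_isomers`.
#' @export
assign_level <- function(candidates, standards, mass_list,
                         rt_predictor = NULL,
                         rt_match_tol_min = 0.1, rt_pred_tol_min = 0.2,
                         tol_ppm = 5) {
  if (is.null(rt_predictor))
    warning("no RT predictor supplied; identification levels capped at 3")
  ann <- candidates[candidates$status == "candidate", , drop = FALSE]
  ann$proposed_name <- NA_character_
  ann$level <- NA_integer_
  ann$standard_name <- NA_character_
  ann$standard_rt_delta_min <- NA_real_
  ann$predicted_rt_min <- NA_real_
  ann$predicted_rt_delta_min <- NA_real_
  ann$mass_list_hit <- FALSE
  ann$ambiguous_isomers <- FALSE
  for (i in seq_len(nrow(ann))) {
    # level 1: reference standard match in mass and RT
    dppm <- abs(standards$anion_mz - ann$mz[i]) / ann$mz[i] * 1e6
    drt <- abs(standards$rt_min - ann$rt_min[i])
    hit <- which(dppm <= tol_ppm & drt <= rt_match_tol_min)
    if (length(hit)) {
      best <- hit[which.min(drt[hit])]
      ann$level[i] <- 1L
      ann$proposed_name[i] <- standards$name[best]
      ann$standard_name[i] <- standards$name[best]
      ann$standard_rt_delta_min[i] <- standards$rt_min[best] - ann$rt_min[i]
      next
    }
    # level 2/3: proposed structures from the mass list + predicted RT
    hits <- screen_mass_list(ann[i, c("mz", "rt_min"), drop = FALSE],
                             mass_list, tol_ppm)
    if (nrow(hits)) {
      ann$mass_list_hit[i] <- TRUE
      pred <- predict_rt(rt_predictor, hits$proposed_name, hits$formula)
      delta <- pred - ann$rt_min[i]
      ok <- which(!is.na(delta) & abs(delta) < rt_pred_tol_min)
      if (length(ok) == 1) {
        ann$level[i] <- 2L
        ann$proposed_name[i] <- hits$proposed_name[ok]
        ann$predicted_rt_min[i] <- pred[ok]
        ann$predicted_rt_delta_min[i] <- delta[ok]
        next
      }
      if (length(ok) >= 2) ann$ambiguous_isomers[i] <- TRUE
      best <- which.min(abs(hits$ppm_error))
      ann$proposed_name[i] <- hits$proposed_name[best]
      ann$predicted_rt_min[i] <- pred[best]
      ann$predicted_rt_delta_min[i] <- delta[best]
    } else {
      ann$proposed_name[i] <- ann$top_formula[i]
    }
    ann$level[i] <- 3L
  }
  rownames(ann) <- NULL
  ann
}
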