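#' Observed/predicted ratio
#'
#' `R = observed / predicted`, the basic model-qualification ratio.
#'
#' @param observed,predicted positive PK parameter values (vectorized).
#' @return ratio(s).
#' @examples
#' obsPredRatio(435.46, 372.41)
#' @export
obsPredRatio <- function(observed, predicted) {
  if (any(predicted <= 0)) stop("predicted values must be > 0")
  if (any(observed <= 0)) stop("observed values must be > 0")
  observed / predicted
}

#' Symmetric fold deviation
#'
#' `max(r, 1/r)`: the fold error irrespective of direction (a ratio of 0.5
#' and of 2 both give 2).
#'
#' @param ratio observed/predicted ratio(s) > 0.
#' @return fold deviation(s) >= 1.
#' @export
foldDeviation <- function(ratio) {
  if (any(ratio <= 0)) stop("ratios must be > 0")
  pmax(ratio, 1 / ratio)
}

#' Arithmetic mean of observed/predicted ratios
#'
#' The "as-printed mean ratio": the reference evaluation tables label this
#' quantity AFE although it is the arithmetic (not geometric) mean of the
#' ratios; both conventions are provided (see [afeGeometric()]).
#'
#' @param ratios positive ratios (length >= 1).
#' @return arithmetic mean.
#' @export
meanRatio <- function(ratios) {
  if (length(ratios) < 1) stop("at least one ratio is required")
  mean(ratios)
}

#' Geometric average fold error
#'
#' `AFE = 10^(mean(log10(fold errors)))` — scale-symmetric:
#' `AFE({r}) * AFE({1/r}) = 1`.
#'
#' @param fold_errors positive fold errors (observed/predicted ratios).
#' @return geometric AFE.
#' @export
afeGeometric <- function(fold_errors) {
  if (length(fold_errors) < 1) stop("at least one fold error is required")
  if (any(fold_errors <= 0)) stop("fold errors must be > 0")
  10^mean(log10(fold_errors))
}

#' Root mean square error
#'
#' `sqrt(mean((observed - predicted)^2))` in the parameter's units.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return RMSE >= 0.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1)
    stop("observed and predicted must have equal length >= 1")
  sqrt(mean((observed - predicted)^2))
}

#' Twofold acceptance check
#'
#' Per-ratio pass flags for the predefined twofold range
#' `0.5 <= R <= 2.0` (bounds inclusive) and the overall verdict (pass iff
#' every ratio is inside the band).
#'
#' @param ratios observed/predicted ratios.
#' @return list with `pass` (logical vector) and `overall` (logical).
#' @examples
#' twofoldCheck(c(0.5, 1.3, 2.0))$overall  # TRUE
#' twofoldCheck(2.01)$overall              # FALSE
#' @export
twofoldCheck <- function(ratios) {
  pass <- ratios >= 0.5 & ratios <= 2.0
  list(pass = pass, overall = all(pass))
}

#' Evaluate a table of study comparisons
#'
#' Computes, per study row, the observed/predicted ratio, fold deviation and
#' twofold flag; and per route x parameter, the study count, arithmetic mean
#' ratio (as-printed convention), geometric AFE, RMSE, ratio range and
#' overall twofold verdict.
#'
#' @param comparisons data.frame with columns `study_id`, `route`,
#'   `parameter`, `observed`, `predicted` (e.g. from
#'   [loadFixture()]`("table1")`).
#' @return an [EvaluationReport-class].
#' @examples
#' rep <- evaluateStudies(loadFixture("table1"))
#' rep
#' @export
evaluateStudies <- function(comparisons) {
  need <- c("study_id", "route", "parameter", "observed", "predicted")
  if (!all(need %in% names(comparisons)))
    stop("comparisons must have columns: ", paste(need, collapse = ", "))
  cmp <- comparisons[need]
  cmp$ratio <- obsPredRatio(cmp$observed, cmp$predicted)
  cmp$fold_error <- foldDeviation(cmp$ratio)
  cmp$twofold_pass <- twofoldCheck(cmp$ratio)$pass

  key <- interaction(cmp$route, cmp$parameter, drop = TRUE)
  summ <- do.call(rbind, lapply(split(cmp, key), function(g) {
    data.frame(route = g$route[1], parameter = g$parameter[1], n = nrow(g),
               mean_ratio = meanRatio(g$ratio),
               afe_geometric = afeGeometric(g$ratio),
               rmse = rmse(g$observed, g$predicted),
               min_ratio = min(g$ratio), max_ratio = max(g$ratio),
               all_twofold = all(g$twofold_pass))
  }))
  rownames(summ) <- NULL
  new("EvaluationReport", comparisons = cmp, summary = summ)
}

#' Render an evaluation report with two-decimal rounding
#'
#' Rounding (half-up, as in the reference tables) is applied only here, at
#' rendering; all computations keep full precision.
#'
#' @param report an [EvaluationReport-class].
#' @param digits decimal places.
#' @return data.frame of the per-study table with a `ratio_2dp` column.
#' @export
renderReport <- function(report, digits = 2) {
  half_up <- function(x) floor(x * 10^digits + 0.5) / 10^digits
  out <- report@comparisons
  out$ratio_2dp <- half_up(out$ratio)
  out
}
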