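#' Simple linear regression of an allelic statistic on one predictor
#'
#' Ordinary least squares of `y` on `x` with a tidy one-row result. The
#' correlation coefficient `r` carries the sign of the slope so that
#' directionality is visible alongside `r_squared`.
#'
#' @param y,x Aligned numeric vectors (one value per population).
#' @param response,predictor Labels stored in the result.
#' @return One-row data frame with columns `response`, `predictor`, `slope`,
#'   `intercept`, `r`, `r_squared`, `n`.
#' @examples
#' ols(c(1, 3, 4), c(0, 1, 2))
#' @export
ols <- function(y, x, response = "y", predictor = "x") {
  check_xy(y, x)
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  regression_row(response, predictor,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = s$r.squared, n = length(y))
}

#' Weighted linear regression
#'
#' Weighted least squares; weights are typically inverse population
#' variances of the mean risk-allele frequency. Equal weights reproduce
#' [ols()] exactly.
#'
#' @inheritParams ols
#' @param weights Positive finite weights (inverse variances).
#' @return One-row data frame as in [ols()] (`r_squared` is the weighted
#'   R-squared).
#' @export
wls <- function(y, x, weights, response = "y", predictor = "x") {
  check_xy(y, x)
  if (length(weights) != length(y)) {
    stop("weights must align with y", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  fit <- stats::lm(y ~ x, weights = weights)
  s <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  regression_row(response, predictor,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = s$r.squared, n = length(y))
}

check_xy <- function(y, x) {
  if (length(y) != length(x)) stop("y and x must align", call. = FALSE)
  if (length(y) < 3L) stop("need at least 3 populations", call. = FALSE)
  if (anyNA(y) || anyNA(x)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate (constant) predictor", call. = FALSE)
  invisible(TRUE)
}

regression_row <- function(response, predictor, slope, intercept, r_squared,
                           n) {
  data.frame(response = response, predictor = predictor, slope = slope,
             intercept = intercept,
             r = sign(slope) * sqrt(max(r_squared, 0)),
             r_squared = r_squared, n = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regress a panel's allelic statistics on every predictor
#'
#' Runs [ols()] (or [wls()] when `weights` are given) of the chosen
#' statistic against each predictor column over a population subset. By
#' convention raw statistics are used against distance and adjusted
#' statistics against environmental variables; both are available for every
#' predictor via the `adjusted` flag.
#'
#' @param profile An [allelic_profile()] data frame.
#' @param predictors Data frame with a `population` column and one numeric
#'   column per predictor (e.g. `distance_km` plus climate variables).
#' @param statistic `"heterozygosity"` or `"risk_freq"`.
#' @param adjusted Use the baseline-adjusted statistic? Default `TRUE`.
#' @param subset Optional character vector of populations to keep (e.g. to
#'   exclude or restrict to African populations).
#' @param weights Optional named vector of positive weights (inverse
#'   variances) keyed by population; triggers [wls()].
#' @return Data frame with one row per predictor.
#' @export
regress_panel <- function(profile, predictors,
                          statistic = c("heterozygosity", "risk_freq"),
                          adjusted = TRUE, subset = NULL, weights = NULL) {
  statistic <- match.arg(statistic)
  if (!"population" %in% names(predictors)) {
    stop("predictors must have a population column", call. = FALSE)
  }
  keep <- if (is.null(subset)) profile$population else
    intersect(profile$population, subset)
  if (length(keep) < 3L) {
    stop("population subset must contain at least 3 populations", call. = FALSE)
  }
  prof <- profile[match(keep, profile$population), ]
  pred <- predictors[match(keep, predictors$population), ]
  if (anyNA(pred$population)) {
    stop("predictors missing for some populations in the subset", call. = FALSE)
  }
  col <- switch(statistic,
                heterozygosity = if (adjusted) "adj_heterozygosity" else "avg_heterozygosity",
                risk_freq = if (adjusted) "adj_risk_freq" else "avg_risk_freq")
  y <- prof[[col]]
  resp <- paste0(if (adjusted) "adj_" else "", statistic)
  vars <- setdiff(names(pred), "population")
  out <- lapply(vars, function(v) {
    x <- pred[[v]]
    if (is.null(weights)) {
      ols(y, x, response = resp, predictor = v)
    } else {
      w <- weights[keep]
      if (anyNA(w)) stop("weights missing for some populations", call. = FALSE)
      wls(y, x, unname(w), response = resp, predictor = v)
    }
  })
  do.call(rbind, out)
}

#' Pairwise Pearson correlations among predictors
#'
#' Documents collinearity among distance and the climate variables (e.g. a
#' latitude/summer-radiation pair with |r| at the `flag_threshold` would be
#' pruned to a single representative before testing). Constant columns give
#' `NA` entries with a warning rather than silent zeros.
#'
#' @param predictors Data frame with a `population` column and numeric
#'   predictor columns.
#' @param flag_threshold Absolute correlation at or above which a pair is
#'   flagged as collinear (default 0.99).
#' @return List with `correlations` (symmetric matrix) and `collinear`
#'   (data frame of flagged pairs).
#' @export
predictor_correlations <- function(predictors, flag_threshold = 0.99) {
  vars <- setdiff(names(predictors), "population")
  if (length(vars) < 2L) stop("need at least 2 predictors", call. = FALSE)
  m <- as.matrix(predictors[, vars, drop = FALSE])
  const <- apply(m, 2L, stats::sd) == 0
  if (any(const)) {
    warning("constant predictor column(s): ",
            paste(vars[const], collapse = ", "),
            "; correlations set to NA", call. = FALSE)
  }
  cc <- suppressWarnings(stats::cor(m))
  cc[const, ] <- NA_real_
  cc[, const] <- NA_real_
  diag(cc) <- 1
  pairs <- which(upper.tri(cc) & abs(cc) >= flag_threshold, arr.ind = TRUE)
  collinear <- data.frame(var1 = vars[pairs[, 1L]], var2 = vars[pairs[, 2L]],
                          r = cc[pairs], stringsAsFactors = FALSE)
  list(correlations = cc, collinear = collinear)
}
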