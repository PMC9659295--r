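#' Weighted Pearson correlation
#'
#' Weighted covariance over the product of weighted standard deviations;
#' pairwise-complete cases. Reduces to the unweighted coefficient at
#' constant weights.
#'
#' @param x,y Numeric vectors.
#' @param w Positive weights (default unit).
#' @return Scalar correlation.
#' @export
weighted_pearson <- function(x, y, w = rep(1, length(x))) {
  ok <- !is.na(x) & !is.na(y) & !is.na(w)
  if (sum(ok) < 3) stop("need at least 3 pairwise-complete cases", call. = FALSE)
  if (any(w[ok] <= 0)) stop("weights must be > 0", call. = FALSE)
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - mx)^2)
  syy <- sum(w * (y - my)^2)
  if (sxx == 0 || syy == 0) stop("zero variance: correlation undefined", call. = FALSE)
  sum(w * (x - mx) * (y - my)) / sqrt(sxx * syy)
}

#' Weighted least-squares regression with standardized coefficients
#'
#' Minimises \eqn{\sum_v w_v (y_v - x_v'b)^2} with listwise deletion;
#' predictors enter as numeric. Reports unstandardized b, standardized
#' \eqn{\beta_j = b_j \, sd_w(x_j) / sd_w(y)} (weighted sds), and the
#' weighted \eqn{R^2}. Errors on a rank-deficient design, naming the
#' collinear columns.
#'
#' @param data Data frame.
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names.
#' @param weights Weight column name (`NULL` for the `weight` column if
#'   present, else unit weights).
#' @return Object of class `hls_regression`: tibble `coef` (`term`, `b`,
#'   `beta`), `r_squared`, `n_valid`, `n_total`, `outcome`, `weighted`.
#' @export
weighted_ols <- function(data, outcome, predictors, weights = NULL) {
  w_all <- resolve_weights(data, weights)
  cols <- c(outcome, predictors)
  num <- lapply(cols, function(cn) {
    v <- data[[cn]]
    if (is.null(v)) stop("column not found: ", cn, call. = FALSE)
    if (is.character(v) || is.factor(v)) as.numeric(as.factor(v)) - 1 else as.numeric(v)
  })
  names(num) <- cols
  df <- tibble::as_tibble(num)
  ok <- stats::complete.cases(df) & !is.na(w_all)
  dfc <- df[ok, , drop = FALSE]
  w <- w_all[ok]
  xm <- as.matrix(dfc[, predictors, drop = FALSE])
  qrx <- qr(sqrt(w) * cbind(1, xm))
  if (qrx$rank < ncol(xm) + 1) {
    bad <- c("(intercept)", predictors)[qrx$pivot[-seq_len(qrx$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.wfit(cbind(`(Intercept)` = 1, xm), dfc[[outcome]], w)
  b <- fit$coefficients
  wsd <- function(v) {
    m <- sum(w * v) / sum(w)
    sqrt(sum(w * (v - m)^2) / sum(w))
  }
  sd_y <- wsd(dfc[[outcome]])
  beta <- vapply(predictors, function(p) {
    b[p] * wsd(dfc[[p]]) / sd_y
  }, numeric(1))
  ybar <- sum(w * dfc[[outcome]]) / sum(w)
  r2 <- 1 - sum(w * fit$residuals^2) / sum(w * (dfc[[outcome]] - ybar)^2)
  structure(list(
    coef = tibble::tibble(term = c("(Intercept)", predictors),
                          b = unname(b),
                          beta = c(NA_real_, unname(beta))),
    r_squared = r2, n_valid = sum(ok), n_total = nrow(data),
    outcome = outcome,
    weighted = !all(w == w[1])
  ), class = "hls_regression")
}

#' @export
print.hls_regression <- function(x, ...) {
  cat("Weighted linear regression: ", x$outcome, " ~ ",
      paste(x$coef$term[-1], collapse = " + "), "\n", sep = "")
  cat(sprintf("  R-squared %.3f, valid n %d of %d\n",
              x$r_squared, x$n_valid, x$n_total))
  print(dplyr::mutate(x$coef, dplyr::across(c(b, beta), ~ round(.x, 3))))
  invisible(x)
}

#' @export
tidy.hls_regression <- function(x, ...) x$coef

#' @export
glance.hls_regression <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_valid = x$n_valid,
                 n_total = x$n_total, outcome = x$outcome)
}

# numeric codings for the standard determinants: sex female=1/male=0,
# others already numeric
determinant_frame <- function(data) {
  out <- data
  if (is.character(out$sex) || is.factor(out$sex)) {
    out$sex <- as.numeric(out$sex == "female")
  }
  out
}

#' Concurrent-validity regression models
#'
#' Two weighted linear models per score type: (1) the general HL score on
#' the five social-gradient determinants (gender, age, education, social
#' status, financial deprivation), and (2) self-perceived health (1 = very
#' good ... 5 = very bad) on the HL score plus the same determinants.
#' Gender is coded female = 1 (male baseline); all predictors enter as
#' numeric.
#'
#' @param scored Tibble from [score_hls()] including covariates.
#' @param score `"score_d"` or `"score_p"`.
#' @param weights Weight column name.
#' @return List with elements `determinants` and `health`, both
#'   `hls_regression`.
#' @export
concurrent_validity_models <- function(scored,
                                       score = c("score_d", "score_p"),
                                       weights = NULL) {
  score <- match.arg(score)
  det <- c("sex", "age", "education", "status", "findep")
  d <- determinant_frame(scored)
  list(
    determinants = weighted_ols(d, score, det, weights),
    health = weighted_ols(d, "health", c(score, det), weights)
  )
}

#' Discriminant-validity check against special-HL scores
#'
#' Weighted Pearson correlations between the general score and each special
#' health-literacy score, with a flag for the target band: correlations
#' should exceed 0.4 (same construct family) but stay below 0.7
#' (distinguishable constructs, no collinearity in joint regressions).
#'
#' @param scored Tibble with the general score and special-score columns.
#' @param score General score column name.
#' @param specials Character vector of special-score column names.
#' @param weights Weight column name.
#' @param band Lower/upper bounds of the target band.
#' @return Tibble: `score`, `special`, `r`, `within_band`, `position`.
#' @export
discriminant_check <- function(scored, score = "score_p",
                               specials = c("digital", "communicative",
                                            "navigational", "vaccination"),
                               weights = NULL, band = c(0.4, 0.7)) {
  w <- resolve_weights(scored, weights)
  purrr::map_dfr(specials, function(sp) {
    r <- weighted_pearson(scored[[score]], scored[[sp]], w)
    tibble::tibble(
      score = score, special = sp, r = r,
      within_band = r > band[1] & r < band[2],
      position = dplyr::case_when(r <= band[1] ~ "below",
                                  r >= band[2] ~ "above",
                                  TRUE ~ "within")
    )
  })
}

#' Short-form representation of a long-form instrument
#'
#' Computes type D and type P scores on the full long-form item set, on the
#' embedded short-form subset, and on named subdimension subsets, and
#' reports the weighted Pearson correlation of each long-form score with
#' its short-form counterpart.
#'
#' @param data Respondent tibble containing all long-form items.
#' @param long_items All long-form item columns.
#' @param short_items The embedded short-form items (subset of
#'   `long_items`).
#' @param subdimensions Optional named list of item subsets of the long
#'   form.
#' @param weights Weight column name.
#' @return Tibble: `scale`, `score_type`, `r`, `n`.
#' @export
shortform_representation <- function(data, long_items,
                                     short_items = hls_items(),
                                     subdimensions = NULL, weights = NULL) {
  if (!all(short_items %in% long_items)) {
    stop("short-form items must be a subset of the long form", call. = FALSE)
  }
  w <- resolve_weights(data, weights)
  short_d <- score_type_d(data, short_items)
  short_p <- score_type_p(data, short_items)
  one <- function(ids, label) {
    ld <- score_type_d(data, ids)
    lp <- score_type_p(data, ids)
    tibble::tibble(
      scale = label,
      score_type = c("D", "P"),
      r = c(weighted_pearson(ld, short_d, w),
            weighted_pearson(lp, short_p, w)),
      n = c(sum(!is.na(ld) & !is.na(short_d)),
            sum(!is.na(lp) & !is.na(short_p)))
    )
  }
  out <- one(long_items, "general")
  if (!is.null(subdimensions)) {
    out <- dplyr::bind_rows(
      out,
      purrr::imap_dfr(subdimensions, function(ids, nm) one(ids, nm))
    )
  }
  out
}
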