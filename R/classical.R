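#' Cronbach's alpha
#'
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_t^2)} with sample variances
#' (n-1 denominator) over listwise-complete cases.
#'
#' @param data Respondent tibble.
#' @param items Item column names.
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(data, items = hls_items()) {
  x <- as.matrix(data[, items, drop = FALSE])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  if (k < 2) stop("alpha needs at least 2 items", call. = FALSE)
  if (nrow(x) < 3) stop("alpha needs at least 3 complete cases", call. = FALSE)
  tot_var <- stats::var(rowSums(x))
  if (tot_var == 0) stop("zero total-score variance: alpha undefined", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / tot_var)
}

# ML estimate of a single polychoric/tetrachoric correlation given fixed
# thresholds; two-step estimator, |rho| capped at 0.999
polychoric_rho <- function(tab, th_r, th_c) {
  a_r <- c(-Inf, th_r, Inf)
  a_c <- c(-Inf, th_c, Inf)
  nr <- length(a_r) - 1; nc <- length(a_c) - 1
  negll <- function(rho) {
    # cell probabilities from the bivariate normal CDF by inclusion-exclusion
    Phi2 <- matrix(0, nr + 1, nc + 1)
    for (i in seq_len(nr + 1)) for (j in seq_len(nc + 1)) {
      u <- a_r[i]; v <- a_c[j]
      Phi2[i, j] <-
        if (u == -Inf || v == -Inf) 0
        else if (u == Inf && v == Inf) 1
        else if (u == Inf) stats::pnorm(v)
        else if (v == Inf) stats::pnorm(u)
        else mvtnorm::pmvnorm(upper = c(u, v),
                              corr = matrix(c(1, rho, rho, 1), 2))[1]
    }
    p <- Phi2[-1, -1, drop = FALSE] - Phi2[-(nr + 1), -1, drop = FALSE] -
      Phi2[-1, -(nc + 1), drop = FALSE] +
      Phi2[-(nr + 1), -(nc + 1), drop = FALSE]
    p <- pmax(p, 1e-12)
    -sum(tab * log(p))
  }
  stats::optimize(negll, interval = c(-0.999, 0.999))$minimum
}

#' Polychoric (or tetrachoric) correlation matrix
#'
#' Two-step estimator: per-item thresholds from the inverse-normal of the
#' cumulative category margins, then per-pair maximum likelihood for the
#' latent bivariate-normal correlation over the contingency-table cell
#' probabilities. Pairwise-complete observations; items with a single
#' observed category are flagged and their entries left missing.
#'
#' @param data Respondent tibble (polytomous 1..4 or dichotomized 0/1 item
#'   columns).
#' @param items Item column names.
#' @return Object of class `hls_polychoric`: list with `rho` (items x items
#'   matrix, unit diagonal), `thresholds` (list per item), `kind`
#'   (`"polychoric"` or `"tetrachoric"`), and `degenerate` (flagged items).
#' @export
polychoric_matrix <- function(data, items = hls_items()) {
  x <- as.matrix(data[, items, drop = FALSE])
  k <- ncol(x)
  cats <- sort(unique(stats::na.omit(as.vector(x))))
  kind <- if (length(cats) <= 2) "tetrachoric" else "polychoric"
  thresholds <- vector("list", k)
  degenerate <- logical(k)
  for (i in seq_len(k)) {
    tabi <- table(factor(x[, i], levels = cats))
    degenerate[i] <- sum(tabi > 0) < 2
    cum <- cumsum(tabi) / sum(tabi)
    thresholds[[i]] <- stats::qnorm(cum[-length(cum)])
  }
  rho <- diag(1, k)
  dimnames(rho) <- list(items, items)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (degenerate[i] || degenerate[j]) {
      rho[i, j] <- rho[j, i] <- NA_real_
      next
    }
    ok <- !is.na(x[, i]) & !is.na(x[, j])
    tab <- table(factor(x[ok, i], levels = cats),
                 factor(x[ok, j], levels = cats))
    r <- polychoric_rho(tab, thresholds[[i]], thresholds[[j]])
    rho[i, j] <- rho[j, i] <- r
  }
  structure(list(rho = rho, thresholds = thresholds, kind = kind,
                 degenerate = stats::setNames(degenerate, items)),
            class = "hls_polychoric")
}

#' Ordinal alpha from a latent correlation matrix
#'
#' Standardized-alpha form applied to the polychoric/tetrachoric matrix:
#' \eqn{\alpha_{ord} = k\bar{r} / (1 + (k-1)\bar{r})} with \eqn{\bar{r}} the
#' mean off-diagonal latent correlation.
#'
#' @param poly `hls_polychoric` object or a correlation matrix.
#' @return Scalar ordinal alpha.
#' @export
ordinal_alpha <- function(poly) {
  r <- if (inherits(poly, "hls_polychoric")) poly$rho else as.matrix(poly)
  k <- ncol(r)
  off <- r[upper.tri(r)]
  if (anyNA(off)) stop("latent correlation matrix has missing entries", call. = FALSE)
  rbar <- mean(off)
  if (rbar <= -1 / (k - 1)) stop("mean correlation too negative: alpha undefined", call. = FALSE)
  k * rbar / (1 + (k - 1) * rbar)
}

#' Single-factor CFA on a correlation matrix of ordinal indicators
#'
#' Fits the one-factor model \eqn{r_{ij} \approx \lambda_i \lambda_j} by
#' minimising \eqn{\sum_{i<j} w_{ij} (r_{ij} - \lambda_i\lambda_j)^2}, with
#' unit weights (ULS) or diagonal weights equal to the inverse approximate
#' asymptotic variance of each correlation (DWLS,
#' \eqn{w_{ij} = n/(1-r_{ij}^2)^2}). Reported fit indices: SRMSR (root mean
#' squared residual correlation), and RMSEA/CFI/TLI from the weighted
#' discrepancy treated as a scaled chi-square against the zero-correlation
#' baseline. The mean-and-variance adjustment of full WLSMV estimation is
#' approximated by this mean-scaled statistic, so RMSEA/CFI/TLI can differ
#' from reference implementations in the second decimal; SRMSR and the
#' loadings are exact per the stated formulas.
#'
#' @param poly `hls_polychoric` object or correlation matrix.
#' @param n Sample size the correlations were estimated from.
#' @param estimator `"dwls"` (default) or `"uls"`.
#' @return Object of class `hls_cfa`: loadings, residual matrix, fit indices
#'   (`srmsr`, `rmsea`, `cfi`, `tli`), discrepancy, df, flags for
#'   non-convergence and Heywood cases.
#' @export
cfa_single_factor <- function(poly, n, estimator = c("dwls", "uls")) {
  estimator <- match.arg(estimator)
  r <- if (inherits(poly, "hls_polychoric")) poly$rho else as.matrix(poly)
  k <- ncol(r)
  if (n < 50) stop("CFA needs n >= 50", call. = FALSE)
  ut <- upper.tri(r)
  w <- if (estimator == "dwls") n / (1 - r^2)^2 else matrix(1, k, k)

  obj <- function(lam) {
    res <- r - tcrossprod(lam)
    sum(w[ut] * res[ut]^2)
  }
  grad <- function(lam) {
    res <- (r - tcrossprod(lam)) * w
    diag(res) <- 0
    -2 * drop(res %*% lam)
  }
  # start at the scaled first eigenvector
  ev <- eigen(r, symmetric = TRUE)
  lam0 <- ev$vectors[, 1] * sqrt(max(ev$values[1], 0.1))
  if (mean(lam0) < 0) lam0 <- -lam0
  opt <- stats::optim(lam0, obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  lam <- opt$par
  if (mean(lam) < 0) lam <- -lam
  residual <- r - tcrossprod(lam)
  diag(residual) <- 0
  srmsr <- sqrt(mean(residual[ut]^2))

  # scaled test statistic: weighted discrepancy (DWLS weights) as T
  w_t <- n / (1 - r^2)^2
  t_stat <- sum(w_t[ut] * residual[ut]^2)
  df <- k * (k - 1) / 2 - k
  t0 <- sum(w_t[ut] * r[ut]^2)
  df0 <- k * (k - 1) / 2
  rmsea <- sqrt(max(0, (t_stat - df) / (df * (n - 1))))
  cfi <- 1 - max(t_stat - df, 0) / max(t0 - df0, t_stat - df, 0)
  tli_num <- t0 / df0 - t_stat / df
  tli <- if (t0 / df0 > 1) tli_num / (t0 / df0 - 1) else NA_real_
  structure(list(
    loadings = stats::setNames(lam, colnames(r)),
    residual = residual, srmsr = srmsr, rmsea = rmsea,
    cfi = min(cfi, 1), tli = min(tli, 1),
    discrepancy = opt$value, statistic = t_stat, df = df, n = n,
    estimator = estimator,
    converged = opt$convergence == 0,
    heywood = any(abs(lam) > 1)
  ), class = "hls_cfa")
}

#' @export
print.hls_cfa <- function(x, ...) {
  cat("Single-factor CFA (", x$estimator, "), n = ", x$n, "\n", sep = "")
  cat(sprintf("  SRMSR %.3f  RMSEA %.3f  CFI %.3f  TLI %.3f\n",
              x$srmsr, x$rmsea, x$cfi, x$tli))
  cat("  loadings:", paste(sprintf("%.2f", x$loadings), collapse = " "), "\n")
  if (x$heywood) cat("  warning: Heywood case (|loading| > 1)\n")
  if (!x$converged) cat("  warning: optimiser did not report convergence\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.hls_cfa <- function(x, ...) {
  tibble::tibble(item = names(x$loadings), loading = unname(x$loadings))
}

#' @export
glance.hls_cfa <- function(x, ...) {
  tibble::tibble(srmsr = x$srmsr, rmsea = x$rmsea, cfi = x$cfi, tli = x$tli,
                 statistic = x$statistic, df = x$df, n = x$n,
                 estimator = x$estimator, converged = x$converged,
                 heywood = x$heywood)
}

#' Internal-consistency report for an item set
#'
#' Cronbach's alpha plus ordinal alpha (from the polychoric or tetrachoric
#' matrix), for the polytomous items and their dichotomized version.
#'
#' @param data Respondent tibble.
#' @param items Item column names.
#' @return Tibble with one row per variant (`polytomous`, `dichotomized`)
#'   and columns `cronbach`, `ordinal`, `k`, `n_complete`.
#' @export
alpha_report <- function(data, items = hls_items()) {
  dich <- dichotomize(data, items)
  mk <- function(d, variant) {
    tibble::tibble(
      variant = variant,
      cronbach = cronbach_alpha(d, items),
      ordinal = ordinal_alpha(polychoric_matrix(d, items)),
      k = length(items),
      n_complete = sum(stats::complete.cases(d[, items]))
    )
  }
  dplyr::bind_rows(mk(data, "polytomous"), mk(dich, "dichotomized"))
}
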