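# conditional category moments of each item at per-person trait values:
# matrices n x k of E, Var, and 4th central moment
pcm_fitted_moments <- function(fit, data, items = fit$items, theta = NULL) {
  if (is.null(theta)) {
    theta <- estimate_persons(fit, data, items = fit$items,
                              method = "wle")$theta
  }
  x <- irt_code_matrix(data, items)
  n <- nrow(x)
  k <- length(items)
  E <- W <- C4 <- matrix(NA_real_, n, k, dimnames = list(NULL, items))
  ok_t <- !is.na(theta)
  for (i in seq_len(k)) {
    d <- fit$delta[[match(items[i], fit$items)]]
    p <- exp(pcm_item_logprob(theta[ok_t], d))
    xs <- matrix(0:length(d), sum(ok_t), length(d) + 1, byrow = TRUE)
    mu <- rowSums(p * xs)
    E[ok_t, i] <- mu
    W[ok_t, i] <- rowSums(p * (xs - mu)^2)
    C4[ok_t, i] <- rowSums(p * (xs - mu)^4)
  }
  list(x = x, E = E, W = W, C4 = C4, theta = theta)
}

#' Item infit statistics with t standardisation
#'
#' Information-weighted mean-square residual per item,
#' \eqn{v_i = \sum_v (x_{vi} - E_{vi})^2 / \sum_v W_{vi}}, with conditional
#' moments evaluated at the WLE person estimates. The expected value is 1;
#' values above 1 flag underfit (the item is less predictable than the model
#' expects), below 1 overfit. The t statistic uses the Wilson--Hilferty
#' cube-root transformation. Flags follow the 0.8/1.2 elimination band, with
#' a screening note at 1.3.
#'
#' @param fit `pcm_fit`.
#' @param data Respondent tibble.
#' @param items Item column names.
#' @return Tibble: `item`, `infit`, `t`, `flag` (`"underfit"`, `"overfit"`,
#'   `"ok"`), `screen_1.3`.
#' @export
infit_stats <- function(fit, data, items = fit$items) {
  mo <- pcm_fitted_moments(fit, data, items)
  res2 <- (mo$x - mo$E)^2
  v <- colSums(res2, na.rm = TRUE) / colSums(mo$W * !is.na(mo$x), na.rm = TRUE)
  # variance of the mean square (kurtosis formula), then Wilson-Hilferty
  qsq <- colSums(mo$C4 - mo$W^2, na.rm = TRUE) /
    colSums(mo$W * !is.na(mo$x), na.rm = TRUE)^2
  qv <- sqrt(pmax(qsq, 1e-12))
  t_stat <- (v^(1 / 3) - 1) * (3 / qv) + qv / 3
  tibble::tibble(
    item = items, infit = unname(v), t = unname(t_stat),
    flag = dplyr::case_when(v > 1.2 ~ "underfit", v < 0.8 ~ "overfit",
                            TRUE ~ "ok"),
    screen_1.3 = v > 1.3
  )
}

#' Q3 family of local-dependence statistics
#'
#' Q3 is the Pearson correlation over persons of the standardised item
#' residuals \eqn{(x - E)/\sqrt{W}} at the WLE estimates; aQ3 centres Q3 at
#' its item-pair mean, and MADaQ3 (the effect size of model fit) is the mean
#' absolute aQ3. Per-pair p-values come from a Fisher-z test of aQ3 against
#' zero (an approximation, since the reference distribution of the centred
#' statistic is not exactly that of a correlation) with Holm adjustment over
#' all pairs. Pairs with fewer than 10 joint observations are excluded.
#'
#' @param fit `pcm_fit`.
#' @param data Respondent tibble.
#' @param items Item column names.
#' @param alpha Significance level for the Holm-adjusted decisions.
#' @return List of class `hls_q3`: `q3`, `aq3` (matrices), `madaq3`, `pairs`
#'   (tibble with `p_holm` and `significant`).
#' @export
q3_family <- function(fit, data, items = fit$items, alpha = 0.001) {
  stopifnot(length(items) >= 3)
  mo <- pcm_fitted_moments(fit, data, items)
  z <- (mo$x - mo$E) / sqrt(mo$W)
  q3 <- stats::cor(z, use = "pairwise.complete.obs")
  njoint <- crossprod(!is.na(z))
  q3[njoint < 10] <- NA
  diag(q3) <- 1
  ut <- upper.tri(q3)
  aq3 <- q3 - mean(q3[ut], na.rm = TRUE)
  diag(aq3) <- 0
  madaq3 <- mean(abs(aq3[ut]), na.rm = TRUE)
  pairs <- which(ut, arr.ind = TRUE)
  tb <- tibble::tibble(
    item_a = items[pairs[, 1]], item_b = items[pairs[, 2]],
    q3 = q3[ut], aq3 = aq3[ut], n = njoint[ut]
  )
  zst <- atanh(pmax(pmin(tb$aq3, 0.9999), -0.9999)) * sqrt(pmax(tb$n - 3, 1))
  tb$p <- 2 * stats::pnorm(-abs(zst))
  tb$p_holm <- stats::p.adjust(tb$p, "holm")
  tb$significant <- tb$p_holm < alpha
  structure(list(q3 = q3, aq3 = aq3, madaq3 = madaq3, pairs = tb,
                 alpha = alpha), class = "hls_q3")
}

#' @export
print.hls_q3 <- function(x, ...) {
  cat(sprintf("Q3 local-dependence analysis: MADaQ3 = %.4f, %d/%d pairs significant (Holm, alpha = %g)\n",
              x$madaq3, sum(x$pairs$significant, na.rm = TRUE),
              nrow(x$pairs), x$alpha))
  invisible(x)
}

#' SRMSR between observed and model-implied item correlations
#'
#' Root mean square difference between the observed Pearson correlations of
#' the item scores and the correlations implied by the fitted model, the
#' latter obtained by integrating the item score moments over the estimated
#' latent distribution on the quadrature grid.
#'
#' @param fit `pcm_fit`.
#' @param data Respondent tibble.
#' @param items Item column names.
#' @return Scalar SRMSR.
#' @export
srmsr_irt <- function(fit, data, items = fit$items) {
  x <- irt_code_matrix(data, items)
  r_obs <- stats::cor(x, use = "pairwise.complete.obs")
  a_t <- latent_weights(fit$grid, fit$sigma)
  k <- length(items)
  mu <- v <- matrix(0, length(fit$grid$theta), k)
  for (i in seq_len(k)) {
    d <- fit$delta[[match(items[i], fit$items)]]
    p <- exp(pcm_item_logprob(fit$grid$theta, d))
    xs <- matrix(0:length(d), nrow(p), length(d) + 1, byrow = TRUE)
    mu[, i] <- rowSums(p * xs)
    v[, i] <- rowSums(p * xs^2)
  }
  e1 <- drop(a_t %*% mu)
  e2 <- drop(a_t %*% v)
  exy <- t(mu) %*% (a_t * mu)
  covm <- exy - tcrossprod(e1)
  sds <- sqrt(e2 - e1^2)
  r_mod <- covm / tcrossprod(sds)
  ut <- upper.tri(r_obs)
  sqrt(mean((r_obs[ut] - r_mod[ut])^2, na.rm = TRUE))
}

#' Agresti--Coull binomial confidence interval
#'
#' Adjusted-Wald interval: \eqn{\tilde{n} = n + z^2},
#' \eqn{\tilde{p} = (x + z^2/2)/\tilde{n}}, bounds
#' \eqn{\tilde{p} \pm z \sqrt{\tilde{p}(1-\tilde{p})/\tilde{n}}}.
#'
#' @param x Number of successes (may be non-integer when reconstructed from
#'   a rounded proportion).
#' @param n Number of trials.
#' @param z Critical value, default 1.96 (95%).
#' @return Tibble with `estimate`, `lower`, `upper`.
#' @export
#' @examples
#' agresti_coull(0.021 * 900, 900)  # lower bound 0.013
agresti_coull <- function(x, n, z = 1.96) {
  stopifnot(n > 0, x >= 0, x <= n)
  n_t <- n + z^2
  p_t <- (x + z^2 / 2) / n_t
  half <- z * sqrt(p_t * (1 - p_t) / n_t)
  tibble::tibble(estimate = x / n,
                 lower = max(0, p_t - half), upper = min(1, p_t + half))
}

#' PCA/t-test unidimensionality check
#'
#' Standardised residuals are decomposed by principal components; items are
#' split into two subsets by the sign of their loading on the first
#' component (zero loadings join the positive set). Person parameters are
#' then WLE-estimated in each subset and compared per person with
#' \eqn{t_v = (\hat\theta_1 - \hat\theta_2)/\sqrt{SE_1^2 + SE_2^2}},
#' significant when \eqn{|t_v| > 1.96}. Unidimensionality is supported when
#' the proportion of significant comparisons is at most 5% or the lower
#' bound of its 95% Agresti--Coull interval is at most 5%.
#'
#' @param fit `pcm_fit`.
#' @param data Respondent tibble.
#' @param items Item column names (at least 4).
#' @return List of class `hls_pca_ttest`: `proportion`, `ci` (tibble),
#'   `supported`, `subsets`, `n_tested`.
#' @export
pca_ttest_unidim <- function(fit, data, items = fit$items) {
  stopifnot(length(items) >= 4)
  mo <- pcm_fitted_moments(fit, data, items)
  z <- (mo$x - mo$E) / sqrt(mo$W)
  cz <- stats::cor(z, use = "pairwise.complete.obs")
  cz[is.na(cz)] <- 0
  load1 <- eigen(cz, symmetric = TRUE)$vectors[, 1]
  if (sum(load1 >= 0) < sum(load1 < 0)) load1 <- -load1
  set1 <- items[load1 >= 0]
  set2 <- items[load1 < 0]
  if (length(set1) == 0 || length(set2) == 0) {
    return(structure(list(proportion = NA_real_, ci = NULL, supported = NA,
                          subsets = list(set1, set2), n_tested = 0L,
                          inconclusive = TRUE), class = "hls_pca_ttest"))
  }
  e1 <- estimate_persons(fit, data, items = set1, method = "wle")
  e2 <- estimate_persons(fit, data, items = set2, method = "wle")
  ok <- !is.na(e1$theta) & !is.na(e2$theta)
  t_v <- (e1$theta - e2$theta) / sqrt(e1$se^2 + e2$se^2)
  sig <- abs(t_v[ok]) > 1.96
  prop <- mean(sig)
  ci <- agresti_coull(sum(sig), sum(ok))
  structure(list(
    proportion = prop, ci = ci,
    supported = prop <= 0.05 || ci$lower <= 0.05,
    subsets = list(positive = set1, negative = set2),
    n_tested = sum(ok), inconclusive = FALSE
  ), class = "hls_pca_ttest")
}

#' @export
print.hls_pca_ttest <- function(x, ...) {
  if (isTRUE(x$inconclusive)) {
    cat("PCA/t-test: inconclusive (one residual subset empty)\n")
    return(invisible(x))
  }
  cat(sprintf("PCA/t-test unidimensionality check: %.1f%% significant (CI lower %.1f%%), n = %d\n",
              100 * x$proportion, 100 * x$ci$lower, x$n_tested))
  cat("  unidimensionality", if (x$supported) "supported" else "not supported", "\n")
  invisible(x)
}

#' Andersen conditional likelihood-ratio test
#'
#' Global test of item-parameter invariance across the groups of a split
#' criterion: \eqn{LR = 2(\sum_g \hat\ell_g - \hat\ell_{pooled})} with CML
#' log-likelihoods, \eqn{df = (k-1)(G-1)}. Aborts naming the subgroup when a
#' subgroup's data are ill-conditioned.
#'
#' @param data Respondent tibble with 0/1 item columns.
#' @param split Factor (or vector) defining the groups.
#' @param items Item column names.
#' @param alpha Decision level.
#' @return Tibble: `lr`, `df`, `p`, `significant`.
#' @export
andersen_lr <- function(data, split, items = hls_items(), alpha = 0.001) {
  split <- as.factor(split)
  stopifnot(nrow(data) == length(split), nlevels(split) >= 2)
  pooled <- fit_rm_cml(data, items)
  ll_g <- vapply(levels(split), function(g) {
    sub <- data[split == g, , drop = FALSE]
    fit <- tryCatch(fit_rm_cml(sub, items), error = function(e) {
      stop("subgroup '", g, "': ", conditionMessage(e), call. = FALSE)
    })
    fit$cll
  }, numeric(1))
  lr <- 2 * (sum(ll_g) - pooled$cll)
  df <- (length(items) - 1) * (nlevels(split) - 1)
  p <- stats::pchisq(lr, df, lower.tail = FALSE)
  tibble::tibble(lr = lr, df = df, p = p, significant = p < alpha)
}

#' Per-item Wald z statistics across a split
#'
#' After fitting the Rasch model separately in the two groups (common
#' sum-to-zero normalisation), \eqn{z_i = (\hat\beta_i^{(1)} -
#' \hat\beta_i^{(2)}) / \sqrt{SE_1^2 + SE_2^2}} locates which items carry a
#' global misfit.
#'
#' @inheritParams andersen_lr
#' @return Tibble: `item`, `beta_1`, `beta_2`, `z`, `p`, `significant`.
#' @export
wald_item_z <- function(data, split, items = hls_items(), alpha = 0.001) {
  split <- as.factor(split)
  stopifnot(nlevels(split) == 2)
  fits <- lapply(levels(split), function(g) {
    tryCatch(fit_rm_cml(data[split == g, , drop = FALSE], items),
             error = function(e) {
               stop("subgroup '", g, "': ", conditionMessage(e), call. = FALSE)
             })
  })
  z <- (fits[[1]]$beta - fits[[2]]$beta) /
    sqrt(fits[[1]]$se^2 + fits[[2]]$se^2)
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(item = items, beta_1 = unname(fits[[1]]$beta),
                 beta_2 = unname(fits[[2]]$beta), z = unname(z),
                 p = unname(p), significant = p < alpha)
}

#' Data for the graphical model test and ICC plots
#'
#' Item difficulties estimated separately in two groups (both sum-to-zero
#' normalised) with 95% confidence radii around the identity line, plus
#' empirical-vs-model ICC data: per raw-score group, the observed proportion
#' of positive responses per item against the model probability at the
#' score-group ability.
#'
#' @inheritParams wald_item_z
#' @return List of class `hls_graphical_test`: `items` (tibble with `beta_1`,
#'   `se_1`, `beta_2`, `se_2`, `radius`), `icc` (tibble with `item`,
#'   `raw_score`, `observed`, `expected`, `n`).
#' @export
graphical_test_data <- function(data, split, items = hls_items()) {
  split <- as.factor(split)
  stopifnot(nlevels(split) == 2)
  fits <- lapply(levels(split), function(g) {
    fit_rm_cml(data[split == g, , drop = FALSE], items)
  })
  item_tb <- tibble::tibble(
    item = items,
    beta_1 = unname(fits[[1]]$beta), se_1 = unname(fits[[1]]$se),
    beta_2 = unname(fits[[2]]$beta), se_2 = unname(fits[[2]]$se),
    radius = 1.96 * sqrt(fits[[1]]$se^2 + fits[[2]]$se^2)
  )
  # ICC: pooled fit; ability per raw-score group solves the ML score equation
  pooled <- fit_rm_cml(data, items)
  x <- irt_code_matrix(data, items)
  complete <- stats::complete.cases(x)
  xc <- x[complete, , drop = FALSE]
  r <- rowSums(xc)
  k <- length(items)
  icc <- purrr::map_dfr(seq_len(k - 1), function(score) {
    idx <- r == score
    if (!any(idx)) return(NULL)
    th <- stats::uniroot(function(t) {
      sum(stats::plogis(t - pooled$beta)) - score
    }, c(-12, 12))$root
    tibble::tibble(
      item = items, raw_score = score,
      observed = colMeans(xc[idx, , drop = FALSE]),
      expected = stats::plogis(th - pooled$beta),
      n = sum(idx)
    )
  })
  structure(list(items = item_tb, icc = icc,
                 groups = levels(split)), class = "hls_graphical_test")
}

#' Facets DIF analysis for the Partial Credit Model
#'
#' Extends the PCM with a group facet: all steps of item i are shifted by
#' \eqn{\tau_{ig}} for group g, with double sum-to-zero identification
#' (\eqn{\sum_g \tau_{ig} = 0} per item, \eqn{\sum_i \tau_{ig} = 0} per
#' group); group-level ability differences are absorbed by group-specific
#' latent means. Estimated by MML-EM; each item's interaction parameter is
#' tested by a Wald statistic with the standard error taken from the
#' curvature of the profile marginal log-likelihood.
#'
#' @param data Respondent tibble.
#' @param group Two-level factor (or vector) of group labels.
#' @param items Item column names.
#' @param q Quadrature nodes.
#' @param tol EM convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param alpha Decision level.
#' @return Object of class `hls_dif_facets`: tibble `dif` with `item`,
#'   `tau_1`, `tau_2`, `se`, `z`, `p`, `significant`; plus `group_means`,
#'   `sigma`, `delta`.
#' @export
dif_facets_pcm <- function(data, group, items = hls_items(), q = 31,
                           tol = 1e-4, max_iter = 200, alpha = 0.001) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2, nrow(data) == length(group))
  x <- irt_code_matrix(data, items)
  k <- length(items)
  m_i <- apply(x, 2, max, na.rm = TRUE)
  gi <- as.integer(group)
  n_g <- tabulate(gi, 2)
  grid <- gh_grid(q)
  nt <- length(grid$theta)

  delta <- lapply(m_i, function(m) seq(-0.5, 0.5, length.out = m))
  tau <- rep(0, k)  # tau_i1 = tau[i], tau_i2 = -tau[i]
  mu <- c(0, 0)
  sigma <- 1

  marg_ll <- function(delta, tau, mu, sigma) {
    ll <- 0
    for (g in 1:2) {
      idx <- gi == g
      log_a <- latent_logweights(grid, sigma, mean = mu[g])
      ll_vt <- matrix(0, sum(idx), nt)
      sg <- if (g == 1) 1 else -1
      for (i in seq_len(k)) {
        lp <- pcm_item_logprob(grid$theta, delta[[i]] + sg * tau[i])
        xi <- x[idx, i]; ok <- !is.na(xi)
        ll_vt[ok, ] <- ll_vt[ok, ] + t(lp[, xi[ok] + 1L, drop = FALSE])
      }
      wll <- sweep(ll_vt, 2, log_a, `+`)
      mx <- apply(wll, 1, max)
      ll <- ll + sum(log(rowSums(exp(wll - mx))) + mx)
    }
    ll
  }

  for (iter in seq_len(max_iter)) {
    old <- c(unlist(delta), tau, mu, sigma)
    # E-step per group
    posts <- n_tx_g <- vector("list", 2)
    for (g in 1:2) {
      idx <- gi == g
      log_a <- latent_logweights(grid, sigma, mean = mu[g])
      ll_vt <- matrix(0, sum(idx), nt)
      sg <- if (g == 1) 1 else -1
      for (i in seq_len(k)) {
        lp <- pcm_item_logprob(grid$theta, delta[[i]] + sg * tau[i])
        xi <- x[idx, i]; ok <- !is.na(xi)
        ll_vt[ok, ] <- ll_vt[ok, ] + t(lp[, xi[ok] + 1L, drop = FALSE])
      }
      wll <- sweep(ll_vt, 2, log_a, `+`)
      mx <- apply(wll, 1, max)
      lw <- exp(wll - mx)
      posts[[g]] <- lw / rowSums(lw)
    }
    # M-step items: per item optimise (delta_i, tau_i)
    for (i in seq_len(k)) {
      ntx <- lapply(1:2, function(g) {
        idx <- gi == g
        xi <- x[idx, i]; ok <- !is.na(xi)
        t(posts[[g]][ok, , drop = FALSE]) %*% outer(xi[ok], 0:m_i[i], `==`)
      })
      par0 <- c(delta[[i]], tau[i])
      negE <- function(par) {
        d <- par[seq_len(m_i[i])]; tt <- par[m_i[i] + 1]
        -sum(ntx[[1]] * pcm_item_logprob(grid$theta, d + tt)) -
          sum(ntx[[2]] * pcm_item_logprob(grid$theta, d - tt))
      }
      opt <- stats::optim(par0, negE, method = "BFGS",
                          control = list(maxit = 100))
      delta[[i]] <- opt$par[seq_len(m_i[i])]
      tau[i] <- opt$par[m_i[i] + 1]
    }
    # identification: item-mean of tau into the group means
    c_shift <- mean(tau)
    tau <- tau - c_shift
    mu <- mu - c(c_shift, -c_shift)
    # latent distribution updates
    n_t1 <- colSums(posts[[1]]); n_t2 <- colSums(posts[[2]])
    mu[1] <- stats::optimize(function(m) {
      latent_objective(n_t1, grid, sigma, mean = m)
    }, c(-4, 4), maximum = TRUE)$maximum
    mu[2] <- stats::optimize(function(m) {
      latent_objective(n_t2, grid, sigma, mean = m)
    }, c(-4, 4), maximum = TRUE)$maximum
    sigma <- stats::optimize(function(s) {
      latent_objective(n_t1, grid, s, mean = mu[1]) +
        latent_objective(n_t2, grid, s, mean = mu[2])
    }, c(0.05, 8), maximum = TRUE)$maximum
    # overall latent mean zero
    wm <- sum(n_g * mu) / sum(n_g)
    mu <- mu - wm
    delta <- lapply(delta, function(d) d - wm)
    if (max(abs(c(unlist(delta), tau, mu, sigma) - old)) < tol) break
  }

  # Wald tests from the profile curvature in tau_i
  h <- 0.05
  ll0 <- marg_ll(delta, tau, mu, sigma)
  se <- z <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    tp <- tau; tp[i] <- tau[i] + h
    tm <- tau; tm[i] <- tau[i] - h
    d2 <- (marg_ll(delta, tp, mu, sigma) - 2 * ll0 +
             marg_ll(delta, tm, mu, sigma)) / h^2
    if (d2 < 0) {
      se[i] <- 1 / sqrt(-d2)
      z[i] <- tau[i] / se[i]
    }
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(
    dif = tibble::tibble(item = items, tau_1 = tau, tau_2 = -tau,
                         se = se, z = z, p = p,
                         significant = !is.na(p) & p < alpha),
    group_means = stats::setNames(mu, levels(group)),
    sigma = sigma, delta = stats::setNames(delta, items),
    converged = iter < max_iter, iterations = iter, alpha = alpha
  ), class = "hls_dif_facets")
}

#' @export
print.hls_dif_facets <- function(x, ...) {
  cat("Facets DIF analysis (PCM + group + item x group)\n")
  cat(sprintf("  groups %s: latent means %.3f / %.3f, sigma %.3f\n",
              paste(names(x$group_means), collapse = " vs "),
              x$group_means[1], x$group_means[2], x$sigma))
  sig <- x$dif$item[x$dif$significant]
  cat("  significant items (alpha =", x$alpha, "):",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @export
tidy.hls_dif_facets <- function(x, ...) x$dif

#' Well-conditioned-data check for CML estimation
#'
#' A unique CML solution for the Rasch item parameters exists iff the data
#' are well-conditioned: in every partition of the items into two non-empty
#' subsets, some person scored 1 on an item of the first subset and 0 on an
#' item of the second. Equivalently, the digraph with an edge i -> j
#' whenever some person has 1 on i and 0 on j is strongly connected; if it
#' is not, a sink strongly-connected component yields a violating
#' partition.
#'
#' @param data Respondent tibble with 0/1 item columns.
#' @param items Item column names.
#' @return List: `well_conditioned` (logical), `partition` (list of the two
#'   item sets witnessing a violation, or `NULL`).
#' @export
well_conditioned_check <- function(data, items = hls_items()) {
  x <- irt_code_matrix(data, items)
  if (any(x > 1L, na.rm = TRUE)) {
    stop("well-conditioned check applies to dichotomous (0/1) data",
         call. = FALSE)
  }
  k <- length(items)
  adj <- matrix(FALSE, k, k)
  one <- !is.na(x) & x == 1L
  zero <- !is.na(x) & x == 0L
  # edge i -> j iff some person has 1 on i and 0 on j
  adj <- (t(one) %*% zero) > 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  if (comp$no == 1) {
    return(list(well_conditioned = TRUE, partition = NULL))
  }
  # find a sink component: no edges leaving it
  for (cc in seq_len(comp$no)) {
    members <- which(comp$membership == cc)
    if (!any(adj[members, -members, drop = FALSE])) {
      return(list(well_conditioned = FALSE,
                  partition = list(items[members], items[-members])))
    }
  }
  # unreachable: a finite DAG of components always has a sink
  list(well_conditioned = FALSE,
       partition = list(items[comp$membership == 1],
                        items[comp$membership != 1]))
}

# attempt `steps` random 2x2 checkerboard swaps on a binary matrix; every
# accepted swap preserves all row and column sums
margin_swap <- function(m, steps) {
  n <- nrow(m); k <- ncol(m)
  rows <- sample.int(n, 2 * steps, replace = TRUE)
  cols <- sample.int(k, 2 * steps, replace = TRUE)
  for (s in seq_len(steps)) {
    r1 <- rows[2 * s - 1]; r2 <- rows[2 * s]
    c1 <- cols[2 * s - 1]; c2 <- cols[2 * s]
    if (r1 == r2 || c1 == c2) next
    a <- m[r1, c1]; b <- m[r1, c2]; cc <- m[r2, c1]; d <- m[r2, c2]
    if (a == d && b == cc && a != b) {  # checkerboard
      m[r1, c1] <- b; m[r1, c2] <- a
      m[r2, c1] <- d; m[r2, c2] <- cc
    }
  }
  m
}

#' Global test for local independence under the Rasch model
#'
#' Test statistic \eqn{T = \sum_{i<j} |r^{obs}_{ij} - \bar{r}_{ij}|}, where
#' \eqn{\bar{r}} is the mean inter-item correlation over binary matrices
#' sampled uniformly from the set with the observed row and column margins
#' (margin-preserving checkerboard-swap MCMC with burn-in and thinning);
#' the p-value is the share of sampled statistics at least as large as the
#' observed one. Constant rows cannot move and constant columns are
#' excluded from the correlations.
#'
#' @param data Respondent tibble with 0/1 item columns.
#' @param items Item column names.
#' @param n_samples Number of sampled matrices.
#' @param burnin Initial swap attempts before sampling; defaults to 10 times
#'   the number of cells, enough for the chain to forget the observed
#'   matrix.
#' @param thin Swap attempts between samples; defaults to the number of
#'   cells.
#' @return Tibble: `statistic`, `p`, `n_samples`, `excluded_items`.
#' @export
global_local_independence_rm <- function(data, items = hls_items(),
                                         n_samples = 500, burnin = NULL,
                                         thin = NULL) {
  x <- irt_code_matrix(data, items)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  keep <- apply(x, 2, function(col) length(unique(col)) > 1)
  excluded <- items[!keep]
  xk <- x[, keep, drop = FALSE]
  k <- ncol(xk)
  ut <- upper.tri(diag(k))
  cor_vec <- function(m) stats::cor(m)[ut]
  r_obs <- cor_vec(xk)

  cur <- xk
  n <- nrow(cur)
  if (is.null(burnin)) burnin <- 10L * n * k
  if (is.null(thin)) thin <- n * k
  cur <- margin_swap(cur, burnin)
  rs <- matrix(NA_real_, n_samples, sum(ut))
  for (s in seq_len(n_samples)) {
    cur <- margin_swap(cur, thin)
    rs[s, ] <- cor_vec(cur)
  }
  r_bar <- colMeans(rs)
  t_obs <- sum(abs(r_obs - r_bar))
  t_null <- rowSums(abs(sweep(rs, 2, r_bar)))
  tibble::tibble(statistic = t_obs, p = mean(t_null >= t_obs),
                 n_samples = n_samples,
                 excluded_items = list(excluded))
}

#' Split a respondent table into disjoint random subsamples
#'
#' Replication harness for running the diagnostic battery on independent
#' subsamples of a large survey.
#'
#' @param data Respondent tibble.
#' @param n_groups Number of disjoint subsamples.
#' @return List of tibbles.
#' @export
random_subsamples <- function(data, n_groups = 4) {
  idx <- sample(rep_len(seq_len(n_groups), nrow(data)))
  lapply(seq_len(n_groups), function(g) data[idx == g, , drop = FALSE])
}
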