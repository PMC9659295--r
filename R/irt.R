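#' Elementary symmetric functions
#'
#' Computes \eqn{\gamma_0, \ldots, \gamma_k} of the item easiness parameters
#' by the summation algorithm, the numerically stable recursion used in
#' conditional maximum likelihood estimation of the Rasch model:
#' \eqn{\sum_r \gamma_r t^r = \prod_i (1 + \epsilon_i t)}.
#'
#' @param eps Numeric vector of item easiness parameters
#'   \eqn{\epsilon_i = e^{-\beta_i}}.
#' @return Numeric vector of length `length(eps) + 1`, with `gamma[1] = 1`.
#' @export
#' @examples
#' esf(c(1, 1))  # binomial coefficients 1 2 1
esf <- function(eps) {
  stopifnot(all(is.finite(eps)))
  g <- c(1, rep(0, length(eps)))
  for (e in eps) {
    k <- which(g != 0)
    g[k + 1] <- g[k + 1] + e * g[k]
  }
  g
}

# leave-one-out ESFs: row i = gamma^{(i)} of eps[-i], padded with 0
esf_loo <- function(eps) {
  k <- length(eps)
  out <- matrix(0, k, k + 1)
  for (i in seq_len(k)) out[i, 1:k] <- esf(eps[-i])
  out
}

# shared internals ----------------------------------------------------------

# 0-based integer category matrix; raw codes 1..m+1 are shifted, 0/1 kept
irt_code_matrix <- function(data, items) {
  x <- resp_matrix(data, items)
  mn <- suppressWarnings(min(x, na.rm = TRUE))
  if (is.finite(mn) && mn >= 1L) x <- x - 1L
  x
}

# log category probabilities of one PCM item at a vector of trait values:
# matrix length(theta) x (m+1)
pcm_item_logprob <- function(theta, delta) {
  m <- length(delta)
  eta <- matrix(0:m, length(theta), m + 1, byrow = TRUE) * theta +
    matrix(c(0, -cumsum(delta)), length(theta), m + 1, byrow = TRUE)
  eta - log(rowSums(exp(eta - apply(eta, 1, max)))) - apply(eta, 1, max)
}

# Gauss-Hermite nodes mapped to the real line: fixed node locations
# theta_t = sqrt(2) x_t with base weights b_t such that
# sum_t b_t f(theta_t) ~ int f(theta) dtheta. Nodes whose raw weight
# underflows to zero carry no usable information and are dropped; the log
# base weights are kept so all downstream work can stay in log space.
gh_grid <- function(q) {
  gh <- pracma::gaussHermite(q)
  keep <- gh$w > 0
  list(theta = sqrt(2) * gh$x[keep],
       log_base = log(gh$w[keep]) + gh$x[keep]^2 + 0.5 * log(2))
}

# log of the normalized latent weights A_t(sigma) on the fixed grid
latent_logweights <- function(grid, sigma, mean = 0) {
  la <- grid$log_base + stats::dnorm(grid$theta, mean, sigma, log = TRUE)
  mx <- max(la)
  la - (mx + log(sum(exp(la - mx))))
}

# normalized latent weights A_t(sigma)
latent_weights <- function(grid, sigma, mean = 0) {
  exp(latent_logweights(grid, sigma, mean))
}

# expected log-likelihood of the latent distribution parameters given
# expected node occupancies; -Inf log-weights at empty nodes contribute 0
latent_objective <- function(n_t, grid, sigma, mean = 0) {
  la <- latent_logweights(grid, sigma, mean)
  sum(n_t[n_t > 0] * la[n_t > 0])
}

# Rasch model by conditional maximum likelihood ------------------------------

#' Fit the dichotomous Rasch model by conditional maximum likelihood
#'
#' Maximises the likelihood conditional on the raw scores, which are
#' sufficient for the person parameters; persons with extreme raw scores (0
#' or all items) contribute nothing. Item difficulties are reported under
#' the sum-to-zero normalisation; standard errors come from the observed
#' information, mapped through the normalisation. Estimation requires
#' well-conditioned data (see [well_conditioned_check()]); otherwise the fit
#' aborts and names a violating item partition.
#'
#' @param data Respondent tibble with 0/1 item columns (see
#'   [dichotomize()]).
#' @param items Item column names.
#' @return Object of class `rm_fit`: `beta` (difficulties, sum-to-zero),
#'   `se`, `cll` (conditional log-likelihood), `n_used`, `items`.
#' @export
fit_rm_cml <- function(data, items = hls_items()) {
  x <- irt_code_matrix(data, items)
  if (any(x > 1L, na.rm = TRUE)) {
    stop("fit_rm_cml expects dichotomous (0/1) responses", call. = FALSE)
  }
  wc <- well_conditioned_check(data, items)
  if (!wc$well_conditioned) {
    stop("ill-conditioned data: no response evidence across the partition {",
         paste(wc$partition[[1]], collapse = ","), "} vs {",
         paste(wc$partition[[2]], collapse = ","), "}", call. = FALSE)
  }
  k <- length(items)

  # group persons by observed-item pattern; extreme scores drop out
  obs_pat <- apply(!is.na(x), 1, paste, collapse = "")
  groups <- split(seq_len(nrow(x)), obs_pat)
  blocks <- list()
  for (g in groups) {
    s <- which(!is.na(x[g[1], ]))
    if (length(s) < 2) next
    r <- rowSums(x[g, s, drop = FALSE])
    keep <- r > 0 & r < length(s)
    if (!any(keep)) next
    blocks[[length(blocks) + 1]] <- list(
      items = s,
      score_tab = tabulate(r[keep], nbins = length(s) - 1),
      item_sums = colSums(x[g[keep], s, drop = FALSE]),
      n = sum(keep)
    )
  }
  if (length(blocks) == 0) stop("no persons with non-extreme scores", call. = FALSE)
  n_used <- sum(vapply(blocks, `[[`, numeric(1), "n"))

  # beta_1 fixed at 0 during optimisation; recentred afterwards
  negll <- function(bfree) {
    b <- c(0, bfree)
    ll <- 0
    for (bl in blocks) {
      eps <- exp(-b[bl$items])
      g <- esf(eps)
      r <- seq_along(bl$score_tab)
      ll <- ll - sum(bl$item_sums * b[bl$items]) -
        sum(bl$score_tab * log(g[r + 1]))
    }
    -ll
  }
  neggr <- function(bfree) {
    b <- c(0, bfree)
    gr <- numeric(k)
    for (bl in blocks) {
      eps <- exp(-b[bl$items])
      g <- esf(eps)
      gl <- esf_loo(eps)
      r <- seq_along(bl$score_tab)
      # expected item totals: sum_r n_r * eps_i gamma^(i)_{r-1} / gamma_r
      expd <- vapply(seq_along(bl$items), function(ii) {
        sum(bl$score_tab * eps[ii] * gl[ii, r] / g[r + 1])
      }, numeric(1))
      gr[bl$items] <- gr[bl$items] + (-bl$item_sums + expd)
    }
    -gr[-1]
  }
  opt <- stats::optim(rep(0, k - 1), negll, neggr, method = "BFGS",
                      hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-14))
  beta <- c(0, opt$par)
  # sum-to-zero recentring and covariance mapping
  m_center <- diag(k) - matrix(1 / k, k, k)
  cov_free <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, k - 1, k - 1)
  })
  a <- m_center[, -1, drop = FALSE]  # beta_1 is a constant
  cov_sz <- a %*% cov_free %*% t(a)
  structure(list(
    beta = stats::setNames(beta - mean(beta), items),
    se = stats::setNames(sqrt(pmax(diag(cov_sz), 0)), items),
    vcov = cov_sz,
    cll = -opt$value, n_used = n_used, items = items,
    converged = opt$convergence == 0
  ), class = "rm_fit")
}

#' @export
print.rm_fit <- function(x, ...) {
  cat("Rasch model (CML), ", length(x$beta), " items, ",
      x$n_used, " informative persons, cll = ", sprintf("%.2f", x$cll),
      "\n", sep = "")
  print(round(x$beta, 3))
  invisible(x)
}

#' @export
tidy.rm_fit <- function(x, ...) {
  tibble::tibble(item = names(x$beta), beta = unname(x$beta),
                 se = unname(x$se))
}

#' @export
glance.rm_fit <- function(x, ...) {
  tibble::tibble(cll = x$cll, n_used = x$n_used, k = length(x$beta),
                 converged = x$converged)
}

# Partial Credit Model by MML-EM ---------------------------------------------

# Newton maximisation of the expected complete-data log-likelihood of one
# PCM item given expected counts n_tx (nodes x categories) at node
# locations theta
pcm_mstep_item <- function(delta, theta, n_tx, max_iter = 20, tol = 1e-9) {
  m <- length(delta)
  n_t <- rowSums(n_tx)
  # observed "step exceedance" totals: sum over t,x of n_tx * 1{x >= l}
  obs_ge <- vapply(1:m, function(l) sum(n_tx[, (l + 1):(m + 1), drop = FALSE]),
                   numeric(1))
  eval_ll <- function(d) {
    lp <- pcm_item_logprob(theta, d)
    sum(n_tx * lp)
  }
  ll <- eval_ll(delta)
  for (it in seq_len(max_iter)) {
    p <- exp(pcm_item_logprob(theta, delta))
    # E_t[s_l] = P(X >= l | theta_t)
    s_ge <- t(apply(p, 1, function(pr) rev(cumsum(rev(pr)))))[, -1, drop = FALSE]
    grad <- -obs_ge + colSums(n_t * s_ge)
    hess <- matrix(0, m, m)
    for (l in 1:m) for (mm in 1:m) {
      lm <- max(l, mm)
      hess[l, mm] <- -sum(n_t * (s_ge[, lm] - s_ge[, l] * s_ge[, mm]))
    }
    step <- tryCatch(solve(hess, grad), error = function(e) grad * 0.1)
    # gradient is of the maximisation problem; Newton: delta - H^{-1} g
    new_delta <- delta - step
    new_ll <- eval_ll(new_delta)
    halvings <- 0
    while (new_ll < ll && halvings < 10) {
      new_delta <- (delta + new_delta) / 2
      new_ll <- eval_ll(new_delta)
      halvings <- halvings + 1
    }
    if (new_ll < ll) break
    moved <- max(abs(new_delta - delta))
    delta <- new_delta
    ll <- new_ll
    if (moved < tol) break
  }
  delta
}

#' Fit the Partial Credit Model by marginal maximum likelihood
#'
#' EM estimation with Gauss--Hermite quadrature on a fixed node grid; the
#' latent trait is normal with mean fixed at 0 and estimated sd. The
#' marginal log-likelihood is non-decreasing across iterations (fixed-grid
#' EM); convergence when the largest parameter change falls below `tol`.
#' Missing responses drop out of the person's likelihood factor (ignorable
#' missingness). Items with unobserved categories are collapsed onto their
#' observed, consecutive categories with a warning. Standard errors are
#' outer-product-of-gradients (BHHH) estimates.
#'
#' @param data Respondent tibble (raw codes 1..m+1 or 0-based categories;
#'   dichotomous 0/1 data give a 2-category PCM).
#' @param items Item column names.
#' @param q Number of quadrature nodes.
#' @param tol Convergence tolerance on the largest absolute parameter
#'   change.
#' @param max_iter Maximum EM iterations.
#' @return Object of class `pcm_fit`: `delta` (list of step-parameter
#'   vectors per item), `se` (matching list), `sigma`, `loglik` (trace),
#'   `grid`, `n`, `converged`, `iterations`, `category_maps`.
#' @export
fit_pcm_mml <- function(data, items = hls_items(), q = 31, tol = 1e-5,
                        max_iter = 500) {
  x <- irt_code_matrix(data, items)
  k <- length(items)
  n <- nrow(x)

  # collapse unobserved categories onto consecutive observed codes
  category_maps <- vector("list", k)
  for (i in seq_len(k)) {
    obs <- sort(unique(stats::na.omit(x[, i])))
    if (length(obs) < 2) {
      stop("item ", items[i], " has fewer than 2 observed categories",
           call. = FALSE)
    }
    full <- seq(min(obs), max(obs))
    if (length(obs) < length(full)) {
      warning("item ", items[i],
              ": unobserved categories collapsed onto observed ones",
              call. = FALSE)
    }
    category_maps[[i]] <- obs
    x[, i] <- match(x[, i], obs) - 1L
  }
  m_i <- vapply(category_maps, function(z) length(z) - 1L, integer(1))

  grid <- gh_grid(q)
  nt <- length(grid$theta)
  delta <- lapply(m_i, function(m) seq(-0.5, 0.5, length.out = m))
  sigma <- 1
  loglik_trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    log_a <- latent_logweights(grid, sigma)
    # E-step: person x node log-likelihoods
    ll_vt <- matrix(0, n, nt)
    logp_list <- vector("list", k)
    for (i in seq_len(k)) {
      lp <- pcm_item_logprob(grid$theta, delta[[i]])  # nt x (m+1)
      logp_list[[i]] <- lp
      xi <- x[, i]
      ok <- !is.na(xi)
      ll_vt[ok, ] <- ll_vt[ok, ] + t(lp[, xi[ok] + 1L, drop = FALSE])
    }
    wll <- sweep(ll_vt, 2, log_a, `+`)
    mx <- apply(wll, 1, max)
    lw <- exp(wll - mx)
    marg <- rowSums(lw)
    loglik <- sum(log(marg) + mx)
    loglik_trace <- c(loglik_trace, loglik)
    post <- lw / marg  # n x nt posterior weights

    # M-step: items
    old_delta <- delta
    old_sigma <- sigma
    for (i in seq_len(k)) {
      xi <- x[, i]
      ok <- !is.na(xi)
      n_tx <- t(post[ok, , drop = FALSE]) %*%
        outer(xi[ok], 0:m_i[i], `==`)  # nt x (m+1)
      delta[[i]] <- pcm_mstep_item(delta[[i]], grid$theta, n_tx)
    }
    # M-step: sigma from the expected node occupancies
    n_t <- colSums(post)
    sigma <- stats::optimize(function(s) {
      latent_objective(n_t, grid, s)
    }, interval = c(0.05, 8), maximum = TRUE)$maximum

    moved <- max(abs(unlist(delta) - unlist(old_delta)), abs(sigma - old_sigma))
    if (moved < tol) {
      converged <- TRUE
      break
    }
  }

  fit <- structure(list(
    delta = stats::setNames(delta, items),
    sigma = sigma, loglik = loglik_trace, grid = grid, q = q,
    n = n, items = items, category_maps = category_maps,
    converged = converged, iterations = length(loglik_trace)
  ), class = "pcm_fit")
  fit$se <- pcm_se_bhhh(fit, x)
  fit
}

# BHHH standard errors for the step parameters of a fitted PCM
pcm_se_bhhh <- function(fit, x) {
  k <- length(fit$items)
  n <- nrow(x)
  nt <- length(fit$grid$theta)
  log_a <- latent_logweights(fit$grid, fit$sigma)
  ll_vt <- matrix(0, n, nt)
  lp_list <- vector("list", k)
  for (i in seq_len(k)) {
    lp <- pcm_item_logprob(fit$grid$theta, fit$delta[[i]])
    lp_list[[i]] <- lp
    xi <- x[, i]; ok <- !is.na(xi)
    ll_vt[ok, ] <- ll_vt[ok, ] + t(lp[, xi[ok] + 1L, drop = FALSE])
  }
  wll <- sweep(ll_vt, 2, log_a, `+`)
  mx <- apply(wll, 1, max)
  lw <- exp(wll - mx)
  post <- lw / rowSums(lw)
  npar <- sum(lengths(fit$delta))
  g <- matrix(0, n, npar)
  col0 <- 0
  for (i in seq_len(k)) {
    m <- length(fit$delta[[i]])
    p <- exp(lp_list[[i]])
    s_ge <- t(apply(p, 1, function(pr) rev(cumsum(rev(pr)))))[, -1, drop = FALSE]
    xi <- x[, i]; ok <- !is.na(xi)
    for (l in 1:m) {
      obs_l <- as.numeric(xi >= l)
      gv <- post %*% s_ge[, l] - obs_l  # d loglik / d delta_il
      gv[!ok] <- 0
      g[, col0 + l] <- gv
    }
    col0 <- col0 + m
  }
  info <- crossprod(g)
  covm <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, npar, npar)
  })
  ses <- sqrt(pmax(diag(covm), 0))
  out <- vector("list", k)
  col0 <- 0
  for (i in seq_len(k)) {
    m <- length(fit$delta[[i]])
    out[[i]] <- ses[col0 + 1:m]
    col0 <- col0 + m
  }
  stats::setNames(out, fit$items)
}

#' @export
print.pcm_fit <- function(x, ...) {
  cat("Partial Credit Model (MML-EM), ", length(x$items), " items, n = ",
      x$n, "\n", sep = "")
  cat(sprintf("  sigma = %.3f, loglik = %.2f, %d iterations (%s)\n",
              x$sigma, utils::tail(x$loglik, 1), x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
tidy.pcm_fit <- function(x, ...) {
  purrr::imap_dfr(x$delta, function(d, nm) {
    tibble::tibble(item = nm, step = seq_along(d), delta = d,
                   se = x$se[[nm]])
  })
}

#' @export
glance.pcm_fit <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, loglik = utils::tail(x$loglik, 1),
                 n = x$n, k = length(x$items), iterations = x$iterations,
                 converged = x$converged)
}

# person estimation ----------------------------------------------------------

# conditional mean, variance, and third central moment of the item scores
# at given trait values, for the observed items of one person
pcm_person_moments <- function(theta, delta_list) {
  mu <- w <- mu3 <- 0
  for (d in delta_list) {
    p <- exp(pcm_item_logprob(theta, d))
    xs <- matrix(0:length(d), length(theta), length(d) + 1, byrow = TRUE)
    mi <- rowSums(p * xs)
    wi <- rowSums(p * (xs - mi)^2)
    m3 <- rowSums(p * (xs - mi)^3)
    mu <- mu + mi; w <- w + wi; mu3 <- mu3 + m3
  }
  list(mu = mu, w = w, mu3 = mu3)
}

#' Person parameter estimates (WLE or EAP)
#'
#' WLE solves the weighted-likelihood score equation
#' \eqn{r - \sum_i \mu_i(\theta) + I'(\theta) / (2 I(\theta)) = 0}
#' (Warm's first-order bias correction; finite for extreme response
#' patterns), with standard error \eqn{1/\sqrt{I(\hat\theta)}}. EAP is the
#' posterior mean under the fitted normal latent distribution, evaluated on
#' the quadrature grid, with the posterior sd as standard error.
#'
#' @param fit `pcm_fit` object.
#' @param data Respondent tibble.
#' @param items Item column names (any subset of the fitted items).
#' @param method `"wle"` or `"eap"`.
#' @return Tibble with `theta`, `se` per person (`NA` for all-missing
#'   persons) and attribute `method`.
#' @export
estimate_persons <- function(fit, data, items = fit$items,
                             method = c("wle", "eap")) {
  method <- match.arg(method)
  stopifnot(all(items %in% fit$items))
  x <- irt_code_matrix(data, items)
  # recode through the fit's category maps
  for (i in seq_along(items)) {
    cm <- fit$category_maps[[match(items[i], fit$items)]]
    x[, i] <- match(x[, i], cm) - 1L
  }
  delta <- fit$delta[items]
  n <- nrow(x)
  theta <- se <- rep(NA_real_, n)

  if (method == "eap") {
    # person posteriors are much narrower than the marginal latent
    # distribution, so integrate them on a finer grid than the EM used
    grid <- gh_grid(max(fit$q, 201))
    log_a <- latent_logweights(grid, fit$sigma)
    nt <- length(grid$theta)
    ll_vt <- matrix(0, n, nt)
    for (i in seq_along(items)) {
      lp <- pcm_item_logprob(grid$theta, delta[[i]])
      xi <- x[, i]; ok <- !is.na(xi)
      ll_vt[ok, ] <- ll_vt[ok, ] + t(lp[, xi[ok] + 1L, drop = FALSE])
    }
    any_obs <- rowSums(!is.na(x)) > 0
    wll <- sweep(ll_vt, 2, log_a, `+`)
    mx <- apply(wll, 1, max)
    post <- exp(wll - mx)
    post <- post / rowSums(post)
    m1 <- drop(post %*% grid$theta)
    m2 <- drop(post %*% grid$theta^2)
    theta[any_obs] <- m1[any_obs]
    se[any_obs] <- sqrt(pmax(m2 - m1^2, 0))[any_obs]
  } else {
    # WLE: solve per distinct (observed-pattern, raw score) class
    obs_key <- apply(!is.na(x), 1, paste, collapse = "")
    r_v <- rowSums(x, na.rm = TRUE)
    key <- paste(obs_key, r_v)
    for (kk in unique(key)) {
      idx <- which(key == kk)
      s <- which(!is.na(x[idx[1], ]))
      if (length(s) == 0) next
      dl <- delta[s]
      r <- r_v[idx[1]]
      f <- function(th) {
        mo <- pcm_person_moments(th, dl)
        r - mo$mu + mo$mu3 / (2 * mo$w)
      }
      root <- tryCatch(stats::uniroot(f, c(-12, 12), tol = 1e-9)$root,
                       error = function(e) NA_real_)
      if (is.na(root)) next
      info <- pcm_person_moments(root, dl)$w
      theta[idx] <- root
      se[idx] <- 1 / sqrt(info)
    }
  }
  out <- tibble::tibble(theta = theta, se = se)
  attr(out, "method") <- method
  out
}

#' WLE and EAP reliability coefficients
#'
#' \eqn{rel_{WLE} = 1 - \overline{SE^2_{WLE}} / var(\hat\theta_{WLE})} and
#' \eqn{rel_{EAP} = var(\hat\theta_{EAP}) / (var(\hat\theta_{EAP}) +
#' \overline{var_{post}})}.
#'
#' @param fit `pcm_fit` object.
#' @param data Respondent tibble.
#' @param items Item column names.
#' @return Tibble with columns `wle`, `eap`.
#' @export
irt_reliability <- function(fit, data, items = fit$items) {
  wle <- estimate_persons(fit, data, items, method = "wle")
  eap <- estimate_persons(fit, data, items, method = "eap")
  v_wle <- stats::var(wle$theta, na.rm = TRUE)
  if (!is.finite(v_wle) || v_wle == 0) {
    stop("degenerate person variance: reliability undefined", call. = FALSE)
  }
  tibble::tibble(
    wle = 1 - mean(wle$se^2, na.rm = TRUE) / v_wle,
    eap = stats::var(eap$theta, na.rm = TRUE) /
      (stats::var(eap$theta, na.rm = TRUE) + mean(eap$se^2, na.rm = TRUE))
  )
}

# Nominal Categories Model ----------------------------------------------------

#' Fit the Nominal Categories Model to check category ordering
#'
#' MML-EM estimation of per-category slope and intercept parameters
#' (\eqn{P(x) \propto \exp(a_x \theta + c_x)}, first category anchored at
#' zero, latent trait standard normal). An item's response categories are
#' flagged as ordered when the estimated slopes are strictly increasing.
#' Categories endorsed by fewer than 1% of respondents make the ordering
#' check unstable and raise a per-item flag.
#'
#' @param data Respondent tibble.
#' @param items Item column names.
#' @param q Quadrature nodes.
#' @param tol Convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return Object of class `nrm_fit` with per-item `slopes`, `intercepts`,
#'   `ordered` and `unstable` flags.
#' @export
fit_nrm <- function(data, items = hls_items(), q = 31, tol = 1e-4,
                    max_iter = 200) {
  x <- irt_code_matrix(data, items)
  k <- length(items)
  n <- nrow(x)
  m_i <- apply(x, 2, max, na.rm = TRUE)
  grid <- gh_grid(q)
  nt <- length(grid$theta)
  log_a <- latent_logweights(grid, 1)

  slopes <- lapply(m_i, function(m) seq(0, m) * 1.0)
  inter <- lapply(m_i, function(m) rep(0, m + 1))

  item_logprob <- function(a, c) {
    eta <- outer(grid$theta, a) + matrix(c, nt, length(c), byrow = TRUE)
    eta - apply(eta, 1, max) -
      log(rowSums(exp(eta - apply(eta, 1, max))))
  }

  for (iter in seq_len(max_iter)) {
    ll_vt <- matrix(0, n, nt)
    lp_list <- vector("list", k)
    for (i in seq_len(k)) {
      lp <- item_logprob(slopes[[i]], inter[[i]])
      lp_list[[i]] <- lp
      xi <- x[, i]; ok <- !is.na(xi)
      ll_vt[ok, ] <- ll_vt[ok, ] + t(lp[, xi[ok] + 1L, drop = FALSE])
    }
    wll <- sweep(ll_vt, 2, log_a, `+`)
    mx <- apply(wll, 1, max)
    lw <- exp(wll - mx)
    post <- lw / rowSums(lw)

    old <- c(unlist(slopes), unlist(inter))
    for (i in seq_len(k)) {
      xi <- x[, i]; ok <- !is.na(xi)
      n_tx <- t(post[ok, , drop = FALSE]) %*% outer(xi[ok], 0:m_i[i], `==`)
      m <- m_i[i]
      par0 <- c(slopes[[i]][-1], inter[[i]][-1])
      negE <- function(par) {
        aa <- c(0, par[1:m]); cc <- c(0, par[(m + 1):(2 * m)])
        -sum(n_tx * item_logprob(aa, cc))
      }
      negG <- function(par) {
        aa <- c(0, par[1:m]); cc <- c(0, par[(m + 1):(2 * m)])
        p <- exp(item_logprob(aa, cc))
        n_t <- rowSums(n_tx)
        dc <- colSums(n_tx - n_t * p)[-1]
        da <- colSums(grid$theta * (n_tx - n_t * p))[-1]
        -c(da, dc)
      }
      opt <- stats::optim(par0, negE, negG, method = "BFGS",
                          control = list(maxit = 200))
      slopes[[i]] <- c(0, opt$par[1:m])
      inter[[i]] <- c(0, opt$par[(m + 1):(2 * m)])
    }
    if (max(abs(c(unlist(slopes), unlist(inter)) - old)) < tol) break
  }

  freq <- lapply(seq_len(k), function(i) {
    tabulate(x[, i] + 1L, nbins = m_i[i] + 1) / sum(!is.na(x[, i]))
  })
  structure(list(
    items = items,
    slopes = stats::setNames(slopes, items),
    intercepts = stats::setNames(inter, items),
    ordered = stats::setNames(
      vapply(slopes, function(a) all(diff(a) > 0), logical(1)), items),
    unstable = stats::setNames(
      vapply(freq, function(f) any(f < 0.01), logical(1)), items),
    category_freq = stats::setNames(freq, items)
  ), class = "nrm_fit")
}

#' @export
print.nrm_fit <- function(x, ...) {
  cat("Nominal Categories Model,", length(x$items), "items\n")
  cat("  ordered:", sum(x$ordered), "of", length(x$ordered), "items")
  if (any(x$unstable)) {
    cat("  (unstable ordering flags:",
        paste(x$items[x$unstable], collapse = ", "), ")")
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.nrm_fit <- function(x, ...) {
  purrr::map_dfr(x$items, function(it) {
    tibble::tibble(item = it, category = seq_along(x$slopes[[it]]) - 1,
                   slope = x$slopes[[it]], intercept = x$intercepts[[it]],
                   ordered = x$ordered[[it]], unstable = x$unstable[[it]])
  })
}
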