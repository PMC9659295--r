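test_that("elementary symmetric functions match brute-force enumeration", {
  expect_equal(esf(c(1, 1)), c(1, 2, 1))
  expect_equal(esf(c(1, 2, 3)), c(1, 6, 11, 6))
  set.seed(40)
  for (k in c(3, 6, 10)) {
    eps <- exp(runif(k, -1.5, 1.5))
    expect_equal(esf(eps), esf_brute(eps), tolerance = 1e-10)
  }
  # polynomial identity sum_r gamma_r t^r = prod_i (1 + eps_i t)
  eps <- exp(runif(5, -1, 1))
  g <- esf(eps)
  for (t in c(0.1, 0.7, 1.3, 2.5)) {
    expect_equal(sum(g * t^(0:5)), prod(1 + eps * t), tolerance = 1e-10)
  }
})

test_that("CML estimates match a grid-search oracle on a 2-item toy", {
  set.seed(41)
  # two items, conditional likelihood depends only on beta2 - beta1
  b_true <- c(-0.4, 0.4)
  p <- plogis(outer(rnorm(400, 0, 1.2), b_true, `-`))
  x <- (matrix(runif(800), 400, 2) < p) + 0
  fit <- fit_rm_cml(make_resp(x), items = c("hl1", "hl2"))
  # oracle: coarse-to-fine grid over d = beta2 - beta1 maximising the
  # conditional likelihood n10 * log p + n01 * log(1-p), p = 1/(1+e^{-d})
  n10 <- sum(x[, 1] == 1 & x[, 2] == 0)
  n01 <- sum(x[, 1] == 0 & x[, 2] == 1)
  cll <- function(d) n10 * plogis(d, log.p = TRUE) +
    n01 * plogis(-d, log.p = TRUE)
  lo <- -4; hi <- 4
  for (pass in 1:6) {
    grid <- seq(lo, hi, length.out = 201)
    best <- grid[which.max(vapply(grid, cll, numeric(1)))]
    step <- grid[2] - grid[1]
    lo <- best - step; hi <- best + step
  }
  expect_equal(unname(fit$beta[2] - fit$beta[1]), best, tolerance = 1e-4)
})

test_that("CML is equivariant under item permutation and sufficient in persons", {
  sim <- simulate_hls(null_config(500), seed = 42)
  db <- dichotomize(sim$data)
  fit <- fit_rm_cml(db)
  expect_equal(sum(fit$beta), 0, tolerance = 1e-10)
  perm <- c(4, 1, 12, 7, 2, 9, 5, 11, 3, 8, 10, 6)
  db_p <- db
  db_p[, hls_items()] <- db[, hls_items()[perm]]
  fit_p <- fit_rm_cml(db_p)
  expect_equal(unname(fit_p$beta), unname(fit$beta[perm]), tolerance = 1e-6)
  # permuting persons never changes estimates
  fit_r <- fit_rm_cml(db[sample(nrow(db)), ])
  expect_equal(fit_r$beta, fit$beta, tolerance = 1e-8)
})

test_that("PCM MML-EM has a monotone log-likelihood and is invariant to duplication", {
  sim <- simulate_hls(sim_config(n_persons = 300), seed = 43)
  fit <- fit_pcm_mml(sim$data, q = 21)
  expect_true(all(diff(fit$loglik) > -1e-7))
  doubled <- dplyr::bind_rows(sim$data, sim$data)
  fit2 <- fit_pcm_mml(doubled, q = 21)
  expect_equal(unlist(fit2$delta), unlist(fit$delta), tolerance = 1e-4)
  expect_equal(fit2$sigma, fit$sigma, tolerance = 1e-4)
})

test_that("quadrature refinement leaves the estimates unchanged", {
  sim <- simulate_hls(sim_config(n_persons = 400), seed = 44)
  f31 <- fit_pcm_mml(sim$data, q = 31, tol = 1e-6)
  f61 <- fit_pcm_mml(sim$data, q = 61, tol = 1e-6)
  expect_lt(max(abs(unlist(f31$delta) - unlist(f61$delta))), 1e-3)
})

test_that("the 2-category PCM agrees with Rasch CML up to normalisation", {
  sim <- simulate_hls(null_config(1500), seed = 45)
  db <- dichotomize(sim$data)
  cml <- fit_rm_cml(db)
  mml <- fit_pcm_mml(db, q = 31)
  b_mml <- unlist(mml$delta)
  expect_equal(cor(b_mml - mean(b_mml), unname(cml$beta)) > 0.999, TRUE)
  expect_equal(unname(rank(b_mml)), unname(rank(cml$beta)))
})

test_that("WLE respects symmetry and EAP shrinks toward the prior mean", {
  # mirror-symmetric 4-item instrument: a central raw score estimates
  # theta = 0 exactly (score equation and bias term both vanish there)
  fit <- structure(list(
    items = paste0("hl", 1:4),
    delta = list(hl1 = c(-1, 0, 1) - 0.6, hl2 = c(-1, 0, 1) + 0.6,
                 hl3 = c(-1, 0, 1) - 0.6, hl4 = c(-1, 0, 1) + 0.6),
    category_maps = rep(list(0:3), 4),
    grid = hlsq12:::gh_grid(31), sigma = 1, q = 31
  ), class = "pcm_fit")
  central <- make_resp(matrix(c(2, 3, 2, 3), 1))  # 0-based score 6 of 12
  wle <- estimate_persons(fit, central, items = paste0("hl", 1:4),
                          method = "wle")
  expect_equal(wle$theta, 0, tolerance = 1e-6)

  sim2 <- simulate_hls(sim_config(n_persons = 300), seed = 47)
  fit2 <- fit_pcm_mml(sim2$data, q = 21)
  wle2 <- estimate_persons(fit2, sim2$data, method = "wle")
  eap2 <- estimate_persons(fit2, sim2$data, method = "eap")
  # posterior contraction: every EAP posterior sd below the prior sd
  expect_true(all(eap2$se < fit2$sigma))
  expect_lt(var(eap2$theta), var(wle2$theta))
  # WLE stays finite on extreme patterns
  extreme <- make_resp(matrix(4, 1, 12))
  w_ex <- estimate_persons(fit2, extreme, method = "wle")
  expect_true(is.finite(w_ex$theta))
})

test_that("EAP matches fine-grid posterior integration", {
  sim <- simulate_hls(sim_config(n_persons = 500), seed = 48)
  fit <- fit_pcm_mml(sim$data, q = 31)
  eap <- estimate_persons(fit, sim$data[1:20, ], method = "eap")
  thg <- seq(-9, 9, length.out = 9001)
  for (v in 1:20) {
    ll <- rep(0, length(thg))
    for (i in seq_along(hls_items())) {
      xi <- sim$data[[hls_items()[i]]][v] - 1L
      ll <- ll + hlsq12:::pcm_item_logprob(thg, fit$delta[[i]])[, xi + 1]
    }
    post <- exp(ll - max(ll)) * dnorm(thg, 0, fit$sigma)
    post <- post / sum(post)
    expect_equal(eap$theta[v], sum(post * thg), tolerance = 1e-4)
  }
})

test_that("reliability grows with the number of items and dies with the trait", {
  sim12 <- simulate_hls(null_config(800), seed = 49)
  long <- simulate_hls_long(n_persons = 800, k = 48, seed = 49)
  items48 <- paste0("hl", 1:48)
  f12 <- fit_pcm_mml(sim12$data, q = 21)
  f48 <- fit_pcm_mml(long$data, items = items48, q = 21)
  r12 <- irt_reliability(f12, sim12$data)
  r48 <- irt_reliability(f48, long$data, items48)
  expect_gt(r48$wle, r12$wle)
  expect_gt(r48$eap, r12$eap)
  # near-zero trait variance: reliabilities collapse
  sim0 <- simulate_hls(null_config(800, latent_sd = 0.1), seed = 50)
  f0 <- fit_pcm_mml(sim0$data, q = 21)
  r0 <- irt_reliability(f0, sim0$data)
  expect_lt(r0$eap, 0.4)
})

test_that("the NRM confirms ordering for PCM data and flags violations", {
  sim <- simulate_hls(sim_config(n_persons = 2000), seed = 51)
  nrm <- fit_nrm(sim$data, q = 21)
  expect_true(all(nrm$ordered))
  # swapping two category labels on one item breaks its ordering
  d2 <- sim$data
  d2$hl4 <- ifelse(d2$hl4 == 2L, 3L, ifelse(d2$hl4 == 3L, 2L, d2$hl4))
  nrm2 <- fit_nrm(d2, q = 21)
  expect_false(nrm2$ordered["hl4"])
  # a category endorsed by < 1% raises the unstable flag
  d3 <- sim$data
  low <- which(d3$hl1 == 1L)
  d3$hl1[low[-seq_len(min(5, length(low)))]] <- 2L
  nrm3 <- fit_nrm(d3, q = 21)
  expect_true(nrm3$unstable["hl1"])
})
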