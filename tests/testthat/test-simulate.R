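test_that("simulation is reproducible under a seed", {
  a <- simulate_hls(sim_config(n_persons = 100), seed = 42)
  b <- simulate_hls(sim_config(n_persons = 100), seed = 42)
  expect_identical(a$data, b$data)
  expect_identical(a$theta, b$theta)
  c <- simulate_hls(sim_config(n_persons = 100), seed = 43)
  expect_false(identical(a$data, c$data))
})

test_that("covariate marginals match their sampling distributions", {
  set.seed(1)
  cov <- sample_covariates(10000)
  expect_equal(mean(cov$sex == "female"), 0.5, tolerance = 0.04)
  expect_true(all(cov$age >= 18 & cov$age <= 80))
  expect_true(all(cov$education %in% 0:8))
  expect_true(all(cov$findep %in% 1:4))
  expect_error(sample_covariates(0), ">= 1")
})

test_that("the trait carries the configured social gradient", {
  cfg <- sim_config(n_persons = 5000)
  set.seed(2)
  cov <- sample_covariates(5000)
  theta <- sample_theta(cov, cfg)
  expect_equal(sd(theta), 1, tolerance = 0.05)
  fit <- lm(theta ~ findep + status, data = cbind(cov, theta = theta))
  expect_lt(coef(fit)["findep"], 0)
  expect_gt(coef(fit)["status"], 0)
  # zero residual sd makes the trait deterministic in the covariates
  cfg0 <- sim_config(n_persons = 10,
                     gradient = c(sex = 0.4, age = 0.3, education = 0.5,
                                  status = 0.5, findep = -0.4),
                     latent_sd = sqrt(0.16 + 0.09 + 0.25 + 0.25 + 0.16))
  t1 <- local({set.seed(3); sample_theta(cov, cfg0)})
  t2 <- local({set.seed(4); sample_theta(cov, cfg0)})
  expect_equal(t1, t2)
})

test_that("pcm_prob matches the closed-form kernel", {
  # all steps zero at theta 0: equiprobable categories
  expect_equal(unname(pcm_prob(0, c(0, 0, 0))[1, ]), rep(0.25, 4))
  # extreme trait concentrates all mass in the top category
  p <- pcm_prob(15, c(-1, 0, 1))
  expect_gt(p[1, 4], 0.999)
  # direct evaluation of the unnormalised kernel
  th <- 0.7; d <- c(-0.5, 0.2, 1.1)
  num <- exp(cumsum(th - d))
  expect_equal(unname(pcm_prob(th, d)[1, ]),
               c(1, num) / (1 + sum(num)))
})

test_that("empirical category frequencies follow the generating PCM", {
  set.seed(5)
  cfg <- null_config(20000)
  theta <- rep(0.3, 20000)
  x <- sample_pcm_responses(theta, cfg)
  p_emp <- tabulate(x[, 4], nbins = 4) / 20000
  p_true <- pcm_prob(0.3, cfg$item_params[4, ])[1, ]
  expect_equal(p_emp, unname(p_true), tolerance = 0.02)
})

test_that("local-dependence copying with kappa 1 duplicates the source item", {
  cfg <- null_config(500, local_dep = data.frame(item_a = "hl2",
                                                 item_b = "hl9", kappa = 1))
  sim <- simulate_hls(cfg, seed = 6)
  expect_equal(sim$data$hl9, sim$data$hl2)
})

test_that("missingness masks after generation without changing the draws", {
  a <- simulate_hls(null_config(300, missing_rate = 0), seed = 7)$data
  b <- simulate_hls(null_config(300, missing_rate = 0.15), seed = 7)$data
  for (it in hls_items()) {
    obs <- !is.na(b[[it]])
    expect_equal(b[[it]][obs], a[[it]][obs])
  }
  rate <- mean(is.na(as.matrix(b[, hls_items()])))
  expect_lt(abs(rate - 0.15), 0.02)
})

test_that("injected DIF shifts the group-conditional distribution as the kernel predicts", {
  cfg <- null_config(40000, dif = data.frame(item = "hl6", by = "sex",
                                             offset = 0.8))
  sim <- simulate_hls(cfg, seed = 8)
  d <- sim$data
  # compare to the shifted closed form at a narrow trait band around 0
  band <- abs(sim$theta) < 0.2
  for (g in c("male", "female")) {
    rows <- band & d$sex == g
    p_emp <- tabulate(d$hl6[rows], nbins = 4) / sum(rows)
    shift <- if (g == "female") 0.4 else -0.4
    p_th <- colMeans(pcm_prob(sim$theta[rows],
                              cfg$item_params["hl6", ] + shift))
    expect_equal(p_emp, unname(p_th), tolerance = 0.03)
  }
})

test_that("special scores hit their target correlation with the trait", {
  set.seed(9)
  theta <- rnorm(5000)
  s <- attach_special_scores(theta, c(a = 0.6, b = 0))
  expect_gt(cor(s$a, theta), 0.55)
  expect_lt(cor(s$a, theta), 0.65)
  expect_lt(abs(cor(s$b, theta)), 0.05)
  expect_true(all(s$a >= 0 & s$a <= 100))
  expect_error(attach_special_scores(theta, c(bad = 1)), "strictly")
})

test_that("self-perceived health responds to the trait with the configured sign", {
  cfg <- null_config(5000)
  sim <- simulate_hls(cfg, seed = 10)
  # health coded 1 = very good: negative trait coefficient means higher
  # literacy, better (lower) health code
  expect_lt(coef(lm(sim$data$health ~ sim$theta))[2], 0)
  # with no trait effect the marginals follow the threshold-implied
  # normal masses (latent noise sd 1 plus the age term, jointly normal)
  cfg0 <- null_config(40000, health_theta = 0)
  sim0 <- simulate_hls(cfg0, seed = 11)
  sd_lat <- sqrt(1 + 0.2^2)
  expected <- diff(c(0, pnorm(cfg0$health_thresholds / sd_lat), 1))
  expect_equal(tabulate(sim0$data$health, nbins = 5) / 40000, expected,
               tolerance = 0.015)
  expect_error(sim_config(health_thresholds = c(0, 0, 1, 2)), "increasing")
})

test_that("response styles inflate both extreme categories without moving the trait", {
  # symmetric items at trait 0 isolate the mechanism: the style shift
  # trades middle-category mass for both extremes
  ip <- matrix(rep(c(-1.1, 0, 1.1), each = 12), 12, 3,
               dimnames = list(paste0("hl", 1:12), NULL))
  theta <- rep(0, 10000)
  set.seed(12)
  x0 <- sample_pcm_responses(theta, null_config(10000, item_params = ip))
  set.seed(13)
  x1 <- sample_pcm_responses(theta, null_config(10000, item_params = ip,
                                                response_style_sd = 1.5))
  expect_gt(mean(x1 %in% c(1, 4)), mean(x0 %in% c(1, 4)) + 0.03)
  # the polytomous mean barely moves: the shift is symmetric
  expect_equal(mean(x1), mean(x0), tolerance = 0.03)
})
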