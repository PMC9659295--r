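test_that("infit separates model-consistent items from constructed misfit", {
  sim <- simulate_hls(sim_config(n_persons = 2000), seed = 60)
  d <- sim$data
  fit <- fit_pcm_mml(d, q = 21)
  inf <- infit_stats(fit, d)
  expect_true(all(inf$infit > 0.85 & inf$infit < 1.15))
  expect_true(all(inf$flag == "ok"))
  # replace one item by independent random categories: underfit
  d2 <- d
  d2$hl7 <- sample(1:4, nrow(d2), replace = TRUE)
  fit2 <- fit_pcm_mml(d2, q = 21)
  inf2 <- infit_stats(fit2, d2)
  expect_gt(inf2$infit[inf2$item == "hl7"], 1.2)
  expect_equal(inf2$flag[inf2$item == "hl7"], "underfit")
  # a duplicated item is more predictable than the model expects: overfit
  d3 <- d
  d3$hl8 <- d3$hl7
  fit3 <- fit_pcm_mml(d3, q = 21)
  inf3 <- infit_stats(fit3, d3)
  expect_lt(inf3$infit[inf3$item == "hl8"],
            min(inf$infit[inf$item %in% c("hl7", "hl8")]))
})

test_that("the Q3 family detects a copied item pair and centres aQ3", {
  cfg <- sim_config(n_persons = 2000,
                    local_dep = data.frame(item_a = "hl3", item_b = "hl4",
                                           kappa = 1))
  sim <- simulate_hls(cfg, seed = 61)
  fit <- fit_pcm_mml(sim$data, q = 21)
  q3 <- q3_family(fit, sim$data)
  ut <- upper.tri(q3$aq3)
  expect_equal(mean(q3$aq3[ut]), 0, tolerance = 1e-12)
  expect_equal(q3$madaq3, mean(abs(q3$aq3[ut])))
  pair <- q3$pairs[q3$pairs$item_a == "hl3" & q3$pairs$item_b == "hl4", ]
  expect_equal(max(q3$pairs$aq3), pair$aq3)
  expect_true(pair$significant)
})

test_that("MADaQ3 stays small under local independence", {
  sim <- simulate_hls(sim_config(n_persons = 2000), seed = 62)
  fit <- fit_pcm_mml(sim$data, q = 21)
  q3 <- q3_family(fit, sim$data)
  expect_lt(q3$madaq3, 0.05)
})

test_that("model-implied correlations match a Monte-Carlo oracle", {
  sim <- simulate_hls(null_config(3000), seed = 63)
  fit <- fit_pcm_mml(sim$data, q = 31)
  # brute-force: simulate a huge sample from the *fitted* model and compare
  # its observed correlations with the SRMSR's model-implied ones
  set.seed(64)
  theta <- rnorm(200000, 0, fit$sigma)
  big <- sample_pcm_responses(theta, sim_config(
    n_persons = 200000,
    item_params = do.call(rbind, fit$delta),
    gradient = c(sex = 0, age = 0, education = 0, status = 0, findep = 0)))
  r_mc <- cor(big)
  # reconstruct the model-implied matrix through srmsr_irt's moments by
  # feeding it the huge simulated sample: SRMSR then measures exactly the
  # MC-vs-quadrature gap
  expect_lt(srmsr_irt(fit, make_resp(big)), 0.01)
})

test_that("SRMSR separates the fitted model from two-block data", {
  sim <- simulate_hls(sim_config(n_persons = 2000), seed = 65)
  fit <- fit_pcm_mml(sim$data, q = 21)
  expect_lte(srmsr_irt(fit, sim$data), 0.05)
  s1 <- simulate_hls(sim_config(n_persons = 2000), seed = 66)$data[, hls_items()[1:6]]
  s2 <- simulate_hls(sim_config(n_persons = 2000), seed = 67)$data[, hls_items()[1:6]]
  names(s2) <- hls_items()[7:12]
  two <- dplyr::bind_cols(s1, s2)
  fit2 <- fit_pcm_mml(two, q = 21)
  expect_gt(srmsr_irt(fit2, two), 0.08)
})

test_that("Agresti-Coull equals its closed form on a table of cases", {
  cases <- expand.grid(x = c(5, 19, 50, 450), n = c(100, 900, 2000))
  cases <- cases[cases$x <= cases$n, ]
  for (i in seq_len(nrow(cases))) {
    x <- cases$x[i]; n <- cases$n[i]; z <- 1.96
    nt <- n + z^2; pt <- (x + z^2 / 2) / nt
    half <- z * sqrt(pt * (1 - pt) / nt)
    got <- agresti_coull(x, n)
    expect_equal(got$lower, max(0, pt - half))
    expect_equal(got$upper, min(1, pt + half))
  }
  # the reconstructed 2.1%-of-900 case: lower bound 1.3%
  ci <- agresti_coull(0.021 * 900, 900)
  expect_equal(round(100 * ci$lower, 1), 1.3)
})

test_that("the PCA/t-test procedure discriminates one factor from two", {
  sim <- simulate_hls(sim_config(n_persons = 2000), seed = 68)
  fit <- fit_pcm_mml(sim$data, q = 21)
  pt1 <- pca_ttest_unidim(fit, sim$data)
  expect_true(pt1$supported)
  s1 <- simulate_hls(sim_config(n_persons = 2000), seed = 69)$data[, hls_items()[1:6]]
  s2 <- simulate_hls(sim_config(n_persons = 2000), seed = 70)$data[, hls_items()[1:6]]
  names(s2) <- hls_items()[7:12]
  two <- dplyr::bind_cols(s1, s2)
  fit2 <- fit_pcm_mml(two, q = 21)
  pt2 <- pca_ttest_unidim(fit2, two)
  expect_gt(pt2$proportion, 0.05)
  expect_gt(pt2$ci$lower, 0.05)
  expect_false(pt2$supported)
  # the PCA split should recover the two blocks
  blocks <- sort(vapply(pt2$subsets, length, integer(1)))
  expect_equal(unname(blocks), c(6L, 6L))
})

test_that("Andersen LR test formulas and power behave as specified", {
  sim <- simulate_hls(null_config(2000), seed = 71)
  db <- dichotomize(sim$data)
  split <- median_split(runif(2000))
  res <- andersen_lr(db, split)
  expect_equal(res$df, 11)
  expect_gt(res$p, 0.001)
  # one item shifted +0.5 logits for one group: detectable
  cfg <- null_config(2000, dif = data.frame(item = "hl5", by = "age",
                                            offset = 1.0))
  simd <- simulate_hls(cfg, seed = 72)
  dbd <- dichotomize(simd$data)
  resd <- andersen_lr(dbd, median_split(simd$data$age))
  expect_lt(resd$p, 0.001)
})

test_that("item Wald z locates the DIF item and vanishes on identical groups", {
  cfg <- null_config(2000, dif = data.frame(item = "hl5", by = "age",
                                            offset = 1.0))
  sim <- simulate_hls(cfg, seed = 73)
  db <- dichotomize(sim$data)
  wz <- wald_item_z(db, median_split(sim$data$age))
  expect_equal(wz$item[which.max(abs(wz$z))], "hl5")
  expect_true(wz$significant[wz$item == "hl5"])
  # same data as both groups: all z = 0
  both <- dplyr::bind_rows(db, db)
  split2 <- rep(c("a", "b"), each = nrow(db))
  wz0 <- wald_item_z(both, split2)
  expect_equal(wz0$z, rep(0, 12), tolerance = 1e-6)
})

test_that("graphical-test data flag the DIF item and ICCs track the model", {
  cfg <- null_config(3000, dif = data.frame(item = "hl5", by = "age",
                                            offset = 1.0))
  sim <- simulate_hls(cfg, seed = 74)
  db <- dichotomize(sim$data)
  gt <- graphical_test_data(db, median_split(sim$data$age))
  dev <- abs(gt$items$beta_1 - gt$items$beta_2)
  expect_equal(gt$items$item[which.max(dev)], "hl5")
  expect_gt(dev[gt$items$item == "hl5"], gt$items$radius[gt$items$item == "hl5"])
  # observed ICC proportions are near the model curve for clean items
  icc <- gt$icc[gt$icc$item == "hl2" & gt$icc$n >= 30, ]
  expect_lt(mean(abs(icc$observed - icc$expected)), 0.05)
})

test_that("facets DIF recovers an injected offset and is null-calibrated", {
  cfg <- sim_config(n_persons = 2000,
                    dif = data.frame(item = "hl6", by = "age", offset = 0.5))
  sim <- simulate_hls(cfg, seed = 75)
  dif <- dif_facets_pcm(sim$data, median_split(sim$data$age), q = 21)
  row <- dif$dif[dif$dif$item == "hl6", ]
  # the generator lowers the steps for the low-age group by offset/2
  expect_lt(abs(row$tau_1 - (-0.25)), 0.1)
  expect_true(row$significant)
  expect_equal(row$tau_1, -row$tau_2)
  # relabelled groups flip the sign
  dif_f <- dif_facets_pcm(sim$data,
                          factor(median_split(sim$data$age),
                                 levels = c("high", "low")), q = 21)
  expect_equal(dif_f$dif$tau_1[dif_f$dif$item == "hl6"], -row$tau_1,
               tolerance = 0.02)
  # identification: interactions sum to zero over items and over groups
  expect_equal(sum(dif$dif$tau_1), 0, tolerance = 1e-6)
  expect_equal(dif$dif$tau_1 + dif$dif$tau_2, rep(0, 12))
})

test_that("the digraph well-conditioned check equals brute-force enumeration", {
  # the canonical small counter-example
  x <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 0, 1))
  res <- well_conditioned_check(make_resp(x), items = paste0("hl", 1:3))
  expect_false(res$well_conditioned)
  expect_false(well_conditioned_brute(x))
  # item 1 is solved by everyone, so the split isolates it from {hl2, hl3}
  expect_true(setequal(res$partition[[1]], "hl1") ||
                setequal(res$partition[[2]], "hl1"))
  set.seed(76)
  for (rep in 1:200) {
    k <- sample(3:6, 1)
    n <- sample(4:10, 1)
    x <- matrix(rbinom(n * k, 1, runif(1, 0.2, 0.8)), n, k)
    got <- well_conditioned_check(make_resp(x), paste0("hl", 1:k))
    expect_equal(got$well_conditioned, well_conditioned_brute(x))
    if (!got$well_conditioned) {
      # the witness partition really lacks cross evidence
      i1 <- match(got$partition[[1]], paste0("hl", 1:k))
      i2 <- match(got$partition[[2]], paste0("hl", 1:k))
      cross <- FALSE
      for (i in i1) for (j in i2) {
        if (any(x[, i] == 1 & x[, j] == 0)) cross <- TRUE
      }
      expect_false(cross)
    }
  }
  sim <- simulate_hls(null_config(900), seed = 77)
  expect_true(well_conditioned_check(dichotomize(sim$data))$well_conditioned)
})

test_that("the margin-preserving sampler keeps margins and detects dependence", {
  sim <- simulate_hls(null_config(250), seed = 78)
  db <- dichotomize(sim$data)
  x <- as.matrix(db[, hls_items()])
  # sampler contract: swaps preserve all row and column sums
  set.seed(79)
  sw <- hlsq12:::margin_swap(x, 50000)
  expect_equal(rowSums(sw), rowSums(x))
  expect_equal(colSums(sw), colSums(x))
  expect_false(identical(sw, x))
  res <- global_local_independence_rm(db, n_samples = 30)
  expect_gte(res$p, 0)
  cfg <- null_config(500, local_dep = data.frame(item_a = "hl5",
                                                 item_b = "hl6", kappa = 1))
  simv <- simulate_hls(cfg, seed = 80)
  set.seed(81)
  resv <- global_local_independence_rm(dichotomize(simv$data),
                                       n_samples = 200)
  expect_lte(resv$p, 0.01)
})

test_that("disjoint random subsamples cover the data exactly once", {
  sim <- simulate_hls(sim_config(n_persons = 903), seed = 81)
  set.seed(82)
  subs <- random_subsamples(sim$data, 4)
  expect_equal(sum(vapply(subs, nrow, integer(1))), 903)
  ids <- sort(unlist(lapply(subs, function(s) s$person)))
  expect_equal(ids, 1:903)
})
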