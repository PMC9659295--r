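test_that("type D score is the share of easy-type answers among valid items", {
  all_easy <- make_resp(matrix(c(rep(3, 6), rep(4, 6)), 1))
  expect_equal(score_type_d(all_easy), 100)
  nine <- make_resp(matrix(c(rep(4, 9), rep(2, 3)), 1))
  expect_equal(score_type_d(nine), 75)
  # 9 valid of 12 is below the 80% validity threshold
  below <- make_resp(matrix(c(rep(4, 9), rep(NA, 3)), 1))
  expect_true(is.na(score_type_d(below)))
  # 10 valid of 12 passes it; denominator is the valid count
  ten <- make_resp(matrix(c(rep(4, 5), rep(2, 5), NA, NA), 1))
  expect_equal(score_type_d(ten), 50)
})

test_that("type P score rescales the sum (or mean, under missingness) to 0-100", {
  expect_equal(score_type_p(make_resp(matrix(4, 1, 12))), 100)
  expect_equal(score_type_p(make_resp(matrix(1, 1, 12))), 0)
  expect_equal(score_type_p(make_resp(matrix(c(rep(2, 6), rep(3, 6)), 1))), 50)
  # mean-based rescaling with two missing: mean 3 -> 66.67
  d <- make_resp(matrix(c(rep(3, 10), NA, NA), 1))
  expect_equal(score_type_p(d), 100 * 2 / 3)
  expect_true(is.na(score_type_p(make_resp(matrix(c(rep(3, 9), NA, NA, NA), 1)))))
})

test_that("type D levels reproduce the worked rule examples", {
  lev <- function(counts) as.character(assign_level_d(profile_row(counts)))
  expect_equal(lev(c(0, 2, 10, 0)), "sufficient")     # 10 easy + 2 difficult
  expect_equal(lev(c(0, 0, 6, 6)), "excellent")       # VE 50%, no difficult
  expect_equal(lev(c(0, 6, 5, 1)), "inadequate")      # 1 VE, 6 difficult
  expect_equal(lev(c(0, 3, 9, 0)), "problematic")     # fails all named rules
  # all "very easy" satisfies both excellent and sufficient; precedence
  # resolves to excellent
  expect_equal(lev(c(0, 0, 0, 12)), "excellent")
  # below the validity threshold the level is missing
  expect_true(is.na(assign_level_d(make_resp(matrix(c(rep(4, 8), rep(NA, 4)), 1)))))
})

test_that("type P levels apply the printed thresholds with their operators", {
  lv <- function(s) as.character(assign_level_p(s))
  expect_equal(lv(100), "excellent")
  expect_equal(lv(83.34), "excellent")
  expect_equal(lv(83.33), "sufficient")   # inclusive upper bound
  expect_equal(lv(66.67), "problematic")  # inclusive upper bound
  expect_equal(lv(50), "inadequate")      # <= 50
  expect_equal(lv(0), "inadequate")
  expect_true(is.na(lv(NA)))
})

test_that("every complete count profile matches the brute-force rule oracle", {
  profiles <- count_profiles(12)
  expect_equal(nrow(profiles), 455)
  got <- vapply(seq_len(nrow(profiles)), function(i) {
    as.character(assign_level_d(profile_row(profiles[i, ])))
  }, character(1))
  want <- vapply(seq_len(nrow(profiles)), function(i) {
    oracle_level_d(profiles[i, ])
  }, character(1))
  expect_equal(got, want)
})

test_that("two profiles with equal type D score can land in different levels", {
  a <- profile_row(c(0, 6, 6, 0))  # 6 easy + 6 difficult -> D = 50
  b <- profile_row(c(0, 6, 0, 6))  # 6 very easy + 6 difficult -> D = 50
  expect_equal(score_type_d(a), 50)
  expect_equal(score_type_d(b), 50)
  expect_equal(as.character(assign_level_d(a)), "inadequate")
  expect_equal(as.character(assign_level_d(b)), "problematic")
})

test_that("the P rules partition the score range", {
  grid <- seq(0, 100, by = 0.01)
  lev <- assign_level_p(grid)
  expect_false(anyNA(lev))
})

test_that("making any single response easier never worsens scores or P level", {
  set.seed(20)
  for (rep in 1:40) {
    x <- sample(1:4, 12, replace = TRUE)
    i <- sample(which(x < 4), 1)
    y <- x
    y[i] <- x[i] + 1
    a <- score_hls(make_resp(matrix(x, 1)))
    b <- score_hls(make_resp(matrix(y, 1)))
    expect_gte(b$score_d, a$score_d)
    expect_gte(b$score_p, a$score_p)
    expect_gte(as.integer(b$level_p), as.integer(a$level_p))
  }
})

test_that("limited HL is the union of problematic and inadequate", {
  sim <- simulate_hls(sim_config(n_persons = 200), seed = 21)
  sc <- score_hls(sim$data)
  expect_equal(sc$limited_p,
               sc$level_p %in% c("problematic", "inadequate"))
  expect_equal(sc$limited_d,
               sc$level_d %in% c("problematic", "inadequate"))
})

test_that("subscale scores follow the same formulas on the subset", {
  d <- make_resp(matrix(c(4, 4, 3, 3, rep(1, 8)), 1))
  hc <- subscale_scores(d, list(hc = paste0("hl", 1:4)))
  expect_equal(hc$score_d, 100)
  expect_equal(hc$score_p, 100 * (14 - 4) / 12)
  # full set equals full scores
  full <- subscale_scores(d, list(all = hls_items()))
  expect_equal(full$score_d, score_type_d(d))
  expect_equal(full$score_p, score_type_p(d))
  # 3 valid of 4 (75%) is below the per-subset validity threshold
  d2 <- make_resp(matrix(c(4, 4, 3, NA, rep(1, 8)), 1))
  expect_true(is.na(subscale_scores(d2, list(hc = paste0("hl", 1:4)))$score_d))
  expect_error(subscale_scores(d, list(bad = "nope")), "unknown item")
})

test_that("weighted descriptives and level shares respect the weights", {
  d <- make_resp(rbind(matrix(1, 1, 12), matrix(4, 1, 12)))
  d$weight <- c(1, 3)
  sc <- score_hls(d)
  desc <- describe_scores(sc)
  expect_equal(desc$mean[desc$score == "score_p"], 75)
  expect_equal(desc$sd[desc$score == "score_d"],
               sqrt(0.25 * 0.75) * 100, tolerance = 1e-9)
  # constant scores: sd 0, all quartiles equal
  dc <- score_hls(make_resp(matrix(3, 5, 12)))
  descc <- describe_scores(dc)
  expect_equal(descc$sd, c(0, 0))
  expect_equal(descc$q25, descc$q75)
  # unit weights equal unweighted
  sc1 <- sc
  sc1$weight <- 1
  lev_w <- level_distribution(sc, "p")
  expect_equal(sum(lev_w$percent), 100)
  expect_equal(lev_w$percent[lev_w$level == "excellent"], 75)
})
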