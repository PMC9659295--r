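#' Configuration for the synthetic respondent generator
#'
#' Defines the population the generator draws from: Partial Credit Model
#' (PCM) item step parameters, a social-gradient structure linking covariates
#' to the latent health-literacy trait, correlated special-HL scores, an
#' ordinal self-perceived-health outcome, and optional violations (DIF, local
#' dependence, extreme response styles, MCAR missingness) used to exercise
#' the diagnostic battery under the alternative.
#'
#' The default item step parameters place the twelve items between "rather
#' easy" and "moderately hard" (item locations from -2.1 to -0.3 logits,
#' step spread 1.1), which yields per-item shares of "difficult"/"very
#' difficult" responses of roughly 8-42% under a standard normal trait -- the band
#' population surveys with this instrument typically report. Gradient
#' coefficients act on standardized covariates; the residual sd is chosen so
#' the marginal trait sd is `latent_sd`.
#'
#' @param n_persons Number of respondents.
#' @param item_params Items x (categories-1) matrix of PCM step parameters
#'   \eqn{\delta_{ik}} in logits. Default: 12 items, 3 steps.
#' @param latent_sd Target marginal sd of the latent trait (mean fixed at 0).
#' @param gradient Named numeric: coefficients of the standardized covariates
#'   (`sex`, `age`, `education`, `status`, `findep`) in the trait model.
#' @param dif Optional tibble/data.frame with columns `item`, `by` (covariate
#'   defining two groups; `"sex"` or `"age"`), `offset` (logits added to all
#'   steps of `item` for the second group, split sum-to-zero across groups).
#' @param local_dep Optional tibble with columns `item_a`, `item_b`, `kappa`:
#'   with probability `kappa` the response on `item_b` is replaced by the
#'   response on `item_a`.
#' @param response_style_sd Sd of a person-specific symmetric shift of the
#'   outer steps (\eqn{\delta_{i1} + e_v}, \eqn{\delta_{i3} - e_v}); positive
#'   draws inflate both extreme categories without moving the trait.
#' @param missing_rate Per-item MCAR missingness probability.
#' @param special_scores Named numeric of target Pearson correlations between
#'   each special-HL score (0-100 scale) and the latent trait; each must lie
#'   strictly inside (-1, 1).
#' @param health_theta Coefficient of the trait in the latent
#'   self-perceived-health model (negative: higher literacy, better health --
#'   health is coded 1 = very good ... 5 = very bad).
#' @param health_thresholds Four increasing cut points for the ordinal health
#'   outcome.
#' @param weights One of `"unit"` (all 1) or `"random"` (uniform 0.5-2
#'   post-stratification-style weights).
#' @return A list of class `hls_sim_config`.
#' @export
sim_config <- function(n_persons = 1000,
                       item_params = default_item_params(),
                       latent_sd = 1,
                       gradient = c(sex = -0.05, age = -0.10,
                                    education = 0.20, status = 0.25,
                                    findep = -0.30),
                       dif = NULL,
                       local_dep = NULL,
                       response_style_sd = 0,
                       missing_rate = 0,
                       special_scores = c(digital = 0.55,
                                          communicative = 0.50,
                                          navigational = 0.50,
                                          vaccination = 0.45),
                       health_theta = -0.4,
                       health_thresholds = c(-1.3, -0.2, 0.8, 1.8),
                       weights = c("unit", "random")) {
  weights <- match.arg(weights)
  item_params <- as.matrix(item_params)
  stopifnot(n_persons >= 0, latent_sd > 0, all(is.finite(item_params)),
            missing_rate >= 0, missing_rate <= 1, response_style_sd >= 0)
  if (length(special_scores) > 0 && any(abs(special_scores) >= 1)) {
    stop("special-score target correlations must lie strictly in (-1, 1)",
         call. = FALSE)
  }
  if (any(diff(health_thresholds) <= 0)) {
    stop("health thresholds must be strictly increasing", call. = FALSE)
  }
  if (sum(gradient^2) > latent_sd^2) {
    stop("gradient coefficients imply a covariate variance share > latent_sd^2",
         call. = FALSE)
  }
  structure(list(
    n_persons = n_persons, item_params = item_params, latent_sd = latent_sd,
    gradient = gradient, dif = dif, local_dep = local_dep,
    response_style_sd = response_style_sd, missing_rate = missing_rate,
    special_scores = special_scores, health_theta = health_theta,
    health_thresholds = health_thresholds, weights = weights
  ), class = "hls_sim_config")
}

#' Default PCM step parameters for a 12-item instrument
#'
#' @param k Number of items.
#' @param locations Item locations in logits; steps are `location + spread *
#'   c(-1, 0, 1)`.
#' @param spread Step spread in logits.
#' @return k x 3 matrix of step parameters.
#' @export
default_item_params <- function(k = 12,
                                locations = seq(-2.1, -0.3, length.out = k),
                                spread = 1.1) {
  m <- outer(locations, spread * c(-1, 0, 1), `+`)
  rownames(m) <- paste0("hl", seq_len(k))
  colnames(m) <- paste0("step", 1:3)
  m
}

#' Sample respondent covariates
#'
#' Sex is Bernoulli(0.5) (`female`/`male`); age uniform 18-80 (rounded);
#' education a discrete ISCED 0-8 distribution peaked at secondary levels;
#' social status discrete 1-10; financial deprivation discrete 1-4 with
#' decreasing mass.
#'
#' @param n Number of respondents.
#' @return Tibble of covariates.
#' @export
sample_covariates <- function(n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  edu_p <- c(0.01, 0.02, 0.07, 0.25, 0.30, 0.05, 0.10, 0.15, 0.05)
  tibble::tibble(
    sex = sample(c("female", "male"), n, replace = TRUE),
    age = round(stats::runif(n, 18, 80)),
    education = sample(0:8, n, replace = TRUE, prob = edu_p),
    status = sample(1:10, n, replace = TRUE,
                    prob = stats::dnorm(1:10, mean = 5.5, sd = 2)),
    findep = sample(1:4, n, replace = TRUE, prob = c(0.45, 0.30, 0.15, 0.10))
  )
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Sample latent trait values with a social gradient
#'
#' \eqn{\theta_v = b \cdot z(x_v) + \epsilon_v} with standardized covariates
#' and \eqn{\epsilon \sim N(0, \sigma_{res})}, where the residual sd is set so
#' the marginal trait sd matches `cfg$latent_sd` when covariates are roughly
#' independent.
#'
#' @param covariates Covariate tibble from [sample_covariates()].
#' @param cfg `hls_sim_config`.
#' @return Numeric vector of trait values.
#' @export
sample_theta <- function(covariates, cfg) {
  b <- cfg$gradient
  z <- cbind(sex = as.numeric(covariates$sex == "female"),
             age = covariates$age,
             education = covariates$education,
             status = covariates$status,
             findep = covariates$findep)
  z <- apply(z, 2, standardize)
  lin <- drop(z[, names(b), drop = FALSE] %*% b)
  res_sd <- sqrt(max(cfg$latent_sd^2 - sum(b^2), 0))
  lin + stats::rnorm(nrow(covariates), 0, res_sd)
}

#' PCM category probabilities
#'
#' \eqn{P(X = x \mid \theta) \propto \exp\{\sum_{k \le x} (\theta -
#' \delta_k)\}} with the empty sum for \eqn{x = 0}; categories 0..m.
#'
#' @param theta Numeric vector of trait values.
#' @param delta Numeric vector of step parameters for one item.
#' @return Matrix `length(theta)` x `(length(delta) + 1)` of probabilities.
#' @export
pcm_prob <- function(theta, delta) {
  m <- length(delta)
  # eta_x = x * theta - sum_{k<=x} delta_k, stabilised by row max
  eta <- matrix(0:m, length(theta), m + 1, byrow = TRUE) * theta +
    matrix(c(0, -cumsum(delta)), length(theta), m + 1, byrow = TRUE)
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p / rowSums(p)
}

#' Draw PCM responses for a person sample
#'
#' Draws each response from the exact PCM category distribution at the
#' person's trait value, with optional injections applied in this order:
#' extreme-response-style step shifts (inside the kernel, since they modify
#' the generating probabilities), DIF offsets, then local-dependence copying
#' and MCAR masking after the draw.
#'
#' @param theta Trait vector.
#' @param cfg `hls_sim_config`.
#' @param covariates Covariates (needed when DIF is configured).
#' @return Integer matrix of raw codes 1..(m+1) with `NA` for masked cells.
#' @export
sample_pcm_responses <- function(theta, cfg, covariates = NULL) {
  n <- length(theta)
  delta <- cfg$item_params
  k <- nrow(delta)
  m <- ncol(delta)
  ers <- if (cfg$response_style_sd > 0) {
    stats::rnorm(n, 0, cfg$response_style_sd)
  } else rep(0, n)

  dif_offset <- matrix(0, n, k)
  if (!is.null(cfg$dif) && nrow(cfg$dif) > 0) {
    if (is.null(covariates)) stop("DIF configured but no covariates given")
    for (r in seq_len(nrow(cfg$dif))) {
      it <- match(cfg$dif$item[r], rownames(delta))
      grp <- dif_group(covariates, cfg$dif$by[r])
      # sum-to-zero split: -offset/2 for group 1, +offset/2 for group 2
      dif_offset[, it] <- dif_offset[, it] +
        ifelse(grp == levels(grp)[2], cfg$dif$offset[r] / 2,
               -cfg$dif$offset[r] / 2)
    }
  }

  x <- matrix(NA_integer_, n, k, dimnames = list(NULL, rownames(delta)))
  u <- matrix(stats::runif(n * k), n, k)
  for (i in seq_len(k)) {
    d <- matrix(delta[i, ], n, m, byrow = TRUE)
    if (m >= 2) {  # symmetric outer-step shift
      d[, 1] <- d[, 1] + ers
      d[, m] <- d[, m] - ers
    }
    d <- d + dif_offset[, i]
    dc <- if (m == 1) d else t(apply(d, 1, cumsum))
    eta <- matrix(0:m, n, m + 1, byrow = TRUE) * theta + cbind(0, -dc)
    eta <- eta - apply(eta, 1, max)
    p <- exp(eta); p <- p / rowSums(p)
    cum <- t(apply(p, 1, cumsum))
    x[, i] <- 1L + rowSums(u[, i] > cum)  # category index in 1..m+1 (raw code)
  }

  if (!is.null(cfg$local_dep) && nrow(cfg$local_dep) > 0) {
    for (r in seq_len(nrow(cfg$local_dep))) {
      ia <- match(cfg$local_dep$item_a[r], rownames(delta))
      ib <- match(cfg$local_dep$item_b[r], rownames(delta))
      copy <- stats::runif(n) < cfg$local_dep$kappa[r]
      x[copy, ib] <- x[copy, ia]
    }
  }
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(n * k) < cfg$missing_rate, n, k)
    x[mask] <- NA_integer_
  }
  x
}

dif_group <- function(covariates, by) {
  switch(by,
    sex = factor(covariates$sex, levels = c("male", "female")),
    age = median_split(covariates$age),
    education = factor(ifelse(covariates$education >= 4, "high", "low"),
                       levels = c("low", "high")),
    stop("unsupported DIF grouping covariate: ", by, call. = FALSE)
  )
}

#' Attach special-HL scores correlated with the trait
#'
#' Each score is \eqn{s = \rho z(\theta) + \sqrt{1-\rho^2}\,\eta} mapped
#' linearly to the 0-100 scale, so its population Pearson correlation with
#' the trait is \eqn{\rho}.
#'
#' @param theta Trait vector.
#' @param rho Named numeric of target correlations, each in (-1, 1).
#' @return Tibble of score columns.
#' @export
attach_special_scores <- function(theta, rho) {
  if (length(rho) > 0 && any(abs(rho) >= 1)) {
    stop("target correlations must lie strictly in (-1, 1)", call. = FALSE)
  }
  z <- standardize(theta)
  out <- lapply(rho, function(r) {
    s <- r * z + sqrt(1 - r^2) * stats::rnorm(length(z))
    pmin(pmax(50 + 15 * s, 0), 100)
  })
  tibble::as_tibble(out)
}

#' Attach an ordinal self-perceived-health outcome
#'
#' A latent health index \eqn{h^* = c_\theta \theta + 0.2 z(age) + noise} is
#' cut at fixed thresholds into five categories (1 = very good ... 5 = very
#' bad); with a negative trait coefficient, higher literacy maps to better
#' (lower-coded) health.
#'
#' @param theta Trait vector.
#' @param covariates Covariate tibble.
#' @param cfg `hls_sim_config`.
#' @return Integer vector in 1..5.
#' @export
attach_health <- function(theta, covariates, cfg) {
  hstar <- cfg$health_theta * theta + 0.2 * standardize(covariates$age) +
    stats::rnorm(length(theta))
  1L + rowSums(outer(hstar, cfg$health_thresholds, `>`))
}

#' Simulate a synthetic HLS19-Q12 respondent population
#'
#' Runs the full generator: covariates, latent trait with social gradient,
#' PCM item responses (with any configured violations), special-HL scores,
#' self-perceived health, and weights. The result is reproducible: the same
#' configuration and seed give an identical dataset.
#'
#' @param cfg `hls_sim_config` from [sim_config()].
#' @param seed Integer seed.
#' @return An object of class `hls_sim`: a list with `data` (respondent
#'   tibble with item, covariate, weight, special-score and health columns),
#'   `theta` (true trait values), `item_params`, `config` and `seed`.
#' @export
#' @examples
#' sim <- simulate_hls(sim_config(n_persons = 50), seed = 1)
#' dplyr::glimpse(sim$data)
simulate_hls <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "hls_sim_config"))
  if (cfg$n_persons < 1) stop("n_persons must be >= 1", call. = FALSE)
  set.seed(seed)
  cov <- sample_covariates(cfg$n_persons)
  theta <- sample_theta(cov, cfg)
  x <- sample_pcm_responses(theta, cfg, covariates = cov)
  specials <- attach_special_scores(theta, cfg$special_scores)
  health <- attach_health(theta, cov, cfg)
  w <- if (cfg$weights == "random") {
    stats::runif(cfg$n_persons, 0.5, 2)
  } else rep(1, cfg$n_persons)
  data <- dplyr::bind_cols(
    tibble::tibble(person = seq_len(cfg$n_persons)),
    tibble::as_tibble(x), cov, specials,
    tibble::tibble(health = health, weight = w)
  )
  structure(list(data = data, theta = theta, item_params = cfg$item_params,
                 config = cfg, seed = seed),
            class = "hls_sim")
}

#' @export
print.hls_sim <- function(x, ...) {
  cat("Synthetic HLS19-style respondent sample\n")
  cat("  persons:", nrow(x$data), " items:", nrow(x$item_params),
      " seed:", x$seed, "\n")
  cat("  injections: dif=", !is.null(x$config$dif),
      " local_dep=", !is.null(x$config$local_dep),
      " response_style_sd=", x$config$response_style_sd,
      " missing_rate=", x$config$missing_rate, "\n", sep = "")
  invisible(x)
}

#' Simulate a long-form instrument embedding the 12-item short form
#'
#' Generates a unidimensional instrument with `k` items whose first 12 step
#' parameter rows equal the canonical short-form defaults, for
#' short-form/long-form representation checks.
#'
#' @param n_persons Respondents.
#' @param k Total number of long-form items (>= 12).
#' @param seed Integer seed.
#' @return `hls_sim` whose data has item columns `hl1..hl<k>`.
#' @export
simulate_hls_long <- function(n_persons = 2000, k = 48, seed = 1) {
  stopifnot(k >= 12)
  ip <- default_item_params(k = k, locations = rep_len(seq(-2.1, -0.3,
                                                           length.out = 12), k))
  ip[1:12, ] <- default_item_params()
  simulate_hls(sim_config(n_persons = n_persons, item_params = ip),
               seed = seed)
}
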