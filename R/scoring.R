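#' Level rule set for the HLS19-Q12 four-level categorisation
#'
#' The cut-offs are applied as the printed decimals (8.334, 83.33, 66.67,
#' 50), not as exact twelfths: that is the only reading under which 10/12 =
#' 83.333% of easy-type answers qualifies as "sufficient" and 1/12 = 8.333%
#' of "very easy" answers stays under the "< 8.334" bound -- matching the
#' rule glosses "at least 10 out of the 12 items" and "one task at the most
#' being very easy".
#'
#' @return A list with components `d` (count-percentage rules for the type D
#'   level), `p` (score thresholds for the type P level) and
#'   `validity_threshold` (minimum % of items with valid responses, 80).
#' @export
level_rules <- function() {
  list(
    d = list(excellent_ve = 50, excellent_diff = 8.334,
             sufficient_easy = 83.33,
             inadequate_ve = 8.334, inadequate_diff = 50),
    p = list(excellent = 83.33, sufficient = 66.67, problematic = 50),
    validity_threshold = 80
  )
}

# per-person category counts over valid items: matrix n x 4 plus n_valid
category_counts <- function(x) {
  counts <- sapply(1:4, function(cat) rowSums(x == cat, na.rm = TRUE))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  list(counts = counts, n_valid = rowSums(!is.na(x)))
}

#' Type D score: percentage of easy-type responses
#'
#' The type D score is the percentage (0-100) of a person's validly answered
#' items rated "easy" or "very easy" (implicit dichotomization). The score is
#' missing unless at least 80% of the instrument's items have valid
#' responses.
#'
#' @param data Respondent tibble.
#' @param items Item column names.
#' @param rules Rule set from [level_rules()].
#' @return Numeric vector of scores in `[0, 100]`, `NA` below the validity
#'   threshold.
#' @export
score_type_d <- function(data, items = hls_items(), rules = level_rules()) {
  x <- resp_matrix(data, items)
  cc <- category_counts(x)
  ok <- 100 * cc$n_valid / length(items) >= rules$validity_threshold
  out <- 100 * rowSums(x >= 3L, na.rm = TRUE) / cc$n_valid
  out[!ok | cc$n_valid == 0] <- NA_real_
  out
}

#' Type P score: rescaled polytomous sum score
#'
#' For complete rows the sum of the item codes (1-4) is rescaled linearly to
#' 0-100: \eqn{100 (\sum x - k) / (3k)}. Rows with missing responses that
#' still meet the 80% validity rule are scored from the mean of the valid
#' codes, \eqn{100 (\bar{x} - 1) / 3}, which coincides with the sum formula
#' on complete rows; below the threshold the score is missing.
#'
#' @inheritParams score_type_d
#' @return Numeric vector of scores in `[0, 100]`.
#' @export
score_type_p <- function(data, items = hls_items(), rules = level_rules()) {
  x <- resp_matrix(data, items)
  n_valid <- rowSums(!is.na(x))
  ok <- 100 * n_valid / length(items) >= rules$validity_threshold
  out <- 100 * (rowMeans(x, na.rm = TRUE) - 1) / 3
  out[!ok | n_valid == 0] <- NA_real_
  out
}

# level from category counts (n x 4, cols = codes 1..4) and n_valid;
# percentages over valid items; precedence excellent -> sufficient ->
# inadequate -> problematic (residual)
level_d_from_counts <- function(counts, n_valid, rules = level_rules()) {
  p_ve <- 100 * counts[, 4] / n_valid
  p_easy <- 100 * (counts[, 3] + counts[, 4]) / n_valid
  p_diff <- 100 * (counts[, 1] + counts[, 2]) / n_valid
  r <- rules$d
  out <- rep(NA_character_, length(n_valid))
  excellent <- p_ve >= r$excellent_ve & p_diff < r$excellent_diff
  sufficient <- !excellent & p_easy > r$sufficient_easy
  inadequate <- !excellent & !sufficient &
    p_ve < r$inadequate_ve & p_diff >= r$inadequate_diff
  out[inadequate] <- "inadequate"
  out[sufficient] <- "sufficient"
  out[excellent] <- "excellent"
  out[!excellent & !sufficient & !inadequate & n_valid > 0] <- "problematic"
  out
}

hl_levels <- c("inadequate", "problematic", "sufficient", "excellent")

#' Assign the type D health-literacy level
#'
#' The type D level is not a function of the type D score alone: it is read
#' off the percentages of response categories among a person's valid items.
#' Excellent: "very easy" >= 50% and "difficult"+"very difficult" < 8.334%.
#' Sufficient: "easy"+"very easy" > 83.33%. Inadequate: "very easy" < 8.334%
#' and "difficult"+"very difficult" >= 50%. Problematic: everyone else.
#' Evaluated in that order; missing below the 80% validity rule.
#'
#' @inheritParams score_type_d
#' @return Ordered factor with levels inadequate < problematic < sufficient
#'   < excellent.
#' @export
assign_level_d <- function(data, items = hls_items(), rules = level_rules()) {
  x <- resp_matrix(data, items)
  cc <- category_counts(x)
  ok <- 100 * cc$n_valid / length(items) >= rules$validity_threshold
  lev <- level_d_from_counts(cc$counts, cc$n_valid, rules)
  lev[!ok] <- NA_character_
  factor(lev, levels = hl_levels, ordered = TRUE)
}

#' Assign the type P health-literacy level
#'
#' Thresholds on the 0-100 type P score: excellent > 83.33; sufficient in
#' (66.67, 83.33]; problematic in (50, 66.67]; inadequate <= 50.
#'
#' @param score_p Numeric vector of type P scores.
#' @param rules Rule set from [level_rules()].
#' @return Ordered factor as in [assign_level_d()].
#' @export
assign_level_p <- function(score_p, rules = level_rules()) {
  r <- rules$p
  lev <- dplyr::case_when(
    is.na(score_p) ~ NA_character_,
    score_p > r$excellent ~ "excellent",
    score_p > r$sufficient ~ "sufficient",
    score_p > r$problematic ~ "problematic",
    TRUE ~ "inadequate"
  )
  factor(lev, levels = hl_levels, ordered = TRUE)
}

#' Score respondents: type D and type P scores, levels, limited-HL flags
#'
#' Appends six columns to the respondent tibble: `score_d`, `score_p`,
#' `level_d`, `level_p`, `limited_d`, `limited_p`. "Limited" health literacy
#' is the union of the problematic and inadequate levels.
#'
#' @inheritParams score_type_d
#' @return The input tibble with the scoring columns appended.
#' @export
#' @examples
#' sim <- simulate_hls(sim_config(n_persons = 20), seed = 1)
#' score_hls(sim$data) |> dplyr::select(score_d:limited_p)
score_hls <- function(data, items = hls_items(), rules = level_rules()) {
  data$score_d <- score_type_d(data, items, rules)
  data$score_p <- score_type_p(data, items, rules)
  data$level_d <- assign_level_d(data, items, rules)
  data$level_p <- assign_level_p(data$score_p, rules)
  data$limited_d <- data$level_d %in% c("problematic", "inadequate")
  data$limited_d[is.na(data$level_d)] <- NA
  data$limited_p <- data$level_p %in% c("problematic", "inadequate")
  data$limited_p[is.na(data$level_p)] <- NA
  data
}

#' Subscale scores for named item subsets
#'
#' Applies the type D and type P formulas (and the 80% validity rule, on the
#' subset's own item count) to each named subset of instrument items, e.g.
#' the conceptual subdimensions.
#'
#' @param data Respondent tibble.
#' @param subsets Named list of character vectors of item ids.
#' @param items Full instrument item set (for membership validation).
#' @param rules Rule set.
#' @return Long tibble: `person` (row index), `subscale`, `score_d`,
#'   `score_p`.
#' @export
subscale_scores <- function(data, subsets, items = hls_items(),
                            rules = level_rules()) {
  stopifnot(is.list(subsets), !is.null(names(subsets)))
  unknown <- setdiff(unlist(subsets), items)
  if (length(unknown) > 0) {
    stop("unknown item ids in subsets: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  purrr::imap_dfr(subsets, function(ids, nm) {
    tibble::tibble(
      person = seq_len(nrow(data)),
      subscale = nm,
      score_d = score_type_d(data, items = ids, rules = rules),
      score_p = score_type_p(data, items = ids, rules = rules)
    )
  })
}

#' Named subsets for the instrument's domains and stages
#'
#' @param instrument Instrument tibble.
#' @return Named list of item-id vectors: one per domain and one per stage.
#' @export
hls_subdimensions <- function(instrument = hls_instrument()) {
  validate_instrument(instrument)
  c(split(instrument$item, instrument$domain),
    split(instrument$item, instrument$stage))
}

# weighted quantile via the weighted empirical cdf (left-continuous inverse)
weighted_quantile <- function(x, w, probs) {
  ok <- !is.na(x)
  x <- x[ok]; w <- w[ok]
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

weighted_mean_sd <- function(x, w) {
  ok <- !is.na(x)
  x <- x[ok]; w <- w[ok]
  m <- sum(w * x) / sum(w)
  v <- sum(w * (x - m)^2) / sum(w)
  c(mean = m, sd = sqrt(v))
}

#' Weighted descriptives of the score distributions
#'
#' @param scored Tibble from [score_hls()].
#' @param weights Optional weight column name (default `"weight"` if
#'   present, else unit weights).
#' @return Tibble: one row per score type with weighted mean, sd, quartiles
#'   and valid n.
#' @export
describe_scores <- function(scored, weights = NULL) {
  w <- resolve_weights(scored, weights)
  purrr::map_dfr(c(score_d = "score_d", score_p = "score_p"), function(col) {
    x <- scored[[col]]
    ms <- weighted_mean_sd(x, w)
    q <- weighted_quantile(x, w, c(0.25, 0.5, 0.75))
    tibble::tibble(mean = unname(ms["mean"]), sd = unname(ms["sd"]),
                   q25 = q[1], median = q[2], q75 = q[3],
                   n_valid = sum(!is.na(x)), n = length(x))
  }, .id = "score")
}

#' Weighted level distribution
#'
#' @param scored Tibble from [score_hls()].
#' @param type `"d"` or `"p"`.
#' @param weights Optional weight column name.
#' @return Tibble of levels with weighted percentage shares (summing to 100
#'   over non-missing levels).
#' @export
level_distribution <- function(scored, type = c("d", "p"), weights = NULL) {
  type <- match.arg(type)
  lev <- scored[[paste0("level_", type)]]
  w <- resolve_weights(scored, weights)
  ok <- !is.na(lev)
  shares <- unname(vapply(hl_levels, function(l) {
    100 * sum(w[ok & lev == l]) / sum(w[ok])
  }, numeric(1)))
  tibble::tibble(level = factor(hl_levels, levels = hl_levels, ordered = TRUE),
                 percent = shares)
}

resolve_weights <- function(data, weights = NULL) {
  if (is.null(weights)) {
    if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  } else {
    data[[weights]]
  }
}
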