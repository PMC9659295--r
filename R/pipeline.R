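#' Per-item weighted share of difficult responses
#'
#' The weighted percentage of respondents rating each task "difficult" or
#' "very difficult" (codes 1-2), ordered from easiest to hardest, optionally
#' per subgroup column.
#'
#' @param data Respondent tibble.
#' @param items Item column names.
#' @param weights Weight column name.
#' @param by Optional grouping column (e.g. `mode`); adds one column of
#'   percentages per group.
#' @return Tibble: `item`, `pct_difficult` (plus one column per group),
#'   ordered by the overall percentage.
#' @export
item_difficulty_table <- function(data, items = hls_items(), weights = NULL,
                                  by = NULL) {
  w <- resolve_weights(data, weights)
  pct <- function(rows) {
    unname(vapply(items, function(it) {
      x <- data[[it]][rows]
      ww <- w[rows]
      ok <- !is.na(x)
      100 * sum(ww[ok & x <= 2]) / sum(ww[ok])
    }, numeric(1)))
  }
  out <- tibble::tibble(item = items, pct_difficult = pct(seq_len(nrow(data))))
  if (!is.null(by)) {
    for (g in unique(data[[by]])) {
      out[[paste0("pct_", g)]] <- pct(which(data[[by]] == g))
    }
  }
  dplyr::arrange(out, .data$pct_difficult)
}

#' Run the full validation pipeline
#'
#' Orchestrates the stages of the instrument validation on a respondent
#' table (or a freshly simulated one): scoring and level assignment,
#' classical psychometrics (alphas, polychoric CFA), Partial Credit and
#' Rasch model estimation with reliabilities, the diagnostic battery
#' (infit, Q3 family, SRMSR, PCA/t-test, DIF, LR tests), and the validity
#' regressions. Deterministic under the seed; any subset of stages can be
#' requested.
#'
#' @param data Respondent tibble, or `NULL` to simulate from `sim`.
#' @param sim `hls_sim_config` used when `data` is `NULL`.
#' @param items Item column names.
#' @param stages Character vector out of `"scoring"`, `"classical"`,
#'   `"irt"`, `"diagnostics"`, `"validity"`.
#' @param seed Integer seed (simulation and any stochastic diagnostics).
#' @param q Quadrature nodes for the IRT stages.
#' @return Object of class `hls_report`: a list of per-stage results plus
#'   `settings`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(sim = sim_config(n_persons = 300), seed = 7,
#'                     stages = c("scoring", "classical"))
#' rep$scoring$descriptives
#' }
run_pipeline <- function(data = NULL, sim = sim_config(),
                         items = hls_items(),
                         stages = c("scoring", "classical", "irt",
                                    "diagnostics", "validity"),
                         seed = 1, q = 31) {
  stages <- match.arg(stages, several.ok = TRUE)
  set.seed(seed)
  if (is.null(data)) {
    data <- simulate_hls(sim, seed = seed)$data
  }
  out <- list(settings = list(stages = stages, seed = seed, q = q,
                              n = nrow(data), items = items))
  scored <- score_hls(data, items)

  if ("scoring" %in% stages) {
    out$scoring <- list(
      scores = dplyr::select(scored, dplyr::any_of(
        c("person", "score_d", "score_p", "level_d", "level_p",
          "limited_d", "limited_p"))),
      descriptives = describe_scores(scored),
      levels_d = level_distribution(scored, "d"),
      levels_p = level_distribution(scored, "p"),
      item_difficulty = item_difficulty_table(data, items)
    )
  }
  if ("classical" %in% stages) {
    poly <- polychoric_matrix(data, items)
    out$classical <- list(
      alphas = alpha_report(data, items),
      polychoric = poly,
      cfa = cfa_single_factor(poly, n = nrow(data))
    )
  }
  dich <- dichotomize(data, items)
  if ("irt" %in% stages || "diagnostics" %in% stages) {
    pcm <- fit_pcm_mml(data, items, q = q)
    out$irt <- list(
      pcm = pcm,
      rm = tryCatch(fit_rm_cml(dich, items), error = function(e) e),
      nrm = fit_nrm(data, items, q = q),
      reliability = irt_reliability(pcm, data, items)
    )
  }
  if ("diagnostics" %in% stages) {
    pcm <- out$irt$pcm
    splits <- list(score = median_split(rowSums(resp_matrix(data, items),
                                                na.rm = TRUE)))
    if ("sex" %in% names(data)) splits$sex <- factor(data$sex)
    if ("age" %in% names(data)) splits$age <- median_split(data$age)
    if ("education" %in% names(data)) {
      splits$education <- factor(ifelse(data$education >= 4, "high", "low"))
    }
    out$diagnostics <- list(
      infit = infit_stats(pcm, data, items),
      q3 = q3_family(pcm, data, items),
      srmsr = srmsr_irt(pcm, data, items),
      pca_ttest = pca_ttest_unidim(pcm, data, items),
      lr_tests = purrr::imap_dfr(splits, function(s, nm) {
        res <- tryCatch(andersen_lr(dich, s, items),
                        error = function(e) {
                          tibble::tibble(lr = NA_real_, df = NA_integer_,
                                         p = NA_real_, significant = NA,
                                         error = conditionMessage(e))
                        })
        dplyr::mutate(res, split = nm, .before = 1)
      }),
      dif_facets = purrr::imap(splits[names(splits) != "score"],
                               function(s, nm) {
                                 dif_facets_pcm(data, s, items, q = q)
                               }),
      well_conditioned = well_conditioned_check(dich, items)
    )
  }
  if ("validity" %in% stages) {
    specials <- intersect(c("digital", "communicative", "navigational",
                            "vaccination"), names(scored))
    out$validity <- list(
      concurrent_d = concurrent_validity_models(scored, "score_d"),
      concurrent_p = concurrent_validity_models(scored, "score_p"),
      discriminant = if (length(specials) > 0) {
        dplyr::bind_rows(
          discriminant_check(scored, "score_d", specials),
          discriminant_check(scored, "score_p", specials)
        )
      }
    )
  }
  structure(out, class = "hls_report")
}

#' @export
print.hls_report <- function(x, ...) {
  cat("HLS19-Q12 validation report (n =", x$settings$n, ")\n")
  cat("  stages:", paste(setdiff(names(x), "settings"), collapse = ", "), "\n")
  if (!is.null(x$scoring)) {
    d <- x$scoring$descriptives
    cat(sprintf("  scores: D mean %.1f (sd %.1f), P mean %.1f (sd %.1f)\n",
                d$mean[1], d$sd[1], d$mean[2], d$sd[2]))
  }
  if (!is.null(x$classical)) {
    a <- x$classical$alphas
    cat(sprintf("  alpha: %.3f (poly) / %.3f (dich); CFA SRMSR %.3f CFI %.3f\n",
                a$cronbach[1], a$cronbach[2],
                x$classical$cfa$srmsr, x$classical$cfa$cfi))
  }
  if (!is.null(x$irt)) {
    r <- x$irt$reliability
    cat(sprintf("  reliability: WLE %.3f, EAP %.3f; sigma %.3f\n",
                r$wle, r$eap, x$irt$pcm$sigma))
  }
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  diagnostics: SRMSR %.3f, MADaQ3 %.4f, PCA/t-test %s\n",
                x$diagnostics$srmsr, x$diagnostics$q3$madaq3,
                if (isTRUE(x$diagnostics$pca_ttest$supported))
                  "supported" else "not supported"))
  }
  invisible(x)
}

#' Serialise a report to JSON
#'
#' Writes the report's tabular content (scores descriptives, level
#' distributions, alphas, fit indices, reliabilities, diagnostic summaries,
#' regression tables) as machine-readable JSON, with the settings and seed
#' embedded for provenance.
#'
#' @param report `hls_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- list(settings = report$settings)
  if (!is.null(report$scoring)) {
    payload$scoring <- list(
      descriptives = report$scoring$descriptives,
      levels_d = report$scoring$levels_d,
      levels_p = report$scoring$levels_p,
      item_difficulty = report$scoring$item_difficulty
    )
  }
  if (!is.null(report$classical)) {
    payload$classical <- list(
      alphas = report$classical$alphas,
      cfa = glance(report$classical$cfa)
    )
  }
  if (!is.null(report$irt)) {
    payload$irt <- list(
      pcm = glance(report$irt$pcm),
      reliability = report$irt$reliability
    )
  }
  if (!is.null(report$diagnostics)) {
    payload$diagnostics <- list(
      infit = report$diagnostics$infit,
      madaq3 = report$diagnostics$q3$madaq3,
      srmsr = report$diagnostics$srmsr,
      pca_ttest = list(proportion = report$diagnostics$pca_ttest$proportion,
                       supported = report$diagnostics$pca_ttest$supported),
      lr_tests = report$diagnostics$lr_tests
    )
  }
  if (!is.null(report$validity)) {
    payload$validity <- list(
      determinants_d = glance(report$validity$concurrent_d$determinants),
      determinants_p = glance(report$validity$concurrent_p$determinants),
      discriminant = report$validity$discriminant
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
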