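#' The canonical HLS19-Q12 instrument definition
#'
#' The 12-item short form measures general health literacy on a 3 x 4
#' conceptual matrix: three domains of health-relevant tasks (health care,
#' disease prevention, health promotion) crossed with four stages of dealing
#' with health information (access, understand, appraise, apply). Each cell
#' is covered by exactly one item; respondents rate the perceived difficulty
#' of each task on a four-point scale (1 = "very difficult" ... 4 = "very
#' easy").
#'
#' @return A tibble with one row per item and columns `item` (identifier,
#'   `"hl1"`..`"hl12"`), `text` (task wording), `domain` and `stage`.
#' @export
#' @examples
#' hls_instrument()
hls_instrument <- function() {
  texts <- c(
    "to find out where to get professional help when you are ill",
    "to understand information about what to do in a medical emergency",
    "to judge the advantages and disadvantages of different treatment options",
    "to act on advice from your doctor or pharmacist",
    "to find information on how to handle mental health problems",
    "to understand information about recommended health screenings or examinations",
    "to judge if information on unhealthy habits are reliable",
    "to decide how you can protect yourself from illness using information from the mass media",
    "to find information on healthy lifestyles",
    "to understand advice concerning your health from family or friends",
    "to judge how your housing conditions may affect your health and well-being",
    "to make decisions to improve your health and well-being"
  )
  tibble::tibble(
    item = paste0("hl", 1:12),
    text = texts,
    domain = rep(c("health_care", "disease_prevention", "health_promotion"), each = 4),
    stage = rep(c("access", "understand", "appraise", "apply"), times = 3)
  )
}

#' Item identifiers of the canonical instrument
#'
#' @param instrument An instrument tibble as returned by [hls_instrument()].
#' @return Character vector of item ids, in instrument order.
#' @export
hls_items <- function(instrument = hls_instrument()) {
  validate_instrument(instrument)
  instrument$item
}

validate_instrument <- function(instrument) {
  stopifnot(is.data.frame(instrument),
            all(c("item", "domain", "stage") %in% names(instrument)))
  if (anyDuplicated(instrument$item) > 0) {
    stop("instrument item ids must be unique", call. = FALSE)
  }
  invisible(instrument)
}

# Assert the 3x4 matrix structure of the canonical short form: 12 items, each
# (domain, stage) cell occupied exactly once.
validate_q12_instrument <- function(instrument) {
  validate_instrument(instrument)
  if (nrow(instrument) != 12L) {
    stop("canonical HLS19-Q12 instrument must have exactly 12 items", call. = FALSE)
  }
  cells <- paste(instrument$domain, instrument$stage)
  if (length(unique(cells)) != 12L) {
    stop("each (domain, stage) cell must be occupied exactly once", call. = FALSE)
  }
  invisible(instrument)
}

#' Read and validate a respondent-level survey table
#'
#' Reads a delimited text file of survey responses and maps its columns onto
#' the roles the analysis pipeline expects: ordinal item responses coded 1-4,
#' an optional post-stratification weight, and optional covariates. Any item
#' entry outside `{1, 2, 3, 4}` (including blanks and "don't know" style
#' codes) is converted to missing; the number of converted cells is reported
#' as a warning so silent recoding never goes unnoticed.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Named list mapping roles to column names. `items` (required)
#'   is a character vector of response columns in instrument order; optional
#'   scalar entries: `weight`, `sex`, `age`, `education`, `status`, `findep`,
#'   `health`, `mode`, `country`.
#' @param instrument Instrument definition; item columns are renamed to its
#'   item ids.
#' @param delim Field delimiter, default `","`.
#' @return A tibble with one row per respondent: item columns named after the
#'   instrument ids, a `weight` column (1 when absent from the file), and any
#'   mapped covariates under their canonical names.
#' @export
read_responses <- function(path, schema, instrument = hls_instrument(),
                           delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(schema$items)) stop("schema must map 'items'", call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(raw) == 0L) stop("input file contains no respondents", call. = FALSE)

  roles <- c("weight", "sex", "age", "education", "status", "findep",
             "health", "mode", "country")
  wanted <- c(schema$items, unlist(schema[intersect(names(schema), roles)]))
  missing_cols <- setdiff(wanted, names(raw))
  if (length(missing_cols) > 0) {
    stop("mapped columns absent from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  items <- hls_items_for(instrument, length(schema$items))
  out <- raw[, schema$items, drop = FALSE]
  names(out) <- items
  for (role in roles) {
    if (!is.null(schema[[role]])) out[[role]] <- raw[[schema[[role]]]]
  }
  if (is.null(schema$weight)) out$weight <- 1
  validate_responses(tibble::as_tibble(out), items = items)
}

hls_items_for <- function(instrument, k) {
  ids <- hls_items(instrument)
  if (length(ids) != k) {
    stop("schema maps ", k, " item columns but instrument has ",
         length(ids), " items", call. = FALSE)
  }
  ids
}

#' Validate a respondent table
#'
#' Coerces item columns to integer, converts out-of-range codes to `NA`
#' (warning with the count of converted cells), and checks that weights are
#' strictly positive.
#'
#' @param data Respondent tibble.
#' @param items Character vector of item column names.
#' @param n_categories Number of ordered response categories (4 for HLS19).
#' @return The validated tibble.
#' @export
validate_responses <- function(data, items = hls_items(), n_categories = 4L) {
  stopifnot(is.data.frame(data))
  absent <- setdiff(items, names(data))
  if (length(absent) > 0) {
    stop("item columns absent from data: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0L) stop("respondent table has zero rows", call. = FALSE)
  n_bad <- 0L
  for (it in items) {
    x <- suppressWarnings(as.integer(data[[it]]))
    bad <- !is.na(x) & (x < 1L | x > n_categories)
    bad <- bad | (!is.na(data[[it]]) & is.na(x))
    n_bad <- n_bad + sum(bad)
    x[bad] <- NA_integer_
    data[[it]] <- x
  }
  if (n_bad > 0) {
    warning(n_bad, " item entr", if (n_bad == 1) "y" else "ies",
            " outside 1..", n_categories, " converted to missing",
            call. = FALSE)
  }
  if (!"weight" %in% names(data)) data$weight <- 1
  if (any(!is.finite(data$weight)) || any(data$weight <= 0)) {
    stop("weights must be finite and > 0", call. = FALSE)
  }
  tibble::as_tibble(data)
}

#' Dichotomize polytomous responses
#'
#' Merges "very easy" with "easy" (codes 3, 4 become 1) and "very difficult"
#' with "difficult" (codes 1, 2 become 0), as required for the dichotomous
#' Rasch analyses and the type D score. Missing entries stay missing.
#'
#' @inheritParams validate_responses
#' @return The input tibble with item columns recoded to 0/1 and an
#'   attribute `dichotomized = TRUE`.
#' @export
#' @examples
#' d <- tibble::tibble(hl1 = c(4, 2, NA))
#' dichotomize(d, items = "hl1")
dichotomize <- function(data, items = hls_items()) {
  for (it in items) {
    data[[it]] <- ifelse(is.na(data[[it]]), NA_integer_,
                         as.integer(data[[it]] >= 3L))
  }
  attr(data, "dichotomized") <- TRUE
  data
}

#' Shift raw response codes to IRT category indices
#'
#' Maps the raw codes 1..4 to the 0..3 indexing used by the item response
#' models; missing preserved.
#'
#' @inheritParams validate_responses
#' @export
shift_to_irt <- function(data, items = hls_items()) {
  for (it in items) data[[it]] <- data[[it]] - 1L
  data
}

# items x persons integer matrix view of the item columns
resp_matrix <- function(data, items = hls_items()) {
  m <- as.matrix(data[, items, drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Median split of a numeric person variable
#'
#' Splits respondents into `low`/`high` groups at the sample median. Persons
#' exactly at the median go to `low`; this tie rule is fixed so that splits
#' (age, raw test score) are reproducible.
#'
#' @param values Numeric vector.
#' @return Factor with levels `low`, `high`.
#' @export
#' @examples
#' median_split(c(20, 30, 40, 50))
median_split <- function(values) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2L) {
    stop("median split needs at least two distinct values", call. = FALSE)
  }
  med <- stats::median(v)
  factor(ifelse(values > med, "high", "low"), levels = c("low", "high"))
}

#' Filter respondents by covariate predicate
#'
#' A thin wrapper over [dplyr::filter()] that errors on an empty result and
#' on references to absent covariates, so subgroup analyses (per data
#' collection mode, per country) fail loudly rather than silently.
#'
#' @param data Respondent tibble.
#' @param ... Filter expressions on covariate columns.
#' @return The row-filtered tibble.
#' @export
subgroup <- function(data, ...) {
  out <- tryCatch(dplyr::filter(data, ...), error = function(e) {
    stop("subgroup predicate failed: ", conditionMessage(e), call. = FALSE)
  })
  if (nrow(out) == 0L) stop("subgroup is empty", call. = FALSE)
  out
}

#' Write a respondent table back to delimited text
#'
#' @param data Respondent tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @export
write_responses <- function(data, path, delim = ",") {
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}
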