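#' Disease catalogs
#'
#' A disease catalog fixes the node universe of every network snapshot: one
#' node per chronic-disease category, identified by a contiguous integer id.
#' Diseases that have not yet co-occurred at early ages stay in the catalog as
#' isolated nodes, so adjacency matrices at different ages are conformable.
#'
#' @param x A data frame with columns `disease_id` and `name`, or the path to
#'   a CSV file with those columns.
#' @return A tibble of class `disease_catalog` with columns `disease_id`
#'   (contiguous integers starting at 1) and `name`.
#' @examples
#' disease_catalog(data.frame(disease_id = 1:3, name = c("a", "b", "c")))
#' @export
disease_catalog <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- readr::read_csv(x, show_col_types = FALSE)
  }
  x <- tibble::as_tibble(x)
  for (col in c("disease_id", "name")) {
    if (!col %in% names(x)) {
      stop("catalog is missing required column '", col, "'", call. = FALSE)
    }
  }
  x$disease_id <- as.integer(x$disease_id)
  x <- dplyr::arrange(x, .data$disease_id)
  ids <- x$disease_id
  # accept 0- or arbitrary-based contiguous ids, renumber to 1..n
  if (!identical(ids, seq(min(ids), length.out = nrow(x)))) {
    stop("catalog ids must be contiguous integers", call. = FALSE)
  }
  if (anyDuplicated(x$name)) {
    stop("catalog names must be unique", call. = FALSE)
  }
  x$disease_id <- seq_len(nrow(x))
  class(x) <- c("disease_catalog", class(x))
  x
}

#' @rdname disease_catalog
#' @details `default_disease_catalog()` returns the 14 chronic-disease
#'   categories surveyed in middle-aged and elderly Chinese cohorts
#'   (CHARLS-style self-reported physician diagnoses).
#' @export
default_disease_catalog <- function() {
  disease_catalog(tibble::tibble(
    disease_id = 1:14,
    name = c(
      "Dyslipidemia",
      "Hypertension",
      "Stomach or other digestive disease",
      "Heart disease",
      "Arthritis or rheumatism",
      "Diabetes or high blood sugar",
      "Chronic lung disease",
      "Stroke",
      "Kidney disease",
      "Liver disease",
      "Memory-related disease",
      "Asthma",
      "Emotional or psychiatric problem",
      "Cancer or malignant tumor"
    )
  ))
}

n_diseases <- function(catalog) nrow(catalog)

#' Published CHARLS 2018 reference tables
#'
#' Small reference tables from the CHARLS 2018 multimorbidity study that this
#' package's methods are benchmarked against: the per-disease prevalence among
#' the 3,333 retained multimorbid patients, and the reported link-prediction
#' ranking metrics (MAP, MRR) of five dynamic-graph models on that cohort.
#' These are reported values, shipped for arithmetic cross-checks and
#' context; the underlying patient-level data is available on request only.
#'
#' @return A tibble. `charls_prevalence()` has columns `name`, `n_patients`,
#'   `percent_reported`; `charls_model_comparison()` has columns `model`,
#'   `map`, `mrr`.
#' @export
charls_prevalence <- function() {
  path <- system.file("extdata", "charls_prevalence.csv", package = "cegcn")
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname charls_prevalence
#' @export
charls_model_comparison <- function() {
  path <- system.file("extdata", "charls_model_comparison.csv", package = "cegcn")
  readr::read_csv(path, show_col_types = FALSE)
}
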