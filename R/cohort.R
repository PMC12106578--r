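#' Load and filter a patient cohort
#'
#' Reads long-form patient-disease-onset records from delimited text and
#' applies the cohort filter used when building multimorbidity networks:
#' records outside the age window are dropped, and patients left with fewer
#' than two distinct diseases are removed entirely (a network edge needs two
#' diseases in the same patient, so single-disease patients carry no signal).
#'
#' The reader accepts either a true onset-age column (`onset_age`) or a
#' single `age` column, which is then interpreted as the onset age of all of
#' that patient's diseases; survey data often records only age at interview,
#' and which convention was used is stated in the drop log. The disease
#' column may hold catalog ids (`disease_id`) or catalog names (`disease`).
#'
#' @param path Path to a CSV/TSV file with a header. Required columns:
#'   `patient_id`, `disease` or `disease_id`, and `onset_age` or `age`.
#' @param catalog A [disease_catalog()].
#' @param age_min,age_max Integer age window, inclusive. Defaults 45 and 90.
#' @return A tibble of class `cohort_table` with columns `patient_id`
#'   (character), `disease_id` (integer, 1-based catalog index) and
#'   `onset_age` (integer). The filtering log is attached as attribute
#'   `drop_log`, the catalog as attribute `catalog`.
#' @seealso [build_snapshots()], [prevalence_table()], [simulate_cohort()]
#' @export
load_cohort <- function(path, catalog, age_min = 45L, age_max = 90L) {
  stopifnot(file.exists(path))
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  as_cohort(raw, catalog, age_min = age_min, age_max = age_max)
}

#' @rdname load_cohort
#' @param records A data frame of raw records, as described for `path`.
#' @export
as_cohort <- function(records, catalog, age_min = 45L, age_max = 90L) {
  records <- tibble::as_tibble(records)
  if (!"patient_id" %in% names(records)) {
    stop("cohort input is missing required column 'patient_id'", call. = FALSE)
  }
  age_col <- intersect(c("onset_age", "age"), names(records))[1]
  if (is.na(age_col)) {
    stop("cohort input is missing required column 'onset_age' (or 'age')",
         call. = FALSE)
  }
  if ("disease_id" %in% names(records)) {
    did <- as.integer(records$disease_id)
    bad <- setdiff(unique(did), catalog$disease_id)
    if (length(bad)) {
      stop("disease ids not in catalog: ", paste(sort(bad), collapse = ", "),
           call. = FALSE)
    }
  } else if ("disease" %in% names(records)) {
    idx <- match(records$disease, catalog$name)
    if (anyNA(idx)) {
      bad <- sort(unique(records$disease[is.na(idx)]))
      stop("disease names not in catalog: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    did <- catalog$disease_id[idx]
  } else {
    stop("cohort input is missing required column 'disease' (or 'disease_id')",
         call. = FALSE)
  }

  x <- tibble::tibble(
    patient_id = as.character(records$patient_id),
    disease_id = did,
    onset_age = as.integer(records[[age_col]])
  )
  n_raw <- nrow(x)
  # one record per (patient, disease): keep the earliest onset
  if (n_raw > 0) {
    x <- x |>
      dplyr::group_by(.data$patient_id, .data$disease_id) |>
      dplyr::summarise(onset_age = min(.data$onset_age), .groups = "drop")
  }
  n_dedup <- n_raw - nrow(x)

  in_window <- x$onset_age >= age_min & x$onset_age <= age_max
  n_age_dropped <- sum(!in_window)
  x <- x[in_window, , drop = FALSE]

  multi <- x |>
    dplyr::count(.data$patient_id) |>
    dplyr::filter(.data$n >= 2)
  n_patients_raw <- dplyr::n_distinct(x$patient_id)
  x <- dplyr::semi_join(x, multi, by = "patient_id") |>
    dplyr::arrange(.data$patient_id, .data$onset_age, .data$disease_id)

  log <- list(
    n_records_in = n_raw,
    n_duplicate_records_merged = n_dedup,
    n_records_outside_age_window = n_age_dropped,
    n_patients_single_disease = n_patients_raw - dplyr::n_distinct(x$patient_id),
    n_patients_retained = dplyr::n_distinct(x$patient_id),
    n_records_retained = nrow(x),
    age_column_used = age_col
  )
  if (nrow(x) == 0) {
    warning("cohort is empty after filtering", call. = FALSE)
  }
  attr(x, "drop_log") <- log
  attr(x, "catalog") <- catalog
  attr(x, "age_range") <- c(age_min, age_max)
  class(x) <- c("cohort_table", class(x))
  x
}

cohort_catalog <- function(cohort, catalog = NULL) {
  if (!is.null(catalog)) return(catalog)
  cat <- attr(cohort, "catalog")
  if (is.null(cat)) stop("no catalog attached to cohort; pass one explicitly",
                         call. = FALSE)
  cat
}

round2 <- function(x) round(x, 2)

prevalence_percent <- function(count, n_patients) {
  round2(100 * count / n_patients)
}

#' Per-disease prevalence of a cohort
#'
#' Counts, for each catalog disease, the number of distinct patients affected
#' and expresses it as a percentage of the cohort, rounded to two decimals
#' and sorted by count descending.
#'
#' @param cohort A `cohort_table` from [load_cohort()] or [as_cohort()].
#' @param catalog Optional [disease_catalog()]; defaults to the one attached
#'   to the cohort.
#' @return A tibble with columns `name`, `n_patients`, `percent`.
#' @examples
#' cat3 <- disease_catalog(data.frame(disease_id = 1:3, name = c("a", "b", "c")))
#' rec <- data.frame(patient_id = c("P1", "P1", "P2", "P2"),
#'                   disease_id = c(1, 2, 1, 3),
#'                   onset_age = c(50, 55, 60, 61))
#' prevalence_table(as_cohort(rec, cat3))
#' @export
prevalence_table <- function(cohort, catalog = NULL) {
  catalog <- cohort_catalog(cohort, catalog)
  if (nrow(cohort) == 0) {
    return(tibble::tibble(name = character(), n_patients = integer(),
                          percent = numeric()))
  }
  n_total <- dplyr::n_distinct(cohort$patient_id)
  cohort |>
    dplyr::distinct(.data$patient_id, .data$disease_id) |>
    dplyr::count(.data$disease_id, name = "n_patients") |>
    dplyr::left_join(catalog, by = "disease_id") |>
    dplyr::mutate(percent = prevalence_percent(.data$n_patients, n_total)) |>
    dplyr::arrange(dplyr::desc(.data$n_patients), .data$name) |>
    dplyr::select("name", "n_patients", "percent")
}
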