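#' Build the age-indexed multimorbidity snapshot sequence
#'
#' Turns a filtered cohort into an ordered sequence of disease-disease graphs
#' G_t, one per integer year of age. Nodes are the catalog diseases (fixed
#' across ages); an edge joins diseases i and j when at least one patient
#' carries both, and its integer weight is the number of such patients. In
#' `"cumulative"` mode (the default) a patient contributes the pair (i, j)
#' at every age t >= max(onset_i, onset_j), so edges persist once formed and
#' the edge set grows monotonically with age. In `"incident"` mode the pair
#' is counted only at the single age t == max(onset_i, onset_j); incident
#' weights summed over all ages equal the cumulative weights at `age_max`.
#'
#' @param cohort A `cohort_table`.
#' @param catalog Optional [disease_catalog()]; defaults to the cohort's.
#' @param age_min,age_max Inclusive integer age window; defaults to the
#'   window the cohort was filtered with (45-90 for the standard pipeline).
#' @param mode `"cumulative"` or `"incident"`.
#' @return An object of class `snapshot_sequence`: a list with elements
#'   `ages` (integer vector), `mode`, `adjacency` (list of n x n binary
#'   matrices), `weights` (list of n x n integer matrices) and `catalog`.
#' @examples
#' cat3 <- disease_catalog(data.frame(disease_id = 1:3, name = c("a", "b", "c")))
#' rec <- data.frame(patient_id = c("P1", "P1"), disease_id = c(1, 2),
#'                   onset_age = c(50, 52))
#' sq <- build_snapshots(as_cohort(rec, cat3, 45, 55), age_min = 45, age_max = 55)
#' sq$adjacency[["52"]][1, 2] # edge appears at the later onset age
#' @export
build_snapshots <- function(cohort, catalog = NULL, age_min = NULL,
                            age_max = NULL, mode = c("cumulative", "incident")) {
  mode <- match.arg(mode)
  catalog <- cohort_catalog(cohort, catalog)
  rng <- attr(cohort, "age_range")
  if (is.null(age_min)) age_min <- if (!is.null(rng)) rng[1] else 45L
  if (is.null(age_max)) age_max <- if (!is.null(rng)) rng[2] else 90L
  stopifnot(age_min < age_max)
  ages <- seq.int(age_min, age_max)
  n <- n_diseases(catalog)

  # per-patient disease pairs with the age at which the pair completes
  pair_ages <- pair_completion_ages(cohort)

  zero <- matrix(0L, n, n, dimnames = list(catalog$name, catalog$name))
  weights <- lapply(ages, function(a) zero)
  names(weights) <- as.character(ages)
  if (nrow(pair_ages)) {
    tal <- pair_ages |>
      dplyr::count(.data$i, .data$j, .data$pair_age, name = "n_patients")
    for (age_chr in names(weights)) {
      a <- as.integer(age_chr)
      sel <- if (mode == "cumulative") tal$pair_age <= a else tal$pair_age == a
      sub <- tal[sel, , drop = FALSE]
      if (!nrow(sub)) next
      w <- zero
      agg <- stats::aggregate(n_patients ~ i + j, data = sub, FUN = sum)
      w[cbind(agg$i, agg$j)] <- agg$n_patients
      w <- w + t(w)
      weights[[age_chr]] <- w
    }
  }
  adjacency <- lapply(weights, function(w) (w >= 1L) + 0L)
  structure(
    list(ages = ages, mode = mode, adjacency = adjacency, weights = weights,
         catalog = catalog),
    class = "snapshot_sequence"
  )
}

# For each patient and unordered disease pair (i < j), the age at which both
# diseases are present: max of the two onset ages.
pair_completion_ages <- function(cohort) {
  if (nrow(cohort) == 0) {
    return(tibble::tibble(patient_id = character(), i = integer(),
                          j = integer(), pair_age = integer()))
  }
  cohort |>
    dplyr::distinct(.data$patient_id, .data$disease_id, .keep_all = TRUE) |>
    dplyr::inner_join(
      dplyr::distinct(cohort, .data$patient_id, .data$disease_id,
                      .keep_all = TRUE),
      by = "patient_id", suffix = c("_a", "_b"),
      relationship = "many-to-many"
    ) |>
    dplyr::filter(.data$disease_id_a < .data$disease_id_b) |>
    dplyr::transmute(
      .data$patient_id,
      i = .data$disease_id_a,
      j = .data$disease_id_b,
      pair_age = pmax(.data$onset_age_a, .data$onset_age_b)
    )
}

#' @export
print.snapshot_sequence <- function(x, ...) {
  n_edges <- vapply(x$adjacency, function(a) sum(a) / 2, numeric(1))
  cat("<snapshot_sequence> ", length(x$ages), " ages (",
      min(x$ages), "-", max(x$ages), "), mode = ", x$mode, ", ",
      n_diseases(x$catalog), " diseases\n", sep = "")
  cat("  edges: ", n_edges[[1]], " at age ", min(x$ages), " -> ",
      n_edges[[length(n_edges)]], " at age ", max(x$ages), "\n", sep = "")
  invisible(x)
}

#' @export
length.snapshot_sequence <- function(x) length(x$ages)

snapshot_at <- function(sequence, age) {
  key <- as.character(age)
  if (!key %in% names(sequence$adjacency)) {
    stop("no snapshot at age ", age, call. = FALSE)
  }
  list(age = age, adjacency = sequence$adjacency[[key]],
       weights = sequence$weights[[key]])
}

#' Edge counts per age as a tidy table
#'
#' @param x A `snapshot_sequence`.
#' @return A tibble with columns `age`, `n_edges`, `total_weight`.
#' @export
edge_summary <- function(x) {
  tibble::tibble(
    age = x$ages,
    n_edges = vapply(x$adjacency, function(a) sum(a) / 2, numeric(1)),
    total_weight = vapply(x$weights, function(w) sum(w) / 2, numeric(1))
  )
}

checksum_catalog <- function(catalog) {
  s <- paste(catalog$disease_id, catalog$name, collapse = ";")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1000000007
}

#' Write and read snapshot sequences as edge lists
#'
#' Serializes a [build_snapshots()] result to one edge-list TSV per age
#' (`src_id`, `dst_id`, `weight`, upper triangle only) plus a JSON manifest
#' holding the ages, mode and catalog. `read_snapshots()` inverts the
#' operation exactly.
#'
#' @param sequence A `snapshot_sequence`.
#' @param dir Output directory; created if missing.
#' @return `write_snapshots()` returns `dir` invisibly; `read_snapshots()`
#'   returns a `snapshot_sequence`.
#' @export
write_snapshots <- function(sequence, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    ages = sequence$ages,
    mode = sequence$mode,
    catalog = list(disease_id = sequence$catalog$disease_id,
                   name = sequence$catalog$name),
    catalog_checksum = checksum_catalog(sequence$catalog)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (age_chr in names(sequence$weights)) {
    w <- sequence$weights[[age_chr]]
    idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    edges <- tibble::tibble(src_id = idx[, 1], dst_id = idx[, 2],
                            weight = w[idx])
    readr::write_tsv(edges, file.path(dir, paste0("age_", age_chr, ".tsv")),
                     progress = FALSE)
  }
  invisible(dir)
}

#' @rdname write_snapshots
#' @export
read_snapshots <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  catalog <- disease_catalog(tibble::tibble(
    disease_id = manifest$catalog$disease_id,
    name = manifest$catalog$name
  ))
  n <- n_diseases(catalog)
  ages <- as.integer(manifest$ages)
  zero <- matrix(0L, n, n, dimnames = list(catalog$name, catalog$name))
  weights <- lapply(ages, function(a) {
    f <- file.path(dir, paste0("age_", a, ".tsv"))
    w <- zero
    if (file.exists(f)) {
      edges <- readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
      if (nrow(edges)) {
        w[cbind(edges$src_id, edges$dst_id)] <- as.integer(edges$weight)
        w <- w + t(w)
      }
    }
    w
  })
  names(weights) <- as.character(ages)
  structure(
    list(ages = ages, mode = manifest$mode,
         adjacency = lapply(weights, function(w) (w >= 1L) + 0L),
         weights = weights, catalog = catalog),
    class = "snapshot_sequence"
  )
}
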