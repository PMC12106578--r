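#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the structure of a CHARLS-like chronic-disease
#' cohort: each patient carries latent exposures to a small number of shared
#' risk factors; each disease loads on one factor; a patient's yearly onset
#' hazard for a disease grows with the exposure-loading product and with a
#' mild linear age ramp. Diseases sharing a factor therefore co-occur more
#' than chance, and co-occurrence accumulates with age — the mechanism the
#' multimorbidity network model is meant to pick up. Setting
#' `loading_scale = 0` gives the exact independence null.
#'
#' @param n_patients Number of simulated individuals (default 3333, the
#'   scale of the reference cohort).
#' @param n_diseases Number of chronic-disease categories (default 14).
#' @param n_factors Number of latent shared risk factors.
#' @param loading_scale Effect size coupling diseases to factors; 0 makes
#'   disease onsets pairwise independent.
#' @param baseline_hazard Per-year baseline onset rate before modulation.
#' @param disease_sd Log-normal spread of per-disease rate multipliers,
#'   giving realistic heterogeneity in marginal prevalence.
#' @param age_min,age_max Simulated onset-age window (default 45-90).
#' @param seed Integer seed; cohorts are bit-reproducible given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 3333, n_diseases = 14, n_factors = 4,
                       loading_scale = 1, baseline_hazard = 0.0008,
                       disease_sd = 0.4, age_min = 45L, age_max = 90L,
                       seed = 1L) {
  stopifnot(n_patients >= 1, n_diseases >= 2, n_factors >= 1,
            loading_scale >= 0, baseline_hazard > 0, baseline_hazard < 1,
            age_min < age_max)
  structure(list(n_patients = as.integer(n_patients),
                 n_diseases = as.integer(n_diseases),
                 n_factors = as.integer(n_factors),
                 loading_scale = loading_scale,
                 baseline_hazard = baseline_hazard, disease_sd = disease_sd,
                 age_min = as.integer(age_min), age_max = as.integer(age_max),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# mild increasing age ramp: 1 at age_min, 2 at age_max
age_ramp <- function(a, age_min, age_max) {
  1 + (a - age_min) / (age_max - age_min)
}

#' Simulate a chronic-disease cohort with shared latent risk factors
#'
#' Draws patient exposures (gamma, mean 1) and disease-factor loadings (each
#' disease assigned to one factor unless `loadings` is supplied), then walks
#' the age axis: at age a, patient p acquires disease d with probability
#' 1 - exp(-baseline_hazard * m_d * (1 + loading_scale * x_p . l_d) * g(a)),
#' where m_d is a per-disease rate multiplier and g(a) a linear age ramp.
#' The first success year is the onset age. Patients with fewer than two
#' diseases are retained in the raw output — filtering is [load_cohort()] /
#' [as_cohort()]'s job, so the fixture path exercises the real reader.
#'
#' @param config A [sim_config()].
#' @param loadings Optional `n_diseases x n_factors` nonnegative loading
#'   matrix; overrides the random one-factor-per-disease default (useful for
#'   planting block structure).
#' @return A list with `records` (tibble: patient_id, disease_id, onset_age —
#'   the CSV dialect [load_cohort()] reads), and `truth` (list: loadings,
#'   exposures, disease_mult, n_multimorbid — the generator's bookkeeping).
#' @export
simulate_cohort <- function(config, loadings = NULL) {
  cf <- config
  withr::with_seed(cf$seed, {
    if (is.null(loadings)) {
      loadings <- matrix(0, cf$n_diseases, cf$n_factors)
      loadings[cbind(seq_len(cf$n_diseases),
                     sample.int(cf$n_factors, cf$n_diseases, replace = TRUE))] <- 1
    }
    stopifnot(nrow(loadings) == cf$n_diseases, all(loadings >= 0))
    n_factors <- ncol(loadings)
    exposures <- matrix(stats::rgamma(cf$n_patients * n_factors,
                                      shape = 2, rate = 2),
                        cf$n_patients, n_factors)
    disease_mult <- exp(stats::rnorm(cf$n_diseases, 0, cf$disease_sd))

    # n_patients x n_diseases matrix of age-independent rate factors
    rate <- cf$baseline_hazard *
      outer(rep(1, cf$n_patients), disease_mult) *
      (1 + cf$loading_scale * exposures %*% t(loadings))

    onset <- matrix(NA_integer_, cf$n_patients, cf$n_diseases)
    for (a in seq.int(cf$age_min, cf$age_max)) {
      p_onset <- 1 - exp(-rate * age_ramp(a, cf$age_min, cf$age_max))
      hit <- is.na(onset) &
        matrix(stats::runif(length(onset)), nrow(onset)) < p_onset
      onset[hit] <- a
    }

    idx <- which(!is.na(onset), arr.ind = TRUE)
    records <- tibble::tibble(
      patient_id = sprintf("P%05d", idx[, 1]),
      disease_id = as.integer(idx[, 2]),
      onset_age = onset[idx]
    ) |>
      dplyr::arrange(.data$patient_id, .data$onset_age, .data$disease_id)

    per_patient <- table(factor(idx[, 1], levels = seq_len(cf$n_patients)))
    truth <- list(loadings = loadings, exposures = exposures,
                  disease_mult = disease_mult,
                  n_multimorbid = sum(per_patient >= 2))
    list(records = records, truth = truth)
  })
}

#' Plant a "common neighbours predict future links" rule into a cohort
#'
#' Augments a simulated cohort so that the structural premise of
#' common-neighbour link prediction is literally true: walking the age axis
#' over the cumulative co-occurrence network, at each age, with probability
#' `min(1, rule_strength / 2)`, the currently *unlinked* disease pair with
#' the highest common-neighbour count (ties broken by ascending node ids)
#' receives an injected patient who carries both diseases with onset at the
#' next age — creating the very future link that a high common-neighbour
#' count is hypothesized to foreshadow. One event per age at most keeps the
#' planted set sparse, so the network does not saturate and planted links
#' keep appearing throughout the age range, including the latest (test)
#' ages. Injected patients get fresh ids prefixed `"INJ"`. The planted
#' (pair, age) events are returned so recovery tests can check that a fitted
#' model ranks the planted pairs highly.
#'
#' @param records A records tibble from [simulate_cohort()].
#' @param config The [sim_config()] used (for age window and disease count).
#' @param rule_strength Nonnegative injection rate scale; 0 returns the
#'   input unchanged, values >= 2 plant one link at every age that has an
#'   eligible pair.
#' @param seed Integer seed for the injection draws; defaults to
#'   `config$seed + 1`.
#' @return A list with `records` (augmented tibble) and `planted` (tibble:
#'   age, i, j).
#' @export
plant_temporal_rule <- function(records, config, rule_strength = 1,
                                seed = config$seed + 1L) {
  if (rule_strength < 0) stop("rule_strength must be >= 0", call. = FALSE)
  if (rule_strength == 0) {
    return(list(records = records,
                planted = tibble::tibble(age = integer(), i = integer(),
                                         j = integer())))
  }
  n <- config$n_diseases
  p_event <- min(1, rule_strength / 2)
  inj <- list()
  planted <- list()
  pairs <- all_node_pairs(n)
  withr::with_seed(seed, {
    for (a in seq.int(config$age_min, config$age_max - 1L)) {
      if (stats::runif(1) >= p_event) next
      all_rec <- if (length(inj)) dplyr::bind_rows(records, inj) else records
      adj <- cumulative_adjacency(all_rec, n, a)
      sq <- adj %*% adj
      cn <- sq[upper.tri(sq)]
      linked <- adj[upper.tri(adj)] == 1
      eligible <- !linked & cn > 0
      if (!any(eligible)) next
      idx <- which(eligible)[order(-cn[eligible], pairs[eligible, 1],
                                   pairs[eligible, 2])[1]]
      i <- pairs[idx, 1]; j <- pairs[idx, 2]
      pid <- sprintf("INJ%05d", length(planted) + 1L)
      inj[[length(inj) + 1L]] <- tibble::tibble(
        patient_id = pid, disease_id = c(i, j),
        onset_age = c(a + 1L, a + 1L)
      )
      planted[[length(planted) + 1L]] <- tibble::tibble(
        age = a + 1L, i = i, j = j
      )
    }
  })
  list(
    records = dplyr::bind_rows(c(list(records), inj)),
    planted = if (length(planted)) dplyr::bind_rows(planted)
              else tibble::tibble(age = integer(), i = integer(),
                                  j = integer())
  )
}

# binary cumulative co-occurrence adjacency at age a, straight from records
cumulative_adjacency <- function(records, n, a) {
  adj <- matrix(0L, n, n)
  rec <- records[records$onset_age <= a, , drop = FALSE]
  if (nrow(rec)) {
    sp <- split(rec$disease_id, rec$patient_id)
    for (ds in sp) {
      ds <- unique(ds)
      if (length(ds) >= 2) {
        cmb <- utils::combn(sort(ds), 2)
        adj[t(cmb)] <- 1L
      }
    }
    adj <- pmax(adj, t(adj))
  }
  adj
}

#' Write cohort records in the CSV dialect the reader expects
#'
#' @param records A records tibble (`patient_id`, `disease_id`, `onset_age`).
#' @param path Output CSV path.
#' @export
write_cohort_csv <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}
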