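#' Build the diagnostic-pathway state-transition model
#'
#' The pathway starts at "suspicion of lung cancer", runs through the four
#' non-terminal stages imaging -> invasive (tissue acquisition) ->
#' functional -> molecular, and terminates in a TNM stage or "no
#' malignancy". Each stage holds the registry modalities tagged with it;
#' each modality carries a per-hospital usage probability. The calibration
#' data specify only marginal usage probabilities and unit costs, so the
#' expected pathway cost reduces to the probability-weighted cost sum
#' \eqn{E[C] = \sum_i p_i c_i}; the stage structure is retained for
#' reporting and future sequencing logic.
#'
#' @param registry a [modality_registry()].
#' @param estimates a `usage_estimate` tibble covering every registry
#'   modality for every hospital present (e.g. rows of [estimate_usage()],
#'   or [usage_estimate()] built from tabulated counts).
#' @return A `pathway_model` list: `start`, `stages` (ordered), `terminal`,
#'   `registry`, `probabilities` (tibble modality_id x hospital -> p), and
#'   the `estimates` used.
#' @export
build_pathway <- function(registry, estimates) {
  stopifnot(inherits(registry, "modality_registry"))
  need <- c("modality_id", "hospital", "rate", "beta_a", "beta_b")
  if (!all(need %in% names(estimates))) {
    stop("estimates must carry columns: ", paste(need, collapse = ", "))
  }
  hospitals <- unique(estimates$hospital)
  for (h in hospitals) {
    have <- estimates$modality_id[estimates$hospital == h]
    gaps <- setdiff(registry$modality_id, have)
    if (length(gaps)) {
      stop("no usage estimate for hospital '", h, "': ",
           paste(gaps, collapse = ", "))
    }
  }
  probs <- estimates[estimates$modality_id %in% registry$modality_id,
                     c("modality_id", "hospital", "rate")]
  out <- list(
    start = "suspicion of lung cancer",
    stages = pathway_stages(),
    terminal = c("TNM stage", "no malignancy"),
    registry = registry,
    probabilities = tibble::as_tibble(probs),
    estimates = tibble::as_tibble(estimates)
  )
  class(out) <- "pathway_model"
  out
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("<pathway_model> ", x$start, " -> ",
      paste(x$stages, collapse = " -> "), " -> {",
      paste(x$terminal, collapse = ", "), "}\n", sep = "")
  cat("  ", nrow(x$registry), " modalities, hospitals: ",
      paste(unique(x$probabilities$hospital), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Shared kernel: expected cost in euros from rates + unit costs (cents).
weighted_cost_eur <- function(p, cents) sum(p * cents) / 100

#' Expected per-patient budget impact of the pathway
#'
#' For each hospital, the expected diagnostic-pathway cost per patient is
#' the usage-probability-weighted sum of unit costs,
#' \eqn{E[C] = \sum_i p_i c_i}, with per-modality contributions reported.
#' Currency arithmetic runs in exact cents internally and is reported in
#' euros.
#'
#' @param pathway a [build_pathway()] model.
#' @param tariffs a [tariff_table()].
#' @param cost_basis `"tariff"` (default) or `"hospital_cost"`.
#' @param mapping named character vector mapping registry modality ids to
#'   tariff keys; modalities absent from the mapping are excluded from the
#'   costing with a message.
#' @param n optional named vector of cohort sizes per hospital; when given,
#'   the cohort total `n * E[C]` is reported.
#' @return A `budget_impact` list with `per_patient` (named vector, euros),
#'   `contributions` (tibble modality x hospital), `cohort_total` (or NULL),
#'   `cost_basis`, `excluded`.
#' @export
expected_cost <- function(pathway, tariffs, cost_basis = c("tariff", "hospital_cost"),
                          mapping = default_tariff_mapping(), n = NULL) {
  stopifnot(inherits(pathway, "pathway_model"), inherits(tariffs, "tariff_table"))
  cost_basis <- match.arg(cost_basis)
  ids <- pathway$registry$modality_id
  excluded <- setdiff(ids, names(mapping))
  if (length(excluded)) {
    message("excluded from costing (no tariff mapping): ",
            paste(excluded, collapse = ", "))
  }
  costed <- setdiff(ids, excluded)
  cents <- tariff_cents(costed, tariffs, mapping, cost_basis)
  probs <- pathway$probabilities
  hospitals <- unique(probs$hospital)
  contributions <- do.call(rbind, lapply(hospitals, function(h) {
    p <- probs$rate[probs$hospital == h][match(costed,
          probs$modality_id[probs$hospital == h])]
    tibble::tibble(modality_id = costed, hospital = h, probability = p,
                   unit_cost = cents / 100, contribution = p * cents / 100)
  }))
  per_patient <- vapply(hospitals, function(h) {
    sum(contributions$contribution[contributions$hospital == h])
  }, 0)
  cohort_total <- NULL
  if (!is.null(n)) {
    if (is.null(names(n)) || !all(hospitals %in% names(n))) {
      stop("n must be a named vector covering every hospital")
    }
    cohort_total <- per_patient * n[hospitals]
  }
  out <- list(
    per_patient = per_patient,
    contributions = tibble::as_tibble(contributions),
    cohort_total = cohort_total,
    cost_basis = cost_basis,
    excluded = excluded
  )
  class(out) <- "budget_impact"
  out
}

#' @export
print.budget_impact <- function(x, ...) {
  cat("<budget_impact> basis:", x$cost_basis, "\n")
  for (h in names(x$per_patient)) {
    cat(sprintf("  %s: EUR %.2f per patient", h, x$per_patient[[h]]))
    if (!is.null(x$cohort_total)) {
      cat(sprintf(" (cohort total EUR %.2f)", x$cohort_total[[h]]))
    }
    cat("\n")
  }
  if (length(x$excluded)) {
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Observed per-patient diagnostic cost
#'
#' Empirical counterpart of [expected_cost()]: each patient's cost is the
#' sum of unit costs over the modalities actually used (non-evaluable flags
#' count as not used). Because the cost is additive, the cohort mean equals
#' the expected cost evaluated at the cohort's empirical usage rates.
#'
#' @param cohort a `dx_cohort`.
#' @param tariffs a [tariff_table()].
#' @param cost_basis `"tariff"` or `"hospital_cost"`.
#' @param mapping modality-to-tariff mapping; unmapped modalities are
#'   excluded, as in [expected_cost()].
#' @return A list with `per_patient` (tibble `patient_id`, `hospital`,
#'   `cost`) and `mean_cost` (named vector per hospital, euros).
#' @export
observed_cost <- function(cohort, tariffs, cost_basis = c("tariff", "hospital_cost"),
                          mapping = default_tariff_mapping()) {
  stopifnot(inherits(cohort, "dx_cohort"), inherits(tariffs, "tariff_table"))
  cost_basis <- match.arg(cost_basis)
  ids <- cohort_registry(cohort)$modality_id
  costed <- intersect(ids, names(mapping))
  cents <- tariff_cents(costed, tariffs, mapping, cost_basis)
  used <- as.matrix(as.data.frame(cohort)[, costed, drop = FALSE])
  used[is.na(used)] <- FALSE
  cost_cents <- as.integer(used %*% cents)
  per_patient <- tibble::tibble(patient_id = cohort$patient_id,
                                hospital = cohort$hospital,
                                cost = cost_cents / 100)
  mean_cost <- vapply(split(per_patient$cost, per_patient$hospital), mean, 0)
  list(per_patient = per_patient, mean_cost = mean_cost)
}

#' Probabilistic sensitivity analysis of the budget impact
#'
#' Propagates usage-rate uncertainty through the cost model: every
#' replicate draws each modality's usage probability from its beta
#' posterior (independently per modality and hospital, reflecting the
#' binomial sampling model) and re-evaluates the expected per-patient cost.
#' One seed drives the whole run; each modality gets a deterministically
#' derived substream so results do not depend on draw order.
#'
#' @param pathway a [build_pathway()] model (its `estimates` supply the
#'   beta posteriors).
#' @param tariffs a [tariff_table()].
#' @param draws number of Monte-Carlo replicates, `>= 1`.
#' @param seed integer seed.
#' @param cost_basis,mapping as in [expected_cost()].
#' @return A `psa_result` list: `draws`, `seed`, `cost_basis`, `costs`
#'   (draws x hospital matrix, euros) and `summary` (tibble with mean, sd,
#'   equal-tailed 95\% interval per hospital).
#' @export
run_psa <- function(pathway, tariffs, draws = 10000, seed = 1,
                    cost_basis = c("tariff", "hospital_cost"),
                    mapping = default_tariff_mapping()) {
  stopifnot(inherits(pathway, "pathway_model"))
  if (!is.numeric(draws) || draws < 1) stop("draws must be >= 1")
  draws <- as.integer(draws)
  cost_basis <- match.arg(cost_basis)
  ids <- pathway$registry$modality_id
  costed <- intersect(ids, names(mapping))
  cents <- tariff_cents(costed, tariffs, mapping, cost_basis)
  est <- pathway$estimates
  hospitals <- unique(est$hospital)

  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  sub_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, length(costed) * length(hospitals)),
    nrow = length(costed), dimnames = list(costed, hospitals)
  )
  costs <- matrix(0, nrow = draws, ncol = length(hospitals),
                  dimnames = list(NULL, hospitals))
  for (h in hospitals) {
    eh <- est[est$hospital == h, ]
    idx <- match(costed, eh$modality_id)
    for (j in seq_along(costed)) {
      set.seed(sub_seeds[costed[j], h])
      p <- stats::rbeta(draws, eh$beta_a[idx[j]], eh$beta_b[idx[j]])
      costs[, h] <- costs[, h] + p * cents[j] / 100
    }
  }
  summary <- tibble::tibble(
    hospital = hospitals,
    mean = apply(costs, 2, mean),
    sd = apply(costs, 2, stats::sd),
    ci_low = apply(costs, 2, stats::quantile, probs = 0.025),
    ci_high = apply(costs, 2, stats::quantile, probs = 0.975)
  )
  out <- list(draws = draws, seed = as.integer(seed), cost_basis = cost_basis,
              costs = costs, summary = summary)
  class(out) <- "psa_result"
  out
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws, seed %d, basis %s\n",
              x$draws, x$seed, x$cost_basis))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %s: mean EUR %.2f (sd %.2f), 95%% CrI [%.2f, %.2f]\n",
                s$hospital, s$mean, s$sd, s$ci_low, s$ci_high))
  }
  invisible(x)
}
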