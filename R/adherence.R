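#' Define a guideline adherence rule
#'
#' A rule states when a modality is indicated by the clinical practice
#' guideline, as a predicate over patient stage and histology, and how
#' large the indicated casemix fraction is. The fraction can be supplied
#' directly (as published audits often do) or left `NULL` to be computed
#' from the cohort's own stage/histology distribution; patients with
#' unknown stage are excluded from stage-conditional predicates.
#'
#' @param modality_id the modality the rule governs.
#' @param stages character vector of stages for which the modality is
#'   indicated (subset of I, II, III, IV), or NULL for no stage condition.
#' @param histologies optional histology condition, same style.
#' @param expected_fraction either `NULL` (compute from cohort), a single
#'   fraction in \[0,1\], or a named vector of fractions per hospital.
#' @return An `adherence_rule` list.
#' @export
adherence_rule <- function(modality_id, stages = NULL, histologies = NULL,
                           expected_fraction = NULL) {
  if (!is.null(stages) && !all(stages %in% setdiff(stage_levels(), "unknown"))) {
    stop("stages must be drawn from I, II, III, IV")
  }
  if (!is.null(histologies) && !all(histologies %in% histology_levels())) {
    stop("unknown histology in rule")
  }
  if (!is.null(expected_fraction) &&
      (any(expected_fraction < 0) || any(expected_fraction > 1))) {
    stop("expected_fraction must lie in [0, 1]")
  }
  out <- list(modality_id = modality_id, stages = stages,
              histologies = histologies,
              expected_fraction = expected_fraction)
  class(out) <- "adherence_rule"
  out
}

#' Default guideline rule set
#'
#' One quantitative rule: brain MRI is indicated if and only if the tumor
#' is stage III. The indicated casemix fractions for the two default
#' cohorts are fixed at the audited stage-III shares: 20\% in the teaching
#' hospital and 16.7\% in the academic hospital. Additional rules are user
#' configuration.
#'
#' @return List of [adherence_rule()] objects.
#' @export
default_rules <- function() {
  list(adherence_rule("mr_brain", stages = "III",
                      expected_fraction = c(teaching = 0.20, academic = 0.167)))
}

# Rule predicate evaluated on cohort rows; NA for records the predicate
# cannot classify (unknown stage under a stage condition).
rule_indicated <- function(rule, cohort) {
  ind <- rep(TRUE, nrow(cohort))
  if (!is.null(rule$stages)) {
    ind <- ind & (cohort$stage %in% rule$stages)
    ind[cohort$stage == "unknown"] <- NA
  }
  if (!is.null(rule$histologies)) {
    ind <- ind & (cohort$histology %in% rule$histologies)
  }
  ind
}

#' Guideline-expected utilization count
#'
#' The number of uses the guideline prescribes for a cohort of size `n`
#' when a fraction `expected_fraction` of the casemix carries the
#' indication: `expected_fraction * n`, rounded half-up to the nearest
#' whole patient.
#'
#' @param expected_fraction fraction of the casemix indicated, in \[0,1\].
#' @param n cohort size, `>= 1`.
#' @return Integer expected count.
#' @examples
#' expected_under_guideline(0.167, 162) # 27
#' expected_under_guideline(0.20, 214)  # 43
#' @export
expected_under_guideline <- function(expected_fraction, n) {
  stopifnot(n >= 1, expected_fraction >= 0, expected_fraction <= 1)
  as.integer(floor(expected_fraction * n + 0.5))
}

#' Audit guideline adherence and its budget consequence
#'
#' For every rule and hospital: the guideline-expected utilization count,
#' the observed count, their deviation (observed minus expected), the
#' direction (over / under / concordant) and the deviation cost at the
#' modality's unit cost. Positive deviation cost is money spent above the
#' guideline-implied budget; negative is underutilization.
#'
#' When a rule carries no `expected_fraction`, the fraction is computed
#' from the cohort as the share of indicated patients among those the
#' predicate can classify (unknown-stage patients are excluded from
#' stage-conditional rules); the mode used is recorded per row.
#'
#' @param cohort a `dx_cohort`.
#' @param rules list of [adherence_rule()]s; default [default_rules()].
#' @param tariffs a [tariff_table()].
#' @param cost_basis,mapping as in [expected_cost()].
#' @return An `adherence_report` tibble: one row per hospital x rule with
#'   `modality_id`, `hospital`, `n`, `expected_fraction`, `fraction_mode`,
#'   `expected_count`, `observed_count`, `deviation`, `direction`,
#'   `unit_cost`, `deviation_cost`.
#' @export
audit <- function(cohort, rules = default_rules(), tariffs = default_tariffs(),
                  cost_basis = c("tariff", "hospital_cost"),
                  mapping = default_tariff_mapping()) {
  stopifnot(inherits(cohort, "dx_cohort"))
  cost_basis <- match.arg(cost_basis)
  registry <- cohort_registry(cohort)
  rows <- list()
  for (rule in rules) {
    if (!rule$modality_id %in% registry$modality_id) {
      stop("adherence rule references unknown modality: ", rule$modality_id)
    }
    cents <- tariff_cents(rule$modality_id, tariffs, mapping, cost_basis)
    for (h in sort(unique(cohort$hospital))) {
      hc <- cohort[cohort$hospital == h, ]
      n <- nrow(hc)
      if (is.null(rule$expected_fraction)) {
        ind <- rule_indicated(rule, hc)
        frac <- sum(ind, na.rm = TRUE) / sum(!is.na(ind))
        mode <- "from_cohort"
      } else {
        frac <- if (length(rule$expected_fraction) == 1 &&
                    is.null(names(rule$expected_fraction))) {
          rule$expected_fraction
        } else {
          if (!h %in% names(rule$expected_fraction)) {
            stop("rule for ", rule$modality_id,
                 " has no expected fraction for hospital '", h, "'")
          }
          rule$expected_fraction[[h]]
        }
        mode <- "given"
      }
      expected <- expected_under_guideline(frac, n)
      observed <- sum(hc[[rule$modality_id]], na.rm = TRUE)
      deviation <- observed - expected
      rows[[length(rows) + 1]] <- tibble::tibble(
        modality_id = rule$modality_id,
        hospital = h,
        n = n,
        expected_fraction = frac,
        fraction_mode = mode,
        expected_count = expected,
        observed_count = as.integer(observed),
        deviation = as.integer(deviation),
        direction = if (deviation > 0) "over" else if (deviation < 0) "under"
                    else "concordant",
        unit_cost = cents / 100,
        deviation_cost = deviation * cents / 100
      )
    }
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  class(out) <- c("adherence_report", class(out))
  out
}

#' Read adherence rules from YAML
#'
#' A YAML sequence of mappings with keys `modality_id`, optional `stages`,
#' `histologies` and `expected_fraction` (scalar or per-hospital mapping).
#'
#' @param path YAML file path.
#' @return List of [adherence_rule()]s.
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    ef <- r$expected_fraction
    if (is.list(ef)) ef <- unlist(ef)
    adherence_rule(r$modality_id, stages = unlist(r$stages),
                   histologies = unlist(r$histologies),
                   expected_fraction = ef)
  })
}

#' Write an adherence report
#'
#' @param report an [audit()] result.
#' @param path destination; `.json` writes JSON records, anything else TSV.
#' @return Invisibly, `path`.
#' @export
write_adherence_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.table(as.data.frame(report), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
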