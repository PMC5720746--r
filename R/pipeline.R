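#' Assemble a pipeline run configuration
#'
#' Collects everything one end-to-end analysis needs: where the cohort
#' comes from (a CSV, or the synthetic generator when `cohort_path` is
#' NULL), the tariff table and rule set (package defaults when NULL), the
#' statistical knobs, and the output directory.
#'
#' @param out_dir output directory; created if absent.
#' @param cohort_path optional cohort CSV; NULL simulates with
#'   [generate_cohort()].
#' @param tariffs_path optional tariff CSV/JSON; NULL uses
#'   [default_tariffs()].
#' @param rules_path optional adherence-rules YAML; NULL uses
#'   [default_rules()].
#' @param seed integer seed for simulation and PSA.
#' @param draws PSA replicates.
#' @param cost_basis `"tariff"` or `"hospital_cost"`.
#' @param prior_a,prior_b beta prior shapes for the usage posteriors.
#' @param correct Yates continuity correction for the chi-squared tests.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, cohort_path = NULL, tariffs_path = NULL,
                       rules_path = NULL, seed = 1L, draws = 5000L,
                       cost_basis = c("tariff", "hospital_cost"),
                       prior_a = 0.5, prior_b = 0.5, correct = FALSE) {
  cfg <- list(out_dir = out_dir, cohort_path = cohort_path,
              tariffs_path = tariffs_path, rules_path = rules_path,
              seed = as.integer(seed), draws = as.integer(draws),
              cost_basis = match.arg(cost_basis),
              prior_a = prior_a, prior_b = prior_b, correct = correct)
  class(cfg) <- "run_config"
  cfg
}

pipeline_artifacts <- function() {
  c(cohort = "cohort.csv", usage = "usage_table.csv",
    budget = "budget_report.json", psa = "psa_summary.json",
    adherence = "adherence_report.tsv", manifest = "manifest.json")
}

#' Run the full diagnostic-pathway analysis pipeline
#'
#' Executes, in order: cohort acquisition (simulation or CSV), usage-rate
#' estimation with between-hospital tests, budget-impact costing,
#' probabilistic sensitivity analysis, and the guideline-adherence audit.
#' Writes five artifacts plus a manifest into `config$out_dir`:
#' `cohort.csv`, `usage_table.csv`, `budget_report.json`,
#' `psa_summary.json`, `adherence_report.tsv`, `manifest.json`. A failure
#' in any stage aborts with the stage name and removes partial outputs of
#' this run. Given the same configuration and seed, all numeric outputs
#' are byte-identical.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `usage`, `budget`, `psa`, `adherence`, `paths`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir, pipeline_artifacts())
  names(paths) <- names(pipeline_artifacts())
  written <- character()
  say <- function(...) if (!quiet) message(...)
  stage <- "setup"
  result <- tryCatch({
    stage <- "simulate"
    if (is.null(config$cohort_path)) {
      say("simulate: generating synthetic two-hospital cohort (seed ",
          config$seed, ")")
      gen <- default_config(seed = config$seed)
      cohort <- generate_cohort(gen)
    } else {
      say("simulate: reading cohort from ", config$cohort_path)
      cohort <- read_cohort(config$cohort_path)
    }
    write_cohort(cohort, paths[["cohort"]])
    written <- c(written, paths[["cohort"]])

    stage <- "rates"
    say("rates: estimating per-modality usage")
    usage <- usage_table(cohort, prior_a = config$prior_a,
                         prior_b = config$prior_b, correct = config$correct)
    write_usage_table(usage, paths[["usage"]])
    written <- c(written, paths[["usage"]])

    stage <- "budget"
    say("budget: costing the pathway (basis ", config$cost_basis, ")")
    tariffs <- if (is.null(config$tariffs_path)) default_tariffs()
               else read_tariffs(config$tariffs_path)
    registry <- cohort_registry(cohort)
    estimates <- do.call(rbind, lapply(registry$modality_id, function(m) {
      estimate_usage(cohort, m, config$prior_a, config$prior_b)
    }))
    pathway <- build_pathway(registry, estimates)
    ns <- vapply(split(cohort$patient_id, cohort$hospital), length, 0L)
    budget <- expected_cost(pathway, tariffs, cost_basis = config$cost_basis,
                            n = ns)
    jsonlite::write_json(list(
      cost_basis = budget$cost_basis,
      per_patient_eur = as.list(round(budget$per_patient, 2)),
      cohort_total_eur = as.list(round(budget$cohort_total, 2)),
      excluded = budget$excluded,
      contributions = as.data.frame(budget$contributions)
    ), paths[["budget"]], auto_unbox = TRUE, digits = NA)
    written <- c(written, paths[["budget"]])

    stage <- "psa"
    say("psa: ", config$draws, " Monte-Carlo replicates")
    psa <- run_psa(pathway, tariffs, draws = config$draws,
                   seed = config$seed, cost_basis = config$cost_basis)
    jsonlite::write_json(list(
      draws = psa$draws, seed = psa$seed, cost_basis = psa$cost_basis,
      summary = as.data.frame(psa$summary)
    ), paths[["psa"]], auto_unbox = TRUE, digits = NA)
    written <- c(written, paths[["psa"]])

    stage <- "audit"
    say("audit: guideline adherence")
    rules <- if (is.null(config$rules_path)) default_rules()
             else read_rules(config$rules_path)
    adherence <- audit(cohort, rules, tariffs,
                       cost_basis = config$cost_basis)
    write_adherence_report(adherence, paths[["adherence"]])
    written <- c(written, paths[["adherence"]])

    stage <- "manifest"
    manifest <- list(
      package = "dxpath",
      version = as.character(utils::packageVersion("dxpath")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = unclass(config)
    )
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         digits = NA, null = "null")
    written <- c(written, paths[["manifest"]])

    list(cohort = cohort, usage = usage, budget = budget, psa = psa,
         adherence = adherence, paths = paths)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Re-create a run configuration from a manifest
#'
#' Reads the `manifest.json` a previous [run_pipeline()] wrote and rebuilds
#' its [run_config()], so the run can be reproduced exactly.
#'
#' @param path path to a manifest JSON file.
#' @return A `run_config`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path)
  cfg <- m$config
  run_config(out_dir = cfg$out_dir,
             cohort_path = cfg$cohort_path,
             tariffs_path = cfg$tariffs_path,
             rules_path = cfg$rules_path,
             seed = cfg$seed, draws = cfg$draws,
             cost_basis = cfg$cost_basis,
             prior_a = cfg$prior_a, prior_b = cfg$prior_b,
             correct = isTRUE(cfg$correct))
}
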