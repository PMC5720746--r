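#' Reference per-modality usage counts for the default cohorts
#'
#' Observed 2012 utilization in the two default hospital cohorts: for every
#' registry modality, how many evaluable patients there were and how many
#' received it. The evaluable denominators (212 of 214 teaching patients,
#' 152 of 162 academic patients) are smaller than the cohorts because some
#' patient files could not be scored for usage.
#'
#' These counts parameterize [default_config()] and the default budget
#' model.
#'
#' @return Tibble with columns `modality_id`, `hospital`, `count`,
#'   `denominator` (38 rows: 19 modalities x 2 hospitals).
#' @export
reference_usage <- function() {
  ids <- default_registry()$modality_id
  tibble::tibble(
    modality_id = rep(ids, 2),
    hospital = rep(c("teaching", "academic"), each = length(ids)),
    count = c(
      186L, 155L, 209L, 12L, 52L, 37L, 9L, 28L, 142L, 33L, 25L, 23L, 23L,
      137L, 1L, 19L, 98L, 64L, 8L,
      131L, 133L, 147L, 9L, 46L, 47L, 2L, 21L, 101L, 24L, 31L, 13L, 17L,
      68L, 34L, 11L, 125L, 41L, 15L
    ),
    denominator = rep(c(212L, 152L), each = length(ids))
  )
}

#' Default synthetic-cohort generator configuration
#'
#' Emulates the two-hospital 2012 lung-cancer cohorts the default model is
#' calibrated to: a large regional teaching hospital (n = 214, mean age
#' 66.95, sd 10.335, 63.6\% male, 20\% stage III) and an academic tertiary
#' hospital (n = 162, mean age 65.77, sd 10.180, 59.9\% male, 16.7\% stage
#' III). Histology fractions follow the observed casemix; per-modality usage
#' probabilities are the [reference_usage()] rates. Stage mass outside stage
#' III is spread uniformly over stages I, II and IV, the simplest allocation
#' consistent with the reported stage-III fractions.
#'
#' @param seed integer seed driving the generator stream.
#' @return A `generator_config` list with elements `registry`, `seed` and
#'   `hospitals` (one sub-list per hospital: `n`, `age_mean`, `age_sd`,
#'   `male_fraction`, `histology_fractions`, `stage_fractions`,
#'   `usage_rates`).
#' @export
default_config <- function(seed = 20120L) {
  usage <- reference_usage()
  rates_for <- function(h) {
    u <- usage[usage$hospital == h, ]
    stats::setNames(u$count / u$denominator, u$modality_id)
  }
  stage_fracs <- function(p3) {
    rest <- (1 - p3) / 3
    c(I = rest, II = rest, III = p3, IV = rest, unknown = 0)
  }
  cfg <- list(
    registry = default_registry(),
    seed = as.integer(seed),
    hospitals = list(
      teaching = list(
        n = 214L, age_mean = 66.95, age_sd = 10.335,
        male_fraction = 136 / 214,
        histology_fractions = c(SCLC = 28, adeno = 89, squamous = 59,
                                large_cell = 3, NSCLC_other = 35) / 214,
        stage_fractions = stage_fracs(0.20),
        usage_rates = rates_for("teaching")
      ),
      academic = list(
        n = 162L, age_mean = 65.77, age_sd = 10.180,
        male_fraction = 97 / 162,
        histology_fractions = c(SCLC = 29, adeno = 64, squamous = 42,
                                large_cell = 11, NSCLC_other = 16) / 162,
        stage_fractions = stage_fracs(0.167),
        usage_rates = rates_for("academic")
      )
    )
  )
  class(cfg) <- "generator_config"
  cfg
}

validate_config <- function(config) {
  if (!is.list(config) || is.null(config$hospitals) || is.null(config$registry)) {
    stop("generator config needs 'registry' and 'hospitals'")
  }
  check_simplex <- function(x, what, hosp) {
    if (any(x < 0) || any(x > 1) || abs(sum(x) - 1) > 1e-9) {
      stop(what, " for hospital '", hosp,
           "' must lie in [0,1] and sum to 1 (got sum ", sum(x), ")")
    }
  }
  for (h in names(config$hospitals)) {
    hc <- config$hospitals[[h]]
    if (is.null(hc$n) || hc$n < 1) stop("cohort size n must be >= 1 for '", h, "'")
    if (hc$age_sd <= 0) stop("age_sd must be positive for '", h, "'")
    if (hc$male_fraction < 0 || hc$male_fraction > 1) {
      stop("male_fraction out of [0,1] for '", h, "'")
    }
    check_simplex(hc$histology_fractions[histology_levels()],
                  "histology_fractions", h)
    check_simplex(hc$stage_fractions[stage_levels()], "stage_fractions", h)
    bad <- setdiff(names(hc$usage_rates), config$registry$modality_id)
    if (length(bad)) {
      stop("usage_rates name modalities outside the registry: ",
           paste(bad, collapse = ", "))
    }
    if (any(hc$usage_rates < 0) || any(hc$usage_rates > 1)) {
      stop("usage rates out of [0,1] for '", h, "'")
    }
  }
  invisible(config)
}

# Normal draw truncated to (lo, hi] by inverse-CDF; deterministic under the
# active RNG stream.
rnorm_trunc <- function(n, mean, sd, lo = 18, hi = 100) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic two-hospital cohort
#'
#' Draws exactly `n` patients per hospital: sex Bernoulli(male fraction),
#' age normal truncated to (18, 100], histology and stage categorical, and
#' each usage flag an independent Bernoulli at the configured rate (marginal
#' rates are all the calibration data specify; between-modality correlation
#' is deliberately not modelled). The draw is fully reproducible: one seed
#' drives the stream, and each hospital gets a deterministically derived
#' sub-seed so cohorts are independent draws.
#'
#' @param config a `generator_config`, e.g. [default_config()].
#' @return A `dx_cohort` with `sum(n)` rows.
#' @export
generate_cohort <- function(config = default_config()) {
  validate_config(config)
  registry <- config$registry
  old_seed <- globalenv()$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L,
                          length(config$hospitals))
  rows <- vector("list", length(config$hospitals))
  for (i in seq_along(config$hospitals)) {
    h <- names(config$hospitals)[i]
    hc <- config$hospitals[[h]]
    set.seed(sub_seeds[i])
    n <- as.integer(hc$n)
    df <- tibble::tibble(
      patient_id = sprintf("%s_%04d", h, seq_len(n)),
      hospital = h,
      age = rnorm_trunc(n, hc$age_mean, hc$age_sd),
      sex = ifelse(stats::runif(n) < hc$male_fraction, "male", "female"),
      histology = sample(histology_levels(), n, replace = TRUE,
                         prob = hc$histology_fractions[histology_levels()]),
      stage = sample(stage_levels(), n, replace = TRUE,
                     prob = hc$stage_fractions[stage_levels()])
    )
    for (m in registry$modality_id) {
      p <- if (m %in% names(hc$usage_rates)) hc$usage_rates[[m]] else 0
      df[[m]] <- stats::runif(n) < p
    }
    rows[[i]] <- df
  }
  as_cohort(do.call(rbind, rows), registry)
}

#' Read a generator configuration from YAML
#'
#' The YAML mirrors the [default_config()] structure (`seed`, plus one
#' mapping per hospital); the registry defaults to [default_registry()].
#'
#' @param path YAML file path.
#' @param registry a [modality_registry()].
#' @return A validated `generator_config`.
#' @export
read_generator_config <- function(path, registry = default_registry()) {
  raw <- yaml::read_yaml(path)
  cfg <- list(
    registry = registry,
    seed = as.integer(raw$seed %||% 1L),
    hospitals = lapply(raw$hospitals, function(hc) {
      list(
        n = as.integer(hc$n),
        age_mean = as.numeric(hc$age_mean),
        age_sd = as.numeric(hc$age_sd),
        male_fraction = as.numeric(hc$male_fraction),
        histology_fractions = unlist(hc$histology_fractions),
        stage_fractions = unlist(hc$stage_fractions),
        usage_rates = unlist(hc$usage_rates)
      )
    })
  )
  class(cfg) <- "generator_config"
  validate_config(cfg)
}
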