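#' @keywords internal
hospital_levels <- function() c("teaching", "academic")

#' @keywords internal
sex_levels <- function() c("male", "female")

#' @keywords internal
histology_levels <- function() {
  c("SCLC", "adeno", "squamous", "large_cell", "NSCLC_other")
}

#' @keywords internal
stage_levels <- function() c("I", "II", "III", "IV", "unknown")

#' Construct and validate a patient cohort
#'
#' A cohort is one row per diagnosed patient: identifier, hospital, age, sex,
#' histology, TNM stage, and one logical usage column per registry modality.
#' `NA` in a usage column means the flag could not be evaluated for that
#' patient; such patients are dropped from that modality's denominator (the
#' "evaluable denominator") but remain in the cohort.
#'
#' Histology uses the closed set `SCLC`, `adeno`, `squamous`, `large_cell`,
#' `NSCLC_other`; stage is `I`, `II`, `III`, `IV` or `unknown`. Patients with
#' unknown stage are retained but excluded from stage-conditional guideline
#' rules.
#'
#' @param data data frame with columns `patient_id`, `hospital`, `age`,
#'   `sex`, `histology`, `stage` plus the usage columns.
#' @param registry a [modality_registry()]; defaults to [default_registry()].
#' @return A `dx_cohort` tibble carrying the registry as an attribute.
#' @export
as_cohort <- function(data, registry = default_registry()) {
  stopifnot(inherits(registry, "modality_registry"))
  data <- tibble::as_tibble(data)
  core <- c("patient_id", "hospital", "age", "sex", "histology", "stage")
  missing <- setdiff(core, names(data))
  if (length(missing)) {
    stop("cohort lacks columns: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(data), c(core, registry$modality_id))
  if (length(extra)) {
    stop("unknown modality columns: ", paste(extra, collapse = ", "),
         " (not in the registry)")
  }
  missing_mod <- setdiff(registry$modality_id, names(data))
  if (length(missing_mod)) {
    stop("cohort lacks usage columns: ", paste(missing_mod, collapse = ", "))
  }
  data$patient_id <- as.character(data$patient_id)
  data$age <- as.numeric(data$age)
  check_enum <- function(col, levels) {
    vals <- as.character(data[[col]])
    bad <- which(!vals %in% levels)
    if (length(bad)) {
      stop("invalid ", col, " value '", vals[bad[1]], "' in row ", bad[1],
           " (allowed: ", paste(levels, collapse = ", "), ")")
    }
    vals
  }
  data$hospital <- check_enum("hospital", hospital_levels())
  data$sex <- check_enum("sex", sex_levels())
  data$histology <- check_enum("histology", histology_levels())
  data$stage <- check_enum("stage", stage_levels())
  bad_age <- which(!is.finite(data$age) | data$age <= 0 | data$age > 120)
  if (length(bad_age)) {
    stop("age out of (0, 120] in row ", bad_age[1], ": ", data$age[bad_age[1]])
  }
  for (m in registry$modality_id) {
    v <- data[[m]]
    if (is.numeric(v)) {
      if (!all(v %in% c(0, 1, NA))) {
        stop("usage column ", m, " must be 0/1/empty")
      }
      v <- as.logical(v)
    }
    if (!is.logical(v)) stop("usage column ", m, " must be logical or 0/1")
    data[[m]] <- v
  }
  data <- data[, c(core, registry$modality_id)]
  attr(data, "registry") <- registry
  class(data) <- c("dx_cohort", class(data))
  data
}

#' Registry attached to a cohort
#' @param cohort a `dx_cohort`.
#' @return The cohort's [modality_registry()].
#' @export
cohort_registry <- function(cohort) {
  stopifnot(inherits(cohort, "dx_cohort"))
  attr(cohort, "registry")
}

#' Read a patient cohort from CSV
#'
#' Comma-separated UTF-8 with a header row; usage flags encoded `1`/`0`,
#' empty cells meaning "not evaluable". The column set must be exactly the
#' core patient columns plus one column per registry modality; unknown
#' columns are rejected.
#'
#' @param path CSV file path.
#' @param registry a [modality_registry()].
#' @return A validated `dx_cohort`.
#' @export
read_cohort <- function(path, registry = default_registry()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                    colClasses = c(patient_id = "character")),
    error = function(e) stop("malformed cohort CSV '", path, "': ",
                             conditionMessage(e))
  )
  as_cohort(df, registry)
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]: usage flags become `1`/`0`, non-evaluable
#' flags empty cells. `write_cohort` then `read_cohort` round-trips the
#' cohort exactly.
#'
#' @param cohort a `dx_cohort`.
#' @param path destination path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "dx_cohort"))
  registry <- cohort_registry(cohort)
  out <- as.data.frame(cohort)
  for (m in registry$modality_id) out[[m]] <- as.integer(out[[m]])
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Summarize cohort composition per hospital
#'
#' Per hospital: size, mean and standard deviation of age, sex counts and
#' fractions, histology counts and fractions (plus the SCLC / NSCLC split),
#' and stage counts and fractions.
#'
#' @param cohort a nonempty `dx_cohort`.
#' @return A `cohort_summary`: a list with `n_total` and one entry per
#'   hospital holding `n`, `age_mean`, `age_sd`, `male_count`,
#'   `male_fraction`, and `histology`, `nsclc`, `stage` tibbles of counts
#'   and fractions.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "dx_cohort"))
  if (nrow(cohort) == 0) stop("cannot summarize an empty cohort")
  per_hospital <- lapply(split(cohort, cohort$hospital), function(h) {
    n <- nrow(h)
    hist_counts <- vapply(histology_levels(),
                          function(l) sum(h$histology == l), 0L)
    stage_counts <- vapply(stage_levels(), function(l) sum(h$stage == l), 0L)
    nsclc_count <- n - hist_counts[["SCLC"]]
    list(
      n = n,
      age_mean = mean(h$age),
      age_sd = stats::sd(h$age),
      male_count = sum(h$sex == "male"),
      male_fraction = sum(h$sex == "male") / n,
      histology = tibble::tibble(histology = histology_levels(),
                                 count = hist_counts,
                                 fraction = hist_counts / n),
      nsclc = tibble::tibble(group = c("SCLC", "NSCLC"),
                             count = c(hist_counts[["SCLC"]], nsclc_count),
                             fraction = c(hist_counts[["SCLC"]], nsclc_count) / n),
      stage = tibble::tibble(stage = stage_levels(),
                             count = stage_counts,
                             fraction = stage_counts / n)
    )
  })
  out <- c(list(n_total = nrow(cohort)), per_hospital)
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> total n =", x$n_total, "\n")
  for (h in setdiff(names(x), "n_total")) {
    s <- x[[h]]
    cat(sprintf("  %s: n = %d, age %.2f (%.3f), male %d (%.1f%%)\n",
                h, s$n, s$age_mean, s$age_sd, s$male_count,
                100 * s$male_fraction))
  }
  invisible(x)
}
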