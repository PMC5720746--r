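#' Beta-posterior usage-rate estimate for one modality
#'
#' Usage of a diagnostic modality is a binomial outcome, so the rate gets a
#' conjugate beta posterior: with `count` uses among `denominator` evaluable
#' patients and a beta(`prior_a`, `prior_b`) prior, the posterior is
#' beta(`count + prior_a`, `denominator - count + prior_b`). The default
#' prior is Jeffreys beta(1/2, 1/2). The reported point estimate is the raw
#' rate `count / denominator`; the 95\% interval is the equal-tailed
#' posterior credible interval.
#'
#' Patients whose usage flag is `NA` are not evaluable and are excluded from
#' the denominator.
#'
#' @param cohort a `dx_cohort` (any number of hospitals, each nonempty).
#' @param modality_id one registry modality id.
#' @param prior_a,prior_b positive beta prior shapes.
#' @return A `usage_estimate` tibble, one row per hospital, with columns
#'   `modality_id`, `hospital`, `count`, `denominator`, `rate`, `beta_a`,
#'   `beta_b`, `ci_low`, `ci_high`.
#' @export
estimate_usage <- function(cohort, modality_id, prior_a = 0.5, prior_b = 0.5) {
  stopifnot(inherits(cohort, "dx_cohort"), prior_a > 0, prior_b > 0)
  registry <- cohort_registry(cohort)
  if (!modality_id %in% registry$modality_id) {
    stop("modality '", modality_id, "' is not in the registry")
  }
  by_hosp <- split(cohort[[modality_id]], cohort$hospital)
  denominator <- vapply(by_hosp, function(f) sum(!is.na(f)), 0L)
  if (any(denominator < 1)) {
    stop("no evaluable patients for '", modality_id, "' in hospital '",
         names(by_hosp)[denominator < 1][1], "'")
  }
  count <- vapply(by_hosp, function(f) sum(f, na.rm = TRUE), 0L)
  usage_estimate(modality_id, names(by_hosp), count, denominator,
                 prior_a, prior_b)
}

#' Build a usage estimate from a count and denominator
#'
#' Same posterior as [estimate_usage()], for when the counts are already
#' tabulated rather than held as patient-level flags.
#'
#' @param modality_id modality id (not checked against a registry here).
#' @param hospital hospital label.
#' @param count integer uses, `0 <= count <= denominator` (vectorized).
#' @param denominator integer evaluable patients, `>= 1` (vectorized).
#' @param prior_a,prior_b positive beta prior shapes.
#' @return A `usage_estimate` tibble, one row per (modality, hospital).
#' @export
usage_estimate <- function(modality_id, hospital, count, denominator,
                           prior_a = 0.5, prior_b = 0.5) {
  stopifnot(all(denominator >= 1), all(count >= 0), all(count <= denominator),
            prior_a > 0, prior_b > 0)
  beta_a <- count + prior_a
  beta_b <- denominator - count + prior_b
  out <- tibble::tibble(
    modality_id = modality_id,
    hospital = hospital,
    count = as.integer(count),
    denominator = as.integer(denominator),
    rate = count / denominator,
    beta_a = beta_a,
    beta_b = beta_b,
    ci_low = stats::qbeta(0.025, beta_a, beta_b),
    ci_high = stats::qbeta(0.975, beta_a, beta_b)
  )
  class(out) <- c("usage_estimate", class(out))
  out
}

#' Chi-squared test of usage independence between two hospitals
#'
#' Pearson chi-squared test on the 2x2 used/not-used by hospital table, 1
#' degree of freedom. The continuity correction is off by default so the
#' statistic is the transparent \eqn{\sum (O - E)^2 / E}.
#'
#' @param counts 2x2 matrix of nonnegative integer counts; rows are
#'   hospitals, columns used / not used (orientation does not affect the
#'   statistic).
#' @param correct apply the Yates continuity correction.
#' @param modality_id optional label carried into the result.
#' @return An `independence_test` list: `modality_id`, `counts`,
#'   `statistic`, `df` (always 1), `p_value`, `correct`.
#' @export
chi2_independence <- function(counts, correct = FALSE, modality_id = NA_character_) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0)) stop("degenerate table: row margin ", which(rs == 0)[1], " is zero")
  if (any(cs == 0)) stop("degenerate table: column margin ", which(cs == 0)[1], " is zero")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  out <- list(
    modality_id = modality_id,
    counts = counts,
    statistic = unname(ht$statistic),
    df = 1L,
    p_value = unname(ht$p.value),
    correct = correct
  )
  class(out) <- "independence_test"
  out
}

#' @export
print.independence_test <- function(x, ...) {
  cat(sprintf("<independence_test> %s: X-squared = %.4g, df = 1, p = %.4g%s\n",
              ifelse(is.na(x$modality_id), "2x2 table", x$modality_id),
              x$statistic, x$p_value,
              if (x$correct) " (Yates-corrected)" else ""))
  invisible(x)
}

#' Per-modality usage table with between-hospital tests
#'
#' The full utilization summary: for every registry modality, usage count,
#' evaluable denominator and rate in each of the two hospitals, plus the
#' chi-squared independence test on the 2x2 used/not-used by hospital
#' table and a significance flag at 0.05.
#'
#' @param cohort a `dx_cohort` containing exactly two hospitals.
#' @param registry defaults to the cohort's registry.
#' @param prior_a,prior_b beta prior shapes passed to [estimate_usage()].
#' @param correct Yates continuity correction for the tests.
#' @return A `usage_table` tibble, one row per modality, with per-hospital
#'   `count_*`, `denominator_*`, `rate_*`, `ci_low_*`, `ci_high_*` columns
#'   (suffixed by hospital), `chi2`, `p_value`, `significant`.
#' @export
usage_table <- function(cohort, registry = cohort_registry(cohort),
                        prior_a = 0.5, prior_b = 0.5, correct = FALSE) {
  stopifnot(inherits(cohort, "dx_cohort"))
  hospitals <- sort(unique(cohort$hospital))
  if (length(hospitals) != 2) {
    stop("usage_table needs exactly two hospitals, found ",
         length(hospitals))
  }
  rows <- lapply(registry$modality_id, function(m) {
    est <- estimate_usage(cohort, m, prior_a, prior_b)
    est <- est[match(hospitals, est$hospital), ]
    tab <- cbind(used = est$count, not_used = est$denominator - est$count)
    test <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      chi2_independence(tab, correct = correct, modality_id = m)
    } else {
      list(statistic = NA_real_, p_value = NA_real_)
    }
    row <- tibble::tibble(modality_id = m)
    for (i in seq_along(hospitals)) {
      h <- hospitals[i]
      row[[paste0("count_", h)]] <- est$count[i]
      row[[paste0("denominator_", h)]] <- est$denominator[i]
      row[[paste0("rate_", h)]] <- est$rate[i]
      row[[paste0("ci_low_", h)]] <- est$ci_low[i]
      row[[paste0("ci_high_", h)]] <- est$ci_high[i]
    }
    row$chi2 <- test$statistic
    row$p_value <- test$p_value
    row$significant <- !is.na(test$p_value) && test$p_value < 0.05
    row
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  class(out) <- c("usage_table", class(out))
  out
}

#' Write a usage table to CSV
#'
#' Rates are exported as percentages rounded to one decimal, mirroring the
#' conventional utilization-table layout; exact rates stay available from
#' the in-memory object.
#'
#' @param table a [usage_table()] result.
#' @param path destination CSV path.
#' @return Invisibly, `path`.
#' @export
write_usage_table <- function(table, path) {
  out <- as.data.frame(table)
  for (col in grep("^(rate|ci_low|ci_high)_", names(out), value = TRUE)) {
    out[[col]] <- round(100 * out[[col]], 1)
  }
  out$chi2 <- signif(out$chi2, 4)
  out$p_value <- signif(out$p_value, 3)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
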