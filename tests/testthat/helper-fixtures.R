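# Fixture builders shared across the suite. Everything is constructed in
# code; nothing is read from disk.

# Minimal two-hospital cohort with a hand-set usage pattern.
make_small_cohort <- function(registry = default_registry()) {
  n <- 6
  df <- tibble::tibble(
    patient_id = sprintf("p%02d", seq_len(n)),
    hospital = rep(c("teaching", "academic"), each = 3),
    age = c(62.1, 70.4, 55.0, 68.3, 77.9, 49.5),
    sex = c("male", "female", "male", "male", "female", "female"),
    histology = c("adeno", "SCLC", "squamous", "adeno", "NSCLC_other",
                  "large_cell"),
    stage = c("III", "I", "unknown", "IV", "III", "II")
  )
  for (m in registry$modality_id) df[[m]] <- FALSE
  df$x_thorax <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  df$bronchoscopy <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  df$mr_brain <- c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  df$ct[3] <- NA  # one non-evaluable flag
  as_cohort(df, registry)
}

# Cohort matching the default two-hospital composition exactly: sizes
# 214/162, male counts 136/97, histology counts per category, and MR-brain
# usage 37/47. Ages are a fixed deterministic grid.
make_reference_cohort <- function(registry = default_registry()) {
  build_hospital <- function(hospital, n, males, hist_counts, mr_used) {
    histology <- rep(names(hist_counts), hist_counts)
    df <- tibble::tibble(
      patient_id = sprintf("%s_%03d", hospital, seq_len(n)),
      hospital = hospital,
      age = 45 + (seq_len(n) %% 40),
      sex = rep(c("male", "female"), c(males, n - males)),
      histology = histology,
      stage = rep(c("III", "I"), c(round(0.2 * n), n - round(0.2 * n)))
    )
    for (m in registry$modality_id) df[[m]] <- FALSE
    df$mr_brain <- seq_len(n) <= mr_used
    df
  }
  teaching <- build_hospital("teaching", 214, 136,
    c(SCLC = 28, adeno = 89, squamous = 59, large_cell = 3,
      NSCLC_other = 35), mr_used = 37)
  academic <- build_hospital("academic", 162, 97,
    c(SCLC = 29, adeno = 64, squamous = 42, large_cell = 11,
      NSCLC_other = 16), mr_used = 47)
  as_cohort(rbind(teaching, academic), registry)
}

# Pathway parameterized by the tabulated reference usage counts.
make_reference_pathway <- function() {
  u <- reference_usage()
  est <- usage_estimate(u$modality_id, u$hospital, u$count, u$denominator)
  build_pathway(default_registry(), est)
}

# Independent Pearson oracle: direct sum of (O - E)^2 / E over the four
# cells, from the margins. Vectorized over table cells a, b, c, d laid out
# as rbind(c(a, b), c(c, d)).
pearson_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  e <- cbind((a + b) * (a + c), (a + b) * (b + d),
             (c + d) * (a + c), (c + d) * (b + d)) / n
  o <- cbind(a, b, c, d)
  rowSums((o - e)^2 / e)
}
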