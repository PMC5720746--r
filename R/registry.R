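#' Modality registry
#'
#' The registry is the closed list of diagnostic modalities the pathway knows
#' about. Every cohort usage column, tariff mapping, usage estimate and
#' adherence rule refers to a `modality_id` from this list. Each modality
#' carries a human-readable label and exactly one pathway stage tag:
#' `imaging`, `invasive` (tissue acquisition), `functional` (operability
#' work-up) or `molecular` (mutation profiling).
#'
#' @param modality_id character vector of unique snake_case identifiers.
#' @param label display names, same length.
#' @param stage pathway stage tag per modality; one of
#'   `"imaging"`, `"invasive"`, `"functional"`, `"molecular"`.
#' @return A `modality_registry`: a tibble with columns `modality_id`,
#'   `label`, `stage`.
#' @examples
#' modality_registry("ct", "CT thorax", "imaging")
#' @export
modality_registry <- function(modality_id, label = modality_id, stage) {
  stopifnot(is.character(modality_id), length(modality_id) >= 1)
  if (anyDuplicated(modality_id)) {
    stop("modality ids must be unique; duplicated: ",
         paste(unique(modality_id[duplicated(modality_id)]), collapse = ", "))
  }
  stage <- match.arg(stage, pathway_stages(), several.ok = TRUE)
  if (length(label) != length(modality_id) || length(stage) != length(modality_id)) {
    stop("label and stage must have one entry per modality")
  }
  out <- tibble::tibble(modality_id = modality_id, label = label, stage = stage)
  class(out) <- c("modality_registry", class(out))
  out
}

#' Ordered pathway stage tags
#'
#' @return Character vector of the four non-terminal stage tags in pathway
#'   order: imaging, invasive, functional, molecular.
#' @export
pathway_stages <- function() {
  c("imaging", "invasive", "functional", "molecular")
}

#' Default lung-cancer modality registry
#'
#' The 19 diagnostic modalities of the default lung-cancer work-up, in the
#' order they are conventionally tabulated: chest imaging and staging scans,
#' tissue-acquisition procedures, cardiopulmonary function tests, and the
#' KRAS/EGFR and ALK molecular assays.
#'
#' @return A [modality_registry()] with 19 rows.
#' @export
default_registry <- function() {
  modality_registry(
    modality_id = c(
      "x_thorax", "pet_ct", "ct", "cervical_mediastinoscopy", "eus_ebus",
      "mr_brain", "bone_scintigraphy", "thoracocentesis", "bronchoscopy",
      "x_ray_guidance_bronchoscopy", "ct_guided_biopsy",
      "x_thorax_after_biopsy", "vo2_max", "broad_lung_function",
      "flow_volume", "ventilation_perfusion_scan", "ecg", "kras_egfr", "alk"
    ),
    label = c(
      "X-thorax", "PET/CT", "CT", "Cervical mediastinoscopy", "EUS/EBUS",
      "MR brain", "Bone scintigraphy", "Thoracocentesis", "Bronchoscopy",
      "X-ray guidance bronchoscopy", "CT guided biopsy",
      "X-thorax after biopsy", "VO2 max", "Broad lung function",
      "Flow volume", "Ventilation / perfusion scan", "ECG", "KRAS / EGFR",
      "ALK"
    ),
    stage = c(
      "imaging", "imaging", "imaging", "invasive", "invasive",
      "imaging", "imaging", "invasive", "invasive",
      "imaging", "invasive",
      "imaging", "functional", "functional",
      "functional", "functional", "functional", "molecular", "molecular"
    )
  )
}

#' Read a modality registry from YAML
#'
#' Expects a YAML sequence of mappings, each with keys `modality_id`,
#' `label` (optional) and `stage`.
#'
#' @param path file path.
#' @return A [modality_registry()].
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) stop("registry file is empty: ", path)
  modality_registry(
    modality_id = vapply(raw, function(x) as.character(x$modality_id), ""),
    label = vapply(raw, function(x) as.character(x$label %||% x$modality_id), ""),
    stage = vapply(raw, function(x) as.character(x$stage), "")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.modality_registry <- function(x, ...) {
  cat("<modality_registry> ", nrow(x), " modalities (",
      paste(sprintf("%s: %d", pathway_stages(),
                    vapply(pathway_stages(), function(s) sum(x$stage == s), 0L)),
            collapse = ", "), ")\n", sep = "")
  NextMethod()
}
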