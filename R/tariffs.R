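#' Tariff tables
#'
#' A tariff table prices procedures: each row maps a procedure key to its
#' Dutch DBC reimbursement code, the national (NZa) tariff in euros, and the
#' hospital's internal cost in euros. Hospital costs never exceed the tariff.
#'
#' @param modality_id character procedure keys (unique).
#' @param procedure_code DBC procedure codes (character; some are compound,
#'   e.g. `"34386/34387"`).
#' @param tariff nonnegative tariff in euros.
#' @param hospital_cost nonnegative hospital cost in euros, `<= tariff`.
#' @return A `tariff_table` tibble.
#' @export
tariff_table <- function(modality_id, procedure_code, tariff, hospital_cost) {
  stopifnot(is.character(modality_id))
  if (anyDuplicated(modality_id)) stop("tariff keys must be unique")
  tariff <- as.numeric(tariff)
  hospital_cost <- as.numeric(hospital_cost)
  if (any(tariff < 0) || any(hospital_cost < 0)) {
    stop("tariffs and hospital costs must be nonnegative")
  }
  over <- hospital_cost > tariff + 1e-9
  if (any(over)) {
    stop("hospital cost exceeds tariff for: ",
         paste(modality_id[over], collapse = ", "))
  }
  out <- tibble::tibble(
    modality_id = modality_id,
    procedure_code = as.character(procedure_code),
    tariff = tariff,
    hospital_cost = hospital_cost
  )
  class(out) <- c("tariff_table", class(out))
  out
}

#' Default procedure tariff table (NZa, 2014)
#'
#' The 17 priced procedures of the default lung-cancer diagnostic pathway,
#' with their DBC reimbursement codes, 2014 NZa tariffs and hospital costs.
#' Two registry modalities have no dedicated row and are priced through
#' [default_tariff_mapping()].
#'
#' @return A [tariff_table()] with 17 rows.
#' @export
default_tariffs <- function() {
  tariff_table(
    modality_id = c(
      "x_thorax", "ct_thorax", "pet_ct", "eus_ebus", "mediastinoscopy",
      "mr_brain", "thoracocentesis", "bronchoscopy", "x_ray_guidance",
      "ct_guided_biopsy", "vo2_max", "flow_volume_diffusion", "flow_volume",
      "ventilation_perfusion_scan", "ecg", "kras_egfr", "alk"
    ),
    procedure_code = c(
      "85002", "85042", "120501", "34386/34387", "29099045",
      "81092", "32684", "32480", "85000",
      "80047", "39844", "39932", "39839",
      "120060", "39757", "50512", "50514"
    ),
    tariff = c(
      43.66, 182.21, 1162.93, 791.15, 2430.00,
      218.29, 50.50, 370.71, 53.14,
      229.63, 170.38, 67.60, 33.11,
      225.78, 26.83, 951.54, 449.30
    ),
    hospital_cost = c(
      36.19, 132.19, 951.29, 622.59, 2430.00,
      173.21, 50.50, 370.71, 48.66,
      162.42, 88.13, 67.60, 33.11,
      165.31, 26.83, 905.18, 393.57
    )
  )
}

#' Default modality-to-tariff mapping
#'
#' Registry modality ids and tariff-table keys do not coincide one-to-one:
#' some modalities are priced under a broader procedure class. The default
#' mapping prices
#' \itemize{
#'   \item `ct` under the CT-thorax tariff,
#'   \item `cervical_mediastinoscopy` under the mediastinoscopy tariff,
#'   \item `x_ray_guidance_bronchoscopy` under the X-ray guidance tariff,
#'   \item `x_thorax_after_biopsy` under the plain X-thorax tariff,
#'   \item `broad_lung_function` under the flow volume + diffusion tariff,
#'   \item `bone_scintigraphy` under the ventilation/perfusion-scan tariff
#'     (nearest nuclear-medicine procedure class; exclude it by dropping the
#'     entry from the mapping if a priced substitute is unacceptable).
#' }
#' All other modalities map to the identically named tariff row.
#'
#' @return Named character vector: names are registry modality ids, values
#'   tariff-table keys.
#' @export
default_tariff_mapping <- function() {
  ids <- default_registry()$modality_id
  map <- stats::setNames(ids, ids)
  map[["ct"]] <- "ct_thorax"
  map[["cervical_mediastinoscopy"]] <- "mediastinoscopy"
  map[["x_ray_guidance_bronchoscopy"]] <- "x_ray_guidance"
  map[["x_thorax_after_biopsy"]] <- "x_thorax"
  map[["broad_lung_function"]] <- "flow_volume_diffusion"
  map[["bone_scintigraphy"]] <- "ventilation_perfusion_scan"
  map
}

#' Read a tariff table from CSV or JSON
#'
#' CSV needs columns `modality_id`, `procedure_code`, `tariff`,
#' `hospital_cost`; JSON is an object keyed by `modality_id` whose values
#' carry the remaining three fields.
#'
#' @param path file path; format inferred from the `.json` extension.
#' @return A [tariff_table()].
#' @export
read_tariffs <- function(path) {
  if (!file.exists(path)) stop("tariff file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path)
    tariff_table(
      modality_id = names(raw),
      procedure_code = vapply(raw, function(x) as.character(x$procedure_code), ""),
      tariff = vapply(raw, function(x) as.numeric(x$tariff), 0),
      hospital_cost = vapply(raw, function(x) as.numeric(x$hospital_cost), 0)
    )
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(procedure_code = "character"))
    need <- c("modality_id", "procedure_code", "tariff", "hospital_cost")
    missing <- setdiff(need, names(df))
    if (length(missing)) {
      stop("tariff CSV lacks columns: ", paste(missing, collapse = ", "))
    }
    tariff_table(df$modality_id, df$procedure_code, df$tariff, df$hospital_cost)
  }
}

#' Write a tariff table
#'
#' @param tariffs a [tariff_table()].
#' @param path destination; `.json` writes the keyed-object form, anything
#'   else CSV.
#' @return Invisibly, `path`.
#' @export
write_tariffs <- function(tariffs, path) {
  stopifnot(inherits(tariffs, "tariff_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- lapply(seq_len(nrow(tariffs)), function(i) {
      list(procedure_code = tariffs$procedure_code[i],
           tariff = tariffs$tariff[i],
           hospital_cost = tariffs$hospital_cost[i])
    })
    names(obj) <- tariffs$modality_id
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(tariffs), path, row.names = FALSE)
  }
  invisible(path)
}

# Resolve unit cost in euro cents for each requested modality.
# Returns integer cents; errors on modalities absent from the mapping.
tariff_cents <- function(modality_id, tariffs, mapping, cost_basis) {
  cost_basis <- match.arg(cost_basis, c("tariff", "hospital_cost"))
  unmapped <- setdiff(modality_id, names(mapping))
  if (length(unmapped)) {
    stop("no tariff mapping for: ", paste(unmapped, collapse = ", "))
  }
  keys <- mapping[modality_id]
  missing <- setdiff(keys, tariffs$modality_id)
  if (length(missing)) {
    stop("tariff table lacks entries for: ", paste(missing, collapse = ", "))
  }
  idx <- match(keys, tariffs$modality_id)
  as.integer(round(tariffs[[cost_basis]][idx] * 100))
}
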