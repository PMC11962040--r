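# Oxidative-stress bookkeeping: paired d-ROMs / BAP assay records, censoring
# flags at the analyzer's accurate detection ranges, deploy-to-retrieve
# changes, and the Carratelli-unit conversion.

#' Analyzer detection limits
#'
#' The free-radical analyzer's accurate detection ranges: 40-1000 U. CARR for
#' d-ROMs and 500-6000 uM/L for BAP.
#'
#' @return A list with elements `drom` and `bap`, each `c(lower, upper)`.
#' @export
detection_limits <- function() {
  list(drom = c(lower = 40, upper = 1000), bap = c(lower = 500, upper = 6000))
}

#' Convert Carratelli units to hydrogen-peroxide equivalents
#'
#' One U. CARR corresponds to 0.08 mg H2O2 per dL.
#'
#' @param x d-ROMs value(s) in U. CARR, non-negative.
#' @return mg H2O2 / dL.
#' @export
ucarr_to_mg_h2o2_dl <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("U. CARR values must be non-negative")
  x * 0.08
}

#' Flag assay values against detection limits
#'
#' Values at or below the lower limit are `below_lower`, at or above the
#' upper limit `above_upper`, and strictly inside the range `in_range`.
#'
#' @param x Assay values.
#' @param limits `c(lower, upper)`.
#' @return Character vector of censor flags.
#' @export
censor_flag <- function(x, limits) {
  if (limits[1] >= limits[2]) abort("lower limit must be below upper limit")
  dplyr::case_when(
    is.na(x) ~ NA_character_,
    x <= limits[1] ~ "below_lower",
    x >= limits[2] ~ "above_upper",
    TRUE ~ "in_range"
  )
}

#' Deploy-to-retrieve changes in oxidative stress
#'
#' For each individual with both a `deploy` and a `retrieve` record, computes
#' retrieve minus deploy for d-ROMs and BAP. Unpaired individuals are
#' retained with missing changes; duplicate timepoints are an error.
#'
#' @param records A data frame with columns `individual_id`,
#'   `timepoint` (`"deploy"`/`"retrieve"`), `drom_ucarr`, `bap_umol_l`.
#' @return A tibble `individual_id`, `drom_deploy`, `drom_retrieve`,
#'   `bap_deploy`, `bap_retrieve`, `delta_drom`, `delta_bap`.
#' @export
compute_changes <- function(records) {
  records <- as_tibble(records)
  need <- c("individual_id", "timepoint", "drom_ucarr", "bap_umol_l")
  if (!all(need %in% names(records))) {
    abort(paste0("records must have columns: ", paste(need, collapse = ", ")))
  }
  if (!all(records$timepoint %in% c("deploy", "retrieve"))) {
    abort("timepoint must be 'deploy' or 'retrieve'")
  }
  dup <- records |>
    count(.data$individual_id, .data$timepoint) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate timepoint for: ", paste(unique(dup$individual_id), collapse = ", ")))
  }
  wide <- records |>
    select("individual_id", "timepoint", "drom_ucarr", "bap_umol_l") |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = c("drom_ucarr", "bap_umol_l"))
  for (col in c("drom_ucarr_deploy", "drom_ucarr_retrieve",
                "bap_umol_l_deploy", "bap_umol_l_retrieve")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide |>
    transmute(
      individual_id = .data$individual_id,
      drom_deploy = .data$drom_ucarr_deploy,
      drom_retrieve = .data$drom_ucarr_retrieve,
      bap_deploy = .data$bap_umol_l_deploy,
      bap_retrieve = .data$bap_umol_l_retrieve,
      delta_drom = .data$drom_retrieve - .data$drom_deploy,
      delta_bap = .data$bap_retrieve - .data$bap_deploy
    )
}

#' Read and write assay tables
#'
#' CSV dialect: `individual_id,timepoint,drom_ucarr,bap_umol_l`.
#'
#' @param path File path.
#' @return A tibble of assay records.
#' @export
read_assay_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    individual_id = readr::col_character(),
    timepoint = readr::col_character(),
    drom_ucarr = readr::col_double(),
    bap_umol_l = readr::col_double()
  ))
}

#' @rdname read_assay_csv
#' @param records An assay record tibble.
#' @export
write_assay_csv <- function(records, path) {
  readr::write_csv(records[, c("individual_id", "timepoint", "drom_ucarr", "bap_umol_l")], path)
  invisible(path)
}
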