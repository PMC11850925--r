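# YAML configuration layer shared by the command-line entry point. Keys are
# unit-tagged (`*_ml`, `*_ul`, `*_um`, `*_kg`, `*_min`, `*_ml_min`): the
# reader refuses configs that give the same quantity in two different
# volume units, the classic mL/uL mix-up.

.unit_suffixes <- c("_ml_min", "_ul_min", "_ml", "_ul", "_um", "_kg", "_min", "_mmhg")

#' Read a unit-tagged YAML configuration
#'
#' @param path YAML file path.
#' @return Named list of the parsed config.
#' @export
read_cif_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  keys <- names(unlist(cfg))
  strip <- function(k, sfx) sub(paste0(sfx, "$"), "", k)
  vol_ml <- grep("_ml$", keys, value = TRUE)
  vol_ul <- grep("_ul$", keys, value = TRUE)
  clash <- intersect(strip(vol_ml, "_ml"), strip(vol_ul, "_ul"))
  if (length(clash)) {
    abort(paste0("Config gives the same volume in both mL and uL: ",
                 paste(clash, collapse = ", ")),
          class = "cifsim_unit_error")
  }
  cfg
}

#' Write a separation result as CSV
#'
#' One row per cell type (`cell_type`, `C_in`, `C_ret`, `C_fil`,
#' `ce_percent`, `cr_fold`) with the volumes and realised flow ratio
#' repeated on each row. CE/CR are written at one-decimal reporting
#' precision; concentrations at full precision.
#'
#' @param sep A `cif_separation`.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_separation <- function(sep, path) {
  stopifnot(inherits(sep, "cif_separation"))
  out <- sep$per_type |>
    dplyr::mutate(ce_percent = round(.data$ce_percent, 1),
                  cr_fold = round(.data$cr_fold, 1),
                  v_in = sep$v_in, v_ret = sep$v_ret, v_fil = sep$v_fil,
                  flow_ratio = sep$flow_ratio)
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a recirculation run as CSV time series plus JSON summary
#'
#' @param run A `cif_recirculation`.
#' @param csv_path Tidy time series (`time`, `cell_type`, `concentration`,
#'   `volume_ml`).
#' @param json_path Summary: per-type final percent of baseline, in-vivo CE
#'   and CR, and eTBV processed.
#' @return The paths, invisibly.
#' @export
write_recirculation <- function(run, csv_path,
                                json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(run, "cif_recirculation"))
  readr::write_csv(run$timeseries, csv_path)
  summary <- list(
    etbv_processed = glance(run)$etbv_processed,
    v_proc_ml = glance(run)$v_proc_ml,
    final_percent = setNames(as.list(round(final_percent(run)$final_percent, 1)),
                             final_percent(run)$cell_type),
    ce_invivo_percent = setNames(
      as.list(round(collection_efficiency_invivo(run)$ce_percent, 1)),
      collection_efficiency_invivo(run)$cell_type)
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}
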