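# Clinical apheresis bookkeeping: estimated total blood volume, processed
# volume in eTBV units, processing rate, and extracorporeal-volume fractions.

#' Estimated total blood volume
#'
#' The 70 mL/kg convention, applied across species for consistency (the
#' coefficient is configurable).
#'
#' @param weight_kg Body weight (kg), > 0. Vectorised.
#' @param ml_per_kg Blood volume coefficient (mL/kg); default 70.
#' @return eTBV in mL.
#' @examples
#' etbv(9)     # 630 mL
#' etbv(0.375) # 26.25 mL
#' @export
etbv <- function(weight_kg, ml_per_kg = 70) {
  if (any(weight_kg <= 0)) abort("`weight_kg` must be positive.", class = "cifsim_domain_error")
  ml_per_kg * weight_kg
}

#' Describe an apheresis procedure
#'
#' @param inlet_ml Inlet (whole blood + anticoagulant) flow volume (mL).
#' @param anticoagulant_ml Anticoagulant flow volume (mL);
#'   `inlet_ml >= anticoagulant_ml >= 0`.
#' @param weight_kg Patient weight (kg), > 0.
#' @param circuit_ecv_ml Extracorporeal volume of the circuit (mL).
#' @param duration_min Procedure duration (min), optional (enables rates).
#' @return An `apheresis_procedure` list.
#' @export
apheresis_procedure <- function(inlet_ml, anticoagulant_ml = 0, weight_kg,
                                circuit_ecv_ml = NA, duration_min = NA) {
  if (weight_kg <= 0) abort("`weight_kg` must be positive.", class = "cifsim_domain_error")
  if (anticoagulant_ml < 0 || inlet_ml < anticoagulant_ml) {
    abort("Need inlet_ml >= anticoagulant_ml >= 0.", class = "cifsim_domain_error")
  }
  structure(list(inlet_ml = inlet_ml, anticoagulant_ml = anticoagulant_ml,
                 weight_kg = weight_kg, circuit_ecv_ml = circuit_ecv_ml,
                 duration_min = duration_min),
            class = "apheresis_procedure")
}

#' Blood volume processed, in eTBV units
#'
#' `(inlet volume - anticoagulant volume) / eTBV`, the standard normalisation
#' of processed volume to the patient's estimated total blood volume;
#' additive over sequential volumes by linearity.
#'
#' @param proc An [apheresis_procedure()], or the inlet volume (mL) with the
#'   remaining quantities as named arguments.
#' @inheritParams apheresis_procedure
#' @param ml_per_kg Passed to [etbv()].
#' @return One-row tibble: `etbv_ml`, `etbv_processed`, and (when a duration
#'   is known) `etbv_per_hr`.
#' @examples
#' etbv_processed(2000, anticoagulant_ml = 200, weight_kg = 9)
#' @export
etbv_processed <- function(proc, anticoagulant_ml = 0, weight_kg = NULL,
                           duration_min = NA, ml_per_kg = 70) {
  if (!inherits(proc, "apheresis_procedure")) {
    proc <- apheresis_procedure(inlet_ml = proc, anticoagulant_ml = anticoagulant_ml,
                                weight_kg = weight_kg, duration_min = duration_min)
  }
  tbv <- etbv(proc$weight_kg, ml_per_kg)
  processed <- (proc$inlet_ml - proc$anticoagulant_ml) / tbv
  tibble::tibble(
    etbv_ml = tbv,
    etbv_processed = processed,
    etbv_per_hr = if (is.na(proc$duration_min)) NA_real_ else
      processed / (proc$duration_min / 60)
  )
}

#' Extracorporeal volume as a fraction of eTBV
#'
#' The key feasibility number for small patients: what fraction of the
#' circulating blood volume sits in the circuit. Scales inversely with
#' patient weight.
#'
#' @param circuit_ecv_ml Circuit extracorporeal volume (mL), > 0.
#' @param weight_kg Patient weight (kg), > 0.
#' @param ml_per_kg Passed to [etbv()].
#' @return Percent of eTBV (unrounded; round for reporting).
#' @examples
#' ecv_fraction(4.2, 9)    # ~0.7 %
#' ecv_fraction(300, 46)   # ~9.3 %
#' @export
ecv_fraction <- function(circuit_ecv_ml, weight_kg, ml_per_kg = 70) {
  if (any(circuit_ecv_ml <= 0)) abort("`circuit_ecv_ml` must be positive.",
                                      class = "cifsim_domain_error")
  100 * circuit_ecv_ml / etbv(weight_kg, ml_per_kg)
}

#' Summarise an apheresis procedure
#'
#' @param proc An [apheresis_procedure()].
#' @param ml_per_kg Passed to [etbv()].
#' @return One-row tibble joining [etbv_processed()] and [ecv_fraction()].
#' @export
apheresis_summary <- function(proc, ml_per_kg = 70) {
  stopifnot(inherits(proc, "apheresis_procedure"))
  out <- etbv_processed(proc, ml_per_kg = ml_per_kg)
  out$ecv_percent_etbv <- if (is.na(proc$circuit_ecv_ml)) NA_real_ else
    ecv_fraction(proc$circuit_ecv_ml, proc$weight_kg, ml_per_kg)
  out
}
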