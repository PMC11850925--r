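# Ready-to-run protocol templates matching the reference procedures:
# the rat extracorporeal recirculation (CIF and sham arms) and the
# projected pediatric multiplexed device.

#' Protocol templates for the reference procedures
#'
#' Three ready-to-run configurations:
#'
#' * `rat_cif` — 3-hour pumpless arteriovenous recirculation in a 0.375 kg
#'   rat: circuit flow 0.45 mL/min (filtrate return), retentate withdrawal
#'   at 5% of the filtrate flow (FR ~ 20), 736 uL circuit ECV, CBC draws of
#'   0.3 mL every 15 min, retentate pooled in 30-min epochs.
#' * `rat_sham` — same subject and schedule across a resistance bridge:
#'   flow 0.319 mL/min, no retentate withdrawal, separation inactive
#'   (`ce_percent` all zero).
#' * `pediatric_multiplex` — eight parallel devices at 9.6 mL/min total
#'   (576 mL/hr) for a 9 kg patient, 4.2 mL combined device + tubing dead
#'   volume.
#'
#' Each entry bundles a [cif_subject()] (built from the species fixture at
#' the given seed), a [recirculation_protocol()], a per-type `ce_percent`
#' preset where the arm defines one, and a [device_array()] where relevant.
#'
#' @param seed Seed forwarded to the blood fixtures.
#' @return Named list `rat_cif`, `rat_sham`, `pediatric_multiplex`.
#' @export
make_protocol_templates <- function(seed = 1L) {
  rat <- make_blood(blood_spec("rat", seed = seed, concentration_cv = 0))
  rat_subject <- cif_subject(weight_kg = 0.375, baseline = rat)

  rat_cif <- list(
    subject = rat_subject,
    protocol = recirculation_protocol(
      duration_min = 180, circuit_flow_ml_min = 0.45,
      retentate_fraction = 0.05, sample_times_min = seq(15, 180, 15),
      sample_volume_ml = 0.3, retentate_epoch_min = 30,
      circuit_ecv_ml = 0.736),
    ce_percent = NULL   # supply from separate_sample() on a chosen design
  )
  rat_sham <- list(
    subject = rat_subject,
    protocol = recirculation_protocol(
      duration_min = 180, circuit_flow_ml_min = 0.319,
      retentate_fraction = 0, sample_times_min = seq(15, 180, 15),
      sample_volume_ml = 0.3, retentate_epoch_min = 30,
      circuit_ecv_ml = 0.736),
    ce_percent = setNames(rep(0, nrow(rat)), rat$cell_type)
  )

  child <- make_blood(blood_spec("human", seed = seed,
                                 preset = "hyperleukocytosis",
                                 blast_concentration = 1.2e5))
  pediatric_multiplex <- list(
    subject = cif_subject(weight_kg = 9, baseline = child),
    array = device_array(n_devices = 8, per_device_flow_ml_min = 1.2,
                         device_dead_volume_ul = 87,
                         tubing_dead_volume_ul = 4200 - 8 * 87),
    protocol = recirculation_protocol(
      duration_min = 180, circuit_flow_ml_min = 9.6,
      retentate_fraction = 0.05, sample_times_min = seq(15, 180, 15),
      sample_volume_ml = 1, retentate_epoch_min = 30,
      circuit_ecv_ml = 4.2),
    ce_percent = NULL
  )

  list(rat_cif = rat_cif, rat_sham = rat_sham,
       pediatric_multiplex = pediatric_multiplex)
}

#' The four reference element designs
#'
#' Generates the four-element design family sharing one architecture and
#' initial retentate width but differing in the initial filtration fraction
#' (`f_gap*` of 0.72, 1.00, 1.28 and 1.70 x 10^-3), which staggers their
#' size cutoffs across the leukocyte size range.
#'
#' @param w_r_star Shared initial retentate width (um).
#' @param target_fr Flow-ratio target for every design.
#' @param ... Passed to [design_element()].
#' @return Named list `design1` ... `design4` of `cif_design` objects.
#' @export
reference_designs <- function(w_r_star = 230, target_fr = 20, ...) {
  f_star <- c(design1 = 0.72e-3, design2 = 1.00e-3,
              design3 = 1.28e-3, design4 = 1.70e-3)
  purrr::map(f_star, design_element, w_r_star = w_r_star,
             target_fr = target_fr, ...)
}
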