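# Multiplexing: identical CIF elements tiled eight to a device, devices
# tiled in parallel arrays. At creeping-flow Reynolds numbers the capture
# physics is flow-rate-agnostic, so parallelization buys throughput without
# touching CE/CR; dead volumes add up.

#' Describe a parallel array of CIF devices
#'
#' @param n_devices Number of identical devices in parallel (>= 1).
#' @param elements_per_device CIF elements per device (8 in the reference
#'   layout).
#' @param per_device_flow_ml_min Whole-blood flow through each device
#'   (mL/min).
#' @param device_dead_volume_ul Dead volume of one device (uL).
#' @param tubing_dead_volume_ul Dead volume of the interconnect tubing for
#'   the whole array (uL).
#' @return A `device_array` list with the derived totals.
#' @examples
#' array_throughput(device_array(8))
#' @export
device_array <- function(n_devices = 1,
                         elements_per_device = 8,
                         per_device_flow_ml_min = 1.2,
                         device_dead_volume_ul = 87,
                         tubing_dead_volume_ul = 214 * n_devices) {
  if (n_devices < 1 || n_devices != round(n_devices)) {
    abort("`n_devices` must be a positive integer.", class = "cifsim_domain_error")
  }
  if (per_device_flow_ml_min <= 0) {
    abort("`per_device_flow_ml_min` must be positive.", class = "cifsim_domain_error")
  }
  structure(
    list(n_devices = as.integer(n_devices),
         elements_per_device = as.integer(elements_per_device),
         per_device_flow_ml_min = per_device_flow_ml_min,
         device_dead_volume_ul = device_dead_volume_ul,
         tubing_dead_volume_ul = tubing_dead_volume_ul),
    class = "device_array"
  )
}

#' Throughput and dead volume of a device array
#'
#' Total flow is the product of device count and per-device flow; per-element
#' flow divides it across all parallel elements; dead volume is the additive
#' sum of device and tubing terms (the array's extracorporeal volume).
#'
#' @param array A [device_array()], or a device count (with
#'   `per_device_flow_ml_min` then giving the flow).
#' @param per_device_flow_ml_min Used only when `array` is given as a count.
#' @return One-row tibble: `n_devices`, `total_flow_ml_min`,
#'   `total_flow_ml_hr`, `per_element_flow_ul_min`, `dead_volume_ul`.
#' @export
array_throughput <- function(array, per_device_flow_ml_min = 1.2) {
  if (!inherits(array, "device_array")) {
    array <- device_array(n_devices = array,
                          per_device_flow_ml_min = per_device_flow_ml_min)
  }
  total <- array$n_devices * array$per_device_flow_ml_min
  tibble::tibble(
    n_devices = array$n_devices,
    total_flow_ml_min = total,
    total_flow_ml_hr = total * 60,
    per_element_flow_ul_min = total * 1000 / (array$n_devices * array$elements_per_device),
    dead_volume_ul = array$n_devices * array$device_dead_volume_ul +
      array$tubing_dead_volume_ul
  )
}

#' Separate a sample through a parallel device array
#'
#' Splits the sample evenly across devices, runs each device as an
#' independent single pass, and pools the retentate and filtrate outputs.
#' In deterministic mode the result is identical to the single-device
#' prediction (the model is flow-rate-agnostic); in Monte-Carlo mode each
#' device gets an independent seed derived from `seed` and the pooled CE
#' agrees with a single device to sampling error. If the per-element flow
#' implied by the array differs from the design's `q_in`, a warning records
#' the deviation (capture is modelled as flow-rate-independent).
#'
#' @param sample A [blood_sample()] (the total volume processed).
#' @param design The element design shared by all devices.
#' @param array A [device_array()].
#' @inheritParams separate_sample
#' @return A `cif_separation` for the pooled outputs, with a
#'   `per_device` element listing each device's separation.
#' @export
separate_array <- function(sample, design, array,
                           mode = c("deterministic", "monte-carlo"),
                           n_cells = 1e5, seed = NULL, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(array, "device_array"))
  thr <- array_throughput(array)
  if (abs(thr$per_element_flow_ul_min - design$q_in) > 1e-9 * design$q_in) {
    warn(sprintf(
      "Per-element flow %.3g uL/min differs from the design flow %.3g uL/min; capture is modelled as flow-rate-independent.",
      thr$per_element_flow_ul_min, design$q_in))
  }
  n <- array$n_devices
  v_split <- sample_volume(sample) / n
  sub <- blood_sample(tibble::as_tibble(sample), volume_ul = v_split,
                      species = sample_species(sample))
  runs <- purrr::map(seq_len(n), function(k) {
    separate_sample(sub, design, mode = mode,
                    n_cells = ceiling(n_cells / n),
                    seed = if (is.null(seed)) NULL else seed + k - 1L, ...)
  })

  v_ret <- sum(purrr::map_dbl(runs, "v_ret"))
  v_fil <- sum(purrr::map_dbl(runs, "v_fil"))
  pooled <- purrr::map_dfr(runs, function(r) {
    dplyr::mutate(r$per_type,
                  cells_ret = .data$C_ret * r$v_ret,
                  cells_fil = .data$C_fil * r$v_fil,
                  cells_in = .data$C_in * r$v_in)
  }) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(dplyr::across(c("cells_in", "cells_ret", "cells_fil"), sum)) |>
    dplyr::mutate(
      C_in = .data$cells_in / sample_volume(sample),
      C_ret = .data$cells_ret / v_ret,
      C_fil = .data$cells_fil / v_fil,
      ce_percent = 100 * .data$cells_ret / .data$cells_in,
      cr_fold = .data$C_ret / .data$C_in
    ) |>
    dplyr::select("cell_type", "C_in", "C_ret", "C_fil", "ce_percent", "cr_fold")

  structure(
    list(per_type = pooled, v_in = sample_volume(sample), v_ret = v_ret,
         v_fil = v_fil, flow_ratio = v_fil / v_ret, mode = mode,
         n_cells = if (mode == "monte-carlo") n_cells else NA, seed = seed,
         steric_model = runs[[1]]$steric_model, design = glance(design),
         cell_log = NULL, per_device = runs, array = array),
    class = "cif_separation"
  )
}
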