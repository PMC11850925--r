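# In-vivo recirculation leukapheresis: a single well-mixed blood compartment
# drained through an extracorporeal CIF circuit. Cells of each type leave at
# rate Q * (CE/100) * C(t) into the continuously withdrawn retentate; the
# filtrate returns to the subject. Serial CBC draws and fluid events perturb
# the compartment at discrete times.

#' Describe the subject of a recirculation procedure
#'
#' @param weight_kg Body weight (kg), > 0.
#' @param baseline A [blood_sample()] giving the circulating concentrations
#'   at connection.
#' @param etbv_ml Estimated total blood volume (mL); default [etbv()] at
#'   70 mL/kg.
#' @param influx_per_min Named numeric vector of zero-order cell influx into
#'   the circulation (cells/min per type, e.g. stress demargination);
#'   default none.
#' @return A `cif_subject` list.
#' @export
cif_subject <- function(weight_kg, baseline, etbv_ml = etbv(weight_kg),
                        influx_per_min = NULL) {
  if (weight_kg <= 0) abort("`weight_kg` must be positive.", class = "cifsim_domain_error")
  if (etbv_ml <= 0) abort("`etbv_ml` must be positive.", class = "cifsim_domain_error")
  stopifnot(inherits(baseline, "blood_sample"))
  if (!is.null(influx_per_min)) {
    if (is.null(names(influx_per_min)) ||
        !all(names(influx_per_min) %in% baseline$cell_type)) {
      abort("`influx_per_min` must be named by baseline cell types.",
            class = "cifsim_validation_error")
    }
    if (any(influx_per_min < 0)) {
      abort("`influx_per_min` must be >= 0.", class = "cifsim_domain_error")
    }
  }
  structure(list(weight_kg = weight_kg, baseline = baseline,
                 etbv_ml = etbv_ml, influx_per_min = influx_per_min),
            class = "cif_subject")
}

#' Describe a recirculation protocol
#'
#' @param duration_min Procedure duration (min); the reference procedure runs
#'   180 min.
#' @param circuit_flow_ml_min Measured filtrate flow returning to the subject
#'   (mL/min).
#' @param retentate_fraction Retentate withdrawal flow as a fraction of the
#'   filtrate return flow, in `[0, 0.5)` (0 models a sham bridge with no
#'   withdrawal; the reference setting is 0.05, i.e. FR ~ 20).
#' @param sample_times_min Times of serial CBC draws (min).
#' @param sample_volume_ml Whole-blood volume of each draw (mL).
#' @param retentate_epoch_min Length of the retentate collection epochs over
#'   which aliquots are pooled (min); default 30.
#' @param fluid_events Data frame `time_min`, `volume_ml` of crystalloid
#'   boluses (volume only, no cells).
#' @param circuit_ecv_ml Extracorporeal volume of the circuit (mL), removed
#'   from the circulating compartment at connection.
#' @param replace_sample_volume If `TRUE` (default) each draw's volume is
#'   replaced by cell-free fluid (flush/refill), so draws dilute counts; if
#'   `FALSE` the compartment volume shrinks instead.
#' @param replace_withdrawal If `TRUE` (default) the continuously withdrawn
#'   retentate volume is replaced 1:1 by saline, keeping `V(t)` constant
#'   between events.
#' @param cbc_noise_cv Multiplicative log-normal noise CV applied to reported
#'   CBC values (default 0 = noiseless; needs `seed` when > 0).
#' @param seed Seed, used only when measurement noise is enabled.
#' @return A `recirculation_protocol` list.
#' @export
recirculation_protocol <- function(duration_min = 180,
                                   circuit_flow_ml_min,
                                   retentate_fraction = 0.05,
                                   sample_times_min = seq(15, duration_min, by = 15),
                                   sample_volume_ml = 0.3,
                                   retentate_epoch_min = 30,
                                   fluid_events = NULL,
                                   circuit_ecv_ml = 0,
                                   replace_sample_volume = TRUE,
                                   replace_withdrawal = TRUE,
                                   cbc_noise_cv = 0,
                                   seed = NULL) {
  if (duration_min <= 0 || circuit_flow_ml_min <= 0) {
    abort("Duration and circuit flow must be positive.", class = "cifsim_domain_error")
  }
  if (retentate_fraction < 0 || retentate_fraction >= 0.5) {
    abort("`retentate_fraction` must lie in [0, 0.5).", class = "cifsim_domain_error")
  }
  if (length(sample_times_min) &&
      (any(sample_times_min < 0) || any(sample_times_min > duration_min))) {
    abort("Sampling schedule must lie within [0, duration].", class = "cifsim_domain_error")
  }
  if (!is.null(fluid_events)) {
    fluid_events <- tibble::as_tibble(fluid_events)
    stopifnot(all(c("time_min", "volume_ml") %in% names(fluid_events)))
    if (any(fluid_events$time_min < 0) || any(fluid_events$time_min > duration_min)) {
      abort("Fluid events must lie within [0, duration].", class = "cifsim_domain_error")
    }
  } else {
    fluid_events <- tibble::tibble(time_min = numeric(), volume_ml = numeric())
  }
  if (cbc_noise_cv > 0 && is.null(seed)) {
    abort("`seed` is required when CBC noise is enabled.", class = "cifsim_domain_error")
  }
  structure(
    list(duration_min = duration_min, circuit_flow_ml_min = circuit_flow_ml_min,
         retentate_fraction = retentate_fraction,
         sample_times_min = sort(unique(sample_times_min)),
         sample_volume_ml = sample_volume_ml,
         retentate_epoch_min = retentate_epoch_min, fluid_events = fluid_events,
         circuit_ecv_ml = circuit_ecv_ml,
         replace_sample_volume = replace_sample_volume,
         replace_withdrawal = replace_withdrawal,
         cbc_noise_cv = cbc_noise_cv, seed = seed),
    class = "recirculation_protocol"
  )
}

#' Simulate an in-vivo recirculation leukapheresis procedure
#'
#' Integrates, per cell type, `dN/dt = -Q (CE/100) C + influx` with
#' `C = N/V`, where `Q` is the circuit flow and CE the device's single-pass
#' collection efficiency for that type, alongside the compartment volume
#' `V(t)` (retentate withdrawal, optional replacement, fluid boluses) and
#' cumulative ledgers for removed cells and processed volume. Serial CBC
#' draws are instantaneous whole-blood removals at the scheduled times.
#' Integration uses `deSolve::lsoda` with events at every draw and bolus.
#'
#' @param subject A [cif_subject()].
#' @param ce_percent Named per-type single-pass collection efficiency (%),
#'   covering every baseline cell type (e.g. from
#'   `tidy(separate_sample(...))`).
#' @param protocol A [recirculation_protocol()].
#' @param rtol Relative integrator tolerance.
#' @return A `cif_recirculation` object: [tidy()] gives the concentration
#'   time series, `$aliquots` the per-epoch retentate collections,
#'   `$ledger` the per-type cell balance, [glance()] the run summary
#'   (processed volume, eTBV processed, fluid totals).
#' @export
simulate_recirculation <- function(subject, ce_percent, protocol, rtol = 1e-8) {
  stopifnot(inherits(subject, "cif_subject"),
            inherits(protocol, "recirculation_protocol"))
  types <- subject$baseline$cell_type
  if (is.null(names(ce_percent)) || !all(types %in% names(ce_percent))) {
    abort("`ce_percent` must be named and cover every baseline cell type.",
          class = "cifsim_validation_error")
  }
  ce <- ce_percent[types]
  if (any(ce < 0 | ce > 100)) {
    abort("`ce_percent` values must lie in [0, 100].", class = "cifsim_domain_error")
  }

  q_ul <- protocol$circuit_flow_ml_min * 1000          # uL/min
  q_ret <- protocol$retentate_fraction * q_ul          # withdrawal, uL/min
  v0 <- (subject$etbv_ml - protocol$circuit_ecv_ml) * 1000
  if (v0 <= 0) abort("Circuit ECV exceeds the subject's blood volume.",
                     class = "cifsim_domain_error")
  c0 <- setNames(subject$baseline$concentration, types)
  influx <- setNames(rep(0, length(types)), types)
  if (!is.null(subject$influx_per_min)) {
    influx[names(subject$influx_per_min)] <- subject$influx_per_min
  }

  nt <- length(types)
  state <- c(c0 * v0,                       # N: circulating cells
             rep(0, nt),                    # R: cumulative cells to retentate
             rep(0, nt),                    # S: cumulative cells to sampling
             V = v0, Vproc = 0)
  iN <- seq_len(nt); iR <- nt + iN; iS <- 2 * nt + iN
  iV <- 3 * nt + 1L; iVp <- 3 * nt + 2L
  dv_cont <- if (protocol$replace_withdrawal) 0 else -q_ret

  deriv <- function(t, y, parms) {
    V <- y[iV]
    conc <- y[iN] / V
    removal <- q_ul * (ce / 100) * conc
    list(c(influx - removal, removal, rep(0, nt), dv_cont, q_ul))
  }
  sample_set <- protocol$sample_times_min
  vol_draw <- protocol$sample_volume_ml * 1000
  fe <- protocol$fluid_events
  eventfun <- function(t, y, parms) {
    if (any(abs(sample_set - t) < 1e-9)) {
      V <- y[iV]
      drawn <- y[iN] * (vol_draw / V)
      y[iN] <- y[iN] - drawn
      y[iS] <- y[iS] + drawn
      if (!protocol$replace_sample_volume) y[iV] <- V - vol_draw
    }
    hit <- abs(fe$time_min - t) < 1e-9
    if (any(hit)) y[iV] <- y[iV] + sum(fe$volume_ml[hit]) * 1000
    y
  }
  event_times <- sort(unique(c(sample_set, fe$time_min)))
  event_times <- event_times[event_times > 0 & event_times < protocol$duration_min]
  epoch_bounds <- unique(c(seq(0, protocol$duration_min, by = protocol$retentate_epoch_min),
                           protocol$duration_min))
  times <- sort(unique(c(seq(0, protocol$duration_min, by = 1),
                         event_times, epoch_bounds, protocol$duration_min)))

  ode_args <- list(y = state, times = times, func = deriv, parms = NULL,
                   rtol = rtol, atol = 1e-6 * max(state), method = "lsoda")
  if (length(event_times)) {
    ode_args$events <- list(func = eventfun, time = event_times)
  }
  sol <- do.call(deSolve::ode, ode_args)
  sol <- as.data.frame(sol)
  if (any(sol[[iV + 1L]] <= 0)) {
    bad <- sol$time[which(sol[[iV + 1L]] <= 0)[1]]
    abort(sprintf("Blood volume depleted at t = %.1f min; adjust fluids/sampling.", bad),
          class = "cifsim_simulation_error")
  }

  v_t <- sol[[iV + 1L]]
  conc_mat <- as.matrix(sol[, 1L + iN, drop = FALSE]) / v_t
  colnames(conc_mat) <- types
  ts <- tibble::tibble(time = rep(sol$time, nt),
                       cell_type = rep(types, each = nrow(sol)),
                       concentration = as.vector(conc_mat),
                       volume_ml = rep(v_t / 1000, nt))
  if (protocol$cbc_noise_cv > 0) {
    sdl <- sqrt(log(1 + protocol$cbc_noise_cv^2))
    ts$reported_concentration <- withr::with_seed(protocol$seed,
      ts$concentration * exp(stats::rnorm(nrow(ts), -sdl^2 / 2, sdl)))
  }

  # retentate aliquots per epoch from the removal ledger
  R_mat <- as.matrix(sol[, 1L + iR, drop = FALSE]); colnames(R_mat) <- types
  bidx <- match(epoch_bounds, sol$time)
  aliquots <- purrr::map_dfr(seq_len(length(epoch_bounds) - 1L), function(k) {
    t0 <- epoch_bounds[k]; t1 <- epoch_bounds[k + 1L]
    vol <- q_ret * (t1 - t0)
    cells <- unname(R_mat[bidx[k + 1L], ] - R_mat[bidx[k], ])
    tibble::tibble(epoch = k, t_start = t0, t_end = t1, cell_type = types,
                   cells_collected = cells, v_ret_ul = vol,
                   c_ret = if (vol > 0) cells / vol else NA_real_)
  })

  final <- nrow(sol)
  ledger <- tibble::tibble(
    cell_type = types,
    baseline_cells = unname(c0 * v0),
    influx_cells = unname(influx * protocol$duration_min),
    circulating_cells = unname(as.matrix(sol[final, 1L + iN])[1, ]),
    retentate_cells = unname(R_mat[final, ]),
    sampled_cells = unname(as.matrix(sol[final, 1L + iS])[1, ])
  )

  structure(
    list(timeseries = ts, aliquots = aliquots, ledger = ledger,
         c_pre = c0, c_post = setNames(conc_mat[final, ], types),
         v_proc_ul = sol[final, 1L + iVp], v0_ul = v0,
         etbv_ml = subject$etbv_ml,
         fluid = tibble::tibble(
           removed_ml = q_ret * protocol$duration_min / 1000 +
             length(protocol$sample_times_min) * protocol$sample_volume_ml,
           given_ml = (if (protocol$replace_withdrawal) q_ret * protocol$duration_min / 1000 else 0) +
             (if (protocol$replace_sample_volume) length(protocol$sample_times_min) * protocol$sample_volume_ml else 0) +
             sum(fe$volume_ml)),
         ce_injected = ce, subject = subject, protocol = protocol),
    class = "cif_recirculation"
  )
}

#' @export
print.cif_recirculation <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cif_recirculation> %g min, %.2f eTBV processed, V_proc = %.0f mL\n",
              x$protocol$duration_min, g$etbv_processed, g$v_proc_ml))
  print(final_percent(x))
  invisible(x)
}

#' @rdname simulate_recirculation
#' @param x,object A `cif_recirculation`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cif_recirculation <- function(x, ...) x$timeseries

#' @rdname simulate_recirculation
#' @exportS3Method generics::glance
glance.cif_recirculation <- function(x, ...) {
  tibble::tibble(
    duration_min = x$protocol$duration_min,
    v_proc_ml = x$v_proc_ul / 1000,
    etbv_ml = x$etbv_ml,
    etbv_processed = x$v_proc_ul / (x$etbv_ml * 1000),
    fluid_removed_ml = x$fluid$removed_ml,
    fluid_given_ml = x$fluid$given_ml,
    n_samples = length(x$protocol$sample_times_min)
  )
}

#' @rdname simulate_recirculation
#' @exportS3Method ggplot2::autoplot
autoplot.cif_recirculation <- function(object, ...) {
  base <- object$timeseries |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::mutate(percent_baseline = 100 * .data$concentration /
                    .data$concentration[.data$time == 0])
  ggplot2::ggplot(base, ggplot2::aes(x = .data$time, y = .data$percent_baseline,
                                     colour = .data$cell_type)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "% of baseline concentration",
                  colour = NULL, title = "Recirculating cell counts") +
    ggplot2::theme_minimal()
}

#' Per-epoch in-vivo concentration ratio
#'
#' Ratio of the retentate aliquot concentration to a reference
#' concentration over the same epoch: the mean filtrate concentration
#' (`denominator = "filtrate"`, the apheresis-laboratory convention) or the
#' contemporaneous circulating blood concentration (`"blood"`). The overall
#' CR for a type is the mean over epochs.
#'
#' @param run A [simulate_recirculation()] result.
#' @param denominator `"filtrate"` or `"blood"`.
#' @return Tibble `cell_type`, `epoch`, `cr`, plus the per-type mean in
#'   `cr_overall`.
#' @export
concentration_ratio_invivo <- function(run, denominator = c("filtrate", "blood")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(run, "cif_recirculation"))
  fr_frac <- run$protocol$retentate_fraction
  ce <- run$ce_injected
  ts <- run$timeseries
  epochs <- dplyr::distinct(run$aliquots, .data$epoch, .data$t_start, .data$t_end)
  mean_blood <- purrr::pmap_dfr(epochs, function(epoch, t_start, t_end) {
    ts |>
      dplyr::filter(.data$time >= t_start, .data$time <= t_end) |>
      dplyr::group_by(.data$cell_type) |>
      dplyr::summarise(c_blood = .trapz_mean(.data$time, .data$concentration)) |>
      dplyr::mutate(epoch = epoch)
  })
  out <- run$aliquots |>
    dplyr::left_join(mean_blood, by = c("epoch", "cell_type")) |>
    dplyr::mutate(
      c_ref = if (denominator == "blood") .data$c_blood else
        .data$c_blood * (1 - ce[.data$cell_type] / 100) / (1 - fr_frac),
      cr = .data$c_ret / .data$c_ref
    )
  if (any(!is.finite(out$cr))) {
    abort("CR denominator is zero (no cells of that type reach the reference stream).",
          class = "cifsim_domain_error")
  }
  out |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::mutate(cr_overall = mean(.data$cr)) |>
    dplyr::ungroup() |>
    dplyr::select("cell_type", "epoch", "cr", "cr_overall")
}

.trapz_mean <- function(t, y) {
  if (length(t) < 2) return(y[1])
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) / (t[length(t)] - t[1])
}

#' Timepoint concentration ratio
#'
#' Plain ratio of a retentate concentration to its reference concentration
#' (mean filtrate, or contemporaneous blood), the per-timepoint building
#' block of the in-vivo CR.
#'
#' @param c_ret_t Retentate concentration at the timepoint (cells/uL).
#' @param c_ref Reference concentration (cells/uL), > 0.
#' @return Fold ratio. Vectorised.
#' @export
cr_timepoint <- function(c_ret_t, c_ref) {
  if (any(c_ref <= 0)) abort("Reference concentration must be positive.",
                             class = "cifsim_domain_error")
  c_ret_t / c_ref
}

#' In-vivo collection efficiency ratio
#'
#' The serial-aliquot estimator of the whole-procedure collection
#' efficiency: collected cells summed over retentate aliquots, divided by
#' the cells offered to the device, taken as the mean of the pre- and
#' post-procedure circulating concentrations times the processed volume:
#' `sum(C_ret_t * V_ret_t) / (((C_pre + C_post)/2) * V_proc)`.
#'
#' @param c_ret_t Aliquot concentrations (cells/uL).
#' @param v_ret_t Aliquot volumes (uL), same length.
#' @param c_pre,c_post Circulating concentration at start / end (cells/uL).
#' @param v_proc Total blood volume processed (uL), > 0.
#' @return The efficiency as a fraction (multiply by 100 for percent).
#' @export
ce_invivo_ratio <- function(c_ret_t, v_ret_t, c_pre, c_post, v_proc) {
  if (v_proc <= 0) abort("`v_proc` must be positive.", class = "cifsim_domain_error")
  if (!length(c_ret_t) || length(c_ret_t) != length(v_ret_t)) {
    abort("Need at least one aliquot, with matching volumes.", class = "cifsim_domain_error")
  }
  sum(c_ret_t * v_ret_t) / (((c_pre + c_post) / 2) * v_proc)
}

#' Per-type in-vivo collection efficiency of a simulated run
#'
#' Applies [ce_invivo_ratio()] to every cell type of a
#' [simulate_recirculation()] result.
#'
#' @param run A `cif_recirculation`.
#' @return Tibble `cell_type`, `ce_percent`.
#' @export
collection_efficiency_invivo <- function(run) {
  stopifnot(inherits(run, "cif_recirculation"))
  purrr::map_dfr(unique(run$aliquots$cell_type), function(type) {
    al <- run$aliquots[run$aliquots$cell_type == type, ]
    tibble::tibble(
      cell_type = type,
      ce_percent = 100 * ce_invivo_ratio(al$c_ret, al$v_ret_ul,
                                         run$c_pre[[type]], run$c_post[[type]],
                                         run$v_proc_ul))
  })
}

#' Final counts as a percentage of baseline, and loss ratios
#'
#' `final_percent()` reports `100 * C_post / C_pre` per type.
#' `final_percent_ratios()` normalises the aggregate WBC and the PLT
#' final-percentages by the RBC final-percentage; a ratio below 1 means the
#' numerator type lost proportionally more than RBC (the signature of
#' selective leukocyte removal, as opposed to sampling dilution which moves
#' all types together).
#'
#' @param run A [simulate_recirculation()] result.
#' @return `final_percent()`: tibble `cell_type`, `final_percent`;
#'   `final_percent_ratios()`: tibble `metric`, `value`.
#' @export
final_percent <- function(run) {
  stopifnot(inherits(run, "cif_recirculation"))
  if (any(run$c_pre <= 0)) abort("Baseline concentrations must be positive.",
                                 class = "cifsim_domain_error")
  tibble::tibble(cell_type = names(run$c_pre),
                 final_percent = 100 * unname(run$c_post / run$c_pre))
}

#' @rdname final_percent
#' @export
final_percent_ratios <- function(run) {
  fp <- final_percent(run)
  wbc_types <- intersect(c("PMN", "LYM", "MON", "EOS", "BLAST"), fp$cell_type)
  agg <- function(types) {
    pre <- sum(run$c_pre[types]); post <- sum(run$c_post[types])
    100 * post / pre
  }
  rbc <- fp$final_percent[fp$cell_type == "RBC"]
  if (!length(rbc) || !length(wbc_types)) {
    abort("Run must include RBC and at least one WBC subtype.",
          class = "cifsim_domain_error")
  }
  wbc <- agg(wbc_types)
  plt <- fp$final_percent[fp$cell_type == "PLT"]
  tibble::tibble(
    metric = c("wbc_final_percent", "rbc_final_percent", "plt_final_percent",
               "wbc_rbc_ratio", "plt_rbc_ratio"),
    value = c(wbc, rbc, if (length(plt)) plt else NA_real_,
              wbc / rbc, if (length(plt)) plt / rbc else NA_real_)
  )
}
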