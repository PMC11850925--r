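# Size-selective transport through a CIF element: per-gap capture
# probabilities, deterministic retention, a Monte-Carlo oracle, and the
# standard apheresis CE/CR statistics.

# capture probability core, vectorised over diameter for one gap geometry.
# f: per-side fraction; w_r: retentate width; w_l: lamina width (all um).
.capture_prob <- function(diameter, f, w_r, w_l,
                          steric_model = "flux", q = 2) {
  r <- pmax(diameter, 0) / 2
  eff <- pmax(w_l - r, 0)
  switch(steric_model,
    flux = f * flux_fraction(eff / w_r) / flux_fraction(w_l / w_r),
    hard = f * as.numeric(r < w_l),
    power = f * (eff / w_l)^q
  )
}

#' Per-gap capture probability of a cell
#'
#' Probability that a cell of the given diameter is pulled through one side
#' of gap `gap` of a design. A point particle follows its streamline, so the
#' probability equals the per-side flow fraction `f_gap(i)`; a cell whose
#' radius reaches the lamina width is sterically excluded (probability 0).
#' Between those limits the default `"flux"` model weights the fraction by
#' the share of the lamina flux accessible to the cell centre, which must
#' stay a radius away from the wall:
#' `p = f_gap * F((w_l - r)/w_r) / F(w_l/w_r)` with `F` the cumulative flux
#' fraction of the velocity profile. `"hard"` is a step cutoff at `r = w_l`;
#' `"power"` uses `((w_l - r)/w_l)^q`.
#'
#' @param diameter Cell diameter (um), vectorised. Degenerate values clamp to
#'   the stated limits rather than erroring.
#' @param gap 0-based gap index.
#' @param design A [design_element()] result.
#' @param steric_model `"flux"` (default), `"hard"`, or `"power"`.
#' @param q Exponent for the `"power"` model.
#' @return Capture probability in `[0, f_gap(gap)]`, non-increasing and
#'   continuous in `diameter`.
#' @export
capture_probability <- function(diameter, gap, design,
                                steric_model = c("flux", "hard", "power"),
                                q = 2) {
  steric_model <- match.arg(steric_model)
  stopifnot(inherits(design, "cif_design"))
  if (gap < 0 || gap >= design$n_gaps) {
    abort(sprintf("`gap` must be in [0, %d).", design$n_gaps), class = "cifsim_domain_error")
  }
  row <- design$gaps[design$gaps$gap == gap, ]
  .capture_prob(diameter, row$f_gap, row$w_r, design$w_l_target, steric_model, q)
}

# unique gap geometries with multiplicities (the floor phase collapses to one
# row), so retention products cost O(#unique) not O(n_gaps)
.gap_groups <- function(design) {
  design$gaps |>
    dplyr::count(.data$f_gap, .data$w_r, name = "n_rep")
}

#' Retention probability across a whole element
#'
#' Probability that a cell of the given diameter survives all gap pairs in
#' the central retentate channel, under the well-mixed assumption (its radial
#' position is resampled from the flux-weighted distribution between gaps, so
#' per-gap captures are independent):
#' `retention(d) = prod_i (1 - 2 p_i(d))`.
#'
#' @inheritParams capture_probability
#' @return Retention probability in `[0, 1]`, non-decreasing in diameter.
#' @export
retention_probability <- function(diameter, design,
                                  steric_model = c("flux", "hard", "power"),
                                  q = 2) {
  steric_model <- match.arg(steric_model)
  stopifnot(inherits(design, "cif_design"))
  if (design$n_gaps == 0L) return(rep(1, length(diameter)))
  grp <- .gap_groups(design)
  log_ret <- rep(0, length(diameter))
  for (k in seq_len(nrow(grp))) {
    p <- .capture_prob(diameter, grp$f_gap[k], grp$w_r[k], design$w_l_target,
                       steric_model, q)
    log_ret <- log_ret + grp$n_rep[k] * log1p(-2 * p)
  }
  exp(log_ret)
}

#' Predict a single-pass separation
#'
#' Partitions every population of a blood sample between the retentate and
#' filtrate outputs of a CIF element (or a parallel array of identical
#' elements — the deterministic prediction is flow-rate- and
#' multiplicity-agnostic). Two transport paths are available:
#'
#' * `"deterministic"`: per-type collection efficiency is the retention
#'   probability integrated over the type's diameter distribution on a
#'   midpoint-quantile grid.
#' * `"monte-carlo"`: individual cells are drawn from the diameter
#'   distributions and walked gap by gap; each survivor faces an independent
#'   capture draw at the next gap (`remix = TRUE`, the default). With
#'   `remix = FALSE` each cell instead keeps a flux-coordinate position that
#'   is renormalised after every extraction, retaining wall depletion.
#'
#' Output volumes split the input by the design's realised flow ratio
#' (`V_ret = V_in/(1+FR)`), and concentrations follow from exact cell and
#' volume conservation.
#'
#' @param sample A [blood_sample()].
#' @param design A [design_element()] result.
#' @param mode `"deterministic"` or `"monte-carlo"`.
#' @param n_cells Total Monte-Carlo cells, allocated to populations in
#'   proportion to concentration (at least 10 per population).
#' @param seed Seed for the Monte-Carlo path (required there; recorded in the
#'   result).
#' @param n_quantiles Diameter-grid size for the deterministic integral.
#' @param remix Well-mixed re-sampling of radial position between gaps
#'   (Monte-Carlo path only).
#' @inheritParams capture_probability
#' @return A `cif_separation` object; [tidy()] gives the per-type table
#'   (`cell_type`, `C_in`, `C_ret`, `C_fil`, `ce_percent`, `cr_fold`),
#'   [glance()] the volumes and realised flow ratio.
#' @examples
#' d <- design_element(1e-3, n_gaps = 50)
#' s <- make_blood(blood_spec("human", seed = 7))
#' tidy(separate_sample(s, d))
#' @export
separate_sample <- function(sample, design,
                            mode = c("deterministic", "monte-carlo"),
                            n_cells = 1e5, seed = NULL,
                            n_quantiles = 201,
                            steric_model = c("flux", "hard", "power"),
                            q = 2, remix = TRUE) {
  mode <- match.arg(mode)
  steric_model <- match.arg(steric_model)
  stopifnot(inherits(sample, "blood_sample"), inherits(design, "cif_design"))

  v_in <- sample_volume(sample)
  fr <- design$flow_ratio
  v_ret <- v_in / (1 + fr)
  v_fil <- v_in - v_ret

  if (mode == "deterministic") {
    per_type <- purrr::pmap_dfr(
      sample[c("cell_type", "concentration", "diameter_mean", "diameter_cv")],
      function(cell_type, concentration, diameter_mean, diameter_cv) {
        d <- diameter_quantiles(diameter_mean, diameter_cv, n_quantiles)
        tibble::tibble(cell_type = cell_type, C_in = concentration,
                       retained = mean(retention_probability(d, design, steric_model, q)))
      })
    mc <- NULL
  } else {
    if (is.null(seed)) abort("`seed` is required for the Monte-Carlo path.",
                             class = "cifsim_domain_error")
    if (n_cells < 1) abort("`n_cells` must be >= 1.", class = "cifsim_domain_error")
    mc <- withr::with_seed(seed, .transport_mc(sample, design, n_cells,
                                               steric_model, q, remix))
    per_type <- mc |>
      dplyr::group_by(.data$cell_type) |>
      dplyr::summarise(n_sim = dplyr::n(), retained = mean(.data$retained)) |>
      dplyr::left_join(
        tibble::tibble(cell_type = sample$cell_type, C_in = sample$concentration),
        by = "cell_type") |>
      dplyr::select("cell_type", "C_in", "retained", "n_sim")
  }

  per_type <- per_type |>
    dplyr::mutate(
      C_ret = .data$C_in * .data$retained * v_in / v_ret,
      C_fil = .data$C_in * (1 - .data$retained) * v_in / v_fil,
      ce_percent = 100 * .data$retained,
      cr_fold = .data$C_ret / .data$C_in
    ) |>
    dplyr::relocate("cell_type", "C_in", "C_ret", "C_fil", "ce_percent", "cr_fold")

  structure(
    list(per_type = per_type, v_in = v_in, v_ret = v_ret, v_fil = v_fil,
         flow_ratio = fr, mode = mode, n_cells = if (mode == "monte-carlo") n_cells else NA,
         seed = seed, steric_model = steric_model, design = glance(design),
         cell_log = mc),
    class = "cif_separation"
  )
}

# Monte-Carlo transport. Cells are allocated across populations by
# concentration; sterically immune cells (r >= w_l) are retained without
# gap-by-gap simulation. Returns one row per simulated cell.
.transport_mc <- function(sample, design, n_cells, steric_model, q, remix) {
  conc <- sample$concentration
  n_per <- pmax(10L, round(n_cells * conc / sum(conc)))
  n_per[conc == 0] <- 0L

  cells <- purrr::pmap_dfr(
    list(sample$cell_type, n_per, sample$diameter_mean, sample$diameter_cv),
    function(type, n, m, cv) {
      if (n == 0L) return(NULL)
      tibble::tibble(cell_type = type, diameter = diameter_draws(n, m, cv))
    })
  n_tot <- nrow(cells)
  retained <- rep(TRUE, n_tot)
  exit_gap <- rep(NA_integer_, n_tot)
  if (design$n_gaps == 0L) {
    return(dplyr::mutate(cells, retained = retained, exit_gap = exit_gap))
  }

  vulnerable <- cells$diameter / 2 < design$w_l_target
  alive <- which(vulnerable)
  gaps <- design$gaps
  if (remix) {
    for (i in seq_len(nrow(gaps))) {
      if (!length(alive)) break
      p <- .capture_prob(cells$diameter[alive], gaps$f_gap[i], gaps$w_r[i],
                         design$w_l_target, steric_model, q)
      hit <- runif(length(alive)) < 2 * p
      if (any(hit)) {
        out <- alive[hit]
        retained[out] <- FALSE
        exit_gap[out] <- gaps$gap[i]
        alive <- alive[!hit]
      }
    }
  } else {
    # flux-coordinate model: s is the cell's flux position within its near
    # half-channel; extraction removes the wall-adjacent flux slab of share
    # f_gap, sterically truncated at the cell's accessible depth
    s <- runif(length(alive), 0, 0.5)
    for (i in seq_len(nrow(gaps))) {
      if (!length(alive)) break
      f <- gaps$f_gap[i]
      cap <- pmin(f, .capture_prob(cells$diameter[alive], gaps$f_gap[i],
                                   gaps$w_r[i], design$w_l_target,
                                   steric_model, q))
      hit <- s < cap
      if (any(hit)) {
        out <- alive[hit]
        retained[out] <- FALSE
        exit_gap[out] <- gaps$gap[i]
        alive <- alive[!hit]
        s <- s[!hit]
      }
      # survivors in the extracted slab are pressed back to the wall
      s <- pmin(pmax(s - f, 0) / (1 - 2 * f), 0.5)
    }
  }
  dplyr::mutate(cells, retained = retained, exit_gap = exit_gap)
}

#' @export
print.cif_separation <- function(x, ...) {
  cat(sprintf("<cif_separation> %s, FR = %.2f, V_ret/V_fil = %.1f/%.1f uL\n",
              x$mode, x$flow_ratio, x$v_ret, x$v_fil))
  print(x$per_type)
  invisible(x)
}

#' @rdname separate_sample
#' @param x,object A `cif_separation`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cif_separation <- function(x, ...) x$per_type

#' @rdname separate_sample
#' @exportS3Method generics::glance
glance.cif_separation <- function(x, ...) {
  tibble::tibble(mode = x$mode, v_in = x$v_in, v_ret = x$v_ret,
                 v_fil = x$v_fil, flow_ratio = x$flow_ratio,
                 n_cells = x$n_cells,
                 seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' @rdname separate_sample
#' @exportS3Method ggplot2::autoplot
autoplot.cif_separation <- function(object, ...) {
  ggplot2::ggplot(object$per_type,
                  ggplot2::aes(x = stats::reorder(.data$cell_type, .data$ce_percent),
                               y = .data$ce_percent)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::labs(x = NULL, y = "collection efficiency (%)",
                  title = sprintf("Single-pass separation (%s, FR = %.1f)",
                                  object$mode, object$flow_ratio)) +
    ggplot2::theme_minimal()
}

#' In-vitro collection efficiency from output CBCs
#'
#' The standard volume-corrected estimator used when input, retentate and
#' filtrate concentrations are measured after a single pass:
#' `CE = C_ret / (C_fil * V_fil / V_ret + C_ret) * 100`.
#'
#' @param c_ret,c_fil Retentate / filtrate concentrations (cells/uL), >= 0.
#' @param v_ret,v_fil Retentate / filtrate volumes (uL); `v_ret` > 0.
#' @return Collection efficiency in percent, in `[0, 100]`. Vectorised.
#' @export
collection_efficiency <- function(c_ret, c_fil, v_ret, v_fil) {
  if (any(v_ret <= 0)) abort("`v_ret` must be positive.", class = "cifsim_domain_error")
  if (any(v_fil < 0)) abort("`v_fil` must be >= 0.", class = "cifsim_domain_error")
  if (any(c_ret < 0) || any(c_fil < 0)) {
    abort("Concentrations must be >= 0.", class = "cifsim_domain_error")
  }
  if (any(c_ret == 0 & c_fil == 0)) {
    abort("CE is undefined when both output concentrations are zero.",
          class = "cifsim_undefined_ce")
  }
  c_ret / (c_fil * v_fil / v_ret + c_ret) * 100
}

#' Spiked-blast collection efficiency from hemocytometer counts
#'
#' Used when only the input and retentate concentrations of a spiked
#' population (e.g. fluorescently labelled MV-4-11 blasts) are counted:
#' `CE = MV411_ret * V_ret / (MV411_input * (V_ret + V_fil)) * 100`.
#' Measurement noise can push the estimate above 100%; such values are
#' flagged with a warning but never clamped.
#'
#' @param blast_ret Blast concentration in the retentate (cells/uL).
#' @param blast_input Blast concentration in the input sample (cells/uL), > 0.
#' @param v_ret,v_fil Output volumes (uL), > 0.
#' @return Collection efficiency in percent. Vectorised.
#' @export
blast_collection_efficiency <- function(blast_ret, blast_input, v_ret, v_fil) {
  if (any(blast_input <= 0)) abort("`blast_input` must be positive.", class = "cifsim_domain_error")
  if (any(v_ret <= 0) || any(v_fil <= 0)) abort("Volumes must be positive.", class = "cifsim_domain_error")
  if (any(blast_ret < 0)) abort("`blast_ret` must be >= 0.", class = "cifsim_domain_error")
  ce <- blast_ret * v_ret / (blast_input * (v_ret + v_fil)) * 100
  if (any(ce > 100)) {
    warn(sprintf("%d CE value(s) exceed 100%% (measurement noise); not clamped.",
                 sum(ce > 100)))
  }
  ce
}

#' Concentration ratio
#'
#' Retentate concentration over input concentration. For a single pass the
#' flow-through identity `CR = (CE/100) * (1 + FR)` links it to the
#' collection efficiency and flow ratio.
#'
#' @param c_ret Retentate concentration (cells/uL).
#' @param c_in Input concentration (cells/uL), > 0.
#' @return Fold concentration. Vectorised.
#' @export
concentration_ratio <- function(c_ret, c_in) {
  if (any(c_in <= 0)) abort("`c_in` must be positive.", class = "cifsim_domain_error")
  c_ret / c_in
}
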