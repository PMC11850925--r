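#' Generate a controlled incremental filtration (CIF) element design
#'
#' A CIF element is a central retentate channel flanked by two symmetric
#' filtrate channels, separated by arrays of filtration gaps. At gap `i` a
#' fraction `f_gap(i)` of the retentate flow `Q_r(i)` leaves through *each*
#' side, so `Q_r(i+1) = Q_r(i) * (1 - 2 f_gap(i))`. The design loop fixes the
#' extracted lamina width `w_l` from the starting pair
#' (`f_gap_star`, `w_r_star`) and then recalculates `f_gap(i)` and the channel
#' widths gap by gap so the lamina width — and therefore the cell-size
#' cutoff — stays constant along the element.
#'
#' With the default `"constant-velocity"` width rule the retentate width
#' shrinks in proportion to its flow (`w_r(i) ~ Q_r(i)`), keeping the mean
#' retentate velocity constant, until it reaches `min_width`; from there the
#' width is held fixed (so `f_gap` is constant for the remaining gaps) when
#' `on_floor = "clamp"`, or the design is declared infeasible when
#' `on_floor = "error"`. The `"fixed-width"` rule keeps `w_r` at `w_r_star`
#' throughout, which makes the whole schedule constant-`f` — the classical
#' reference geometry.
#'
#' @param f_gap_star Initial per-side filtration fraction, in `(0, 0.05]`.
#'   Typical values are around `1e-3`.
#' @param w_r_star Initial retentate channel width (um). Default 230, which
#'   places the size cutoff of an `f_gap_star = 1e-3` element (~8.5 um)
#'   between lymphocyte and monocyte diameters.
#' @param gap_width Filtration gap opening (um). Default 20.
#' @param depth Channel depth (um). Default 150. Carried as metadata; the
#'   lamina model is depth-averaged.
#' @param n_gaps Number of gap pairs. Give either `n_gaps` or `target_fr`.
#' @param target_fr Target flow ratio (filtrate volume / retentate volume).
#'   The element gets the smallest gap count whose realised FR meets it.
#' @param q_in Element inlet flow (uL/min). Default 150 (1.2 mL/min across an
#'   eight-element device). The schedule scales linearly with `q_in`.
#' @param width_rule `"constant-velocity"` (default) or `"fixed-width"`.
#' @param min_width Minimum manufacturable retentate width (um). Default
#'   `2 * gap_width` so the posts between gaps remain separable.
#' @param on_floor What to do when the width rule would drive `w_r` below
#'   `min_width`: `"clamp"` (hold the width at the floor and continue) or
#'   `"error"` (infeasible-design error naming the failing gap).
#' @param profile Velocity profile passed to [lamina_width_from_fraction()].
#' @return An object of class `cif_design`: the design header plus a
#'   gap-indexed tibble (`gap` 0-based, `f_gap`, `w_r`, `w_f`, `Q_r`, `Q_gap`,
#'   `Q_fil_cum`, `w_l`). Retrieve the table with [tidy()], the header with
#'   [glance()].
#' @examples
#' d2 <- design_element(f_gap_star = 1e-3, target_fr = 20)
#' glance(d2)
#' @export
design_element <- function(f_gap_star,
                           w_r_star = 230,
                           gap_width = 20,
                           depth = 150,
                           n_gaps = NULL,
                           target_fr = NULL,
                           q_in = 150,
                           width_rule = c("constant-velocity", "fixed-width"),
                           min_width = 2 * gap_width,
                           on_floor = c("clamp", "error"),
                           profile = c("parabolic", "plug")) {
  width_rule <- match.arg(width_rule)
  on_floor <- match.arg(on_floor)
  profile <- match.arg(profile)
  if (!is.numeric(f_gap_star) || length(f_gap_star) != 1L ||
      f_gap_star <= 0 || f_gap_star > 0.05) {
    abort("`f_gap_star` must lie in (0, 0.05].", class = "cifsim_domain_error")
  }
  if (w_r_star <= 0 || gap_width <= 0 || depth <= 0 || q_in <= 0) {
    abort("Geometry and flow parameters must be positive.", class = "cifsim_domain_error")
  }
  if (is.null(n_gaps) == is.null(target_fr)) {
    abort("Give exactly one of `n_gaps` or `target_fr`.", class = "cifsim_domain_error")
  }
  if (!is.null(target_fr) && target_fr <= 0) {
    abort("`target_fr` must be positive.", class = "cifsim_domain_error")
  }
  if (!is.null(n_gaps) && (n_gaps < 0 || n_gaps != round(n_gaps))) {
    abort("`n_gaps` must be a non-negative integer.", class = "cifsim_domain_error")
  }

  w_l <- lamina_width_from_fraction(f_gap_star, w_r_star, profile)
  if (w_r_star <= 2 * w_l) {
    abort("`w_r_star` must exceed twice the lamina width implied by `f_gap_star`.",
          class = "cifsim_domain_error")
  }

  max_gaps <- if (!is.null(n_gaps)) n_gaps else 200000L
  f_seq <- numeric(0); wr_seq <- numeric(0); wf_seq <- numeric(0)
  qr_seq <- numeric(0); qg_seq <- numeric(0); qf_seq <- numeric(0)

  w_r_cur <- w_r_star
  q_r_cur <- q_in
  q_fil_cum <- 0
  ret_frac <- 1
  i <- 0L
  while (i < max_gaps) {
    if (w_l >= w_r_cur / 2) {
      abort(sprintf(
        "Infeasible design: lamina width %.3g um no longer fits in the retentate channel (w_r = %.3g um) at gap %d.",
        w_l, w_r_cur, i), class = "cifsim_infeasible_design")
    }
    f_i <- fraction_from_lamina_width(w_l, w_r_cur, profile)
    q_gap_i <- f_i * q_r_cur
    q_r_next <- q_r_cur * (1 - 2 * f_i)
    q_fil_cum <- q_fil_cum + 2 * q_gap_i
    ret_frac <- ret_frac * (1 - 2 * f_i)

    f_seq[i + 1L] <- f_i
    wr_seq[i + 1L] <- w_r_cur
    qr_seq[i + 1L] <- q_r_next
    qg_seq[i + 1L] <- q_gap_i
    qf_seq[i + 1L] <- q_fil_cum
    # per-side filtrate width sized for constant mean velocity, floored at the gap width
    wf_seq[i + 1L] <- max(gap_width, w_r_star * (q_fil_cum / 2) / q_in)

    if (width_rule == "constant-velocity") {
      w_r_next <- w_r_cur * q_r_next / q_r_cur
      if (w_r_next < min_width) {
        if (on_floor == "error") {
          abort(sprintf(
            "Infeasible design: retentate width would fall below the %.3g um minimum at gap %d before reaching the target.",
            min_width, i + 1L), class = "cifsim_infeasible_design")
        }
        w_r_next <- min_width
      }
      w_r_cur <- w_r_next
    }
    q_r_cur <- q_r_next
    i <- i + 1L
    if (!is.null(target_fr) && (1 - ret_frac) / ret_frac >= target_fr) break
  }
  if (!is.null(target_fr) && (1 - ret_frac) / ret_frac < target_fr) {
    abort(sprintf("Target flow ratio %.3g not reached within %d gaps.", target_fr, max_gaps),
          class = "cifsim_infeasible_design")
  }

  gaps <- tibble::tibble(
    gap = seq_len(i) - 1L,
    f_gap = f_seq,
    w_r = wr_seq,
    w_f = wf_seq,
    Q_r = qr_seq,
    Q_gap = qg_seq,
    Q_fil_cum = qf_seq,
    w_l = vapply(seq_len(i), function(k) {
      lamina_width_from_fraction(f_seq[k], wr_seq[k], profile)
    }, numeric(1))
  )
  fr <- if (i == 0L) 0 else (1 - ret_frac) / ret_frac

  structure(
    list(
      f_gap_star = f_gap_star, w_r_star = w_r_star, gap_width = gap_width,
      depth = depth, n_gaps = i, q_in = q_in, w_l_target = w_l,
      flow_ratio = fr, retentate_fraction = ret_frac,
      width_rule = width_rule, min_width = min_width, profile = profile,
      gaps = gaps
    ),
    class = "cif_design"
  )
}

#' @export
print.cif_design <- function(x, ...) {
  cat("<cif_design>\n")
  cat(sprintf("  f_gap* = %.3g, w_r* = %g um, gap = %g um, depth = %g um\n",
              x$f_gap_star, x$w_r_star, x$gap_width, x$depth))
  cat(sprintf("  %d gap pairs, lamina width %.3f um (size cutoff ~%.1f um)\n",
              x$n_gaps, x$w_l_target, 2 * x$w_l_target))
  cat(sprintf("  flow ratio %.2f (retentate keeps %.2f%% of inlet flow)\n",
              x$flow_ratio, 100 * x$retentate_fraction))
  invisible(x)
}

#' @rdname design_element
#' @param x,object A `cif_design`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cif_design <- function(x, ...) x$gaps

#' @rdname design_element
#' @exportS3Method generics::glance
glance.cif_design <- function(x, ...) {
  tibble::tibble(
    f_gap_star = x$f_gap_star, w_r_star = x$w_r_star,
    gap_width = x$gap_width, depth = x$depth, n_gaps = x$n_gaps,
    q_in = x$q_in, w_l_target = x$w_l_target, flow_ratio = x$flow_ratio,
    retentate_fraction = x$retentate_fraction,
    width_rule = x$width_rule, profile = x$profile
  )
}

#' Theoretical small-cell loss and concentration limits of a flow ratio
#'
#' The flow ratio FR (collected filtrate volume over retentate volume) caps
#' what a CIF element can do regardless of geometry: a fraction
#' `1/(1 + FR)` of the fluid — and with it the cells below the size cutoff —
#' ends up in the retentate (the "loss" of small cells from the filtrate
#' product), and cells above the cutoff can be concentrated at most
#' `(1 + FR)`-fold.
#'
#' @param fr Flow ratio(s), non-negative. Vectorised.
#' @return A tibble with columns `flow_ratio`, `small_cell_loss_percent`
#'   (`100/(1+FR)`) and `max_concentration_fold` (`1+FR`).
#' @examples
#' flow_ratio_theory(c(20, 21.1, 22.6))
#' @export
flow_ratio_theory <- function(fr) {
  if (any(!is.finite(fr)) || any(fr < 0)) {
    abort("`fr` must be non-negative.", class = "cifsim_domain_error")
  }
  tibble::tibble(
    flow_ratio = fr,
    small_cell_loss_percent = 100 / (1 + fr),
    max_concentration_fold = 1 + fr
  )
}

#' Write / read a CIF design as a CSV + JSON pair
#'
#' The gap table goes to CSV (one row per gap: `gap`, `f_gap`, `w_r`, `w_f`,
#' `Q_r`, `Q_gap`, `Q_fil_cum`, `w_l`); the design header (`f_gap_star`,
#' `w_r_star`, `gap_width`, `depth`, `n_gaps`, `flow_ratio`, `w_l_target`,
#' ...) goes to JSON next to it.
#'
#' @param design A `cif_design`.
#' @param csv_path Path for the gap table CSV.
#' @param json_path Path for the JSON header; defaults to `csv_path` with a
#'   `.json` extension.
#' @return `write_cif_design()` returns the paths invisibly;
#'   `read_cif_design()` returns the reconstructed `cif_design`.
#' @export
write_cif_design <- function(design, csv_path,
                             json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(design, "cif_design"))
  readr::write_csv(design$gaps, csv_path)
  header <- design[setdiff(names(design), "gaps")]
  jsonlite::write_json(header, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}

#' @rdname write_cif_design
#' @export
read_cif_design <- function(csv_path,
                            json_path = sub("\\.csv$", ".json", csv_path)) {
  header <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  gaps <- readr::read_csv(csv_path, show_col_types = FALSE)
  gaps$gap <- as.integer(gaps$gap)
  out <- c(header, list(gaps = tibble::as_tibble(gaps)))
  out$n_gaps <- as.integer(out$n_gaps)
  structure(out, class = "cif_design")
}

#' @rdname design_element
#' @exportS3Method ggplot2::autoplot
autoplot.cif_design <- function(object, ...) {
  long <- object$gaps |>
    dplyr::select("gap", "f_gap", "w_r", "Q_r") |>
    tidyr::pivot_longer(-"gap", names_to = "quantity", values_to = "value") |>
    dplyr::mutate(quantity = factor(.data$quantity,
      levels = c("f_gap", "w_r", "Q_r"),
      labels = c("per-side filtration fraction",
                 "retentate width (um)",
                 "retentate flow (uL/min)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gap, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "gap index", y = NULL,
                  title = sprintf("CIF element schedule (f_gap* = %.3g, FR = %.1f)",
                                  object$f_gap_star, object$flow_ratio)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
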