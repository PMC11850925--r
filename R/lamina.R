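#' Cumulative flux fraction of a wall-adjacent lamina
#'
#' For laminar flow in a channel of width `w`, the fluid lamina of width `d`
#' adjacent to one wall carries a fraction of the total volumetric flow that
#' depends on the velocity profile across the width. For the depth-averaged
#' plane-Poiseuille (parabolic) profile this fraction has the closed form
#' \eqn{F(x) = 3x^2 - 2x^3} with \eqn{x = d/w}.
#'
#' @param x Normalised lamina width `d/w`, in `[0, 1]`.
#' @param profile Velocity profile across the channel width. `"parabolic"`
#'   (default) is the depth-averaged plane-Poiseuille profile; `"plug"` is a
#'   flat profile (fraction equals the width fraction), useful as a degenerate
#'   reference.
#' @return Fraction of the total channel flow carried by the lamina.
#' @keywords internal
flux_fraction <- function(x, profile = c("parabolic", "plug")) {
  profile <- match.arg(profile)
  switch(profile,
    parabolic = 3 * x^2 - 2 * x^3,
    plug = x
  )
}

#' Width of the fluid lamina extracted by a given flow fraction
#'
#' At each filtration gap a fraction `f` of the retentate channel flow is
#' pulled sideways through the gap. The streamlines feeding the gap occupy a
#' wall-adjacent lamina whose width `w_l` sets the cell-size cutoff: cells
#' whose centres ride inside the lamina follow the extracted fluid, larger
#' cells stay in the central channel. This function converts the per-side flow
#' fraction into the lamina width under a chosen depth-averaged velocity
#' profile.
#'
#' @param f Per-side flow fraction, in `[0, 0.5]`. Vectorised.
#' @param w Channel width in micrometres (scalar, positive).
#' @inheritParams flux_fraction
#' @return Lamina width in micrometres, in `[0, w/2]`; strictly increasing
#'   in `f`.
#' @seealso [fraction_from_lamina_width()] for the exact inverse.
#' @examples
#' lamina_width_from_fraction(1e-3, w = 100) # ~1.84 um
#' @export
lamina_width_from_fraction <- function(f, w, profile = c("parabolic", "plug")) {
  profile <- match.arg(profile)
  if (!is.numeric(w) || length(w) != 1L || w <= 0) {
    abort("`w` must be a single positive channel width (um).", class = "cifsim_domain_error")
  }
  if (any(!is.finite(f)) || any(f < 0) || any(f > 0.5)) {
    abort("`f` must lie in [0, 0.5] (per-side flow fraction).", class = "cifsim_domain_error")
  }
  if (profile == "plug") {
    return(f * w)
  }
  vapply(f, function(fi) {
    if (fi == 0) return(0)
    if (fi == 0.5) return(w / 2)
    x <- uniroot(function(x) flux_fraction(x) - fi,
                 interval = c(0, 0.5), tol = .Machine$double.eps^0.75)$root
    x * w
  }, numeric(1))
}

#' Flow fraction carried by a lamina of given width
#'
#' Exact inverse of [lamina_width_from_fraction()]: the fraction of the
#' channel flow carried by a wall-adjacent lamina of width `d` in a channel of
#' width `w`. Closed-form for both supported profiles, so the round-trip with
#' [lamina_width_from_fraction()] is exact to solver tolerance.
#'
#' @param d Lamina width in micrometres, in `[0, w/2]`. Vectorised.
#' @inheritParams lamina_width_from_fraction
#' @return Per-side flow fraction in `[0, 0.5]`.
#' @export
fraction_from_lamina_width <- function(d, w, profile = c("parabolic", "plug")) {
  profile <- match.arg(profile)
  if (!is.numeric(w) || length(w) != 1L || w <= 0) {
    abort("`w` must be a single positive channel width (um).", class = "cifsim_domain_error")
  }
  if (any(!is.finite(d)) || any(d < 0) || any(d > w / 2 + 1e-12 * w)) {
    abort("`d` must lie in [0, w/2].", class = "cifsim_domain_error")
  }
  flux_fraction(pmin(d / w, 0.5), profile)
}
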