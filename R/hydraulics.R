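# Lumped-element hydraulics: rectangular-duct resistances and a linear
# Kirchhoff solver for multiplexed devices and pumpless arteriovenous
# circuits.

# unit conversion: Pa.s/m^3 -> mmHg per (uL/min)
.SI_TO_MMHG_UL_MIN <- (1 / 133.322) * (1e-9 / 60)

#' Laminar resistance of a rectangular microchannel
#'
#' Hydraulic resistance of a straight duct of rectangular cross-section
#' (width `w`, height `h`, length `L`) in fully developed laminar flow,
#' from the classical odd-term series
#' `R = 12 mu L / (a b^3) / (1 - 192 b/(pi^5 a) * sum tanh(n pi a / (2b))/n^5)`
#' with `b = min(w, h)`, `a = max(w, h)` — symmetric in `w` and `h` by
#' construction and linear in `L` and viscosity. Five odd terms are kept;
#' the series converges as `1/n^5` so the truncation error is far below
#' fabrication tolerances.
#'
#' @param w,h Cross-section width and height (um), > 0.
#' @param L Channel length (mm), > 0.
#' @param viscosity Dynamic viscosity (mPa s); default 4, a constant-viscosity
#'   Newtonian stand-in for undiluted whole blood.
#' @param units `"mmHg_min_uL"` (default; mmHg per uL/min, convenient at
#'   physiologic boundaries) or `"SI"` (Pa s m^-3).
#' @return Hydraulic resistance. Vectorised over all geometry arguments.
#' @export
rect_channel_resistance <- function(w, h, L, viscosity = 4,
                                    units = c("mmHg_min_uL", "SI")) {
  units <- match.arg(units)
  if (any(w <= 0) || any(h <= 0) || any(L <= 0) || any(viscosity <= 0)) {
    abort("`w`, `h`, `L` and `viscosity` must be positive.", class = "cifsim_domain_error")
  }
  b <- pmin(w, h) * 1e-6   # m
  a <- pmax(w, h) * 1e-6
  len <- L * 1e-3          # m
  mu <- viscosity * 1e-3   # Pa s
  n <- c(1, 3, 5, 7, 9)
  series <- vapply(seq_along(b), function(i) {
    sum(tanh(n * pi * a[i] / (2 * b[i])) / n^5)
  }, numeric(1))
  r_si <- 12 * mu * len / (a * b^3 * (1 - 192 * b / (pi^5 * a) * series))
  if (units == "SI") r_si else r_si * .SI_TO_MMHG_UL_MIN
}

#' Build a lumped hydraulic network
#'
#' Nodes are junctions; an `NA` pressure marks an interior (free) node,
#' a number fixes the boundary pressure there (e.g. arterial and venous
#' sides, in mmHg). Edges are channels carrying either a positive
#' `resistance` (same pressure/flow units as the nodes) or a prescribed
#' `flow` (a fixed-flow element such as a withdrawal pump), never both.
#'
#' @param nodes Data frame with columns `node` (name) and `pressure`.
#' @param edges Data frame with columns `from`, `to`, and `resistance`
#'   and/or `flow` (use `NA` for the one that does not apply).
#' @return A `hydraulic_network` object.
#' @seealso [solve_network()]
#' @export
hydraulic_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (!all(c("node", "pressure") %in% names(nodes))) {
    abort("`nodes` needs columns `node`, `pressure`.", class = "cifsim_validation_error")
  }
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` needs columns `from`, `to`.", class = "cifsim_validation_error")
  }
  if (!"resistance" %in% names(edges)) edges$resistance <- NA_real_
  if (!"flow" %in% names(edges)) edges$flow <- NA_real_
  if (anyDuplicated(nodes$node)) {
    abort("Node names must be unique.", class = "cifsim_validation_error")
  }
  if (!all(c(edges$from, edges$to) %in% nodes$node)) {
    abort("Every edge endpoint must be a declared node.", class = "cifsim_validation_error")
  }
  fixed_flow <- !is.na(edges$flow)
  if (any(!fixed_flow & (is.na(edges$resistance) | edges$resistance <= 0))) {
    abort("Every resistive edge needs a strictly positive `resistance`.",
          class = "cifsim_validation_error")
  }
  if (any(fixed_flow & !is.na(edges$resistance))) {
    abort("An edge is either resistive or fixed-flow, not both.",
          class = "cifsim_validation_error")
  }
  if (!any(!is.na(nodes$pressure))) {
    abort("At least one node needs a fixed pressure.", class = "cifsim_validation_error")
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE,
                                     vertices = nodes$node)
  if (igraph::components(g)$no != 1L) {
    abort("Network is disconnected.", class = "cifsim_network_error")
  }
  structure(list(nodes = nodes, edges = edges), class = "hydraulic_network")
}

#' Solve a hydraulic network
#'
#' Kirchhoff current balance at every free node with Ohm-analogue edges
#' (`Q = dP / R`) yields a linear system in the unknown node pressures;
#' fixed-flow edges enter as source terms. The laminar solution is unique
#' for a connected network with at least one fixed-pressure node.
#'
#' @param net A [hydraulic_network()].
#' @return A list with tibbles `nodes` (`node`, `pressure`) and `edges`
#'   (`from`, `to`, `resistance`, `flow`, positive from `from` to `to`).
#' @export
solve_network <- function(net) {
  stopifnot(inherits(net, "hydraulic_network"))
  nodes <- net$nodes
  edges <- net$edges
  free <- which(is.na(nodes$pressure))
  p <- setNames(nodes$pressure, nodes$node)

  if (length(free)) {
    idx <- setNames(seq_along(free), nodes$node[free])
    A <- matrix(0, length(free), length(free))
    b <- numeric(length(free))
    for (e in seq_len(nrow(edges))) {
      u <- edges$from[e]; v <- edges$to[e]
      if (!is.na(edges$flow[e])) {
        q <- edges$flow[e]
        if (u %in% names(idx)) b[idx[[u]]] <- b[idx[[u]]] - q
        if (v %in% names(idx)) b[idx[[v]]] <- b[idx[[v]]] + q
        next
      }
      g <- 1 / edges$resistance[e]
      for (end in list(c(u, v, 1), c(v, u, 1))) {
        a <- end[1]; o <- end[2]
        if (a %in% names(idx)) {
          A[idx[[a]], idx[[a]]] <- A[idx[[a]], idx[[a]]] + g
          if (o %in% names(idx)) {
            A[idx[[a]], idx[[o]]] <- A[idx[[a]], idx[[o]]] - g
          } else {
            b[idx[[a]]] <- b[idx[[a]]] + g * p[[o]]
          }
        }
      }
    }
    sol <- tryCatch(solve(A, b), error = function(err) {
      abort("Network is singular or over-constrained.",
            class = "cifsim_network_error", parent = err)
    })
    p[nodes$node[free]] <- sol
  }

  edges$flow <- ifelse(is.na(edges$flow),
                       (p[edges$from] - p[edges$to]) / edges$resistance,
                       edges$flow)
  list(nodes = tibble::tibble(node = nodes$node, pressure = unname(p[nodes$node])),
       edges = tibble::as_tibble(edges))
}

#' Pumpless arteriovenous leukapheresis circuit
#'
#' Lumped template for in-vivo operation: arterial source node at the mean
#' arterial pressure, device and return-line resistances in series to the
#' venous node, and a fixed-flow retentate withdrawal branch (syringe pump)
#' tapping the device outlet.
#'
#' @param map_mmHg Mean arterial pressure at the access (mmHg).
#' @param venous_mmHg Venous pressure at the return (mmHg).
#' @param device_resistance Device hydraulic resistance (mmHg per uL/min).
#' @param line_resistance Total tubing/flowmeter resistance (mmHg per uL/min),
#'   split evenly between the arterial and venous limbs.
#' @param withdrawal_ul_min Retentate withdrawal flow (uL/min).
#' @return A [hydraulic_network()]; solve with [solve_network()]. The edge
#'   named flow from `device_out` to `vein` is the filtrate return.
#' @export
invivo_circuit <- function(map_mmHg, venous_mmHg = 5,
                           device_resistance, line_resistance,
                           withdrawal_ul_min) {
  hydraulic_network(
    nodes = tibble::tibble(
      node = c("artery", "device_in", "device_out", "vein", "collect"),
      # the collection syringe is at ambient pressure; the pump fixes its flow
      pressure = c(map_mmHg, NA, NA, venous_mmHg, 0)),
    edges = tibble::tibble(
      from = c("artery", "device_in", "device_out", "device_out"),
      to = c("device_in", "device_out", "vein", "collect"),
      resistance = c(line_resistance / 2, device_resistance,
                     line_resistance / 2, NA),
      flow = c(NA, NA, NA, withdrawal_ul_min))
  )
}
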