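# Duct resistances and the Kirchhoff network solver.

# independent oracle: 50-term odd series for rectangular-duct resistance
series_resistance_si <- function(w_um, h_um, L_mm, mu_mpas, n_terms = 50) {
  b <- min(w_um, h_um) * 1e-6
  a <- max(w_um, h_um) * 1e-6
  mu <- mu_mpas * 1e-3
  n <- seq(1, by = 2, length.out = n_terms)
  s <- sum(tanh(n * pi * a / (2 * b)) / n^5)
  12 * mu * (L_mm * 1e-3) / (a * b^3 * (1 - 192 * b / (pi^5 * a) * s))
}

test_that("rectangular-duct resistance matches a 50-term series within 0.1%", {
  cases <- list(c(100, 150, 10), c(230, 150, 25), c(50, 50, 5), c(760, 760, 300))
  for (cs in cases) {
    got <- rect_channel_resistance(cs[1], cs[2], cs[3], viscosity = 1, units = "SI")
    want <- series_resistance_si(cs[1], cs[2], cs[3], 1)
    expect_lt(abs(got - want) / want, 1e-3)
  }
})

test_that("duct resistance is symmetric in w/h and linear in L and viscosity", {
  expect_equal(rect_channel_resistance(100, 150, 10),
               rect_channel_resistance(150, 100, 10))
  expect_equal(rect_channel_resistance(100, 150, 20),
               2 * rect_channel_resistance(100, 150, 10))
  expect_equal(rect_channel_resistance(100, 150, 10, viscosity = 8),
               2 * rect_channel_resistance(100, 150, 10, viscosity = 4))
  expect_error(rect_channel_resistance(-1, 10, 1), class = "cifsim_domain_error")
})

test_that("a single channel obeys the Ohm analogy and parallel branches split evenly", {
  one <- solve_network(hydraulic_network(
    nodes = data.frame(node = c("a", "b"), pressure = c(10, 0)),
    edges = data.frame(from = "a", to = "b", resistance = 4)))
  expect_equal(one$edges$flow, 2.5)

  par2 <- solve_network(hydraulic_network(
    nodes = data.frame(node = c("a", "m", "b"), pressure = c(100, NA, 0)),
    edges = data.frame(from = c("a", "m", "m"), to = c("m", "b", "b"),
                       resistance = c(1, 6, 6))))
  expect_equal(par2$edges$flow[2], par2$edges$flow[3])
  # adding an identical parallel branch halves the equivalent resistance:
  # total flow equals that of a single branch of R/2
  single_half <- solve_network(hydraulic_network(
    nodes = data.frame(node = c("a", "m", "b"), pressure = c(100, NA, 0)),
    edges = data.frame(from = c("a", "m"), to = c("m", "b"), resistance = c(1, 3))))
  expect_equal(par2$edges$flow[1], single_half$edges$flow[1], tolerance = 1e-12)
})

test_that("a symmetric bifurcation tree feeds 8 devices equally", {
  # inlet -> 2 -> 4 -> 8 device branches, all identical resistances
  nodes <- data.frame(
    node = c("in", paste0("l1_", 1:2), paste0("l2_", 1:4), "out"),
    pressure = c(100, rep(NA, 6), 0))
  edges <- rbind(
    data.frame(from = "in", to = paste0("l1_", 1:2), resistance = 2),
    data.frame(from = rep(paste0("l1_", 1:2), each = 2),
               to = paste0("l2_", 1:4), resistance = 3),
    data.frame(from = rep(paste0("l2_", 1:4), each = 2), to = "out",
               resistance = 5))
  sol <- solve_network(hydraulic_network(nodes, edges))
  leaf <- sol$edges$flow[sol$edges$to == "out"]
  total <- sum(sol$edges$flow[sol$edges$from == "in"])
  expect_equal(leaf, rep(total / 8, 8), tolerance = 1e-9)
  # Kirchhoff balance at every interior node
  for (nd in nodes$node[is.na(nodes$pressure)]) {
    net_flow <- sum(sol$edges$flow[sol$edges$to == nd]) -
      sum(sol$edges$flow[sol$edges$from == nd])
    expect_lt(abs(net_flow) / total, 1e-9)
  }
})

test_that("solutions are invariant under joint rescaling of pressure and resistance", {
  nodes <- data.frame(node = c("a", "m", "b"), pressure = c(80, NA, 5))
  edges <- data.frame(from = c("a", "m"), to = c("m", "b"), resistance = c(0.3, 0.7))
  base <- solve_network(hydraulic_network(nodes, edges))
  nodes2 <- transform(nodes, pressure = pressure * 133.322)
  edges2 <- transform(edges, resistance = resistance * 133.322)
  scaled <- solve_network(hydraulic_network(nodes2, edges2))
  expect_equal(scaled$edges$flow, base$edges$flow, tolerance = 1e-12)
})

test_that("fixed-flow withdrawal edges carry exactly their prescribed flow", {
  sol <- solve_network(invivo_circuit(100, 5, device_resistance = 0.2,
                                      line_resistance = 0.01,
                                      withdrawal_ul_min = 22.5))
  expect_equal(sol$edges$flow[sol$edges$to == "collect"], 22.5)
  # conservation at the device outlet: inflow = filtrate return + withdrawal
  dev_in <- sol$edges$flow[sol$edges$to == "device_out"]
  expect_equal(dev_in, sum(sol$edges$flow[sol$edges$from == "device_out"]),
               tolerance = 1e-9)
})

test_that("malformed networks raise structured errors", {
  expect_error(hydraulic_network(
    nodes = data.frame(node = c("a", "b", "c", "d"), pressure = c(1, 0, NA, NA)),
    edges = data.frame(from = c("a", "c"), to = c("b", "d"), resistance = 1)),
    class = "cifsim_network_error")
  expect_error(hydraulic_network(
    nodes = data.frame(node = c("a", "b"), pressure = c(NA_real_, NA_real_)),
    edges = data.frame(from = "a", to = "b", resistance = 1)),
    class = "cifsim_validation_error")
  expect_error(hydraulic_network(
    nodes = data.frame(node = c("a", "b"), pressure = c(1, 0)),
    edges = data.frame(from = "a", to = "b", resistance = -2)),
    class = "cifsim_validation_error")
})
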