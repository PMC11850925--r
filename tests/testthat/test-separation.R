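# Capture model, transport (deterministic and Monte-Carlo), and the CE/CR
# estimators.

test_that("capture probability has the point-particle and steric limits", {
  d <- quick_design(n_gaps = 20)
  f0 <- d$gaps$f_gap[1]
  w_l <- d$w_l_target
  expect_equal(capture_probability(0, 0, d), f0)
  expect_equal(capture_probability(2 * w_l, 0, d), 0)
  expect_equal(capture_probability(5 * w_l, 0, d), 0)  # clamps, no error
  # half-radius cell: flux model reduces to ~ a quarter of f in the
  # thin-lamina (quadratic) limit; direct evaluation of F is the oracle
  x_l <- w_l / d$gaps$w_r[1]
  want <- f0 * (3 * (x_l / 2)^2 - 2 * (x_l / 2)^3) / (3 * x_l^2 - 2 * x_l^3)
  expect_equal(capture_probability(w_l, 0, d), want, tolerance = 1e-12)
  expect_equal(want / f0, 0.25, tolerance = 0.01)
  # non-increasing and bounded
  p <- capture_probability(seq(0, 3 * w_l, length.out = 100), 0, d)
  expect_true(all(diff(p) <= 1e-15))
  expect_true(all(p >= 0 & p <= f0))
})

test_that("point particles through a constant-f element leave the closed-form share", {
  d <- constant_f_design(f = 1e-3, n_gaps = 1521, w_r_star = 100)
  ret <- retention_probability(1e-9, d)
  expect_equal(ret, (1 - 2e-3)^1521, tolerance = 1e-6)
  expect_equal(ret, 1 / (1 + d$flow_ratio), tolerance = 1e-6)
  # ~ 1/21
  expect_equal(ret, 0.0476, tolerance = 1e-3)
})

test_that("deterministic CE has the fluid-share and full-retention limits and is monotone", {
  d <- quick_design(n_gaps = 120)
  diam <- seq(0.1, 14, length.out = 60)
  ret <- retention_probability(diam, d)
  expect_true(all(diff(ret) >= -1e-12))
  expect_equal(retention_probability(1e-6, d), 1 / (1 + d$flow_ratio),
               tolerance = 1e-6)
  expect_equal(retention_probability(2.5 * d$w_l_target, d), 1)
  # lower flow ratio leaves a larger retained fluid share for small cells
  d_short <- quick_design(n_gaps = 30)
  expect_gt(retention_probability(0.1, d_short), retention_probability(0.1, d))
})

test_that("separation conserves cells and volume and satisfies the CR-CE identity", {
  d <- quick_design(n_gaps = 80)
  s <- make_blood(blood_spec("human", seed = 5))
  for (sep in list(separate_sample(s, d),
                   separate_sample(s, d, mode = "monte-carlo",
                                   n_cells = 2e4, seed = 9))) {
    tt <- tidy(sep)
    v_in <- glance(sep)$v_in
    expect_equal(glance(sep)$v_ret + glance(sep)$v_fil, v_in, tolerance = 1e-12)
    lhs <- tt$C_in * v_in
    rhs <- tt$C_ret * glance(sep)$v_ret + tt$C_fil * glance(sep)$v_fil
    expect_true(all(abs(lhs - rhs) / lhs < 1e-9))
    expect_true(all(tt$ce_percent >= 0 & tt$ce_percent <= 100))
    # CR = (CE/100) * (1 + FR)
    expect_true(all(abs(tt$cr_fold - tt$ce_percent / 100 * (1 + sep$flow_ratio)) < 1e-9))
  }
})

test_that("Monte-Carlo transport is seed-reproducible and matches the closed form", {
  d <- constant_f_design(f = 1e-3, n_gaps = 1521, w_r_star = 100)
  s <- point_particle_sample()
  a <- separate_sample(s, d, mode = "monte-carlo", n_cells = 1e5, seed = 21)
  b <- separate_sample(s, d, mode = "monte-carlo", n_cells = 1e5, seed = 21)
  expect_identical(a$cell_log, b$cell_log)
  p_hat <- tidy(a)$ce_percent / 100
  p <- (1 - 2e-3)^1521
  expect_lt(abs(p_hat - p), 3 * binom_se(p, 1e5))
  expect_error(separate_sample(s, d, mode = "monte-carlo", n_cells = 0, seed = 1),
               class = "cifsim_domain_error")
  expect_error(separate_sample(s, d, mode = "monte-carlo", n_cells = 100),
               class = "cifsim_domain_error")
})

test_that("a zero-gap element retains every cell in both transport modes", {
  d <- design_element(1e-3, n_gaps = 0)
  s <- make_blood(blood_spec("human", seed = 3))
  expect_true(all(tidy(separate_sample(s, d))$ce_percent == 100))
  mc <- separate_sample(s, d, mode = "monte-carlo", n_cells = 1000, seed = 2)
  expect_true(all(mc$cell_log$retained))
})

test_that("the no-remix flux-coordinate mode is reproducible and conservative", {
  d <- quick_design(n_gaps = 60)
  s <- make_blood(blood_spec("human", seed = 5))
  a <- separate_sample(s, d, mode = "monte-carlo", n_cells = 5e3, seed = 4,
                       remix = FALSE)
  b <- separate_sample(s, d, mode = "monte-carlo", n_cells = 5e3, seed = 4,
                       remix = FALSE)
  expect_identical(a$cell_log, b$cell_log)
  tt <- tidy(a)
  lhs <- tt$C_in * a$v_in
  rhs <- tt$C_ret * a$v_ret + tt$C_fil * a$v_fil
  expect_true(all(abs(lhs - rhs) / lhs < 1e-9))
})

test_that("a tighter lamina (lower f_gap*) collects intermediate cells better", {
  designs <- reference_designs(target_fr = 15)
  blasts <- blood_sample(
    data.frame(cell_type = "BLAST", concentration = 1000,
               diameter_mean = 10.5, diameter_cv = 0.08),
    volume_ul = 1000)
  ce <- vapply(designs, function(d) tidy(separate_sample(blasts, d))$ce_percent,
               numeric(1))
  expect_gt(ce[["design2"]], ce[["design4"]])
  expect_true(all(diff(ce) <= 0))
})

test_that("the in-vitro CE formula reproduces hand arithmetic and its limits", {
  expect_equal(collection_efficiency(100, 0, 100, 2000), 100)
  expect_equal(collection_efficiency(100, 10, 100, 2000), 100 / 3, tolerance = 1e-12)
  # equal concentrations at FR = V_fil/V_ret recover the fluid-share loss
  fr <- 20
  expect_equal(collection_efficiency(50, 50, 100, 100 * fr), 100 / (1 + fr))
  expect_error(collection_efficiency(10, 5, 0, 100), class = "cifsim_domain_error")
  expect_error(collection_efficiency(0, 0, 100, 100), class = "cifsim_undefined_ce")
})

test_that("the spiked-blast CE formula reproduces hand arithmetic and flags >100%", {
  expect_equal(blast_collection_efficiency(0, 50, 100, 2000), 0)
  expect_equal(blast_collection_efficiency(900, 50, 100, 2000),
               900 * 100 / (50 * 2100) * 100, tolerance = 1e-12)
  expect_equal(round(blast_collection_efficiency(900, 50, 100, 2000), 1), 85.7)
  # perfect capture: every input cell ends up in the retentate
  expect_equal(blast_collection_efficiency(50 * 2100 / 100, 50, 100, 2000), 100)
  expect_warning(blast_collection_efficiency(5000, 50, 100, 2000),
                 "exceed 100")
  expect_error(blast_collection_efficiency(10, 0, 100, 100),
               class = "cifsim_domain_error")
})

test_that("concentration ratio is the plain fold and errors on zero input", {
  expect_equal(concentration_ratio(500, 500), 1)
  expect_equal(concentration_ratio(2100, 100), 21)
  expect_error(concentration_ratio(1, 0), class = "cifsim_domain_error")
})
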