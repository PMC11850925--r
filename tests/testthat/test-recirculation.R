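# Well-mixed recirculation compartment, its ledgers, and the in-vivo CE/CR
# estimators.

rat_baseline <- function() noiseless_rat(seed = 11)

simple_subject <- function(etbv_ml = 26, conc = 1e4) {
  baseline <- blood_sample(
    data.frame(cell_type = "LYM", concentration = conc,
               diameter_mean = 7, diameter_cv = 0),
    volume_ul = 1000, species = "rat")
  cif_subject(weight_kg = etbv_ml / 70, baseline = baseline, etbv_ml = etbv_ml)
}

plain_protocol <- function(...) {
  recirculation_protocol(duration_min = 180, circuit_flow_ml_min = 0.45,
                         retentate_fraction = 0.05,
                         sample_times_min = numeric(0), ...)
}

test_that("constant conditions match the exponential closed form to 1e-6", {
  subj <- simple_subject()
  run <- simulate_recirculation(subj, c(LYM = 60), plain_protocol())
  x <- glance(run)$etbv_processed
  expect_equal(x, 0.45 * 180 / 26, tolerance = 1e-10)
  expect_equal(x, 3.115, tolerance = 1e-3)
  want <- exp(-0.6 * x)
  expect_lt(abs(run$c_post / run$c_pre - want) / want, 1e-6)
})

test_that("zero CE leaves concentrations untouched; influx balances removal", {
  subj <- simple_subject()
  run0 <- simulate_recirculation(subj, c(LYM = 0), plain_protocol())
  expect_equal(unname(run0$c_post / run0$c_pre), 1, tolerance = 1e-9)

  # influx tuned to the initial removal flux gives a steady state
  q_ul <- 0.45 * 1000
  influx <- q_ul * 0.60 * 1e4
  subj_in <- cif_subject(weight_kg = 26 / 70, baseline = subj$baseline,
                         etbv_ml = 26, influx_per_min = c(LYM = influx))
  run_in <- simulate_recirculation(subj_in, c(LYM = 60), plain_protocol())
  ts <- tidy(run_in)
  expect_lt(max(abs(ts$concentration - 1e4)) / 1e4, 1e-6)
})

test_that("cell and volume ledgers balance with sampling, withdrawal and boluses", {
  subj <- cif_subject(0.375, rat_baseline())
  prot <- recirculation_protocol(
    duration_min = 180, circuit_flow_ml_min = 0.45, retentate_fraction = 0.05,
    sample_times_min = seq(15, 180, 15), sample_volume_ml = 0.3,
    fluid_events = data.frame(time_min = c(60, 120), volume_ml = c(0.5, 0.5)),
    circuit_ecv_ml = 0.736)
  ce <- c(RBC = 5, PLT = 4, PMN = 70, LYM = 30, MON = 60, EOS = 80)
  run <- simulate_recirculation(subj, ce, prot)
  l <- run$ledger
  imbalance <- abs(l$baseline_cells + l$influx_cells - l$circulating_cells -
                     l$retentate_cells - l$sampled_cells) / l$baseline_cells
  expect_true(all(imbalance < 1e-6))
  g <- glance(run)
  expect_equal(g$v_proc_ml, 0.45 * 180)
  expect_equal(g$fluid_removed_ml, 0.05 * 0.45 * 180 + 12 * 0.3)
})

test_that("the in-vivo CR estimators behave at the flow-ratio limit", {
  expect_equal(cr_timepoint(40, 2), 20)
  expect_equal(cr_timepoint(5, 5), 1)
  expect_error(cr_timepoint(1, 0), class = "cifsim_domain_error")

  subj <- simple_subject()
  run <- simulate_recirculation(subj, c(LYM = 100), plain_protocol())
  # full capture with withdrawal at 5% of the circuit flow concentrates the
  # retentate ~(1/0.05)-fold over circulating blood, approximating 1 + FR
  cr_blood <- dplyr::distinct(concentration_ratio_invivo(run, "blood"),
                              cell_type, cr_overall)$cr_overall
  expect_equal(cr_blood, 20, tolerance = 0.01)
  expect_equal(cr_blood, 21, tolerance = 0.05)
  # moderate CE: filtrate-denominator CR exceeds the blood-denominator CR
  run60 <- simulate_recirculation(subj, c(LYM = 60), plain_protocol())
  cr_fil <- dplyr::distinct(concentration_ratio_invivo(run60, "filtrate"),
                            cell_type, cr_overall)$cr_overall
  cr_bld <- dplyr::distinct(concentration_ratio_invivo(run60, "blood"),
                            cell_type, cr_overall)$cr_overall
  expect_gt(cr_fil, cr_bld)
})

test_that("the serial-aliquot CE ratio reproduces hand arithmetic", {
  expect_equal(ce_invivo_ratio(c(40, 40), c(500, 500), 10, 6, 5e4), 0.10)
  expect_equal(ce_invivo_ratio(0, 500, 10, 6, 5e4), 0)
  expect_error(ce_invivo_ratio(40, 500, 10, 6, 0), class = "cifsim_domain_error")
  expect_error(ce_invivo_ratio(numeric(0), numeric(0), 10, 6, 1),
               class = "cifsim_domain_error")
})

test_that("the aliquot estimator recovers a moderate injected CE within 5%", {
  subj <- simple_subject()
  run <- simulate_recirculation(subj, c(LYM = 20), plain_protocol())
  est <- collection_efficiency_invivo(run)$ce_percent
  expect_lt(abs(est - 20) / 20, 0.05)
})

test_that("final percentages and loss ratios separate selective removal from dilution", {
  subj <- cif_subject(0.375, rat_baseline())
  prot <- recirculation_protocol(
    duration_min = 180, circuit_flow_ml_min = 0.45, retentate_fraction = 0.05,
    sample_times_min = seq(15, 180, 15), sample_volume_ml = 0.3,
    circuit_ecv_ml = 0.736)
  ce_active <- c(RBC = 5, PLT = 4, PMN = 70, LYM = 30, MON = 60, EOS = 80)
  active <- simulate_recirculation(subj, ce_active, prot)
  r_active <- final_percent_ratios(active)
  expect_lt(r_active$value[r_active$metric == "wbc_rbc_ratio"], 1)

  # sham: no removal anywhere; sampling dilutes all types equally
  sham <- simulate_recirculation(
    subj, setNames(rep(0, 6), names(ce_active)),
    recirculation_protocol(duration_min = 180, circuit_flow_ml_min = 0.319,
                           retentate_fraction = 0,
                           sample_times_min = seq(15, 180, 15),
                           sample_volume_ml = 0.3, circuit_ecv_ml = 0.736))
  rbc_ts <- dplyr::filter(tidy(sham), cell_type == "RBC")
  expect_true(all(diff(rbc_ts$concentration) <= 1e-9))
  expect_lt(dplyr::last(rbc_ts$concentration) / rbc_ts$concentration[1], 1)
  r_sham <- final_percent_ratios(sham)
  expect_gte(round(r_sham$value[r_sham$metric == "wbc_rbc_ratio"], 9), 1)

  # WBC CE below RBC CE flips the ratio above 1
  flipped <- simulate_recirculation(
    subj, c(RBC = 30, PLT = 4, PMN = 5, LYM = 5, MON = 5, EOS = 5), prot)
  r_flip <- final_percent_ratios(flipped)
  expect_gt(r_flip$value[r_flip$metric == "wbc_rbc_ratio"], 1)
})

test_that("no-removal runs keep every final percent at 100 and ratios at 1", {
  subj <- cif_subject(0.375, rat_baseline())
  run <- simulate_recirculation(
    subj, setNames(rep(0, 6), subj$baseline$cell_type),
    plain_protocol())
  expect_equal(final_percent(run)$final_percent, rep(100, 6), tolerance = 1e-9)
  rr <- final_percent_ratios(run)
  expect_equal(rr$value[rr$metric %in% c("wbc_rbc_ratio", "plt_rbc_ratio")],
               c(1, 1), tolerance = 1e-9)
})

test_that("volume depletion aborts with a diagnostic", {
  subj <- simple_subject(etbv_ml = 5)
  prot <- recirculation_protocol(
    duration_min = 180, circuit_flow_ml_min = 0.45, retentate_fraction = 0.4,
    sample_times_min = numeric(0), replace_withdrawal = FALSE)
  expect_error(simulate_recirculation(subj, c(LYM = 50), prot),
               class = "cifsim_simulation_error")
})

test_that("CBC measurement noise is seed-reproducible and off by default", {
  subj <- simple_subject()
  run <- simulate_recirculation(subj, c(LYM = 30), plain_protocol())
  expect_false("reported_concentration" %in% names(tidy(run)))
  noisy_prot <- plain_protocol(cbc_noise_cv = 0.05, seed = 4)
  n1 <- simulate_recirculation(subj, c(LYM = 30), noisy_prot)
  n2 <- simulate_recirculation(subj, c(LYM = 30), noisy_prot)
  expect_identical(tidy(n1)$reported_concentration,
                   tidy(n2)$reported_concentration)
  expect_error(plain_protocol(cbc_noise_cv = 0.05), class = "cifsim_domain_error")
})
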