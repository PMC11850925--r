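# Shared fixtures, built in code. Small gap counts keep unit tests fast;
# the full reference designs are exercised where the science needs them.

quick_design <- function(n_gaps = 50, f_gap_star = 1e-3, ...) {
  design_element(f_gap_star, n_gaps = n_gaps, ...)
}

# constant-f reference element: fixed width so every gap extracts the same
# fraction; closed-form retention (1 - 2f)^N
constant_f_design <- function(f = 1e-3, n_gaps = 100, w_r_star = 230) {
  design_element(f, w_r_star = w_r_star, n_gaps = n_gaps,
                 width_rule = "fixed-width")
}

point_particle_sample <- function(concentration = 1e4, volume_ul = 1000) {
  blood_sample(
    data.frame(cell_type = "POINT", concentration = concentration,
               diameter_mean = 1e-9, diameter_cv = 0),
    volume_ul = volume_ul, species = "test"
  )
}

noiseless_rat <- function(seed = 11) {
  make_blood(blood_spec("rat", seed = seed, concentration_cv = 0))
}

# binomial standard error of an empirical proportion
binom_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / n)
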