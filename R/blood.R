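# Synthetic blood fixtures: reproducible CBC-style samples for humans and
# rats, with optional leukemic-blast spiking. Concentration defaults are
# literature-informed fixture values, not measurements.

# physiologic plausibility bounds (cells/uL) used by the validator
.conc_bounds <- list(
  RBC = c(2e6, 1.2e7),
  PLT = c(1e4, 2e6),
  WBC = c(5e2, 5e5),
  BLAST = c(0, 5e5)
)

# default cell-type panels: mean concentration (cells/uL), mean diameter (um),
# diameter CV. WBC subtype fractions sum to 1 by construction.
.human_panel <- function() {
  tibble::tibble(
    cell_type = c("RBC", "PLT", "PMN", "LYM", "MON", "EOS"),
    concentration = c(5e6, 2.5e5, 7e3 * 0.60, 7e3 * 0.30, 7e3 * 0.07, 7e3 * 0.03),
    diameter_mean = c(5.5, 2.5, 8.5, 7.5, 9.5, 9.0),
    diameter_cv = c(0.08, 0.12, 0.08, 0.08, 0.08, 0.08)
  )
}

.rat_panel <- function() {
  # rats run lymphocyte-rich differentials; EOS and PMN are their two
  # largest WBC subtypes, so their diameters sit above MON here
  tibble::tibble(
    cell_type = c("RBC", "PLT", "PMN", "LYM", "MON", "EOS"),
    concentration = c(7e6, 8e5, 8e3 * 0.20, 8e3 * 0.70, 8e3 * 0.05, 8e3 * 0.05),
    diameter_mean = c(5.0, 2.0, 9.0, 7.0, 8.5, 9.5),
    diameter_cv = c(0.08, 0.12, 0.08, 0.08, 0.08, 0.08)
  )
}

.wbc_subtypes <- c("PMN", "LYM", "MON", "EOS", "BLAST")

#' Specify a synthetic blood fixture
#'
#' Builds the recipe that [make_blood()] turns into a reproducible
#' CBC-style sample: a species panel of cell types with mean concentrations
#' and log-normal diameter distributions, multiplicative log-normal
#' concentration noise, and an optional leukemic-blast spike (modelled on
#' MV-4-11 cells).
#'
#' @param species `"human"` or `"rat"`.
#' @param seed Integer seed; mandatory so every fixture is reproducible.
#' @param volume_ul Sample volume (uL).
#' @param wbc_total Total WBC concentration (cells/uL); overrides the panel
#'   default while keeping the differential fractions. The
#'   `"hyperleukocytosis"` preset sets it above 1e5/uL.
#' @param preset `"normal"` or `"hyperleukocytosis"` (circulating WBC
#'   > 100,000/uL, the clinical threshold).
#' @param blast_concentration Optional spike of BLAST cells (cells/uL) added
#'   to the sample, e.g. from a 1e6/mL cell-line stock diluted into blood.
#' @param blast_diameter_mean,blast_diameter_cv Blast size distribution (um).
#' @param concentration_cv CV of the log-normal concentration noise applied
#'   to RBC, PLT and total WBC (default 0.10). Set 0 for noiseless panels.
#' @return A `blood_spec` list.
#' @export
blood_spec <- function(species = c("human", "rat"),
                       seed,
                       volume_ul = 1000,
                       wbc_total = NULL,
                       preset = c("normal", "hyperleukocytosis"),
                       blast_concentration = NULL,
                       blast_diameter_mean = 10.5,
                       blast_diameter_cv = 0.08,
                       concentration_cv = 0.10) {
  species <- match.arg(species)
  preset <- match.arg(preset)
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory for blood fixtures.", class = "cifsim_domain_error")
  }
  if (volume_ul <= 0) abort("`volume_ul` must be positive.", class = "cifsim_domain_error")
  if (concentration_cv < 0) abort("`concentration_cv` must be >= 0.", class = "cifsim_domain_error")
  panel <- if (species == "human") .human_panel() else .rat_panel()
  if (preset == "hyperleukocytosis" && is.null(wbc_total)) wbc_total <- 1.5e5
  structure(
    list(species = species, seed = as.integer(seed), volume_ul = volume_ul,
         panel = panel, wbc_total = wbc_total, preset = preset,
         blast_concentration = blast_concentration,
         blast_diameter_mean = blast_diameter_mean,
         blast_diameter_cv = blast_diameter_cv,
         concentration_cv = concentration_cv),
    class = "blood_spec"
  )
}

#' Generate a synthetic blood sample
#'
#' Draws a reproducible CBC-style sample from a [blood_spec()]: per-type
#' concentrations with log-normal noise (WBC subtypes always sum exactly to
#' the drawn WBC total) and log-normal cell diameter distributions. The
#' result is a `blood_sample` tibble — one row per cell population with
#' columns `cell_type`, `concentration` (cells/uL), `diameter_mean` (um),
#' `diameter_cv` — carrying the sample volume and species as attributes.
#'
#' @param spec A [blood_spec()].
#' @return A `blood_sample` tibble.
#' @examples
#' make_blood(blood_spec("human", seed = 1))
#' @export
make_blood <- function(spec) {
  stopifnot(inherits(spec, "blood_spec"))
  panel <- spec$panel
  wbc_rows <- panel$cell_type %in% .wbc_subtypes
  wbc_mean <- if (is.null(spec$wbc_total)) sum(panel$concentration[wbc_rows]) else spec$wbc_total
  frac <- panel$concentration[wbc_rows] / sum(panel$concentration[wbc_rows])

  withr::with_seed(spec$seed, {
    cv <- spec$concentration_cv
    noisy <- function(mu, n = length(mu)) {
      if (cv == 0) return(mu)
      sdl <- sqrt(log(1 + cv^2))
      mu * exp(stats::rnorm(n, -sdl^2 / 2, sdl))
    }
    rbc <- noisy(panel$concentration[panel$cell_type == "RBC"])
    plt <- noisy(panel$concentration[panel$cell_type == "PLT"])
    wbc <- noisy(wbc_mean)
    frac_noisy <- noisy(frac)
    frac_noisy <- frac_noisy / sum(frac_noisy)     # differential closes exactly
    conc <- panel$concentration
    conc[panel$cell_type == "RBC"] <- rbc
    conc[panel$cell_type == "PLT"] <- plt
    conc[wbc_rows] <- wbc * frac_noisy
  })
  panel$concentration <- conc

  if (!is.null(spec$blast_concentration)) {
    if (spec$blast_concentration < 0) {
      abort("Blast spike concentration must be >= 0.", class = "cifsim_validation_error")
    }
    panel <- dplyr::bind_rows(panel, tibble::tibble(
      cell_type = "BLAST", concentration = spec$blast_concentration,
      diameter_mean = spec$blast_diameter_mean,
      diameter_cv = spec$blast_diameter_cv
    ))
  }
  validate_blood_sample(new_blood_sample(panel, spec$volume_ul, spec$species))
}

new_blood_sample <- function(populations, volume_ul, species) {
  out <- tibble::as_tibble(populations)
  attr(out, "volume_ul") <- volume_ul
  attr(out, "species") <- species
  class(out) <- c("blood_sample", class(out))
  out
}

#' Assemble a blood sample from explicit populations
#'
#' Lower-level constructor used when you want full control over the panel
#' (e.g. single-population point-particle samples in tests).
#'
#' @param populations Data frame with columns `cell_type`, `concentration`
#'   (cells/uL), `diameter_mean` (um), `diameter_cv`.
#' @param volume_ul Sample volume (uL).
#' @param species Species tag (free text; `"human"` and `"rat"` are the
#'   fixture species).
#' @return A validated `blood_sample` tibble.
#' @export
blood_sample <- function(populations, volume_ul = 1000, species = "human") {
  need <- c("cell_type", "concentration", "diameter_mean", "diameter_cv")
  if (!all(need %in% names(populations))) {
    abort(paste("`populations` needs columns:", paste(need, collapse = ", ")),
          class = "cifsim_validation_error")
  }
  validate_blood_sample(new_blood_sample(populations[need], volume_ul, species))
}

validate_blood_sample <- function(x) {
  if (anyDuplicated(x$cell_type)) {
    abort("Population names must be unique.", class = "cifsim_validation_error")
  }
  if (any(x$concentration < 0) || any(x$diameter_mean <= 0) || any(x$diameter_cv < 0)) {
    abort("Concentrations must be >= 0, diameters > 0, spreads >= 0.",
          class = "cifsim_validation_error")
  }
  if (attr(x, "volume_ul") <= 0) {
    abort("Sample volume must be positive.", class = "cifsim_validation_error")
  }
  # physiologic bounds: generous, meant to catch unit mistakes not biology
  chk <- function(type, value) {
    b <- .conc_bounds[[type]]
    if (!is.null(b) && length(value) && (value < b[1] || value > b[2])) {
      abort(sprintf("%s concentration %.3g/uL outside plausible range [%.3g, %.3g].",
                    type, value, b[1], b[2]), class = "cifsim_validation_error")
    }
  }
  chk("RBC", x$concentration[x$cell_type == "RBC"])
  chk("PLT", x$concentration[x$cell_type == "PLT"])
  wbc <- sum(x$concentration[x$cell_type %in% .wbc_subtypes])
  if (any(x$cell_type %in% .wbc_subtypes)) chk("WBC", wbc)
  x
}

#' @export
print.blood_sample <- function(x, ...) {
  cat(sprintf("<blood_sample> %s, %g uL\n", attr(x, "species"), attr(x, "volume_ul")))
  NextMethod()
}

#' Sample volume and species of a blood sample
#' @param sample A `blood_sample`.
#' @return Volume in uL / species tag.
#' @export
sample_volume <- function(sample) attr(sample, "volume_ul")

#' @rdname sample_volume
#' @export
sample_species <- function(sample) attr(sample, "species")

#' Write / read blood samples as CSV
#'
#' One row per population (`cell_type`, `concentration`, `diameter_mean`,
#' `diameter_cv`) plus `volume_ul` and `species` columns repeated on each row
#' so the file is self-contained.
#'
#' @param sample A `blood_sample`.
#' @param path CSV path.
#' @return The path (write) or the `blood_sample` (read).
#' @export
write_blood_sample <- function(sample, path) {
  out <- tibble::as_tibble(sample)
  out$volume_ul <- sample_volume(sample)
  out$species <- sample_species(sample)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_blood_sample
#' @export
read_blood_sample <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  blood_sample(x, volume_ul = x$volume_ul[1], species = x$species[1])
}

# quantile grid of a population's log-normal diameter distribution;
# midpoint probabilities give a deterministic, fast integration rule
diameter_quantiles <- function(diameter_mean, diameter_cv, n = 201) {
  if (diameter_cv == 0) return(rep(diameter_mean, 1L))
  sdlog <- sqrt(log(1 + diameter_cv^2))
  meanlog <- log(diameter_mean) - sdlog^2 / 2
  qlnorm((seq_len(n) - 0.5) / n, meanlog, sdlog)
}

# random diameters for the Monte-Carlo path (same parametrisation)
diameter_draws <- function(n, diameter_mean, diameter_cv) {
  if (diameter_cv == 0) return(rep(diameter_mean, n))
  sdlog <- sqrt(log(1 + diameter_cv^2))
  meanlog <- log(diameter_mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}
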