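#' Synthetic noisy quasi-static stress-strain curve
#'
#' Simulates the wall-ensemble model at the given moduli, samples the curve at
#' \code{strain_points}, and adds independent Gaussian measurement noise with
#' standard deviation \code{noise_sd_fraction * max(stress)} — the simplest
#' stand-in for force-transducer noise on a quasi-static loading limb. The
#' stress at zero strain is forced back to 0 (the reference configuration is
#' measured unloaded).
#'
#' @param moduli a [tissue_moduli] object.
#' @param config a [simulation_config]; \code{max_strain} must cover
#'   \code{strain_points}.
#' @param strain_points sampling strains (default 0 to 0.6 in steps of 0.02,
#'   a typical quasi-static ramp density).
#' @param noise_sd_fraction noise sd as a fraction of peak stress (>= 0).
#' @param seed integer seed for the noise; NULL draws from the global stream.
#' @return A [stress_strain_curve].
#' @export
generate_noisy_curve <- function(moduli, config = simulation_config(),
                                 strain_points = seq(0, 0.6, by = 0.02),
                                 noise_sd_fraction = 0.01, seed = NULL) {
  check_number(noise_sd_fraction, "noise_sd_fraction", lower = 0)
  if (max(strain_points) > config$max_strain + 1e-12)
    stopf("strain_points exceed config max_strain")
  clean <- predict_at_strains(moduli, config, strain_points)
  noisy <- if (noise_sd_fraction > 0) {
    sd <- noise_sd_fraction * max(clean)
    clean + with_seed(seed, stats::rnorm(length(clean), sd = sd))
  } else clean
  noisy[strain_points == 0] <- 0
  stress_strain_curve(strain_points, noisy)
}

#' Cohort specification for synthetic samples
#'
#' @param group group label.
#' @param n_samples number of samples (>= 1).
#' @param moduli_mean [tissue_moduli] cohort mean.
#' @param moduli_cv coefficient of variation of the per-sample moduli
#'   (log-normal inter-sample variation; one value applied to both moduli or
#'   a length-2 vector \code{c(cv_y_ae, cv_y_be)}).
#' @param noise_sd_fraction measurement noise as fraction of peak stress.
#' @param strain_points sampling strains.
#' @param seed integer seed.
#' @return An object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(group, n_samples, moduli_mean, moduli_cv = 0.2,
                        noise_sd_fraction = 0.01,
                        strain_points = seq(0, 0.6, by = 0.02), seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples", lower = 1L)
  moduli_mean <- as_tissue_moduli(moduli_mean, "moduli_mean")
  if (length(moduli_cv) == 1L) moduli_cv <- rep(moduli_cv, 2L)
  if (any(moduli_cv < 0)) stopf("moduli_cv must be >= 0")
  check_number(noise_sd_fraction, "noise_sd_fraction", lower = 0)
  structure(list(group = as.character(group), n_samples = n_samples,
                 moduli_mean = moduli_mean, moduli_cv = moduli_cv,
                 noise_sd_fraction = noise_sd_fraction,
                 strain_points = strain_points, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of stress-strain measurements
#'
#' Per-sample true moduli are drawn log-normally around the cohort means with
#' the given coefficients of variation (log-normality keeps moduli positive;
#' the log-normal is parameterized so its arithmetic mean equals the cohort
#' mean). Each sample's curve comes from [generate_noisy_curve]. The true
#' moduli are retained so parameter-recovery performance can be scored.
#'
#' @param spec a [cohort_spec].
#' @param config a [simulation_config] for the forward simulations.
#' @return A list of class \code{"cohort"}; each element has \code{sample_id},
#'   \code{group}, \code{truth} ([tissue_moduli]) and \code{curve}.
#' @export
generate_cohort <- function(spec, config = simulation_config()) {
  if (!inherits(spec, "cohort_spec")) stopf("'spec' must be a cohort_spec")
  draw_lognormal <- function(mean, cv, n) {
    if (cv == 0) return(rep(mean, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  }
  with_seed(spec$seed, {
    y_ae <- draw_lognormal(spec$moduli_mean$y_ae, spec$moduli_cv[1L],
                           spec$n_samples)
    y_be <- draw_lognormal(spec$moduli_mean$y_be, spec$moduli_cv[2L],
                           spec$n_samples)
    noise_seeds <- sample.int(.Machine$integer.max, spec$n_samples)
  })
  out <- vector("list", spec$n_samples)
  for (i in seq_len(spec$n_samples)) {
    truth <- tissue_moduli(y_ae[i], y_be[i])
    out[[i]] <- list(
      sample_id = sprintf("%s_%02d", spec$group, i),
      group = spec$group, truth = truth,
      curve = generate_noisy_curve(truth, config, spec$strain_points,
                                   spec$noise_sd_fraction,
                                   seed = noise_seeds[i]))
  }
  structure(out, class = "cohort")
}

#' Group-mean moduli behind the exemplar fixtures
#'
#' Reported effective moduli (kPa) for seven experimental groups: rat
#' parenchymal strips bathed in normal, hypotonic and hypertonic saline;
#' control and collagen-deficient (MRTF-A knockout) mice; and young and old
#' mice.
#'
#' @return data.frame with columns \code{group}, \code{y_ae}, \code{y_be}.
#' @export
exemplar_moduli <- function() {
  data.frame(
    group = c("normal", "hypotonic", "hypertonic", "control", "knockout",
              "young", "old"),
    y_ae = c(1.94, 3.28, 1.78, 5.96, 3.94, 4.36, 5.86),
    y_be = c(0.27, 0.84, 0.11, 1.28, 0.84, 0.114, 0.161)
  )
}

#' Deterministic exemplar stress-strain fixtures
#'
#' Noiseless curves simulated from each group-mean moduli pair of
#' [exemplar_moduli] — a reproducible reference set for round-trip fitting
#' tests and worked examples.
#'
#' @param config a [simulation_config].
#' @param strain_points sampling strains (default 0 to 0.6 in steps of 0.02).
#' @return Named list of [stress_strain_curve] objects (names as in
#'   [exemplar_moduli]).
#' @export
exemplar_fixtures <- function(config = simulation_config(),
                              strain_points = seq(0, 0.6, by = 0.02)) {
  tab <- exemplar_moduli()
  out <- lapply(seq_len(nrow(tab)), function(i) {
    generate_noisy_curve(tissue_moduli(tab$y_ae[i], tab$y_be[i]), config,
                         strain_points, noise_sd_fraction = 0)
  })
  names(out) <- tab$group
  out
}
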