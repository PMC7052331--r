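#' Stress-strain curve container
#'
#' A light data.frame subclass holding paired macroscopic strain
#' (dimensionless, strictly increasing, starting at or above 0) and tissue
#' stress (kPa) samples — the I/O currency of both simulation and fitting.
#'
#' @param strain numeric vector of strains, strictly increasing.
#' @param stress numeric vector of stresses (kPa), same length.
#' @return A data.frame of class \code{"stress_strain_curve"} with columns
#'   \code{strain} and \code{stress}.
#' @export
stress_strain_curve <- function(strain, stress) {
  if (length(strain) != length(stress))
    stopf("strain and stress must have equal length")
  if (length(strain) == 0L) stopf("curve must contain at least one point")
  if (any(!is.finite(strain)) || any(!is.finite(stress)))
    stopf("strain and stress must be finite")
  if (any(diff(strain) <= 0)) stopf("strain must be strictly increasing")
  if (strain[1L] < 0) stopf("strain must start at or above 0")
  if (strain[1L] == 0 && stress[1L] != 0)
    stopf("stress at zero strain must be 0")
  structure(data.frame(strain = as.numeric(strain), stress = as.numeric(stress)),
            class = c("stress_strain_curve", "data.frame"))
}

#' Macroscopic tissue stress for one incremental stretch
#'
#' The tissue stress at the next strain step is the effective tensile modulus
#' times the unweighted ensemble mean of the per-wall updated strains: the
#' printed closed form of [wall_strain_update] wherever the wall's
#' energy-stationary rotation is interior, and the strain implied by the
#' affine projection constraint at the clamped rotation otherwise (a wall
#' whose rotation has stalled elongates by exactly the macroscopic
#' increment). For a fully aligned ensemble this is exactly
#' \code{Y_ae * (d_eps + mean(eps))} — an arbitrary number of linear walls in
#' parallel, the asymptotic linear regime whose slope identifies \code{Y_ae}.
#'
#' @param state a [init_ensemble] wall ensemble.
#' @param moduli a [tissue_moduli] object.
#' @param d_eps incremental macroscopic strain (> 0).
#' @return Tissue stress (kPa) at the strain reached after this increment.
#' @export
tissue_stress <- function(state, moduli, d_eps) {
  if (!inherits(state, "wall_ensemble")) stopf("'state' must be a wall_ensemble")
  if (state$n_walls < 1L) stopf("empty wall ensemble")
  moduli <- as_tissue_moduli(moduli)
  check_number(d_eps, "d_eps", lower = 0, strict_lower = TRUE)
  check_wall_args(state$theta0, state$theta, state$eps)
  moduli$y_ae *
    mean(wall_step(state$theta0, state$theta, state$eps, moduli, d_eps)$eps)
}

#' Simulate a macroscopic stress-strain curve
#'
#' Iterates the per-wall energy-minimizing alignment/elongation update over
#' small macroscopic strain increments: at each step every wall's angle and
#' strain are advanced jointly to the clamped energy-stationary configuration
#' ([wall_angle_update]; the strain equals [wall_strain_update] wherever the
#' rotation is interior) and the tissue stress at the new strain is the
#' effective tensile modulus times the mean updated wall strain
#' ([tissue_stress]).
#' The strain grid is \code{0, d_eps, 2 d_eps, ...} up to
#' \code{config$max_strain}, with a final partial step when \code{max_strain}
#' is not a multiple of \code{d_eps}; stress at zero strain is 0.
#'
#' @param config a [simulation_config].
#' @param moduli a [tissue_moduli] object.
#' @param snapshot_strains optional strains at which to record the full wall
#'   microstate (angles and strains per wall); each is matched to the first
#'   grid strain at or beyond it.
#' @return A list of class \code{"alveo_simulation"}: \code{curve} (a
#'   [stress_strain_curve]), \code{snapshots} (data.frame with columns
#'   \code{strain, wall_id, theta0, theta, eps}; empty if none requested),
#'   \code{final_state}, \code{config}, \code{moduli}.
#' @examples
#' sim <- simulate_curve(simulation_config(n_walls = 500, max_strain = 0.3),
#'                       tissue_moduli(4.36, 0.114))
#' head(sim$curve)
#' @export
simulate_curve <- function(config, moduli, snapshot_strains = NULL) {
  if (!inherits(config, "simulation_config"))
    stopf("'config' must be a simulation_config object")
  moduli <- as_tissue_moduli(moduli)

  n_full <- floor(config$max_strain / config$d_eps + 1e-9)
  steps <- rep(config$d_eps, n_full)
  rem <- config$max_strain - n_full * config$d_eps
  if (rem > 1e-12) steps <- c(steps, rem)
  strain_grid <- c(0, cumsum(steps))

  state <- init_ensemble(config)
  stress <- numeric(length(strain_grid))
  snaps <- vector("list", length(snapshot_strains))
  snap_due <- if (is.null(snapshot_strains)) numeric(0) else
    vapply(snapshot_strains, function(s) {
      i <- which(strain_grid >= s - 1e-12)[1L]
      if (is.na(i)) stopf("snapshot strain %g beyond max_strain", s)
      strain_grid[i]
    }, numeric(1))

  record <- function(at) {
    data.frame(strain = at, wall_id = seq_len(state$n_walls),
               theta0 = state$theta0, theta = state$theta, eps = state$eps)
  }
  hit <- which(abs(snap_due - 0) < 1e-12)
  for (h in hit) snaps[[h]] <- record(0)

  for (s in seq_along(steps)) {
    d <- steps[s]
    upd <- wall_step(state$theta0, state$theta, state$eps, moduli, d)
    stress[s + 1L] <- moduli$y_ae * mean(upd$eps)
    state$eps <- upd$eps
    state$theta <- upd$theta
    hit <- which(abs(snap_due - strain_grid[s + 1L]) < 1e-12)
    for (h in hit) snaps[[h]] <- record(strain_grid[s + 1L])
  }

  snapshots <- if (length(snaps)) do.call(rbind, snaps) else
    data.frame(strain = numeric(0), wall_id = integer(0), theta0 = numeric(0),
               theta = numeric(0), eps = numeric(0))
  structure(list(curve = stress_strain_curve(strain_grid, stress),
                 snapshots = snapshots, final_state = state,
                 config = config, moduli = moduli),
            class = "alveo_simulation")
}

#' @export
print.alveo_simulation <- function(x, ...) {
  cat(sprintf(
    "Wall-ensemble simulation: %d walls, %d strain points to %.3g, peak stress %.4g kPa\n",
    x$config$n_walls, nrow(x$curve), max(x$curve$strain), max(x$curve$stress)))
  invisible(x)
}

#' Normalize a curve by its stress at maximum strain
#'
#' @param curve a [stress_strain_curve].
#' @return The curve with stress divided by its terminal value.
#' @export
normalize_curve <- function(curve) {
  if (!inherits(curve, "stress_strain_curve"))
    stopf("'curve' must be a stress_strain_curve")
  terminal <- curve$stress[nrow(curve)]
  if (terminal <= 0) stopf("terminal stress must be positive to normalize")
  stress_strain_curve(curve$strain, curve$stress / terminal)
}

#' Sensitivity of simulated stress to the two moduli
#'
#' For each fractional perturbation applied to \code{Y_ae} and, separately, to
#' \code{Y_be}, the percent change in stress relative to the baseline curve is
#' reported at every positive strain on the grid (the zero-strain row, where
#' baseline stress is 0, is omitted). Raising \code{Y_ae} stiffens the tissue
#' at all strains, with the largest effect at high strain where the aligned
#' walls carry the load. Raising \code{Y_be} also stiffens the response, but
#' almost entirely at low strain: stiffer bonds block the soft alignment path
#' and force early elongation (the initial slope is
#' \code{Y_ae * mean(1 / (1 + (Y_ae/Y_be) tan^2 theta0))}, increasing in
#' \code{Y_be}), while once walls are aligned the bending modulus has no
#' further influence and its effect decays toward zero.
#'
#' @param base_moduli a [tissue_moduli] baseline.
#' @param fractional_perturbations numeric vector of fractional changes
#'   (e.g. \code{c(0.1, 0.2, 0.4)}); each must exceed -1.
#' @param config a [simulation_config].
#' @return data.frame with columns \code{parameter} ("y_ae" or "y_be"),
#'   \code{perturbation}, \code{strain}, \code{pct_change}.
#' @export
sensitivity_scan <- function(base_moduli, fractional_perturbations, config) {
  base_moduli <- as_tissue_moduli(base_moduli)
  if (any(fractional_perturbations <= -1))
    stopf("fractional perturbations must be > -1")
  base <- simulate_curve(config, base_moduli)$curve
  keep <- base$strain > 0
  rows <- list()
  for (par in c("y_ae", "y_be")) {
    for (f in fractional_perturbations) {
      m <- base_moduli
      m[[par]] <- m[[par]] * (1 + f)
      pert <- simulate_curve(config, tissue_moduli(m$y_ae, m$y_be))$curve
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, perturbation = f, strain = base$strain[keep],
        pct_change = 100 * (pert$stress[keep] - base$stress[keep]) /
          base$stress[keep])
    }
  }
  do.call(rbind, rows)
}
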