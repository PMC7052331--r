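#' Read a stress-strain curve from CSV
#'
#' Expects a header \code{strain,stress_kPa} (a plain \code{stress} column is
#' also accepted); lines starting with \code{#} are ignored. Parse problems
#' are reported with the offending line.
#'
#' @param path CSV file path.
#' @return A [stress_strain_curve].
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", strip.white = TRUE),
    error = function(e) stopf("malformed CSV %s: %s", path, conditionMessage(e)))
  stress_col <- intersect(c("stress_kPa", "stress"), names(df))[1L]
  if (!"strain" %in% names(df) || is.na(stress_col))
    stopf("%s: expected columns 'strain' and 'stress_kPa'", path)
  strain <- suppressWarnings(as.numeric(df$strain))
  stress <- suppressWarnings(as.numeric(df[[stress_col]]))
  bad <- which(!is.finite(strain) | !is.finite(stress))
  if (length(bad))
    stopf("%s: non-numeric value on data line %d", path, bad[1L])
  if (anyDuplicated(strain))
    stopf("%s: duplicate strain value on data line %d", path,
          anyDuplicated(strain))
  stress_strain_curve(strain, stress)
}

#' Write a stress-strain curve to CSV
#'
#' Header \code{strain,stress_kPa}, one row per point, full float precision.
#'
#' @param curve a [stress_strain_curve].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  curve <- as_curve(curve)
  df <- data.frame(strain = format(curve$strain, digits = 17, trim = TRUE),
                   stress_kPa = format(curve$stress, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write wall-ensemble snapshots to CSV
#'
#' Columns \code{strain,wall_id,theta0,theta,eps}.
#'
#' @param snapshots the \code{snapshots} data.frame of an [simulate_curve]
#'   result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_snapshots_csv <- function(snapshots, path) {
  need <- c("strain", "wall_id", "theta0", "theta", "eps")
  if (!all(need %in% names(snapshots)))
    stopf("snapshots must have columns %s", paste(need, collapse = ", "))
  utils::write.csv(snapshots[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit report as JSON
#'
#' Fields \code{y_ae_kpa}, \code{y_be_kpa}, \code{sse}, \code{converged},
#' \code{n_iterations}, plus a \code{derived} block (\code{y_a_kpa},
#' \code{y_b_kpa}, \code{y_f_kpa} and the fractions) when volume fractions
#' are supplied.
#'
#' @param fit an [fit_moduli] result.
#' @param path output path.
#' @param fractions optional [volume_fractions].
#' @return \code{path}, invisibly.
#' @export
write_fit_report <- function(fit, path, fractions = NULL) {
  if (!inherits(fit, "alveo_fit")) stopf("'fit' must be an alveo_fit")
  report <- list(y_ae_kpa = fit$moduli$y_ae, y_be_kpa = fit$moduli$y_be,
                 sse = fit$sse, converged = fit$converged,
                 n_iterations = fit$n_iterations, y_be_flat = fit$y_be_flat)
  if (!is.null(fractions)) {
    d <- derived_moduli(fit$moduli, fractions)
    report$derived <- list(y_a_kpa = d$y_a, y_b_kpa = d$y_b, y_f_kpa = d$y_f,
                           delta_v_w = fractions$delta_v_w,
                           delta_v_f = fractions$delta_v_f)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a cohort to disk
#'
#' One curve CSV per sample plus a manifest CSV
#' (\code{sample_id,group,path,true_y_ae,true_y_be}).
#'
#' @param cohort a [generate_cohort] result.
#' @param dir output directory (created if absent).
#' @return Manifest path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    p <- file.path(dir, paste0(s$sample_id, ".csv"))
    write_curve_csv(s$curve, p)
    data.frame(sample_id = s$sample_id, group = s$group, path = p,
               true_y_ae = s$truth$y_ae, true_y_be = s$truth$y_be)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  invisible(manifest)
}

#' Write hexagonal network geometry to CSV
#'
#' Two files: \code{<stem>_nodes.csv} (\code{node_id,x,y,left,right}) and
#' \code{<stem>_springs.csv} (\code{spring_id,from,to,l0}).
#'
#' @param network a [build_hex_lattice] network.
#' @param stem output path stem.
#' @return Character vector of the two paths, invisibly.
#' @export
write_network_csv <- function(network, stem) {
  if (!inherits(network, "hex_network")) stopf("'network' must be a hex_network")
  nodes_path <- paste0(stem, "_nodes.csv")
  springs_path <- paste0(stem, "_springs.csv")
  nn <- nrow(network$nodes)
  utils::write.csv(data.frame(
    node_id = seq_len(nn), x = network$nodes[, 1L], y = network$nodes[, 2L],
    left = seq_len(nn) %in% network$left_boundary,
    right = seq_len(nn) %in% network$right_boundary),
    nodes_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(cbind(spring_id = seq_len(nrow(network$springs)),
                         network$springs),
                   springs_path, row.names = FALSE, quote = FALSE)
  invisible(c(nodes_path, springs_path))
}
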