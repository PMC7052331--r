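#' Fit every sample of a cohort
#'
#' @param cohort a [generate_cohort] result (or any list whose elements carry
#'   \code{sample_id}, \code{group}, \code{curve} and optionally \code{truth}).
#' @param config a [simulation_config] for the fits.
#' @return data.frame with one row per sample: \code{sample_id}, \code{group},
#'   \code{y_ae}, \code{y_be}, \code{sse}, \code{converged}, and when truth is
#'   available \code{true_y_ae}, \code{true_y_be}.
#' @export
fit_cohort <- function(cohort, config = simulation_config()) {
  rows <- lapply(cohort, function(s) {
    fit <- fit_moduli(s$curve, config)
    row <- data.frame(sample_id = s$sample_id, group = s$group,
                      y_ae = fit$moduli$y_ae, y_be = fit$moduli$y_be,
                      sse = fit$sse, converged = fit$converged)
    if (!is.null(s$truth)) {
      row$true_y_ae <- s$truth$y_ae
      row$true_y_be <- s$truth$y_be
    }
    row
  })
  do.call(rbind, rows)
}

#' Group summary of fitted moduli
#'
#' Mean and standard error of the fitted moduli per group, with percent change
#' relative to a baseline group and two-sided t-test p-values against it —
#' the standard reporting shape for cohort comparisons of fitted parameters.
#'
#' @param fits data.frame from [fit_cohort].
#' @param baseline baseline group label (default: first group encountered).
#' @param paired use a paired t-test (groups must then be equally sized,
#'   ordered pairwise).
#' @return data.frame with one row per group and modulus: \code{group},
#'   \code{modulus}, \code{mean}, \code{se}, \code{n}, \code{pct_change},
#'   \code{p_value} (NA for the baseline rows). Groups of size 1 yield NA
#'   statistics with a warning.
#' @export
group_stats <- function(fits, baseline = NULL, paired = FALSE) {
  groups <- unique(fits$group)
  if (is.null(baseline)) baseline <- groups[1L]
  if (!baseline %in% groups) stopf("baseline group '%s' not present", baseline)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- list()
  for (mod in c("y_ae", "y_be")) {
    base_vals <- fits[[mod]][fits$group == baseline]
    for (g in groups) {
      vals <- fits[[mod]][fits$group == g]
      if (length(vals) < 2L) {
        warning(sprintf("group '%s' has < 2 samples; statistics suppressed", g),
                call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, modulus = mod, mean = mean(vals), se = NA_real_,
          n = length(vals), pct_change = NA_real_, p_value = NA_real_)
        next
      }
      p <- if (g == baseline) NA_real_ else
        group_compare(base_vals, vals, paired = paired)
      pc <- if (g == baseline) NA_real_ else
        percent_change(mean(base_vals), mean(vals))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, modulus = mod, mean = mean(vals), se = se(vals),
        n = length(vals), pct_change = pc, p_value = p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
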