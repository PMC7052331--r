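#' Effective tissue moduli
#'
#' Bundle the two effective elastic moduli of the tissue: the effective wall
#' tensile modulus \code{Y_ae} and the effective wall-wall bond-bending modulus
#' \code{Y_be}, both in kPa. "Effective" means the per-wall modulus scaled by
#' the wall volume fraction of the tissue, so that the pair applies directly to
#' bulk tissue stress. The ratio \code{Y_ae / Y_be} controls how much of an
#' imposed macroscopic strain is accommodated by wall alignment (rotation
#' toward the stretch axis) versus wall elongation, and hence how strongly the
#' simulated stress-strain curve strain-stiffens.
#'
#' @param y_ae effective wall tensile modulus (kPa), strictly positive.
#' @param y_be effective bond-bending modulus (kPa), strictly positive.
#' @return An object of class \code{"tissue_moduli"}: a list with elements
#'   \code{y_ae} and \code{y_be}.
#' @examples
#' tissue_moduli(4.36, 0.114)
#' @export
tissue_moduli <- function(y_ae, y_be) {
  check_number(y_ae, "y_ae", lower = 0, strict_lower = TRUE)
  check_number(y_be, "y_be", lower = 0, strict_lower = TRUE)
  structure(list(y_ae = as.numeric(y_ae), y_be = as.numeric(y_be)),
            class = "tissue_moduli")
}

#' @export
print.tissue_moduli <- function(x, ...) {
  cat(sprintf("Effective tissue moduli: Y_ae = %g kPa, Y_be = %g kPa (ratio %g)\n",
              x$y_ae, x$y_be, x$y_ae / x$y_be))
  invisible(x)
}

as_tissue_moduli <- function(x, name = "moduli") {
  if (inherits(x, "tissue_moduli")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(tissue_moduli(x[[1L]], x[[2L]]))
  if (is.list(x) && all(c("y_ae", "y_be") %in% names(x)))
    return(tissue_moduli(x$y_ae, x$y_be))
  stopf("'%s' must be a tissue_moduli object or a length-2 numeric (y_ae, y_be)",
        name)
}

#' Volume fractions linking tissue, wall and fiber scales
#'
#' @param delta_v_w fraction of tissue volume occupied by alveolar walls,
#'   in (0, 1].
#' @param delta_v_f fraction of wall volume occupied by load-bearing fiber
#'   (collagen plus elastin), in (0, 1].
#' @return An object of class \code{"volume_fractions"}.
#' @examples
#' # morphometric literature values for mouse parenchyma
#' volume_fractions(delta_v_w = 0.35, delta_v_f = 0.04)
#' @export
volume_fractions <- function(delta_v_w, delta_v_f) {
  check_number(delta_v_w, "delta_v_w", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(delta_v_f, "delta_v_f", lower = 0, upper = 1, strict_lower = TRUE)
  structure(list(delta_v_w = as.numeric(delta_v_w),
                 delta_v_f = as.numeric(delta_v_f)),
            class = "volume_fractions")
}

#' Per-wall and per-fiber moduli from effective tissue moduli
#'
#' Undo the volume-fraction scaling: the wall tensile modulus is
#' \code{Y_a = Y_ae / delta_v_w}, the wall bond-bending modulus is
#' \code{Y_b = Y_be / delta_v_w}, and — assuming the fibers carry essentially
#' all of the wall's tensile load — the mean tensile modulus of a single fiber
#' is \code{Y_f = Y_a / delta_v_f = Y_ae / (delta_v_w * delta_v_f)}.
#'
#' @param moduli a [tissue_moduli] object (effective moduli, kPa).
#' @param fractions a [volume_fractions] object.
#' @return An object of class \code{"derived_moduli"}: list with \code{y_a},
#'   \code{y_b}, \code{y_f} (kPa).
#' @examples
#' derived_moduli(tissue_moduli(4.36, 0.114), volume_fractions(0.35, 0.04))
#' @export
derived_moduli <- function(moduli, fractions) {
  moduli <- as_tissue_moduli(moduli)
  if (!inherits(fractions, "volume_fractions"))
    stopf("'fractions' must be a volume_fractions object")
  structure(list(
    y_a = moduli$y_ae / fractions$delta_v_w,
    y_b = moduli$y_be / fractions$delta_v_w,
    y_f = moduli$y_ae / (fractions$delta_v_w * fractions$delta_v_f)
  ), class = "derived_moduli")
}

#' @export
print.derived_moduli <- function(x, ...) {
  cat(sprintf("Wall moduli: Y_a = %g kPa, Y_b = %g kPa; fiber modulus Y_f = %g kPa\n",
              x$y_a, x$y_b, x$y_f))
  invisible(x)
}

#' Percent change between two group means
#'
#' Convenience used in group summary tables: \code{100 * (to - from) / from}.
#'
#' @param from baseline value (nonzero).
#' @param to comparison value.
#' @return Percent change (numeric, vectorized).
#' @export
percent_change <- function(from, to) {
  if (any(from == 0)) stopf("'from' must be nonzero")
  100 * (to - from) / from
}
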