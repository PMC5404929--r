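#' ApoE twist angle of a pore shape
#'
#' The pore is a toroid of waist radius \code{r_po} and rim membrane
#' separation \code{h} formed between the disc and the planar membrane.
#' Small pores are fully toroidal.  When \code{r_po + h/2 + delta >= D/2}
#' the toroid no longer fits inside the disc: the shape is truncated at the
#' disc rim and the scaffold proteins there must rotate by a twist angle
#' phi = asin((r_po + h/2 + delta - D/2) / (h/2)).
#'
#' @param r_po pore (waist) radius, nm
#' @param h membrane separation parameter, nm (vectorised)
#' @param params a \code{\link{model_params}} object
#' @return twist angle in radians, 0 for fully toroidal shapes
#' @export
twist_angle <- function(r_po, h, params) {
  arg <- (r_po + h / 2 + params$delta - params$D / 2) / (h / 2)
  if (any(arg > 1 + 1e-12))
    stop("invalid pore shape: r_po + h/2 + delta exceeds D/2 by more than h/2 ",
         "(no truncated toroid exists for this (r_po, h))", call. = FALSE)
  ifelse(arg <= 0, 0, asin(pmin(pmax(arg, -1), 1)))
}

#' Geometric description of a pore shape
#'
#' Resolves the toroidal shape parameters into the quantities the energy
#' terms use: midplane semicircle radius \code{H = h/2 + delta/2}, midplane
#' waist radius \code{R = r_po + delta/2}, twist angle \code{phi}, regime,
#' and the membrane separation at the disc rim \code{h_po}, which equals
#' \code{h} for toroidal shapes and \code{(h/2)(1 + cos(phi))} for partially
#' toroidal ones.
#'
#' @inheritParams twist_angle
#' @param h membrane separation parameter, nm (scalar here)
#' @return an object of class \code{"pore_shape"}
#' @export
pore_shape <- function(r_po, h, params) {
  stopifnot(length(r_po) == 1L, length(h) == 1L)
  if (!is.finite(r_po) || r_po <= 0) stop("r_po must be positive", call. = FALSE)
  if (!is.finite(h) || h < 0) stop("h must be non-negative", call. = FALSE)
  phi <- twist_angle(r_po, h, params)
  s <- list(r_po = r_po, h = h, phi = phi,
            regime = if (phi > 0) "partial" else "toroidal",
            H = h / 2 + params$delta / 2,
            R = r_po + params$delta / 2,
            h_po = if (phi > 0) (h / 2) * (1 + cos(phi)) else h)
  class(s) <- "pore_shape"
  s
}

#' @export
print.pore_shape <- function(x, ...) {
  cat(sprintf("pore shape: r_po = %.3g nm, h = %.3g nm (%s", x$r_po, x$h, x$regime))
  if (x$regime == "partial")
    cat(sprintf(", phi = %.3f rad, h_po = %.3g nm", x$phi, x$h_po))
  cat(")\n")
  invisible(x)
}
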