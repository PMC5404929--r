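# Staged derivation of best-fit model parameters against a reference
# free-energy curve.  The recipe is deliberately sequential, mirroring how
# the membrane parameters are identified before the SNARE and scaffold
# parameters: (1) hydration decay length from the minimum position and
# membrane tension from the slope just beyond it, on a SNARE-free curve;
# (2) zippering energy from the slope of a many-SNARE curve; (3) scaffold
# torque from the slope in the partially toroidal window.  All slope
# matching is least squares on finite-difference slopes over the stated
# window, optimised by golden-section search with fixed tolerance.

fit_result <- function(parameter, value, units, window, residual, reference_id) {
  structure(list(parameter = parameter, value = value, units = units,
                 window = window, residual = residual,
                 reference_id = reference_id),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit: %s = %.4g %s (window %.3g-%.3g nm, residual %.3g)\n",
              x$parameter, x$value, x$units, x$window[1L], x$window[2L],
              x$residual))
  invisible(x)
}

# finite-difference slopes of a curve restricted to a window
.window_slopes <- function(r, U, window) {
  w <- r >= window[1L] - 1e-9 & r <= window[2L] + 1e-9
  if (sum(w) < 3)
    stop(sprintf("fewer than 3 reference points in window [%g, %g] nm",
                 window[1L], window[2L]), call. = FALSE)
  list(r = r[w], slopes = diff(U[w]) / diff(r[w]))
}

# model slopes at the same abscissae as the reference window
.model_slopes <- function(r, N, params, ...) {
  U <- vapply(r, free_energy, numeric(1), N = N, params = params, ...)
  diff(U) / diff(r)
}

.slope_mismatch <- function(r, ref_slopes, N, params, ...) {
  sum((.model_slopes(r, N, params, ...) - ref_slopes)^2)
}

#' Fit hydration decay length and membrane tension to a SNARE-free curve
#'
#' Stage one of the fitting recipe.  The hydration decay length
#' \code{lam_hyd} controls where the short-range repulsive wall sits and is
#' adjusted so the model's minimum-energy radius matches the reference's;
#' the membrane tension \code{gamma} largely determines the slope just
#' beyond the minimum and is then adjusted to match the reference slope on
#' \code{slope_window}.  The bending modulus is held fixed.
#'
#' @param reference a \code{\link{free_energy_profile}} (model-generated or
#'   read from a table) for a SNARE-free-comparable pore, with a single
#'   interior minimum
#' @param params0 starting \code{\link{model_params}}
#' @param lam_range,gamma_range search intervals.  The gamma upper bound
#'   deliberately stays in the physiological range: beyond ~1.5 pN/nm the
#'   window slope becomes non-monotone in the tension (high tension clamps
#'   the membrane separation to its minimum, reshaping the landscape), and
#'   the slope match would acquire a second, unphysical solution branch.
#' @param slope_window radius window (nm) for the tension slope match
#' @param tol optimizer tolerance in parameter units
#' @param reference_id label stored in the results
#' @return list with elements \code{lam_hyd} and \code{gamma}, each a
#'   \code{fit_result}, plus \code{params}: \code{params0} updated with the
#'   fitted values
#' @export
fit_hydration_and_tension <- function(reference, params0,
                                      lam_range = c(0.03, 0.3),
                                      gamma_range = c(0.05, 1.5),
                                      slope_window = c(0.5, 1.0),
                                      tol = 1e-3,
                                      reference_id = "reference") {
  stopifnot(inherits(reference, "free_energy_profile"))
  i <- which.min(reference$U)
  if (i == 1L || i == nrow(reference))
    stop("reference curve has no interior minimum", call. = FALSE)
  target <- argmin_refined(reference$r_po, reference$U)

  # local grid around the target on which the model argmin is located
  am_grid <- seq(max(0.15, target - 0.75), target + 0.75, by = 0.025)
  model_argmin <- function(lam) {
    p <- params0; p$lam_hyd <- lam
    U <- vapply(am_grid, free_energy, numeric(1), N = 0, params = p)
    argmin_refined(am_grid, U)
  }
  opt1 <- stats::optimize(function(lam) (model_argmin(lam) - target)^2,
                          lam_range, tol = tol)
  p1 <- params0; p1$lam_hyd <- opt1$minimum

  ref <- .window_slopes(reference$r_po, reference$U, slope_window)
  opt2 <- stats::optimize(function(g) {
    p <- p1; p$gamma <- g
    .slope_mismatch(ref$r, ref$slopes, 0, p)
  }, gamma_range, tol = tol)
  p2 <- p1; p2$gamma <- opt2$minimum

  list(lam_hyd = fit_result("lam_hyd", opt1$minimum, "nm",
                            range(am_grid), sqrt(opt1$objective), reference_id),
       gamma = fit_result("gamma", opt2$minimum, "pN/nm",
                          slope_window, opt2$objective, reference_id),
       params = p2)
}

#' Fit the zippering energy to a many-SNARE curve
#'
#' Stage two: with the membrane parameters fixed, the zippering energy
#' \code{eps_zip} sets how strongly SNARE crowding flattens the profile
#' beyond the minimum.  It is fitted by matching finite-difference slopes
#' on \code{window} (default 0.5-2.5 nm) for the given SNARE count.
#'
#' @param reference a \code{\link{free_energy_profile}} for a pore with
#'   \code{N} SNAREs per face
#' @param N SNARE count of the reference (must be >= 1)
#' @param params \code{\link{model_params}} with membrane parameters fixed
#' @param window radius window, nm
#' @param bounds allowed \code{eps_zip} range, kT
#' @param tol optimizer tolerance, kT
#' @param reference_id label stored in the result
#' @return a \code{fit_result}
#' @export
fit_zippering <- function(reference, N, params, window = c(0.5, 2.5),
                          bounds = c(0, 30), tol = 1e-3,
                          reference_id = "reference") {
  stopifnot(inherits(reference, "free_energy_profile"))
  if (N < 1) stop("zippering energy is not identifiable at N = 0", call. = FALSE)
  ref <- .window_slopes(reference$r_po, reference$U, window)
  opt <- stats::optimize(function(eps) {
    p <- params; p$eps_zip <- eps
    .slope_mismatch(ref$r, ref$slopes, N, p)
  }, bounds, tol = tol)
  fit_result("eps_zip", opt$minimum, "kT", window, opt$objective, reference_id)
}

#' Fit the scaffold torque to the partially toroidal window
#'
#' Stage three: in the window where the pore shape is constrained by the
#' disc edge (default 4-4.5 nm) the slope is controlled by the torque per
#' unit length \code{tau} resisting scaffold twisting.  Errors if the
#' window lies inside the fully toroidal range, where \code{tau} has no
#' effect.
#'
#' @inheritParams fit_zippering
#' @param N SNARE count of the reference (default 4)
#' @param bounds allowed \code{tau} range, pN
#' @return a \code{fit_result}
#' @export
fit_torque <- function(reference, N = 4, params, window = c(4.0, 4.5),
                       bounds = c(0, 40), tol = 1e-3,
                       reference_id = "reference") {
  stopifnot(inherits(reference, "free_energy_profile"))
  if (largest_toroidal_radius(params) >= window[2L])
    stop("the fitting window lies in the fully toroidal regime; ",
         "the scaffold torque is not identifiable there", call. = FALSE)
  ref <- .window_slopes(reference$r_po, reference$U, window)
  opt <- stats::optimize(function(tau) {
    p <- params; p$tau <- tau
    .slope_mismatch(ref$r, ref$slopes, N, p)
  }, bounds, tol = tol)
  fit_result("tau", opt$minimum, "pN", window, opt$objective, reference_id)
}

#' Zippering-energy shift for lipid-anchored SNAREs
#'
#' Mimics replacing the v-SNARE transmembrane domain with a lipid anchor:
#' the membrane footprint of the zippered rod in the ring excluded-volume
#' term is reduced by \code{reduction} (default 50%, the maximal case),
#' and the zippering energy is lowered by bisection until the
#' Boltzmann-mean pore radius at \code{N} SNAREs matches the unmodified
#' model.  Returns the required decrease in \code{eps_zip}.
#'
#' @param params a \code{\link{model_params}}
#' @param N SNARE count (default 15 per face)
#' @param reduction fractional footprint reduction of the zippered rod
#' @param grid radius grid for the mean-radius computation
#' @param bounds search interval for the decrease, kT
#' @param tol bisection tolerance, kT
#' @return the decrease in \code{eps_zip}, kT (positive)
#' @export
lipid_anchor_delta <- function(params, N = 15, reduction = 0.5,
                               grid = default_radius_grid(),
                               bounds = c(0, 5), tol = 0.01) {
  stopifnot(N >= 1, reduction >= 0, reduction < 1)
  mean_r <- function(p) {
    prof <- suppressWarnings(free_energy_profile(grid, N, p))
    suppressWarnings(boltzmann_mean_radius(prof))
  }
  r_ref <- mean_r(params)
  if (reduction == 0) return(0)
  ph <- params
  ph$b_zip <- params$b_snare * (1 - reduction)
  f <- function(de) { q <- ph; q$eps_zip <- params$eps_zip - de; mean_r(q) - r_ref }
  lo <- bounds[1L]; hi <- bounds[2L]
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0)
    stop("no zippering-energy shift in the search interval restores the mean radius",
         call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) * flo > 0) { lo <- mid } else hi <- mid
  }
  (lo + hi) / 2
}
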