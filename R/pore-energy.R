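# Energy terms of one fusion-pore state, all in kT.
#
# Geometry conventions: the membrane midplane of the pore wall is the
# surface of revolution of a (possibly truncated) semicircle of radius
# H = h/2 + delta/2 whose waist sits at R = r_po + delta/2 from the axis,
# i.e. x(theta) = (R + H) - H cos(theta), z(theta) = H sin(theta),
# theta in [-pi/2, theta_c] with theta_c = pi/2 - phi.  All areas and
# curvature integrals are evaluated over this midplane.
#
# Bending uses the Helfrich form kappa * integral C^2 dA with C the mean
# curvature (c1 + c2)/2; see the methods vignette for the convention.

# antiderivative piece of integral dtheta / (a - H cos theta), a = R + H
.tor_F <- function(theta, R, H) {
  2 / sqrt(R * (R + 2 * H)) * atan(sqrt((R + 2 * H) / R) * tan(theta / 2))
}

# closed-form kappa * int C^2 dA over the (truncated) toroid midplane, in kT
.bend_closed <- function(R, H, theta_c, kappa) {
  a <- R + H
  Jc <- .tor_F(theta_c, R, H) + .tor_F(pi / 2, R, H)
  0.5 * kappa * pi * (a^2 * Jc / H - 4 * (1 + sin(theta_c)))
}

# membrane area change Delta A = A_pore_wall - A_rims, nm^2
# toroidal: wall = 2 pi H (pi a - 2 H); rims = two discs of radius a.
# partial (truncated at theta_c = pi/2 - phi): wall loses the top segment;
# the disc-side rim is the whole disc face, the planar side keeps radius a.
.area_change <- function(R, H, phi, D) {
  a <- R + H
  ifelse(phi == 0,
         2 * pi * H * (pi * a - 2 * H) - 2 * pi * a^2,
         2 * pi * H * (a * (pi - phi) - H * (1 + cos(phi))) -
           pi * a^2 - pi * (D / 2)^2)
}

# all membrane-level terms, vectorised over h; returns energies in kT and
# a 'bad' flag for (r_po, h) with no admissible shape
membrane_energy_terms <- function(r_po, h, params) {
  p <- params
  H <- h / 2 + p$delta / 2
  R <- r_po + p$delta / 2
  arg <- (r_po + h / 2 + p$delta - p$D / 2) / (h / 2)
  bad <- arg > 1
  phi <- ifelse(arg <= 0, 0, asin(pmin(pmax(arg, -1), 1)))
  theta_c <- pi / 2 - phi
  bend <- .bend_closed(R, H, theta_c, p$kappa)
  tension <- (p$gamma / p$kT_pN_nm) * .area_change(R, H, phi, p$D)
  # steric hydration: flat-flat term + pore-rim term, toroidal states only
  l <- 2 * sqrt(p$lam_hyd * (h / 2 + p$delta))
  P0 <- p$P0_pN_nm2 / p$kT_pN_nm           # kT / nm^3
  hyd <- ifelse(phi == 0,
                P0 * (p$lam_hyd * (pi * p$D^2 / 4) * exp(-h / p$lam_hyd) +
                        2 * pi * l * exp(-2 * r_po / p$lam_hyd) *
                        (p$lam_hyd * r_po / 2 + (p$lam_hyd / 2)^2)),
                0)
  apoe <- (p$tau / p$kT_pN_nm) * pi * p$D * phi
  list(bend = bend, tension = tension, hyd = hyd, apoe = apoe,
       phi = phi, bad = bad)
}

#' Membrane bending and tension energy of a pore shape
#'
#' Bending is the Helfrich curvature energy of the (possibly truncated)
#' toroidal pore wall, evaluated in closed form over the midplane; tension
#' is \code{gamma * Delta A} where \code{Delta A} is the change in total
#' membrane area caused by forming the pore (wall area minus the rim discs
#' it replaces).  Both are continuous across the toroidal/partial boundary.
#'
#' @param shape a \code{\link{pore_shape}}
#' @param params a \code{\link{model_params}}
#' @return named numeric vector \code{c(bend =, tension =)} in kT
#' @export
membrane_energy <- function(shape, params) {
  stopifnot(inherits(shape, "pore_shape"))
  e <- membrane_energy_terms(shape$r_po, shape$h, params)
  if (e$bad) stop("invalid pore shape", call. = FALSE)
  c(bend = e$bend, tension = e$tension)
}

#' Steric-hydration energy of a toroidal pore shape
#'
#' Short-ranged exponential repulsion between the apposed bilayers, acting
#' both across the flat disc-membrane gap and across the pore lumen.  Only
#' fully toroidal shapes carry this term (its range, ~0.1 nm, is negligible
#' once the shape reaches the disc rim).
#'
#' @inheritParams membrane_energy
#' @return energy in kT (non-negative)
#' @export
hydration_energy <- function(shape, params) {
  stopifnot(inherits(shape, "pore_shape"))
  if (shape$regime != "toroidal")
    stop("hydration_energy is defined for toroidal shapes only", call. = FALSE)
  membrane_energy_terms(shape$r_po, shape$h, params)$hyd
}

#' ApoE scaffold twisting energy
#'
#' \code{tau * pi * D * phi} in kT: the scaffold proteins lining the disc rim
#' resist rotation with a constant torque per unit length, so partially
#' toroidal shapes pay an energy linear in the twist angle.  Zero for fully
#' toroidal shapes.
#'
#' @inheritParams membrane_energy
#' @return energy in kT
#' @export
apoe_energy <- function(shape, params) {
  stopifnot(inherits(shape, "pore_shape"))
  (params$tau / params$kT_pN_nm) * pi * params$D * shape$phi
}

# per-state SNARE free energy, in kT; returns +Inf for excluded (ring
# over-filled) states so callers assign them zero Boltzmann weight.
# p$b_zip is the membrane footprint of a zippered rod in the excluded-volume
# term; it equals b_snare except in the lipid-anchor variant.
snare_energy_state <- function(r_po, Nz, Nuz, params) {
  p <- params
  bz <- if (is.null(p$b_zip)) p$b_snare else p$b_zip
  if (Nz * bz >= 2 * pi * r_po) return(Inf)
  Uz <- 0
  if (Nz > 0) {
    ring <- log((2 * pi * r_po - Nz * bz) / p$b_snare) + 1
    if (p$ring_stirling) ring <- ring - log(Nz)
    Uz <- -Nz * ring - Nz * p$eps_zip -
      p$tmd_anchors * Nz * log(p$omega_z)
  }
  Uuz <- if (Nuz > 0) -Nuz * (log(2 * pi * p$D / p$b_snare) + log(pi)) else 0
  Uz + Uuz
}

#' SNARE free energy of a zippering state
#'
#' Free energy (in kT) of \code{Nz} fully zippered SNAREpins forming a ring
#' of rods of footprint \code{b_snare} at the pore waist plus \code{Nuz}
#' partially zippered pins roaming the disc, relative to the empty state.
#' The zippered ring contributes one-dimensional positional entropy on the
#' free waist circumference, the zippering energy \code{-eps_zip} per pin,
#' and an orientational confinement penalty per transmembrane anchor; the
#' roaming pins contribute their positional and orientational entropy.
#'
#' States whose ring does not fit (\code{Nz * b_snare >= 2 pi r_po}) are
#' excluded: the function returns \code{Inf}, which downstream Boltzmann
#' sums treat as zero weight.
#'
#' @param r_po pore radius, nm
#' @param Nz number of fully zippered SNAREs
#' @param Nuz number of partially zippered SNAREs
#' @param params a \code{\link{model_params}}
#' @return energy in kT, or \code{Inf} for an excluded state
#' @export
snare_energy <- function(r_po, Nz, Nuz, params) {
  stopifnot(Nz >= 0, Nuz >= 0, r_po > 0)
  snare_energy_state(r_po, Nz, Nuz, params)
}

#' Total free energy of one fusion-pore state
#'
#' Sum of the membrane (bending + tension), steric-hydration (toroidal
#' shapes only), ApoE twisting and SNARE terms for a single microstate
#' \code{(r_po, h, Nz)} with \code{N} SNAREs available.
#'
#' @inheritParams membrane_energy
#' @param N total v-SNAREs on the disc face
#' @param Nz number of fully zippered SNAREs
#' @return energy in kT; \code{Inf} for an excluded SNARE state
#' @export
state_energy <- function(shape, N, Nz, params) {
  stopifnot(inherits(shape, "pore_shape"), Nz <= N)
  e <- membrane_energy_terms(shape$r_po, shape$h, params)
  if (e$bad) stop("invalid pore shape", call. = FALSE)
  e$bend + e$tension + e$hyd + e$apoe +
    snare_energy_state(shape$r_po, Nz, N - Nz, params)
}
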