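# shared oracles and fixture builders (everything is generated in code)

# independent quadrature of the Helfrich bending energy kappa * int C^2 dA
# over the (possibly truncated) toroid midplane, C = (c1 + c2)/2:
# x(theta) = (R+H) - H cos(theta), meridian curvature 1/H, parallel
# curvature -cos(theta)/x, area element x * H dtheta dphi
bend_quadrature <- function(r_po, h, params, phi_twist = 0) {
  H <- h / 2 + params$delta / 2
  R <- r_po + params$delta / 2
  theta_c <- pi / 2 - phi_twist
  f <- function(th) {
    x <- (R + H) - H * cos(th)
    ((1 / H - cos(th) / x) / 2)^2 * x * H
  }
  2 * pi * params$kappa *
    stats::integrate(f, -pi / 2, theta_c, rel.tol = 1e-10)$value
}

# independent quadrature of the pore-wall midplane area
wall_area_quadrature <- function(r_po, h, params, phi_twist = 0) {
  H <- h / 2 + params$delta / 2
  R <- r_po + params$delta / 2
  f <- function(th) ((R + H) - H * cos(th)) * H
  2 * pi * stats::integrate(f, -pi / 2, pi / 2 - phi_twist,
                            rel.tol = 1e-10)$value
}

# area change oracle: wall area minus the rim discs it replaces
area_change_quadrature <- function(r_po, h, params) {
  shape <- pore_shape(r_po, h, params)
  a <- shape$R + shape$H
  wall <- wall_area_quadrature(r_po, h, params, shape$phi)
  if (shape$regime == "toroidal") wall - 2 * pi * a^2
  else wall - pi * a^2 - pi * (params$D / 2)^2
}

# build a profile object from arbitrary (r, U) values for unit tests
fake_profile <- function(r, U, params = model_params(), N = 0L) {
  out <- data.frame(r_po = r, U = U)
  class(out) <- c("free_energy_profile", "data.frame")
  attr(out, "N") <- N
  attr(out, "params") <- params
  attr(out, "argmin") <- r[which.min(U)]
  out
}

# coarse grid used by model tests that do not pin the default grid
coarse_grid <- function(lo = 0.25, hi = 7, by = 0.05) seq(lo, hi, by = by)

# suppress the (expected) range warnings of Boltzmann means on broad
# N = 15 profiles
quiet_bmr <- function(profile) suppressWarnings(boltzmann_mean_radius(profile))
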