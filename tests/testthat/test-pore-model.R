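# the equilibrium pore model: geometry, energy terms, state sum

p_def <- model_params()

test_that("model parameters validate and convert units once", {
  expect_equal(p_def$kT_pN_nm, 1.380649e-2 * 298, tolerance = 1e-12)
  expect_equal(p_def$kT_pN_nm, 4.11, tolerance = 2e-3)
  # 5e11 dyn/cm^2 = 5e10 Pa = 5e4 pN/nm^2
  expect_equal(p_def$P0_pN_nm2, 5e4)
  expect_error(model_params(delta = 30), "smaller than the disc diameter")
  expect_error(model_params(gamma = -1), "positive")
  expect_warning(model_params(lam_hyd = 2), "decay length")
})

test_that("twist angle separates toroidal and partial regimes", {
  expect_identical(twist_angle(1, 2, p_def), 0)      # 1 + 1 + 5 < 12
  expect_equal(twist_angle(6.5, 2, p_def), pi / 6)   # asin(0.5/1)
  expect_error(twist_angle(8, 0.5, p_def), "invalid pore shape")
  # regime boundary from the shape object
  s <- pore_shape(6.5, 2, p_def)
  expect_identical(s$regime, "partial")
  expect_equal(s$h_po, (2 / 2) * (1 + cos(pi / 6)))
  expect_identical(pore_shape(1, 2, p_def)$regime, "toroidal")
})

test_that("closed-form bending and area match independent quadrature", {
  set.seed(42)
  for (k in 1:20) {
    r <- runif(1, 0.3, 6.5)
    h_hi <- 2 * (p_def$D / 2 - p_def$delta - r) + 0.9 * runif(1, 0, 2)
    h <- runif(1, 1, max(1.5, h_hi))
    sh <- pore_shape(r, h, p_def)
    e <- membrane_energy(sh, p_def)
    expect_equal(unname(e["bend"]), bend_quadrature(r, h, p_def, sh$phi),
                 tolerance = 1e-6)
    dA_model <- unname(e["tension"]) / (p_def$gamma / p_def$kT_pN_nm)
    expect_equal(dA_model, area_change_quadrature(r, h, p_def),
                 tolerance = 1e-6)
  }
})

test_that("membrane energy is continuous across the regime boundary", {
  # left/right limits at r + h/2 + delta = D/2 agree to 1e-6 kT
  h <- 6
  r_b <- p_def$D / 2 - p_def$delta - h / 2   # boundary radius = 4
  E <- function(r) {
    sh <- pore_shape(r, h, p_def)
    sum(membrane_energy(sh, p_def)) + apoe_energy(sh, p_def)
  }
  eps <- 1e-9
  expect_equal(E(r_b - eps), E(r_b + eps), tolerance = 1e-6)
  expect_equal(E(r_b), E(r_b + eps), tolerance = 1e-6)
  # and the full free energy crosses the boundary without jumps: the
  # grid-step increments shrink in proportion to the step
  rs_c <- seq(3.0, 4.2, by = 0.05)
  rs_f <- seq(3.0, 4.2, by = 0.01)
  U_c <- vapply(rs_c, free_energy, numeric(1), N = 0, params = p_def)
  U_f <- vapply(rs_f, free_energy, numeric(1), N = 0, params = p_def)
  expect_lt(max(abs(diff(U_f))), max(abs(diff(U_c))) / 2)
})

test_that("hydration energy follows the printed closed form and decays", {
  r <- 0.5; h <- 2
  sh <- pore_shape(r, h, p_def)
  # independent term-by-term evaluation with SI unit conversion
  kT_J <- 1.380649e-23 * 298
  P0_SI <- 5e11 * 0.1                      # dyn/cm^2 -> Pa
  lam <- 0.10e-9; D <- 24e-9; del <- 5e-9
  r_m <- r * 1e-9; h_m <- h * 1e-9
  l <- 2 * sqrt(lam * (h_m / 2 + del))
  U_flat <- P0_SI * lam * (pi * D^2 / 4) * exp(-h_m / lam)
  U_rim <- P0_SI * 2 * pi * l * exp(-2 * r_m / lam) *
    (lam * r_m / 2 + (lam / 2)^2)
  expect_equal(hydration_energy(sh, p_def), (U_flat + U_rim) / kT_J,
               tolerance = 1e-10)
  # monotone decreasing in r at fixed h, and vanishing far away
  hs <- vapply(seq(0.3, 2, 0.1), function(rr)
    hydration_energy(pore_shape(rr, 2, p_def), p_def), numeric(1))
  expect_true(all(diff(hs) < 0))
  expect_lt(hydration_energy(pore_shape(5, 3, p_def), p_def), 1e-6)
  expect_error(hydration_energy(pore_shape(6.5, 2, p_def), p_def),
               "toroidal")
})

test_that("ApoE twisting energy is linear in torque and zero when untwisted", {
  expect_identical(apoe_energy(pore_shape(1, 2, p_def), p_def), 0)
  sh <- pore_shape(6.5, 2, p_def)          # phi = pi/6
  expect_equal(apoe_energy(sh, p_def),
               8.43 * pi * 24 * (pi / 6) / p_def$kT_pN_nm, tolerance = 1e-12)
  p2 <- model_params(tau = 2 * 8.43)
  expect_equal(apoe_energy(sh, p2), 2 * apoe_energy(sh, p_def),
               tolerance = 1e-12)
})

test_that("SNARE ring energy: empty state, derivative, exclusion", {
  expect_identical(snare_energy(2, 0, 0, p_def), 0)
  # entropic expansion force: dUz/dr = -Nz * 2*pi / (2*pi*r - Nz*b)
  r <- 2; Nz <- 3; dr <- 1e-6
  num <- (snare_energy(r + dr, Nz, 0, p_def) -
            snare_energy(r - dr, Nz, 0, p_def)) / (2 * dr)
  expect_equal(num, -Nz * 2 * pi / (2 * pi * r - Nz * p_def$b_snare),
               tolerance = 1e-6)
  # over-filled ring is an excluded state, not an error
  expect_identical(snare_energy(0.5, 2, 0, p_def), Inf)
  # zippering energy enters linearly
  p2 <- model_params(eps_zip = 9.6 + 1.5)
  expect_equal(snare_energy(2, 3, 4, p2),
               snare_energy(2, 3, 4, p_def) - 3 * 1.5, tolerance = 1e-10)
})

test_that("state energy recomposes from its terms", {
  for (r in c(0.6, 2, 5.5)) for (h in c(2.5, 6)) {
    sh <- pore_shape(r, h, p_def)
    expected <- sum(membrane_energy(sh, p_def)) +
      (if (sh$regime == "toroidal") hydration_energy(sh, p_def) else 0) +
      apoe_energy(sh, p_def) + snare_energy(r, 1, 3, p_def)
    expect_equal(state_energy(sh, 4, 1, p_def), expected, tolerance = 1e-12)
  }
})

test_that("free energy state sum: term dropout, quadrature, tail", {
  # N = 0 reduces to the membrane-only integral
  expect_equal(free_energy(1, 0, p_def),
               free_energy(1, 0, model_params(eps_zip = 3)), tolerance = 1e-12)
  # doubling the node count changes U by < 1e-6 kT across the grid
  for (r in c(0.5, 1.5, 3, 4.4, 5.4)) {
    expect_lt(abs(free_energy(r, 0, p_def, n_h = 400) -
                    free_energy(r, 0, p_def, n_h = 800)), 1e-6)
  }
  expect_lt(abs(free_energy(2, 15, p_def, n_h = 400) -
                  free_energy(2, 15, p_def, n_h = 800)), 1e-6)
  # extending h_max does not move U (tail is converged)
  expect_lt(abs(free_energy(2, 0, p_def, h_max = 20) -
                  free_energy(2, 0, p_def, h_max = 26, n_h = 520)), 1e-6)
  # truncating the integral grossly triggers the tail warning
  expect_warning(free_energy(0.5, 0, p_def, h_max = 3.5), "h_max")
})

test_that("SNARE crowding lowers the free energy of expansion", {
  rs <- seq(0.5, 5, 0.25)
  U0 <- vapply(rs, free_energy, numeric(1), N = 0, params = p_def)
  U15 <- vapply(rs, free_energy, numeric(1), N = 15, params = p_def)
  dU <- U15 - U0
  expect_true(all(diff(dU) < 1e-8))   # non-increasing difference
})

test_that("profile minimum, shift invariance and argmin refinement", {
  prof <- free_energy_profile(coarse_grid(), 0, p_def)
  expect_equal(min(prof$U), 0)
  expect_equal(attr(prof, "argmin"), 0.5, tolerance = 0.15)
  # N = 15 minimum barely moves
  prof15 <- free_energy_profile(coarse_grid(), 15, p_def)
  expect_lt(abs(attr(prof15, "argmin") - attr(prof, "argmin")), 0.1)
  # constant shifts leave forces unchanged
  shifted <- fake_profile(prof$r_po, prof$U + 7.3, p_def)
  expect_equal(net_inward_force(shifted, 1.5, 3),
               net_inward_force(prof, 1.5, 3), tolerance = 1e-12)
})

test_that("net inward force converts kT/nm to pN at the model temperature", {
  r <- seq(0.5, 3, 0.05)
  lin <- fake_profile(r, r * 1.0, p_def)   # slope 1 kT/nm
  expect_equal(net_inward_force(lin, 1, 2.5), 4.11, tolerance = 0.01)
  expect_error(net_inward_force(lin, 0.1, 2), "within the profile grid")
})

test_that("mean zippered count respects capacity and saturates", {
  expect_identical(mean_zippered(2, 0, p_def), 0)
  rs <- seq(0.5, 6, 0.5)
  mz <- vapply(rs, mean_zippered, numeric(1), N = 15, params = p_def)
  expect_true(all(diff(mz) > 0))                        # non-decreasing
  expect_true(all(mz <= 2 * pi * rs / p_def$b_snare))   # ring capacity
  # strong zippering saturates the ring: capacity 6 at r = 2
  p_sat <- model_params(eps_zip = 60)
  expect_equal(mean_zippered(2, 15, p_sat), 6, tolerance = 1e-3)
})

test_that("Boltzmann mean radius: symmetry, deep minimum, refinement", {
  r <- seq(0.2, 1.8, 0.01)
  sym <- fake_profile(r, 30 * (r - 1)^2, p_def)
  expect_equal(boltzmann_mean_radius(sym), 1, tolerance = 1e-6)
  deep <- fake_profile(r, 500 * (r - 1.25)^2, p_def)
  expect_equal(boltzmann_mean_radius(deep), 1.25, tolerance = 1e-3)
  # grid refinement changes the estimate by < 1%
  r2 <- seq(0.2, 1.8, 0.0025)
  sym2 <- fake_profile(r2, 30 * (r2 - 1)^2, p_def)
  expect_equal(boltzmann_mean_radius(sym2), boltzmann_mean_radius(sym),
               tolerance = 0.01)
  flat <- fake_profile(r, rep(1, length(r)), p_def)
  expect_warning(boltzmann_mean_radius(flat), "grid edge")
})

test_that("degenerate limit: removing all force scales flattens the profile", {
  p0 <- suppressWarnings(
    model_params(P0 = 1e-30, tau = 1e-12, gamma = 1e-12, kappa = 1e-12))
  rs <- seq(0.5, 5, 0.5)
  # the flat integrand has weight at h_max, so the tail check warns
  U <- suppressWarnings(
    vapply(rs, free_energy, numeric(1), N = 0, params = p0))
  expect_lt(max(U) - min(U), 1e-6)
})

test_that("config round trip preserves parameters", {
  tmp <- tempfile(fileext = ".yaml")
  p2 <- model_params(eps_zip = 7.7, tau = 5.5)
  write_model_config(p2, tmp)
  p3 <- read_model_config(tmp)
  expect_equal(p3$eps_zip, 7.7)
  expect_equal(p3$tau, 5.5)
  expect_equal(p3$kT_pN_nm, p2$kT_pN_nm)
  writeLines(c("eps_zip: 7", "bogus_key: 1"), tmp)
  expect_error(read_model_config(tmp), "unknown model config keys")
})
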