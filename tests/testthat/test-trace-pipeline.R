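# filtering, idealization, conductance/radius conversion and cohort stats

test_that("preprocess preserves DC, attenuates line noise, reduces rms", {
  n <- 20000 * 4
  tr_c <- current_trace(rep(-3, n))
  pc <- preprocess(tr_c)
  expect_equal(pc$rate, 250)
  expect_true(all(abs(pc$current[10:(length(pc$current) - 10)] + 3) < 1e-6))
  # 60 Hz line contamination: notch attenuates by > 20 dB
  t <- (seq_len(n) - 1) / 20000
  sine <- current_trace(sin(2 * pi * 60 * t))
  amp <- function(x) sqrt(2) * stats::sd(x$current[50:(length(x$current) - 50)])
  a_plain <- amp(preprocess(sine))
  a_notch <- amp(preprocess(sine, notch = 60))
  expect_lt(a_notch / a_plain, 0.1)
  # white noise: post-processing rms matches the bandwidth-ratio estimate
  set.seed(1)
  noise <- current_trace(rnorm(n, 0, 2))
  pn <- preprocess(noise)
  # block means at 250/s of (filtered) white noise: the 280 Hz low-pass
  # dominates, leaving roughly sigma * sqrt(125 / 10000)
  expect_equal(stats::sd(pn$current), 2 * sqrt(125 / 10000), tolerance = 0.2)
  expect_error(preprocess(current_trace(rnorm(10))), "shorter than one")
  expect_error(preprocess(current_trace(rnorm(n), rate = 400)), "twice the")
})

test_that("burst detection applies amplitude and duration criteria", {
  rate <- 250
  mk <- function(cur) structure(
    list(current = cur, rate = rate, voltage = 16, resistivity = 0.6,
         id = "t", condition = NA,
         filter = list(cutoff = NA, block = 80, notch = NULL, order = 8)),
    class = "processed_trace")
  expect_equal(nrow(detect_bursts(mk(numeric(2000)))), 0)
  # -7.2 pA for 400 ms qualifies; 100 ms does not
  x <- numeric(2000); x[501:600] <- -7.2                  # 400 ms
  b <- detect_bursts(mk(x))
  expect_equal(nrow(b), 1)
  expect_equal(b$T0, 0.4)
  expect_equal(b$start, 500 / rate)                       # 2.0 s
  y <- numeric(2000); y[501:525] <- -7.2                  # 100 ms
  expect_equal(nrow(detect_bursts(mk(y))), 0)
  # flickering burst: above-threshold runs merged across short closures
  z <- numeric(4000)
  z[1001:1100] <- -7.2; z[1111:1210] <- -7.2; z[1221:1320] <- -7.2
  bz <- detect_bursts(mk(z))
  expect_equal(nrow(bz), 1)
  expect_equal(bz$T0, (1320 - 1000) / rate)
  # two well-separated bursts stay separate
  w <- numeric(4000); w[501:700] <- -7.2; w[2501:2700] <- -7.2
  expect_equal(nrow(detect_bursts(mk(w))), 2)
})

test_that("flicker detection applies the open threshold and 15-point rule", {
  rate <- 250
  mk <- function(cur) structure(
    list(current = cur, rate = rate, voltage = 16, resistivity = 0.6,
         id = "t", condition = NA,
         filter = list(cutoff = NA, block = 80, notch = NULL, order = 8)),
    class = "processed_trace")
  x <- numeric(4000)
  # 5 open periods of 20 points separated by 5-point closures
  st <- 1001
  for (k in 0:4) x[(st + k * 25):(st + k * 25 + 19)] <- -7.2
  p <- mk(x)
  b <- detect_bursts(p)
  fl <- detect_flickers(p, b[1, ])
  expect_equal(nrow(fl), 5)
  # a 14-point excursion is closed; 15 points is open
  y <- numeric(2000); y[501:600] <- -7.2; y[901:1000] <- -7.2
  y[701:714] <- -0.5          # 14 points below open threshold
  y[801:815] <- -0.5          # 15 points
  pb <- mk(y)
  bb <- detect_bursts(pb, max_gap = 2)
  expect_equal(nrow(bb), 1)   # one merged burst spanning the excursions
  fl2 <- detect_flickers(pb, bb[1, ])
  expect_equal(nrow(fl2), 3)  # two big steps plus the 15-point excursion
  # never-open burst yields zero flickers
  z <- numeric(2000); z[501:600] <- 7.2   # positive current
  bz <- detect_bursts(mk(z))
  expect_equal(nrow(detect_flickers(mk(z), bz[1, ])), 0)
  expect_error(detect_flickers(mk(z), list(i_start = 0, i_end = 10)),
               "outside the trace")
})

test_that("pore records convert currents to conductances and occupancies", {
  rate <- 250
  mk <- function(cur) structure(
    list(current = cur, rate = rate, voltage = 16, resistivity = 0.6,
         id = "t", condition = NA,
         filter = list(cutoff = NA, block = 80, notch = NULL, order = 8)),
    class = "processed_trace")
  x <- numeric(2000); x[501:600] <- -7.2
  p <- mk(x)
  b <- detect_bursts(p)
  rec <- pore_record(p, b[1, ], detect_flickers(p, b[1, ]))
  expect_equal(rec$G_po, 450)            # 7.2 pA / 16 mV = 450 pS
  expect_equal(rec$P_o, 1)
  expect_equal(rec$n_flickers, 1)
  # two equal open periods covering half the burst
  y <- numeric(4000); y[1001:1100] <- -7.2; y[1301:1400] <- -7.2
  py <- mk(y)
  by <- detect_bursts(py)
  ry <- pore_record(py, by[1, ], detect_flickers(py, by[1, ]))
  expect_equal(ry$P_o, 0.5)
  # zero open time flags G_po as undefined
  z <- numeric(2000); z[501:600] <- 7.2
  pz <- mk(z)
  bz <- detect_bursts(pz)
  rz <- pore_record(pz, bz[1, ], detect_flickers(pz, bz[1, ]))
  expect_identical(rz$P_o, 0)
  expect_true(is.na(rz$G_po))
})

test_that("conductance-radius conversion is exact and invertible", {
  expect_identical(radius_from_conductance(0), 0)
  expect_equal(radius_from_conductance(1000, 0.60), 1.7, tolerance = 0.03)
  # hand evaluation at the mean conductance scale
  expect_equal(radius_from_conductance(450, 0.60),
               sqrt(0.60 * 15e-9 * 450e-12 / pi) * 1e9, tolerance = 1e-12)
  G <- c(10, 450, 1000, 7210)
  expect_equal(conductance_from_radius(radius_from_conductance(G)), G,
               tolerance = 1e-12)
  expect_error(radius_from_conductance(-5), "non-negative")
})

test_that("averaged distributions weight pores equally and normalise", {
  mk_rec <- function(G) structure(
    list(G_samples = G, r_samples = radius_from_conductance(G),
         n_flickers = 1, T0 = 1, P_o = 1, G_po = mean(G)),
    class = "pore_record")
  # two delta-like pores with very different open durations
  r1 <- mk_rec(rep(300, 1000))
  r2 <- mk_rec(rep(7000, 10))
  pdf <- averaged_pdf(list(r1, r2), "G", bin_width = 50)
  expect_equal(sum(pdf$density) * pdf$bin_width, 1, tolerance = 1e-9)
  m1 <- sum(pdf$density[pdf$mids < 1000]) * pdf$bin_width
  expect_equal(m1, 0.5, tolerance = 1e-9)   # equal weight despite 100x samples
  # pooled histogram would give ~0.99 mass to the first pore instead
  pooled <- graphics::hist(c(rep(300, 1000), rep(7000, 10)),
                           breaks = pdf$breaks, plot = FALSE)
  expect_gt(sum(pooled$density[pdf$mids < 1000]) * 50, 0.9)
  # single pore: its own normalized histogram
  solo <- averaged_pdf(list(r1), "G", bin_width = 50)
  expect_equal(sum(solo$density) * 50, 1, tolerance = 1e-9)
  expect_error(averaged_pdf(list(), "G"), "no records")
})

test_that("Boltzmann inversion recovers energies from densities", {
  expect_equal(energy_from_pdf(rep(0.2, 5), 1), rep(0, 5))
  U2 <- energy_from_pdf(c(0.9, 0.1), 1)
  expect_equal(U2[2] - U2[1], log(9), tolerance = 1e-12)
  expect_true(is.na(energy_from_pdf(c(0.5, 0, 0.5), 1)[2]))
  expect_error(energy_from_pdf(c(0, 0), 1), "zero everywhere")
  # round trip: sample from exp(-U0), rebuild U within 0.3 kT
  r_grid <- seq(0.55, 2.45, by = 0.1)
  U0 <- 4 * (r_grid - 1.4)^2
  set.seed(99)
  samp <- sample(r_grid, 1e4, replace = TRUE, prob = exp(-U0))
  h <- graphics::hist(samp, breaks = seq(0.5, 2.5, 0.1), plot = FALSE)
  U_rec <- energy_from_pdf(h$density, 0.1)
  ok <- !is.na(U_rec)
  expect_lt(max(abs((U_rec - (U0 - min(U0)))[ok])), 0.3)
})

test_that("geometric flicker fit: MLE, edge case and CI coverage", {
  mk <- function(n) structure(list(n_flickers = n), class = "pore_record")
  recs <- lapply(c(16, 16, 16, 16, 16), mk)
  fit <- fit_flicker_geometric(recs)
  expect_equal(fit$p, 1 / 17, tolerance = 1e-12)
  expect_identical(fit_flicker_geometric(rep(0L, 8))$p, 1)
  expect_error(fit_flicker_geometric(c(1, 2)), "at least 5")
  # coverage of the 95% CI at the fitted flicker parameter, 64 bursts
  set.seed(7)
  p_true <- 0.0573
  cover <- mean(vapply(1:200, function(i) {
    fit <- fit_flicker_geometric(stats::rgeom(64, p_true))
    fit$ci[1] <= p_true && p_true <= fit$ci[2]
  }, logical(1)))
  expect_gte(cover, 0.90)
})

test_that("exponential lifetime fit and nucleation-rate bookkeeping", {
  fit <- fit_burst_exponential(rep(10.3, 5))
  expect_equal(fit$mean_T0, 10.3)
  expect_equal(fit$se, 10.3 / sqrt(5))
  set.seed(3)
  T0 <- stats::rexp(64, 1 / 10.3)
  f2 <- fit_burst_exponential(T0)
  expect_lt(abs(f2$mean_T0 - 10.3), 2 * 10.3 / sqrt(64))
  expect_error(fit_burst_exponential(c(-1, rep(1, 5))), "positive")
  # 2 bursts in 10 minutes -> 0.2 per minute
  b <- data.frame(start = c(100, 400))
  nr <- nucleation_rate(list(b), 600)
  expect_equal(nr$rate, 0.2)
  # exclusions remove both the burst inside them and their duration
  nr2 <- nucleation_rate(list(b), 600,
                         exclusions = list(cbind(90, 150)))
  expect_equal(nr2$rate, 1 / (540 / 60))
  # mean of per-recording rates differs from the pooled rate
  nr3 <- nucleation_rate(list(data.frame(start = c(10, 20, 30)),
                              data.frame(start = 10)),
                         c(60, 600))
  expect_equal(nr3$rate, mean(c(3, 0.1)))
  expect_false(isTRUE(all.equal(nr3$rate, 4 / 11)))
})

test_that("trace text files round-trip with metadata", {
  tr <- current_trace(c(0, -1, -2, 0.5), rate = 100, voltage = 16,
                      resistivity = 0.88, id = "patch-3")
  tmp <- tempfile(fileext = ".tsv")
  write_trace(tr, tmp)
  back <- read_trace(tmp)
  expect_equal(back$current, tr$current)
  expect_equal(back$rate, 100)
  expect_equal(back$resistivity, 0.88)
  expect_equal(back$id, "patch-3")
})
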