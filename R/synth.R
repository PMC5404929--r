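# Synthetic cell-attached patch recordings with known ground truth.
#
# The generator emulates the statistical structure the analysis pipeline
# assumes: a flat noisy baseline; rare current bursts placed by a renewal
# process (~0.2/min); within-burst open/closed flickering with a
# geometric flicker-count distribution; burst lifetimes that are sums of a
# geometric number of exponential dwells and hence approximately
# exponential; negative-going open currents equal to -G x V; and white
# Gaussian noise at the acquisition rate.  Event boundaries are quantised
# to the decimated (block-mean) grid so that, without noise, the pipeline
# recovers every ground-truth quantity exactly.

#' Specification for a synthetic recording
#'
#' @param seed integer seed; mandatory, every draw is a pure function of
#'   (spec, seed)
#' @param duration recording length, s
#' @param burst_rate expected bursts per minute
#' @param p_flicker geometric parameter of the flicker-count distribution
#'   (support 0, 1, 2, ...; mean (1-p)/p)
#' @param mean_T0 target mean burst lifetime, s
#' @param closed_dwell_mean mean intra-burst closed dwell, s
#' @param open_dwell_mean mean open dwell, s; when NULL it is derived from
#'   \code{mean_T0} and \code{p_flicker} so that the emergent burst
#'   lifetime has the target mean
#' @param conductance open-state conductance source: one of
#'   \code{list(type = "fixed", G = <pS>)},
#'   \code{list(type = "mixture", means =, sds =, weights =)} (per-burst
#'   draw, pS), or \code{list(type = "boltzmann", profile = <free_energy_profile>)}
#'   (per-sample radii drawn from exp(-U), converted to conductance)
#' @param voltage driving voltage, mV
#' @param resistivity solution resistivity, Ohm m
#' @param noise_sd white-noise standard deviation at the raw rate, pA
#' @param rate raw sampling rate, samples/s
#' @param block decimation block size assumed by the analysis (events are
#'   aligned to this grid)
#' @param n_bursts force exactly this many bursts at deterministic,
#'   evenly spaced positions instead of the renewal process
#' @return an object of class \code{"synth_spec"}
#' @export
synth_spec <- function(seed,
                       duration = 600,
                       burst_rate = 0.2,
                       p_flicker = 0.0573,
                       mean_T0 = 10.3,
                       closed_dwell_mean = 0.06,
                       open_dwell_mean = NULL,
                       conductance = list(type = "fixed", G = 450),
                       voltage = 16,
                       resistivity = 0.60,
                       noise_sd = 0,
                       rate = 20000,
                       block = 80,
                       n_bursts = NULL) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("synth_spec: an integer 'seed' is mandatory", call. = FALSE)
  stopifnot(duration > 0, burst_rate > 0, p_flicker > 0, p_flicker <= 1,
            mean_T0 > 0, closed_dwell_mean > 0, voltage > 0,
            resistivity > 0, noise_sd >= 0, rate > 0, block >= 1)
  if (is.null(open_dwell_mean)) {
    # mean flickers ~ 1/p; per open/closed cycle mean_T0 * p seconds
    open_dwell_mean <- max(mean_T0 * p_flicker - closed_dwell_mean, 0.1)
  }
  if (identical(conductance$type, "mixture")) {
    if (abs(sum(conductance$weights) - 1) > 1e-9)
      stop("mixture weights must sum to 1", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), duration = duration,
                 burst_rate = burst_rate, p_flicker = p_flicker,
                 mean_T0 = mean_T0, closed_dwell_mean = closed_dwell_mean,
                 open_dwell_mean = open_dwell_mean,
                 conductance = conductance, voltage = voltage,
                 resistivity = resistivity, noise_sd = noise_sd,
                 rate = rate, block = block, n_bursts = n_bursts),
            class = "synth_spec")
}

# draw one open-state conductance trajectory (pS) of n decimated samples
.draw_G <- function(spec, n) {
  src <- spec$conductance
  switch(src$type,
         fixed = rep(src$G, n),
         mixture = {
           k <- sample.int(length(src$means), 1L, prob = src$weights)
           rep(stats::rnorm(1L, src$means[k], src$sds[k]), n)
         },
         boltzmann = {
           prof <- src$profile
           w <- exp(-(prof$U - min(prof$U)))
           r <- sample(prof$r_po, n, replace = TRUE, prob = w)
           conductance_from_radius(r, spec$resistivity)
         },
         stop("unknown conductance source type", call. = FALSE))
}

#' Generate a synthetic recording with ground truth
#'
#' @param spec a \code{\link{synth_spec}}
#' @return list with \code{trace} (a \code{\link{current_trace}}) and
#'   \code{truth}: burst table (\code{start}, \code{end}, \code{T0} in s,
#'   \code{n_flickers}, \code{G_po} the mean open conductance), a list of
#'   per-burst open-period tables, and the per-burst open-sample
#'   conductances
#' @export
synth_trace <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, .synth_trace_impl(spec))
}

.synth_trace_impl <- function(spec) {
  dec_rate <- spec$rate / spec$block
  n_dec <- floor(spec$duration * dec_rate)
  cur <- numeric(n_dec)                      # decimated-grid current, pA
  min_open <- 15L                            # detection floor, samples
  min_gap <- 4L

  # a burst must carry at least 250 ms of cumulative open time to be
  # acceptable at all; the first opening provides it
  min_first <- max(min_open, ceiling(0.25 * dec_rate) + 1L)

  draw_burst <- function() {
    n_open <- max(1L, stats::rgeom(1L, spec$p_flicker))
    opens <- pmax(min_open, round(stats::rexp(n_open, 1 / spec$open_dwell_mean) * dec_rate))
    opens[1L] <- max(opens[1L], min_first)
    gaps <- if (n_open > 1L)
      pmax(min_gap, round(stats::rexp(n_open - 1L, 1 / spec$closed_dwell_mean) * dec_rate))
    else integer(0)
    list(n_open = n_open, opens = opens, gaps = gaps,
         len = sum(opens) + sum(gaps))
  }

  bursts <- list()
  if (!is.null(spec$n_bursts)) {
    # forced bursts: placed sequentially with a fixed 2 s guard interval
    gap <- ceiling(2 * dec_rate)
    pos <- gap
    for (j in seq_len(spec$n_bursts)) {
      b <- draw_burst()
      b$i_start <- pos
      bursts[[length(bursts) + 1L]] <- b
      pos <- pos + b$len + gap
    }
  } else {
    pos <- 1L + round(stats::rexp(1L, spec$burst_rate / 60) * dec_rate)
    repeat {
      b <- draw_burst()
      if (pos + b$len + 1L > n_dec) break
      b$i_start <- pos
      bursts[[length(bursts) + 1L]] <- b
      pos <- pos + b$len + max(min_gap,
                               round(stats::rexp(1L, spec$burst_rate / 60) * dec_rate))
    }
  }
  # overlapping forced bursts cannot be packed
  if (length(bursts) >= 2L) {
    for (j in 2:length(bursts))
      if (bursts[[j]]$i_start <= bursts[[j - 1L]]$i_start + bursts[[j - 1L]]$len)
        stop("synthetic bursts overlap: recording too short for the requested bursts",
             call. = FALSE)
  }
  if (length(bursts) &&
      bursts[[length(bursts)]]$i_start + bursts[[length(bursts)]]$len > n_dec)
    stop("synthetic burst extends beyond the recording", call. = FALSE)

  truth_rows <- list(); truth_opens <- list(); truth_G <- list()
  for (b in bursts) {
    i <- b$i_start
    o_start <- integer(b$n_open); o_end <- integer(b$n_open)
    G_all <- numeric(0)
    # fixed/mixture sources give one conductance per burst; the Boltzmann
    # source fluctuates sample-by-sample
    per_sample <- identical(spec$conductance$type, "boltzmann")
    G_burst <- if (!per_sample) .draw_G(spec, 1L)[1L]
    for (k in seq_len(b$n_open)) {
      o_start[k] <- i
      o_end[k] <- i + b$opens[k]
      G <- if (per_sample) .draw_G(spec, b$opens[k]) else rep(G_burst, b$opens[k])
      cur[o_start[k]:(o_end[k] - 1L)] <- -G * spec$voltage * 1e-3  # pS x mV -> pA
      G_all <- c(G_all, G)
      i <- o_end[k] + if (k < b$n_open) b$gaps[k] else 0L
    }
    truth_rows[[length(truth_rows) + 1L]] <-
      data.frame(start = (b$i_start - 1L) / dec_rate,
                 end = (b$i_start - 1L + b$len) / dec_rate,
                 T0 = b$len / dec_rate,
                 n_flickers = b$n_open,
                 G_po = mean(G_all))
    truth_opens[[length(truth_opens) + 1L]] <-
      data.frame(start = (o_start - 1L) / dec_rate, end = (o_end - 1L) / dec_rate)
    truth_G[[length(truth_G) + 1L]] <- G_all
  }

  raw <- rep(cur, each = spec$block)
  n_raw <- floor(spec$duration * spec$rate)
  if (length(raw) < n_raw) raw <- c(raw, numeric(n_raw - length(raw)))
  if (spec$noise_sd > 0) raw <- raw + stats::rnorm(length(raw), 0, spec$noise_sd)

  list(trace = current_trace(raw, rate = spec$rate, voltage = spec$voltage,
                             resistivity = spec$resistivity,
                             id = sprintf("synth-%d", spec$seed)),
       truth = list(bursts = if (length(truth_rows)) do.call(rbind, truth_rows)
                    else data.frame(start = numeric(0), end = numeric(0),
                                    T0 = numeric(0), n_flickers = integer(0),
                                    G_po = numeric(0)),
                    opens = truth_opens,
                    G_samples = truth_G,
                    dec_rate = dec_rate))
}

#' Synthetic cohort of per-pore summaries
#'
#' Draws per-pore mean open conductances for each condition from a
#' two-component mixture (or a fixed value), mirroring the structure of a
#' multi-condition dilation experiment.
#'
#' @param conditions data frame with columns \code{condition},
#'   \code{N_per_face}, \code{n_pores}, and either \code{G_fixed} or the
#'   mixture columns \code{mean_small}, \code{sd_small}, \code{mean_large},
#'   \code{sd_large}, \code{w_large}
#' @param seed integer seed
#' @return data frame with one row per pore: \code{condition},
#'   \code{N_per_face}, \code{G_po}, and the ground-truth component
#'   \code{component} ("small"/"large")
#' @export
synth_cohort <- function(conditions, seed) {
  stopifnot(is.data.frame(conditions), nrow(conditions) >= 1,
            all(conditions$n_pores >= 1))
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(conditions)), function(i) {
      cd <- conditions[i, ]
      n <- cd$n_pores
      if (!is.null(conditions$G_fixed) && !is.na(cd$G_fixed)) {
        G <- rep(cd$G_fixed, n)
        comp <- rep(if (cd$G_fixed > 1000) "large" else "small", n)
      } else {
        large <- stats::runif(n) < cd$w_large
        G <- ifelse(large,
                    stats::rnorm(n, cd$mean_large, cd$sd_large),
                    stats::rnorm(n, cd$mean_small, cd$sd_small))
        G <- pmax(G, 1)                     # conductances are positive
        comp <- ifelse(large, "large", "small")
      }
      data.frame(condition = cd$condition, N_per_face = cd$N_per_face,
                 G_po = G, component = comp, stringsAsFactors = FALSE)
    }))
  })
}

#' Reference free-energy curves for fit-recovery tests
#'
#' Model-generated profiles with optional additive Gaussian noise and a
#' recorded constant offset; the offset must not change any fit.
#'
#' @param params a \code{\link{model_params}}
#' @param N SNARE count
#' @param grid radius grid, nm
#' @param noise_sd standard deviation of additive noise, kT
#' @param offset constant added to the curve, kT
#' @param seed integer seed (required when \code{noise_sd > 0})
#' @return a \code{\link{free_energy_profile}} (not re-shifted: the offset
#'   is kept, since downstream fits must be invariant to it)
#' @export
synth_profile_curves <- function(params, N, grid = default_radius_grid(),
                                 noise_sd = 0, offset = 0, seed = NULL) {
  prof <- free_energy_profile(grid, N, params)
  U <- prof$U + offset
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is required when noise_sd > 0", call. = FALSE)
    U <- U + withr::with_seed(seed, stats::rnorm(length(U), 0, noise_sd))
  }
  out <- data.frame(r_po = prof$r_po, U = U)
  class(out) <- c("free_energy_profile", "data.frame")
  attr(out, "N") <- N
  attr(out, "params") <- params
  attr(out, "argmin") <- argmin_refined(out$r_po, out$U)
  out
}
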