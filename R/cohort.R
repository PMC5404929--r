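# Cohort-level statistics over per-pore records: equal-weight averaged
# distributions, Boltzmann inversion to an apparent free-energy profile,
# dwell-statistics fits, and nucleation rates.

#' Equal-weight averaged probability density across pores
#'
#' Computes a normalized histogram (fixed bin width, shared binning) for
#' each pore's open-state samples individually, then averages the
#' densities across pores.  This gives every pore equal weight regardless
#' of how long it stayed open, unlike pooling all samples.
#'
#' @param records list of \code{\link{pore_record}}s
#' @param value which per-record samples to use: open-state conductance
#'   (\code{"G"}, pS) or radius (\code{"r"}, nm)
#' @param bin_width fixed bin width (default 50 pS for conductance,
#'   0.1 nm for radius)
#' @param range optional c(lo, hi) for the shared binning; defaults to the
#'   pooled sample range padded to whole bins
#' @return list with \code{mids}, \code{breaks}, \code{density} (mean
#'   density per bin; integrates to 1) and \code{n_pores}
#' @export
averaged_pdf <- function(records, value = c("G", "r"), bin_width = NULL,
                         range = NULL) {
  value <- match.arg(value)
  field <- if (value == "G") "G_samples" else "r_samples"
  samples <- lapply(records, `[[`, field)
  samples <- samples[vapply(samples, length, 1L) > 0]
  if (!length(samples)) stop("no records with open-state samples", call. = FALSE)
  if (is.null(bin_width)) bin_width <- if (value == "G") 50 else 0.1
  if (is.null(range)) {
    lo <- floor(min(unlist(samples)) / bin_width) * bin_width
    hi <- ceiling(max(unlist(samples)) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    range <- c(lo, hi)
  }
  breaks <- seq(range[1L], range[2L], by = bin_width)
  if (breaks[length(breaks)] < range[2L])
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  dens <- vapply(samples, function(x) {
    h <- graphics::hist(pmin(pmax(x, breaks[1L]), breaks[length(breaks)]),
                        breaks = breaks, plot = FALSE)
    h$density
  }, numeric(length(breaks) - 1L))
  if (is.null(dim(dens))) dens <- matrix(dens, ncol = 1L)
  list(mids = (breaks[-1L] + breaks[-length(breaks)]) / 2,
       breaks = breaks,
       density = rowMeans(dens),
       bin_width = bin_width,
       n_pores = length(samples))
}

#' Apparent free energy from an observed density (Boltzmann inversion)
#'
#' \code{U/kT = -log(P) + A} where \code{P} is the probability mass per
#' bin (density times bin width) and the constant \code{A} is chosen so
#' the minimum of \code{U} is zero.  Bins with zero mass are returned as
#' \code{NA} (unobserved, not infinitely costly).
#'
#' @param density per-bin density values (or the list returned by
#'   \code{\link{averaged_pdf}})
#' @param bin_width bin width; taken from the list input when omitted
#' @return numeric vector of energies in kT (min 0; NA where unobserved)
#' @export
energy_from_pdf <- function(density, bin_width = NULL) {
  if (is.list(density)) {
    if (is.null(bin_width)) bin_width <- density$bin_width
    density <- density$density
  }
  if (is.null(bin_width)) stop("bin_width is required", call. = FALSE)
  if (any(density < 0)) stop("density must be non-negative", call. = FALSE)
  if (all(density == 0)) stop("density is zero everywhere", call. = FALSE)
  P <- density * bin_width
  U <- ifelse(P > 0, -log(P), NA_real_)
  U - min(U, na.rm = TRUE)
}

#' Geometric fit to flicker counts
#'
#' Flicker numbers per burst follow a geometric distribution
#' \code{p (1-p)^n} on n = 0, 1, 2, ...  The maximum-likelihood estimate
#' is \code{p = 1 / (1 + mean(n))}; a normal-approximation 95% CI on p is
#' attached (delta method on the mean).
#'
#' @param records list of \code{\link{pore_record}}s, or an integer vector
#'   of flicker counts
#' @param conf confidence level
#' @return list with \code{p}, \code{ci}, \code{mean_flickers}, \code{n}
#' @export
fit_flicker_geometric <- function(records, conf = 0.95) {
  n_fl <- if (is.numeric(records)) records
          else vapply(records, `[[`, numeric(1), "n_flickers")
  if (length(n_fl) < 5) stop("need at least 5 bursts", call. = FALSE)
  if (any(n_fl < 0)) stop("flicker counts must be non-negative", call. = FALSE)
  m <- mean(n_fl)
  p <- 1 / (1 + m)
  # Var(n) = (1-p)/p^2 under the model; dp/dm = -p^2
  se <- p * sqrt((1 - p) / length(n_fl))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(p = p, ci = c(max(0, p - z * se), min(1, p + z * se)),
       mean_flickers = m, n = length(n_fl))
}

#' Exponential fit to burst lifetimes
#'
#' Burst lifetimes T0 are exponentially distributed; the MLE of the mean
#' is the sample mean, with standard error \code{mean / sqrt(n)}.
#'
#' @param records list of \code{\link{pore_record}}s, or a numeric vector
#'   of lifetimes (s)
#' @return list with \code{mean_T0}, \code{se}, \code{rate}, \code{n}
#' @export
fit_burst_exponential <- function(records) {
  T0 <- if (is.numeric(records)) records
        else vapply(records, `[[`, numeric(1), "T0")
  if (length(T0) < 5) stop("need at least 5 bursts", call. = FALSE)
  if (any(T0 <= 0)) stop("burst lifetimes must be positive", call. = FALSE)
  m <- mean(T0)
  list(mean_T0 = m, se = m / sqrt(length(T0)), rate = 1 / m, n = length(T0))
}

#' Pore nucleation rate
#'
#' Bursts per minute of usable recording.  For each recording, excluded
#' windows (unstable baseline, end-of-record pore pileups) are removed
#' from the denominator, and bursts starting inside them are removed from
#' the numerator; the per-recording rates are then averaged unweighted
#' across recordings.
#'
#' @param bursts list (one element per recording) of burst data frames
#'   from \code{\link{detect_bursts}} (only \code{start} is used)
#' @param durations recording durations, s
#' @param exclusions optional list (same length) of two-column matrices of
#'   excluded \code{[start, end)} windows, s
#' @return list with \code{rate} (mean bursts/min across recordings) and
#'   \code{per_recording} (bursts/min per recording)
#' @export
nucleation_rate <- function(bursts, durations, exclusions = NULL) {
  stopifnot(length(bursts) == length(durations))
  per <- vapply(seq_along(bursts), function(k) {
    dur <- durations[k]
    starts <- bursts[[k]]$start
    if (!is.null(exclusions) && !is.null(exclusions[[k]]) &&
        nrow(exclusions[[k]])) {
      ex <- exclusions[[k]]
      dur <- dur - sum(pmin(ex[, 2L], durations[k]) - pmax(ex[, 1L], 0))
      inside <- vapply(starts, function(s)
        any(s >= ex[, 1L] & s < ex[, 2L]), logical(1))
      starts <- starts[!inside]
    }
    if (dur <= 0) {
      warning(sprintf("recording %d has no usable duration; dropped", k),
              call. = FALSE)
      return(NA_real_)
    }
    length(starts) / (dur / 60)
  }, numeric(1))
  list(rate = mean(per, na.rm = TRUE), per_recording = per)
}

#' Flatten pore records to a cohort table
#'
#' One row per pore with the summary statistics used by the dilation
#' analysis; suitable for CSV export.
#'
#' @param records list of \code{\link{pore_record}}s
#' @return data frame with columns \code{id}, \code{condition},
#'   \code{start}, \code{T0}, \code{n_flickers}, \code{P_o}, \code{G_po},
#'   \code{r_po_mean}, \code{fluctuation}
#' @export
cohort_table <- function(records) {
  do.call(rbind, lapply(records, function(x) data.frame(
    id = x$id, condition = x$condition, start = x$start, T0 = x$T0,
    n_flickers = x$n_flickers, P_o = x$P_o, G_po = x$G_po,
    r_po_mean = if (length(x$r_samples)) mean(x$r_samples) else NA_real_,
    fluctuation = tryCatch(fluctuation_ratio(x), error = function(e) NA_real_),
    stringsAsFactors = FALSE)))
}
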