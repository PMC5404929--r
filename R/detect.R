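# Idealization of processed traces into current bursts and intra-burst
# open periods (flickers).  Time is handled as half-open sample intervals
# [start, end) at the decimated rate; durations are (end - start) / rate.

# maximal runs where 'flag' is TRUE, as an integer matrix of sample
# start/end (end exclusive)
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep] + 1L)
}

#' Detect fusion-pore current bursts
#'
#' A burst is a cluster of above-threshold excursions
#' (\code{|I| > amp_thresh}) belonging to one pore: excursions separated
#' by sub-threshold gaps shorter than \code{max_gap} (pore flickers) are
#' merged, and the cluster is accepted when its cumulative
#' above-threshold time reaches \code{min_dur}.  Bursts are well
#' separated in time, so the merge gap only has to sit between the
#' flicker timescale and the burst-separation timescale.  The burst
#' lifetime T0 is threshold-to-threshold, including intra-burst closed
#' periods.
#'
#' @param p a \code{\link{preprocess}}ed trace
#' @param amp_thresh amplitude threshold, pA (applied to \code{|I|})
#' @param min_dur minimum cumulative above-threshold time, s
#' @param max_gap sub-threshold gaps shorter than this are treated as
#'   intra-burst closures, s
#' @return data frame with columns \code{start}, \code{end} (s, half-open),
#'   \code{T0} (s) and the sample indices \code{i_start}, \code{i_end};
#'   zero rows when nothing qualifies
#' @export
detect_bursts <- function(p, amp_thresh = 2.0, min_dur = 0.25, max_gap = 1.0) {
  stopifnot(inherits(p, "processed_trace"))
  runs <- .runs(abs(p$current) > amp_thresh)
  empty <- data.frame(start = numeric(0), end = numeric(0), T0 = numeric(0),
                      i_start = integer(0), i_end = integer(0))
  if (!nrow(runs)) return(empty)
  gap_pts <- max_gap * p$rate
  grp <- cumsum(c(1L, (runs[-1L, "start"] - runs[-nrow(runs), "end"]) >= gap_pts))
  merged <- do.call(rbind, lapply(split(seq_len(nrow(runs)), grp), function(i) {
    c(start = unname(runs[i[1L], "start"]),
      end = unname(runs[i[length(i)], "end"]),
      above = sum(runs[i, "end"] - runs[i, "start"]))
  }))
  need <- ceiling(min_dur * p$rate)
  merged <- merged[merged[, "above"] >= need, , drop = FALSE]
  if (!nrow(merged)) return(empty)
  data.frame(start = (merged[, "start"] - 1L) / p$rate,
             end = (merged[, "end"] - 1L) / p$rate,
             T0 = (merged[, "end"] - merged[, "start"]) / p$rate,
             i_start = as.integer(merged[, "start"]),
             i_end = as.integer(merged[, "end"]))
}

#' Detect open periods (flickers) within a burst
#'
#' Within a burst, the pore is open while the current is below
#' \code{open_thresh} (inward currents are negative) for at least
#' \code{min_pts} consecutive samples (15 points = 60 ms at 125 Hz);
#' everything else is closed.  The number of open periods is the flicker
#' count of the burst.
#'
#' @param p a \code{\link{preprocess}}ed trace
#' @param burst one row of \code{\link{detect_bursts}} output (or any list
#'   with \code{i_start}, \code{i_end})
#' @param open_thresh open threshold, pA (signed; default -0.25)
#' @param min_pts minimum run length in samples
#' @return data frame of open subperiods with columns \code{start},
#'   \code{end} (s), \code{i_start}, \code{i_end}
#' @export
detect_flickers <- function(p, burst, open_thresh = -0.25, min_pts = 15) {
  stopifnot(inherits(p, "processed_trace"))
  i0 <- burst$i_start[1L]; i1 <- burst$i_end[1L]
  if (is.null(i0) || i0 < 1L || i1 > length(p$current) + 1L || i0 >= i1)
    stop("burst bounds outside the trace", call. = FALSE)
  seg <- p$current[i0:(i1 - 1L)]
  runs <- .runs(seg < open_thresh)
  keep <- (runs[, "end"] - runs[, "start"]) >= min_pts
  runs <- runs[keep, , drop = FALSE]
  data.frame(start = (i0 - 1L + runs[, "start"] - 1L) / p$rate,
             end = (i0 - 1L + runs[, "end"] - 1L) / p$rate,
             i_start = i0 + runs[, "start"] - 1L,
             i_end = i0 + runs[, "end"] - 1L)
}

#' Per-burst pore record
#'
#' Collects the open-state statistics of one burst: point-by-point
#' open-state conductances \code{G = |I|/V} (pS from pA and mV), their
#' mean \code{G_po}, the open probability \code{P_o} (open time / T0), the
#' flicker count, and the corresponding open-pore radii.
#'
#' @param p a \code{\link{preprocess}}ed trace
#' @param burst one row of \code{\link{detect_bursts}} output
#' @param opens output of \code{\link{detect_flickers}} for that burst
#' @return an object of class \code{"pore_record"}
#' @export
pore_record <- function(p, burst, opens) {
  stopifnot(inherits(p, "processed_trace"))
  idx <- unlist(lapply(seq_len(nrow(opens)), function(k)
    seq.int(opens$i_start[k], opens$i_end[k] - 1L)), use.names = FALSE)
  open_I <- p$current[idx]
  G <- abs(open_I) / p$voltage * 1000      # pA/mV = nS -> pS
  open_time <- length(idx) / p$rate
  rec <- list(id = p$id, condition = p$condition,
              start = burst$start[1L], end = burst$end[1L],
              T0 = burst$T0[1L],
              n_flickers = nrow(opens),
              opens = opens[, c("start", "end")],
              open_samples_pA = open_I,
              G_samples = G,
              G_po = if (length(G)) mean(G) else NA_real_,
              P_o = open_time / burst$T0[1L],
              r_samples = radius_from_conductance(G, p$resistivity),
              voltage = p$voltage, resistivity = p$resistivity)
  class(rec) <- "pore_record"
  rec
}

#' @export
print.pore_record <- function(x, ...) {
  cat(sprintf("pore record (%s): T0 = %.2f s, %d flickers, P_o = %.2f, G_po = %s pS\n",
              x$id, x$T0, x$n_flickers, x$P_o,
              if (is.na(x$G_po)) "NA" else sprintf("%.0f", x$G_po)))
  invisible(x)
}

#' Idealize a whole processed trace into pore records
#'
#' Convenience wrapper: burst detection, flicker detection per burst, and
#' record assembly.
#'
#' @param p a \code{\link{preprocess}}ed trace
#' @param amp_thresh,min_dur burst criteria (see \code{\link{detect_bursts}})
#' @param open_thresh,min_pts open criteria (see \code{\link{detect_flickers}})
#' @return list of \code{\link{pore_record}} objects
#' @export
idealize_trace <- function(p, amp_thresh = 2.0, min_dur = 0.25,
                           open_thresh = -0.25, min_pts = 15) {
  bursts <- detect_bursts(p, amp_thresh, min_dur)
  lapply(seq_len(nrow(bursts)), function(k) {
    b <- bursts[k, ]
    pore_record(p, b, detect_flickers(p, b, open_thresh, min_pts))
  })
}

#' Pore radius from open-pore conductance
#'
#' Cylinder approximation for the pore lumen:
#' \code{r_po = sqrt(rho * L * G / pi)}, with \code{rho} the solution
#' resistivity, \code{L} the cylinder length (the two bilayers plus the
#' gap, 15 nm) and \code{G} the open-pore conductance.  With
#' \code{rho = 0.60} Ohm m, 1 nS corresponds to about 1.7 nm.
#'
#' @param G conductance(s), pS
#' @param resistivity solution resistivity, Ohm m
#' @param L_channel cylinder length, nm
#' @return radius in nm (vectorised)
#' @export
radius_from_conductance <- function(G, resistivity = 0.60, L_channel = 15) {
  if (any(G < 0)) stop("conductance must be non-negative", call. = FALSE)
  # SI: rho [Ohm m] * L [m] * G [S] / pi = r^2 [m^2]; converted to nm
  sqrt(resistivity * (L_channel * 1e-9) * (G * 1e-12) / pi) * 1e9
}

#' Open-pore conductance from radius
#'
#' Inverse of \code{\link{radius_from_conductance}}; used by the synthetic
#' generator.
#'
#' @param r_po radius, nm
#' @inheritParams radius_from_conductance
#' @return conductance in pS
#' @export
conductance_from_radius <- function(r_po, resistivity = 0.60, L_channel = 15) {
  if (any(r_po < 0)) stop("radius must be non-negative", call. = FALSE)
  (r_po * 1e-9)^2 * pi / (resistivity * (L_channel * 1e-9)) * 1e12
}
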