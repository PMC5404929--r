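# Small/large conductance-state classification and the dilation-probability
# sigmoid versus SNARE copy number.

#' Two-component Gaussian mixture over per-pore mean conductances
#'
#' Clusters the distribution of per-pore mean open conductances into a
#' small-pore and a large-pore component (around 300 pS and several nS in
#' the crowded-SNARE regime) by an EM Gaussian mixture with
#' unequal variances and a deterministic hierarchical initialisation
#' (via \pkg{mclust}).  The classification boundary is the conductance at
#' which the component responsibilities cross 0.5.
#'
#' @param G per-pore mean conductances, pS (>= 10 values)
#' @param log_scale fit on log10 conductance instead of the linear scale
#'   (the two populations are more than a decade apart, so this is more
#'   robust for small samples); boundary and means are reported back on
#'   the linear scale
#' @importFrom mclust Mclust mclustBIC
#' @return an object of class \code{"mixture_fit"}: list with ordered
#'   component \code{means}, \code{sds}, \code{weights} (sum 1), per-pore
#'   \code{responsibility} (probability of the large component),
#'   \code{boundary} (pS; NA when the components are not separated) and
#'   \code{labels} ("small"/"large")
#' @export
fit_conductance_mixture <- function(G, log_scale = FALSE) {
  if (length(G) < 10) stop("need at least 10 conductance values", call. = FALSE)
  if (any(G <= 0)) stop("conductances must be positive", call. = FALSE)
  x <- if (log_scale) log10(G) else G
  if (stats::sd(x) < 1e-8 * max(abs(x), 1)) {
    # one point mass: report equal components and an undefined boundary
    out <- list(means = rep(if (log_scale) 10^mean(x) else mean(x), 2L),
                sds = rep(0, 2L), weights = c(0.5, 0.5),
                responsibility = rep(0.5, length(G)), boundary = NA_real_,
                labels = rep("small", length(G)),
                log_scale = log_scale, n = length(G))
    class(out) <- "mixture_fit"
    return(out)
  }
  fit <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit))
    stop("mixture fit failed to converge", call. = FALSE)
  mu <- as.numeric(fit$parameters$mean)
  sd <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sd) == 1L) sd <- rep(sd, 2L)
  w <- as.numeric(fit$parameters$pro)
  o <- order(mu)
  mu <- mu[o]; sd <- sd[o]; w <- w[o]
  resp <- fit$z[, o[2L]]
  # responsibility crossing: solve w1 N(x|1) = w2 N(x|2) between the means
  f <- function(v) log(w[2L]) + stats::dnorm(v, mu[2L], sd[2L], log = TRUE) -
    log(w[1L]) - stats::dnorm(v, mu[1L], sd[1L], log = TRUE)
  boundary <- if (abs(mu[2L] - mu[1L]) < 1e-8 * max(abs(mu), 1) ||
                  f(mu[1L]) * f(mu[2L]) > 0) NA_real_
              else stats::uniroot(f, c(mu[1L], mu[2L]))$root
  back <- function(v) if (log_scale) 10^v else v
  out <- list(means = back(mu), sds = sd, weights = w,
              responsibility = resp,
              boundary = if (is.na(boundary)) NA_real_ else back(boundary),
              labels = ifelse(resp > 0.5, "large", "small"),
              log_scale = log_scale, n = length(G))
  class(out) <- "mixture_fit"
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("conductance mixture (n = %d%s):\n", x$n,
              if (x$log_scale) ", log scale" else ""))
  cat(sprintf("  small: mean %.3g pS (weight %.2f)\n", x$means[1L], x$weights[1L]))
  cat(sprintf("  large: mean %.3g pS (weight %.2f)\n", x$means[2L], x$weights[2L]))
  cat(sprintf("  boundary: %s\n",
              if (is.na(x$boundary)) "undefined (components not separated)"
              else sprintf("%.3g pS", x$boundary)))
  invisible(x)
}

#' Classify pores as small or large conductance
#'
#' A pore is "large" when its mean open conductance strictly exceeds the
#' threshold (default 1 nS = 1000 pS; a pore exactly at threshold is
#' small).  The threshold may be replaced by a mixture-derived boundary.
#'
#' @param records list of \code{\link{pore_record}}s, or a numeric vector
#'   of mean conductances in pS
#' @param threshold classification threshold, pS
#' @return character vector of \code{"small"} / \code{"large"}
#' @export
classify_pores <- function(records, threshold = 1000) {
  G <- if (is.numeric(records)) records
       else vapply(records, `[[`, numeric(1), "G_po")
  ifelse(G > threshold, "large", "small")
}

#' Dilation probability per condition
#'
#' For each condition (SNARE copies per disc face) the dilation
#' probability is the fraction of pores classified large, with a Wilson
#' binomial confidence interval.
#'
#' @param labels character vector from \code{\link{classify_pores}}
#' @param N_per_face numeric vector (same length) of SNARE copies per face
#' @param conf confidence level for the Wilson interval
#' @return an object of class \code{"dilation_curve"}: data frame with
#'   columns \code{N_per_face}, \code{k_large}, \code{n_total},
#'   \code{P_dilation}, \code{lo}, \code{hi}
#' @export
dilation_probability <- function(labels, N_per_face, conf = 0.95) {
  stopifnot(length(labels) == length(N_per_face))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- do.call(rbind, lapply(sort(unique(N_per_face)), function(Nf) {
    lab <- labels[N_per_face == Nf]
    k <- sum(lab == "large"); n <- length(lab)
    ph <- k / n
    centre <- (ph + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    data.frame(N_per_face = Nf, k_large = k, n_total = n, P_dilation = ph,
               lo = max(0, centre - half), hi = min(1, centre + half))
  }))
  class(out) <- c("dilation_curve", "data.frame")
  out
}

#' Logistic (Boltzmann two-state) dilation curve
#'
#' \code{P(N) = exp((N - N0)/b) / (1 + exp((N - N0)/b))}: the odds of the
#' large-conductance state are a Boltzmann factor linear in the SNARE copy
#' number, with \code{N0} the copy number at which dilation is 50% likely
#' and \code{b} the transition width.
#'
#' @param N SNARE copies per face (vectorised)
#' @param N0 midpoint copy number
#' @param b_dil transition width, copies (> 0)
#' @return probability in (0, 1)
#' @export
eval_sigmoid <- function(N, N0, b_dil) {
  stopifnot(b_dil > 0)
  stats::plogis((N - N0) / b_dil)
}

#' Fit the dilation sigmoid
#'
#' Unweighted least squares of \code{\link{eval_sigmoid}} to the observed
#' dilation fractions versus copies per face.  Needs at least three
#' conditions spanning a range of N.
#'
#' @param points a \code{\link{dilation_probability}} result, or any data
#'   frame with columns \code{N_per_face} and \code{P_dilation}
#' @return list with \code{N0}, \code{b_dil}, \code{r_squared} and the
#'   fitted \code{nls} object
#' @export
fit_dilation_sigmoid <- function(points) {
  stopifnot(all(c("N_per_face", "P_dilation") %in% names(points)))
  if (nrow(points) < 3 || length(unique(points$N_per_face)) < 3)
    stop("need at least 3 distinct copy numbers", call. = FALSE)
  df <- data.frame(N = points$N_per_face, P = points$P_dilation)
  # starting values from the logit linearisation: logit(P) = (N - N0)/b is
  # linear in N, so an ordinary regression on the interior points gives
  # exact starts for noise-free data
  N0_0 <- max(df$N); b_0 <- max(diff(range(df$N)) / 4, 1)
  inside <- df$P > 0 & df$P < 1
  if (sum(inside) >= 2) {
    lf <- stats::lm(stats::qlogis(P) ~ N, data = df[inside, ])
    sl <- unname(stats::coef(lf)[2L])
    if (is.finite(sl) && sl > 0) {
      b_0 <- 1 / sl
      N0_0 <- -unname(stats::coef(lf)[1L]) * b_0
    }
  }
  fit <- tryCatch(
    stats::nls(P ~ stats::plogis((N - N0) / b), data = df,
               start = list(N0 = N0_0, b = b_0),
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e)
      stop("sigmoid fit did not converge: ", conditionMessage(e), call. = FALSE))
  co <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((df$P - mean(df$P))^2)
  list(N0 = unname(co["N0"]), b_dil = unname(co["b"]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       fit = fit)
}

#' Relative conductance fluctuation of a pore
#'
#' Root-mean-square deviation of the open-state conductance about its
#' mean, divided by the mean.  Scale invariant; rises sharply for pores
#' above the ~1 nS boundary.
#'
#' @param record a \code{\link{pore_record}} (or numeric vector of
#'   open-state conductances)
#' @return dimensionless ratio
#' @export
fluctuation_ratio <- function(record) {
  G <- if (is.numeric(record)) record else record$G_samples
  if (length(G) < 2) stop("need at least 2 open-state samples", call. = FALSE)
  m <- mean(G)
  sqrt(mean((G - m)^2)) / m
}
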