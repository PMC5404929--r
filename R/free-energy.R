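#' Equilibrium free energy of the pore at a given radius
#'
#' Boltzmann sum over all microstates at fixed pore radius: the membrane
#' separation \code{h} is integrated from \code{b_snare} (the zippered
#' bundle sets the minimal gap) to \code{h_max} by deterministic
#' trapezoidal quadrature on \code{n_h} nodes, and the zippering number
#' \code{Nz} is summed exactly from 0 to \code{N}:
#' \deqn{exp(-U(r,N)/kT) = \sum_{Nz} m(Nz) \int_b^{hmax} e^{-U_{tot}(r,h,Nz)/kT} dh}
#' where \code{m(Nz)} is the state multiplicity (binomial by default, see
#' \code{\link{model_params}}).  The returned free energy is in kT and is
#' defined up to an additive constant.
#'
#' A warning is raised when the integrand has not decayed at \code{h_max}
#' (tail weight above \code{tail_tol} of the peak), which would indicate a
#' truncated integral.
#'
#' @param r_po pore radius, nm (scalar)
#' @param N total available v-SNAREs on the disc face
#' @param params a \code{\link{model_params}}
#' @param h_max upper limit of the membrane-separation integral, nm
#' @param n_h number of quadrature nodes
#' @param tail_tol relative tail-weight tolerance for the convergence check
#' @return free energy in kT
#' @export
free_energy <- function(r_po, N, params, h_max = 20, n_h = 400,
                        tail_tol = 1e-8) {
  .state_sum(r_po, N, params, h_max, n_h, tail_tol)$U
}

# composite Simpson nodes/weights on [a, b] with a graded stencil around
# each interior kink point (the integrand is smooth on each panel, so
# Simpson converges at O(n^-4) per panel).  The scaffold torque switches
# on at the kink and makes the integrand decay on a ~0.03 nm scale just
# above it, while the integrand often peaks in a cusp right at the kink;
# both sides therefore get short, finely resolved sub-panels, and the
# remaining nodes cover the smooth panels proportional to sqrt(length).
.trap_nodes <- function(a, b, n, kinks = numeric(0)) {
  kinks <- kinks[kinks > a & kinks < b]
  offs <- c(-0.3, 0, 0.15, 0.75, 2.5)      # sub-panel edges relative to a kink
  spac <- c(0.01, 0.004, 0.015, 0.05)      # spacing between those edges
  edges <- a
  spacing <- numeric(0)
  pts <- sort(unique(as.vector(outer(kinks, offs, "+"))))
  for (k in kinks) {
    for (j in seq_along(spac)) {
      e1 <- max(a, min(b, k + offs[j]))
      e2 <- max(a, min(b, k + offs[j + 1L]))
      if (e2 > max(edges)) {
        if (e1 > max(edges)) { edges <- c(edges, e1); spacing <- c(spacing, NA) }
        edges <- c(edges, e2); spacing <- c(spacing, spac[j])
      }
    }
  }
  if (b > max(edges)) { edges <- c(edges, b); spacing <- c(spacing, NA) }
  lens <- diff(edges)
  n_panel <- integer(length(lens))
  fixed <- !is.na(spacing)
  n_panel[fixed] <- ceiling(lens[fixed] / spacing[fixed])
  left <- max(n - sum(n_panel), 10L * sum(!fixed))
  if (any(!fixed))
    n_panel[!fixed] <- pmax(5L, round(left * sqrt(lens[!fixed]) / sum(sqrt(lens[!fixed]))))
  n_panel <- pmax(n_panel, 5L)
  n_panel <- n_panel + (1L - n_panel %% 2L)
  x <- numeric(0); w <- numeric(0)
  for (k in seq_along(lens)) {
    m <- n_panel[k]
    xs <- seq(edges[k], edges[k + 1L], length.out = m)
    d <- xs[2L] - xs[1L]
    ws <- rep(c(2, 4), length.out = m); ws[c(1L, m)] <- 1
    x <- c(x, xs); w <- c(w, ws * d / 3)
  }
  list(x = x, w = w)
}

# core partition computation; returns U (kT), mean Nz, and diagnostics
.state_sum <- function(r_po, N, params, h_max = 20, n_h = 400,
                       tail_tol = 1e-8, check_tail = TRUE) {
  stopifnot(length(r_po) == 1L, r_po > 0, N >= 0, n_h >= 2)
  p <- params
  # the toroidal/partial regime boundary in h is a derivative kink of the
  # integrand; quadrature panels are split there
  h_kink <- 2 * (p$D / 2 - p$delta - r_po)
  nd <- .trap_nodes(p$b_snare, h_max, n_h, h_kink)
  h <- nd$x
  nh <- length(h)
  e <- membrane_energy_terms(r_po, h, p)
  Umem <- e$bend + e$tension + e$hyd + e$apoe
  Umem[e$bad] <- Inf
  # common offset keeps exp() in range; cancels in -log and in ratios
  U0 <- min(Umem)
  if (!is.finite(U0))
    stop(sprintf("no admissible pore shape at r_po = %g nm", r_po), call. = FALSE)
  Z <- 0; Zn <- 0; tail <- 0; peak <- 0
  for (Nz in 0:N) {
    Us <- snare_energy_state(r_po, Nz, N - Nz, p)
    if (!is.finite(Us)) next
    lmult <- if (p$state_multiplicity) lchoose(N, Nz) else 0
    w <- exp(-(Umem - U0 + Us) + lmult)
    Zk <- sum(nd$w * w)
    Z <- Z + Zk
    Zn <- Zn + Nz * Zk
    tail <- max(tail, w[nh])
    peak <- max(peak, max(w))
  }
  if (Z <= 0)
    stop(sprintf("all SNARE states excluded at r_po = %g nm (ring capacity)", r_po),
         call. = FALSE)
  if (check_tail && peak > 0 && tail / peak > tail_tol)
    warning(sprintf(paste0("free_energy: integrand weight at h_max = %g nm is %.2g of ",
                           "its peak; increase h_max"), h_max, tail / peak),
            call. = FALSE)
  list(U = U0 - log(Z), mean_Nz = Zn / Z)
}

#' Free-energy profile over a radius grid
#'
#' Evaluates \code{\link{free_energy}} on a strictly increasing radius grid
#' and shifts the curve so its minimum is zero.  The default grid spans
#' 0.25-8 nm in 0.025 nm steps, covering the radii accessible to a ~24 nm
#' disc.
#'
#' @param grid pore radii, nm; strictly increasing, positive
#' @param N total available v-SNAREs on the disc face
#' @param params a \code{\link{model_params}}
#' @param ... passed to \code{\link{free_energy}}
#' @return an object of class \code{"free_energy_profile"}: a data frame
#'   with columns \code{r_po} (nm) and \code{U} (kT, min 0), with
#'   attributes \code{N}, \code{params} and \code{argmin} (parabolically
#'   refined minimum radius).
#' @export
free_energy_profile <- function(grid = default_radius_grid(), N, params, ...) {
  stopifnot(is.numeric(grid), length(grid) >= 3, all(diff(grid) > 0),
            all(grid > 0))
  if (any(grid > params$D / 2 - params$delta))
    stop("radius grid exceeds D/2 - delta, the largest radius at which a ",
         "(truncated) toroidal shape exists", call. = FALSE)
  U <- vapply(grid, free_energy, numeric(1), N = N, params = params, ...)
  U <- U - min(U)
  out <- data.frame(r_po = grid, U = U)
  class(out) <- c("free_energy_profile", "data.frame")
  attr(out, "N") <- N
  attr(out, "params") <- params
  attr(out, "argmin") <- argmin_refined(grid, U)
  out
}

#' @rdname free_energy_profile
#' @export
default_radius_grid <- function() seq(0.25, 7, by = 0.025)

# sub-grid minimum location by parabolic interpolation through the three
# points around the discrete argmin
argmin_refined <- function(x, y) {
  i <- which.min(y)
  if (i == 1L || i == length(y)) return(x[i])
  x3 <- x[(i - 1L):(i + 1L)]; y3 <- y[(i - 1L):(i + 1L)]
  d2 <- (y3[1L] - 2 * y3[2L] + y3[3L])
  if (d2 <= 0) return(x[i])
  x3[2L] - (x3[2L] - x3[1L]) * (y3[3L] - y3[1L]) / (2 * d2)
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("free-energy profile: N = %d SNAREs, %d radii in [%.3g, %.3g] nm\n",
              attr(x, "N"), nrow(x), min(x$r_po), max(x$r_po)))
  cat(sprintf("  minimum at r_po = %.3f nm; U range %.2f kT\n",
              attr(x, "argmin"), max(x$U)))
  invisible(x)
}

#' Mean net inward force over a radius window
#'
#' Average of \code{dU/dr_po} (finite differences) over
#' \code{[r_min, r_max]}, converted from kT/nm to pN.  Positive values
#' resist pore expansion.  The default window starts at 1.5 nm and ends at
#' the largest fully toroidal radius (see
#' \code{\link{largest_toroidal_radius}}), the range over which the pore is
#' an unconstrained toroid.
#'
#' @param profile a \code{\link{free_energy_profile}}
#' @param r_min,r_max window bounds, nm; both must lie within the grid
#' @return force in pN
#' @export
net_inward_force <- function(profile, r_min = 1.5, r_max = NULL) {
  stopifnot(inherits(profile, "free_energy_profile"))
  p <- attr(profile, "params")
  if (is.null(r_max)) r_max <- largest_toroidal_radius(p)
  g <- profile$r_po
  if (r_min < min(g) || r_max > max(g) || r_min >= r_max)
    stop("force window [r_min, r_max] must lie within the profile grid",
         call. = FALSE)
  w <- g >= r_min - 1e-9 & g <= r_max + 1e-9
  if (sum(w) < 2) stop("force window contains fewer than two grid points",
                       call. = FALSE)
  U <- profile$U[w]; r <- g[w]
  mean(diff(U) / diff(r)) * p$kT_pN_nm
}

#' Largest fully toroidal pore radius
#'
#' The largest radius at which the conditionally optimal membrane shape
#' (the separation \code{h} minimising the SNARE-free state energy) is an
#' interior toroid, i.e. not pressed against the partial-toroidal boundary
#' \code{r_po + h/2 + delta = D/2}.  Beyond this radius the disc edge
#' constrains the shape and the scaffold-twisting regime takes over.
#'
#' @param params a \code{\link{model_params}}
#' @param grid radii to scan, nm
#' @param h_max upper bound of the separation search, nm
#' @param margin slack (nm of h) used to decide that the optimum is pinned
#'   at the regime boundary
#' @return radius in nm
#' @export
largest_toroidal_radius <- function(params, grid = default_radius_grid(),
                                    h_max = 30, margin = 0.1) {
  ok <- vapply(grid, function(r) {
    hs <- conditional_h(r, params, h_max = h_max)
    hb <- 2 * (params$D / 2 - params$delta - r)  # h at the regime boundary
    hs < hb - margin
  }, logical(1))
  if (!any(ok)) stop("no fully toroidal radius on the grid", call. = FALSE)
  max(grid[ok])
}

# membrane separation minimising the N = 0 state energy at fixed radius
conditional_h <- function(r_po, params, h_max = 30) {
  obj <- function(h) {
    e <- membrane_energy_terms(r_po, h, params)
    # large finite penalty for inadmissible shapes keeps optimize() quiet
    ifelse(e$bad, 1e12, e$bend + e$tension + e$hyd + e$apoe)
  }
  stats::optimize(obj, c(params$b_snare, h_max), tol = 1e-6)$minimum
}

#' Bending and tension work over a radius expansion
#'
#' Decomposes the cost of expanding a SNARE-free pore from \code{r_from} to
#' \code{r_from + dr}: each term is evaluated at the conditionally optimal
#' membrane separation of its radius and the change is returned.  By
#' default \code{r_from} is the free-energy minimum radius and
#' \code{dr = 1} nm.
#'
#' @param params a \code{\link{model_params}}
#' @param r_from starting radius, nm; default the SNARE-free argmin
#' @param dr expansion, nm
#' @param ... passed to \code{\link{free_energy_profile}} when the argmin
#'   must be located
#' @return named numeric vector \code{c(tension =, bend =)} in kT
#' @export
membrane_work_decomposition <- function(params, r_from = NULL, dr = 1, ...) {
  if (is.null(r_from)) {
    prof <- free_energy_profile(N = 0, params = params, ...)
    r_from <- attr(prof, "argmin")
  }
  term <- function(r) {
    h <- conditional_h(r, params)
    e <- membrane_energy_terms(r, h, params)
    c(tension = e$tension, bend = e$bend)
  }
  term(r_from + dr) - term(r_from)
}

#' Boltzmann-weighted mean number of zippered SNAREs
#'
#' \code{<Nz>} under the same state sum as \code{\link{free_energy}}.
#' Bounded by the ring capacity \code{2 pi r_po / b_snare} and
#' non-decreasing in \code{r_po} at the default parameters: larger pores
#' make room for more zippered pins at the waist.
#'
#' @inheritParams free_energy
#' @return real-valued mean count in \code{[0, N]}
#' @export
mean_zippered <- function(r_po, N, params, h_max = 20, n_h = 400) {
  .state_sum(r_po, N, params, h_max, n_h, check_tail = FALSE)$mean_Nz
}

#' Boltzmann-mean pore radius of a profile
#'
#' \code{<r> = sum(r exp(-U)) / sum(exp(-U))} over the profile grid.  A
#' warning is raised when the profile does not rise at least
#' \code{edge_kT} above its minimum at both ends, since the mean is then
#' sensitive to the grid range.
#'
#' @param profile a \code{\link{free_energy_profile}}
#' @param edge_kT required rise of U at the grid edges, kT
#' @return mean radius in nm
#' @export
boltzmann_mean_radius <- function(profile, edge_kT = 10) {
  stopifnot(inherits(profile, "free_energy_profile"))
  U <- profile$U
  if (any(!is.finite(U))) stop("profile contains non-finite energies", call. = FALSE)
  if (U[1L] < edge_kT || U[length(U)] < edge_kT)
    warning(sprintf("profile rises less than %g kT above its minimum at a grid edge; ",
                    edge_kT), "Boltzmann-mean radius may be range-limited",
            call. = FALSE)
  w <- exp(-(U - min(U)))
  sum(profile$r_po * w) / sum(w)
}

#' Write / read a free-energy profile as delimited text plus JSON metadata
#'
#' The profile is stored as a two-column tab-separated table
#' (\code{r_po_nm}, \code{U_kT}); a sidecar \code{<path>.json} records the
#' SNARE count, the model parameters, the refined argmin and the default
#' net inward force.
#'
#' @param profile a \code{\link{free_energy_profile}}
#' @param path output path for the table
#' @return \code{read_profile} returns a \code{free_energy_profile} (with
#'   parameter attributes restored when the sidecar is present).
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "free_energy_profile"))
  tab <- data.frame(r_po_nm = profile$r_po, U_kT = profile$U)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  p <- attr(profile, "params")
  meta <- list(N = attr(profile, "N"),
               argmin_nm = attr(profile, "argmin"),
               params = unclass(p)[names(formals(model_params))])
  meta$net_inward_force_pN <- tryCatch(net_inward_force(profile),
                                       error = function(e) NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(ncol(tab) >= 2)
  out <- data.frame(r_po = tab[[1L]], U = tab[[2L]] - min(tab[[2L]]))
  class(out) <- c("free_energy_profile", "data.frame")
  meta_path <- paste0(path, ".json")
  N <- NA_integer_; params <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    N <- meta$N
    params <- do.call(model_params, meta$params)
  }
  attr(out, "N") <- N
  attr(out, "params") <- params
  attr(out, "argmin") <- argmin_refined(out$r_po, out$U)
  out
}
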