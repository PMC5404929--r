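#' Model parameters for the nanodisc-cell fusion pore
#'
#' Bundle the physical parameters of the equilibrium fusion-pore model: a
#' ~24 nm protein-scaffolded bilayer disc (an ApoE nanolipoprotein particle)
#' fused to an effectively infinite planar membrane, with v-/t-SNARE pins
#' that can zipper into a crowded ring at the pore waist.  All downstream
#' model functions take one of these objects; it is the single source of
#' truth for symbols and units.
#'
#' Internally the package works in nm / kT / pN.  The hydration pressure
#' prefactor is supplied in dyn/cm^2 (as conventionally tabulated) and is
#' converted once here.
#'
#' @param b_snare Thickness of the zippered SNARE bundle (its membrane
#'   footprint diameter), nm.
#' @param eps_zip Free energy released when a partially assembled SNAREpin
#'   completes zippering of its linker and transmembrane domains, kT.
#' @param delta Bilayer thickness, nm.
#' @param D Disc (NLP) diameter, nm.
#' @param lam_hyd Decay length of the inter-membrane steric-hydration
#'   repulsion, nm.
#' @param P0 Hydration pressure prefactor, dyn/cm^2.
#' @param tau Torque per unit length resisting twisting of the ApoE scaffold
#'   at the disc rim, pN.
#' @param kappa Membrane bending modulus, kT.
#' @param gamma Membrane tension, pN/nm.
#' @param omega_z Solid angle explored by the stiff zippered SNARE rod about
#'   its equilibrium orientation, steradian.
#' @param T Absolute temperature, K.  Sets the kT <-> pN nm conversion
#'   (4.11 pN nm at 298 K).
#' @param state_multiplicity Logical; count SNARE zippering states with the
#'   binomial multiplicity choose(N, Nz) (which subset of the N identical
#'   SNAREs is zippered).  Default TRUE; see the methods vignette.
#' @param tmd_anchors Number of transmembrane anchors through which a fully
#'   zippered SNAREpin pays the orientational confinement penalty
#'   \code{-kT log(omega_z)}.  Default 2 (the pin bridges both membranes);
#'   set 1 for a single-factor convention.
#' @param ring_stirling Logical; if TRUE the positional entropy of the
#'   zippered ring treats the rods as indistinguishable (an extra
#'   \code{-kT log(Nz)} per rod, Stirling form).  Default FALSE.  The
#'   entropic expansion force is identical in both forms.
#'
#' @return An object of class \code{"model_params"}: a list with the fields
#'   above plus derived constants \code{kT_pN_nm} (thermal energy in pN nm)
#'   and \code{P0_pN_nm2} (hydration prefactor in pN/nm^2).
#'
#' @examples
#' p <- model_params()
#' p$kT_pN_nm     # ~4.11 pN nm at 298 K
#'
#' @export
model_params <- function(b_snare = 2,
                         eps_zip = 9.6,
                         delta = 5,
                         D = 24,
                         lam_hyd = 0.10,
                         P0 = 5.0e11,
                         tau = 8.43,
                         kappa = 20,
                         gamma = 0.66,
                         omega_z = 0.05,
                         T = 298,
                         state_multiplicity = TRUE,
                         tmd_anchors = 2,
                         ring_stirling = FALSE) {
  p <- list(b_snare = b_snare, eps_zip = eps_zip, delta = delta, D = D,
            lam_hyd = lam_hyd, P0 = P0, tau = tau, kappa = kappa,
            gamma = gamma, omega_z = omega_z, T = T,
            state_multiplicity = isTRUE(state_multiplicity),
            tmd_anchors = tmd_anchors,
            ring_stirling = isTRUE(ring_stirling))
  # derived constants, converted once
  p$kT_pN_nm <- kT_pN_nm(T)
  # dyn/cm^2 -> Pa (x0.1) -> pN/nm^2 (x1e-6)
  p$P0_pN_nm2 <- P0 * 1e-7
  class(p) <- "model_params"
  validate_model_params(p)
  p
}

#' Thermal energy in pN nm
#'
#' @param T absolute temperature, K
#' @return kT in pN nm (Boltzmann constant 1.380649e-23 J/K)
#' @export
kT_pN_nm <- function(T = 298) 1.380649e-2 * T

validate_model_params <- function(p) {
  num <- c("b_snare", "eps_zip", "delta", "D", "lam_hyd", "P0", "tau",
           "kappa", "gamma", "omega_z", "T")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("model_params: '%s' must be a single positive number", f),
           call. = FALSE)
  }
  if (p$delta >= p$D)
    stop("model_params: bilayer thickness 'delta' must be smaller than the disc diameter 'D'",
         call. = FALSE)
  if (p$lam_hyd > p$delta / 5)
    warning("model_params: hydration decay length 'lam_hyd' is not small compared to 'delta'; ",
            "the short-range treatment of the hydration term assumes lam_hyd << delta",
            call. = FALSE)
  if (!p$tmd_anchors %in% c(1, 2))
    stop("model_params: 'tmd_anchors' must be 1 or 2", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Fusion pore model parameters (nm / kT / pN internally)\n")
  fmt <- function(sym, val, unit, what)
    cat(sprintf("  %-8s %10g %-9s %s\n", sym, val, unit, what))
  fmt("b",      x$b_snare, "nm",      "zippered SNARE bundle thickness")
  fmt("eps_zip", x$eps_zip, "kT",     "zippering energy")
  fmt("delta",  x$delta,   "nm",      "bilayer thickness")
  fmt("D",      x$D,       "nm",      "disc diameter")
  fmt("lambda", x$lam_hyd, "nm",      "steric-hydration decay length")
  fmt("P0",     x$P0,      "dyn/cm2", "hydration pressure prefactor")
  fmt("tau",    x$tau,     "pN",      "ApoE twisting torque per length")
  fmt("kappa",  x$kappa,   "kT",      "bending modulus")
  fmt("gamma",  x$gamma,   "pN/nm",   "membrane tension")
  fmt("Omega_z", x$omega_z, "sr",     "zippered-rod solid angle")
  fmt("T",      x$T,       "K",       sprintf("temperature (kT = %.3f pN nm)", x$kT_pN_nm))
  cat(sprintf("  options: state_multiplicity=%s, tmd_anchors=%d, ring_stirling=%s\n",
              x$state_multiplicity, x$tmd_anchors, x$ring_stirling))
  invisible(x)
}

#' Read / write model parameters as a YAML config
#'
#' The config mirrors the argument names of \code{\link{model_params}};
#' unknown keys are rejected so that typos do not silently fall back to
#' defaults.
#'
#' @param path file path
#' @return \code{read_model_config} returns a \code{model_params} object.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(model_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown model config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(model_params, cfg)
}

#' @rdname read_model_config
#' @param params a \code{model_params} object
#' @export
write_model_config <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  keep <- names(formals(model_params))
  yaml::write_yaml(unclass(params)[keep], path)
  invisible(path)
}
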