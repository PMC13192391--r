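#' Model parameters for the single-compartment plateau model
#'
#' Constructs and validates the full parameter set of the model: a spherical
#' compartment carrying a passive leak, a GHK-flux voltage-gated Ca2+ channel
#' (VGCC) with Ca2+-dependent inactivation, an SK-type Ca2+-activated K+
#' current, an exponential-decay inhibitory synapse, and a submembrane Ca2+
#' pool with first-order removal.
#'
#' The compartment is a 10 um sphere (surface area pi * d^2 ~ 3.14e-6 cm2)
#' simulated at 32 degrees C with a 0.025 ms step. The maximal VGCC scale
#' `gbar_cal` and SK conductance density `gbar_kca` have no canonical printed
#' values; the defaults here are the output of [grid_search()] run with the
#' package defaults (see the methods vignette) and can be overridden freely.
#'
#' @param diameter compartment sphere diameter, um.
#' @param Cm specific membrane capacitance, uF/cm2.
#' @param g_pas leak conductance density, S/cm2.
#' @param E_pas leak reversal potential, mV.
#' @param gbar_cal VGCC maximal permeability-like scale; the product
#'   `gbar_cal * m * h^2 * ghk` has units mA/cm2.
#' @param tfa dimensionless scale dividing the VGCC activation time constant.
#' @param ki half-inactivation Ca2+ concentration of the VGCC h-gate, mM.
#' @param cao extracellular Ca2+ concentration, mM.
#' @param gbar_kca SK maximal conductance density, S/cm2.
#' @param E_K potassium reversal potential, mV.
#' @param cac SK half-activation Ca2+ concentration, mM.
#' @param beta_kca SK backward rate constant, 1/ms.
#' @param q10_kca,temp_ref_kca temperature adjustment of SK kinetics:
#'   `tadj = q10_kca^((temperature - temp_ref_kca)/10)` divides the SK time
#'   constant.
#' @param depth submembrane Ca2+ shell depth, um.
#' @param tau_r Ca2+ removal time constant, ms.
#' @param ca_inf steady-state intracellular Ca2+ concentration, mM.
#' @param E_GABA inhibitory synaptic reversal potential, mV.
#' @param temperature simulation temperature, degrees C.
#' @param dt integration time step, ms.
#' @param ca_drive_clamp logical; if `TRUE` (default) the Ca2+ influx term of
#'   the pool is clamped at zero when the VGCC current is outward, preventing
#'   unphysical depletion of the shell.
#'
#' @return An object of class `model_parameters`: a named list of the above
#'   plus `area` (cm2), `F` (Faraday constant, C/mol) and `R_gas`
#'   (J/(mol K)).
#' @examples
#' p <- model_parameters()
#' p$area            # ~3.14e-6 cm2
#' p$Cm / p$g_pas    # membrane time constant, ms (uF/cm2 over S/cm2 * 1e-3)
#' @export
model_parameters <- function(diameter = 10,
                             Cm = 1,
                             g_pas = 5e-5,
                             E_pas = -65,
                             gbar_cal = 1.1288379e-3,
                             tfa = 1,
                             ki = 0.01,
                             cao = 2,
                             gbar_kca = 1e-5,
                             E_K = -90,
                             cac = 0.1,
                             beta_kca = 0.03,
                             q10_kca = 3,
                             temp_ref_kca = 22,
                             depth = 0.1,
                             tau_r = 200,
                             ca_inf = 1e-4,
                             E_GABA = -75,
                             temperature = 32,
                             dt = 0.025,
                             ca_drive_clamp = TRUE) {
  p <- list(
    diameter = diameter,
    # sphere surface: pi * d^2, d in um -> cm (1 um = 1e-4 cm)
    area = pi * (diameter * 1e-4)^2,
    Cm = Cm, g_pas = g_pas, E_pas = E_pas,
    gbar_cal = gbar_cal, tfa = tfa, ki = ki, cao = cao,
    gbar_kca = gbar_kca, E_K = E_K, cac = cac, beta_kca = beta_kca,
    q10_kca = q10_kca, temp_ref_kca = temp_ref_kca,
    depth = depth, tau_r = tau_r, ca_inf = ca_inf,
    E_GABA = E_GABA, temperature = temperature, dt = dt,
    ca_drive_clamp = isTRUE(ca_drive_clamp),
    F = 96485, R_gas = 8.314
  )
  class(p) <- "model_parameters"
  validate_parameters(p)
}

#' @rdname model_parameters
#' @param p a `model_parameters` object.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "model_parameters"))
  num <- vapply(p[setdiff(names(p), "ca_drive_clamp")], function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num)) {
    stop("non-finite or non-scalar parameter(s): ",
         paste(names(num)[!num], collapse = ", "))
  }
  if (p$diameter <= 0) stop("diameter must be > 0")
  if (abs(p$area - pi * (p$diameter * 1e-4)^2) > 1e-3 * p$area) {
    stop("area inconsistent with sphere of given diameter")
  }
  for (f in c("gbar_cal", "gbar_kca", "g_pas", "ca_inf")) {
    if (p[[f]] < 0) stop(f, " must be >= 0")
  }
  for (f in c("Cm", "cao", "cac", "ki", "tau_r", "depth", "dt", "tfa",
              "beta_kca")) {
    if (p[[f]] <= 0) stop(f, " must be > 0")
  }
  if (p$ca_inf >= p$cao) stop("ca_inf must be below cao")
  p
}

#' Temperature adjustment factor for SK kinetics
#'
#' `tadj = q10^((T - T_ref)/10)`; divides the SK time constant so kinetics
#' speed up at the 32 C recording temperature relative to the 22 C reference.
#'
#' @param p a `model_parameters` object.
#' @return dimensionless scalar.
#' @export
tadj_kca <- function(p) p$q10_kca^((p$temperature - p$temp_ref_kca) / 10)

#' Update selected fields of a parameter set
#'
#' Convenience for pharmacology-style manipulations (`gbar_kca = 0`, ...) and
#' calibration grids; re-derives the area if the diameter changes and
#' revalidates.
#'
#' @param p a `model_parameters` object.
#' @param ... named fields to replace.
#' @return a validated `model_parameters` object.
#' @export
update_parameters <- function(p, ...) {
  stopifnot(inherits(p, "model_parameters"))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  if ("diameter" %in% names(dots) && !("area" %in% names(dots))) {
    p$area <- pi * (p$diameter * 1e-4)^2
  }
  validate_parameters(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  cat(sprintf("  sphere d = %g um (area %.3e cm2), Cm = %g uF/cm2, %g C, dt = %g ms\n",
              x$diameter, x$area, x$Cm, x$temperature, x$dt))
  cat(sprintf("  leak:  g_pas = %g S/cm2, E_pas = %g mV\n", x$g_pas, x$E_pas))
  cat(sprintf("  VGCC:  gbar_cal = %g, ki = %g mM, cao = %g mM, tfa = %g\n",
              x$gbar_cal, x$ki, x$cao, x$tfa))
  cat(sprintf("  SK:    gbar_kca = %g S/cm2, E_K = %g mV, cac = %g mM, beta = %g /ms\n",
              x$gbar_kca, x$E_K, x$cac, x$beta_kca))
  cat(sprintf("  Ca2+:  depth = %g um, tau_r = %g ms, ca_inf = %g mM, clamp = %s\n",
              x$depth, x$tau_r, x$ca_inf, x$ca_drive_clamp))
  cat(sprintf("  GABA:  E_GABA = %g mV\n", x$E_GABA))
  invisible(x)
}
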