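#' @useDynLib plateaukit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# x/(exp(x)-1) with the removable singularity at 0 handled by its series.
efun <- function(z) {
  out <- numeric(length(z))
  small <- abs(z) < 1e-4
  out[small] <- 1 - z[small] / 2
  out[!small] <- z[!small] / (exp(z[!small]) - 1)
  out
}

#' Instantaneous state of the model
#'
#' @param V membrane potential, mV.
#' @param m_cal VGCC activation gate in `[0, 1]`.
#' @param m_kca SK activation gate in `[0, 1]`.
#' @param cai intracellular Ca2+ in the submembrane shell, mM.
#' @param g_syn inhibitory synaptic conductance, uS.
#' @param t time, ms.
#' @return a named list of class `model_state`.
#' @export
model_state <- function(V, m_cal, m_kca, cai, g_syn = 0, t = 0) {
  stopifnot(is.finite(V), is.finite(cai))
  if (m_cal < 0 || m_cal > 1 || m_kca < 0 || m_kca > 1) {
    stop("gating variables must lie in [0, 1]")
  }
  if (cai < 0) stop("cai must be >= 0")
  if (g_syn < 0) stop("g_syn must be >= 0")
  structure(list(t = t, V = V, m_cal = m_cal, m_kca = m_kca,
                 cai = cai, g_syn = g_syn),
            class = "model_state")
}

#' VGCC activation-gate kinetics
#'
#' Voltage-dependent forward/backward rates of the high-voltage-activated
#' Ca2+ channel activation gate:
#' `alpha(V) = 0.055 (-27.01 - V) / (exp((-27.01 - V)/3.8) - 1)`,
#' `beta(V) = 0.94 exp((-63.01 - V)/17)`, with `m_inf = alpha/(alpha+beta)`
#' and `tau_m = 1/(tfa (alpha+beta))`. The removable singularity at
#' V = -27.01 mV is evaluated by series so the rates are continuous there.
#'
#' @param V membrane potential, mV (vectorised).
#' @param p a [model_parameters()] object.
#' @return a data.frame with columns `alpha`, `beta` (1/ms), `m_inf`,
#'   `tau_m` (ms).
#' @examples
#' cal_rates(-27.01, model_parameters())$alpha  # 0.055 * 3.8 = 0.209
#' @export
cal_rates <- function(V, p) {
  if (!all(is.finite(V))) stop("V must be finite")
  u <- -27.01 - V
  alpha <- 0.055 * 3.8 * efun(u / 3.8)
  beta <- 0.94 * exp((-63.01 - V) / 17)
  m_inf <- alpha / (alpha + beta)
  tau_m <- 1 / (p$tfa * (alpha + beta))
  data.frame(alpha = alpha, beta = beta, m_inf = m_inf, tau_m = tau_m)
}

#' Goldman-Hodgkin-Katz flux factor for Ca2+
#'
#' Constant-field flux `1e-3 * 2F * (cai * efun(-z) - cao * efun(z))` with
#' `z = 2FV * 1e-3 / (R T)` and `efun(z) = z/(exp(z) - 1)`. Negative (inward)
#' below the Ca2+ Nernst potential for `cai << cao`, exactly zero at it, and
#' continuous through V = 0 (series expansion for small `|z|`). Multiplied by
#' `gbar_cal * m * h^2` this yields the VGCC current density in mA/cm2.
#'
#' @param V membrane potential, mV (vectorised).
#' @param cai,cao intra/extracellular Ca2+, mM.
#' @param temperature temperature, degrees C.
#' @param F Faraday constant, C/mol.
#' @param R_gas gas constant, J/(mol K).
#' @return flux factor (mM-weighted charge flux; see Details).
#' @examples
#' ghk_flux(0, 1e-4, 2, 32)  # ~ -385.9
#' @export
ghk_flux <- function(V, cai, cao, temperature, F = 96485, R_gas = 8.314) {
  if (any(cao <= 0)) stop("cao must be > 0")
  if (any(cai < 0)) stop("cai must be >= 0")
  TK <- temperature + 273.15
  z <- 2 * F * V * 1e-3 / (R_gas * TK)
  1e-3 * 2 * F * (cai * efun(-z) - cao * efun(z))
}

#' Nernst equilibrium potential for Ca2+
#'
#' @inheritParams ghk_flux
#' @return potential, mV.
#' @export
nernst_ca <- function(cai, cao, temperature, F = 96485, R_gas = 8.314) {
  TK <- temperature + 273.15
  1e3 * R_gas * TK / (2 * F) * log(cao / cai)
}

#' Ca2+-dependent inactivation of the VGCC
#'
#' `h(cai) = ki / (ki + cai)`: fully available at zero Ca2+, half-available
#' at `cai = ki`, monotonically suppressed as the submembrane shell loads.
#' Enters the VGCC current squared.
#'
#' @param cai intracellular Ca2+, mM (vectorised).
#' @param p a [model_parameters()] object.
#' @return dimensionless availability in `(0, 1]`.
#' @export
h_cal <- function(cai, p) {
  if (any(cai < 0)) stop("cai must be >= 0")
  p$ki / (p$ki + cai)
}

#' SK gate kinetics
#'
#' Purely Ca2+-gated: `m_inf = (cai/cac)^2 / (1 + (cai/cac)^2)` and
#' `tau_m = 1 / (beta (1 + (cai/cac)^2)) / tadj`, where
#' `tadj = q10^((T - T_ref)/10)` speeds kinetics at recording temperature.
#'
#' @param cai intracellular Ca2+, mM (vectorised).
#' @param p a [model_parameters()] object.
#' @return a data.frame with columns `m_inf` and `tau_m` (ms).
#' @export
kca_gate <- function(cai, p) {
  if (any(cai < 0)) stop("cai must be >= 0")
  r2 <- (cai / p$cac)^2
  m_inf <- r2 / (1 + r2)
  tau_m <- 1 / (p$beta_kca * (1 + r2)) / tadj_kca(p)
  data.frame(m_inf = m_inf, tau_m = tau_m)
}

#' Membrane current decomposition
#'
#' Computes every membrane current density for a given state:
#' `I_pas = g_pas (V - E_pas)`, `I_VGCC = gbar_cal m h^2(cai) ghk(V)`,
#' `I_KCa = gbar_kca m^3 (V - E_K)`, and the synaptic current
#' `I_GABA = g_syn (V - E_GABA) / area` converted from uS (point process)
#' to density. `I_sum = I_pas + I_VGCC + I_KCa + I_GABA - I_inj` by
#' construction.
#'
#' @param s a [model_state()] (or any named list with `V`, `m_cal`, `m_kca`,
#'   `cai`, `g_syn`).
#' @param p a [model_parameters()] object.
#' @param I_inj injected current density, mA/cm2.
#' @return a named list with components `I_pas`, `I_VGCC`, `I_KCa`,
#'   `I_GABA`, `I_inj`, `I_sum`, all mA/cm2.
#' @export
membrane_currents <- function(s, p, I_inj = 0) {
  I_pas <- p$g_pas * (s$V - p$E_pas)
  h <- h_cal(s$cai, p)
  I_VGCC <- p$gbar_cal * s$m_cal * h^2 *
    ghk_flux(s$V, s$cai, p$cao, p$temperature, p$F, p$R_gas)
  I_KCa <- p$gbar_kca * s$m_kca^3 * (s$V - p$E_K)
  # uS * mV = nA; nA -> mA is 1e-6; divide by area for density
  I_GABA <- s$g_syn * 1e-6 * (s$V - p$E_GABA) / p$area
  list(I_pas = I_pas, I_VGCC = I_VGCC, I_KCa = I_KCa, I_GABA = I_GABA,
       I_inj = I_inj, I_sum = I_pas + I_VGCC + I_KCa + I_GABA - I_inj)
}

#' Time derivatives of the state
#'
#' The membrane equation is `Cm dV/dt = -(I_pas + I_VGCC + I_KCa + I_GABA -
#' I_inj)`; with `Cm` in uF/cm2 and currents in mA/cm2 the rate in mV/ms is
#' `dV/dt = -1000 I_sum / Cm` (1 mA/uF = 1000 mV/ms). Gates relax first-order
#' toward their steady states. The Ca2+ pool obeys
#' `dcai/dt = -1e4 I_VGCC / (2 F depth) + (ca_inf - cai)/tau_r` (depth in um,
#' the 1e4 converts the surface flux to shell concentration in mM/ms); when
#' `ca_drive_clamp` is set the influx term is floored at zero for outward
#' VGCC current.
#'
#' @inheritParams membrane_currents
#' @return a named list `dV`, `dm_cal`, `dm_kca`, `dcai` (native units/ms).
#' @export
derivatives <- function(s, p, I_inj = 0) {
  cur <- membrane_currents(s, p, I_inj)
  rc <- cal_rates(s$V, p)
  rk <- kca_gate(s$cai, p)
  drive <- -1e4 * cur$I_VGCC / (2 * p$F * p$depth)
  if (p$ca_drive_clamp && drive < 0) drive <- 0
  list(dV = -1000 * cur$I_sum / p$Cm,
       dm_cal = (rc$m_inf - s$m_cal) / rc$tau_m,
       dm_kca = (rk$m_inf - s$m_kca) / rk$tau_m,
       dcai = drive + (p$ca_inf - s$cai) / p$tau_r)
}
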