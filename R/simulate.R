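#' Find the stimulus-free resting state
#'
#' Relaxes the model from a passive initial guess (V = E_pas, gates at their
#' steady states, cai = ca_inf) for at least `settle` ms of simulated time,
#' extending in chunks until every state derivative is below `tol` in native
#' units (mV/ms, 1/ms, mM/ms).
#'
#' @param p a [model_parameters()] object.
#' @param settle initial relaxation time, ms.
#' @param max_settle give up beyond this much simulated time, ms.
#' @param tol derivative tolerance at rest.
#' @return a [model_state()] at rest (t = 0, g_syn = 0).
#' @export
initialize_rest <- function(p, settle = 2000, max_settle = 32000,
                            tol = 1e-9) {
  stopifnot(inherits(p, "model_parameters"))
  empty <- matrix(numeric(0), 0, 3)
  # Seed the relaxation at the most hyperpolarized fixed point of the
  # reduced system (gates at steady state, cai balancing influx/removal).
  # Starting from a naive (E_pas, ca_inf) guess can transiently ignite a
  # plateau during settling, which never ends when SK is absent and then
  # settles onto the depolarized state instead of rest.
  cai_eq <- function(V) {
    f <- function(ca) {
      Iv <- p$gbar_cal * cal_rates(V, p)$m_inf * h_cal(ca, p)^2 *
        ghk_flux(V, ca, p$cao, p$temperature, p$F, p$R_gas)
      max(-1e4 * Iv / (2 * p$F * p$depth), 0) + (p$ca_inf - ca) / p$tau_r
    }
    if (p$gbar_cal == 0) return(p$ca_inf)
    stats::uniroot(f, c(p$ca_inf * (1 - 1e-9), 100), tol = 1e-11)$root
  }
  I_red <- function(V) {
    ca <- cai_eq(V)
    s <- list(V = V, m_cal = cal_rates(V, p)$m_inf,
              m_kca = kca_gate(ca, p)$m_inf, cai = ca, g_syn = 0)
    membrane_currents(s, p)$I_sum
  }
  Vg <- seq(p$E_K, -40, by = 1)
  Ig <- vapply(Vg, I_red, 0)
  cross <- which(diff(sign(Ig)) != 0)
  if (length(cross)) {
    lo <- Vg[cross[1]]; hi <- Vg[cross[1] + 1]
    V0 <- stats::uniroot(I_red, c(lo, hi), tol = 1e-10)$root
  } else {
    V0 <- p$E_pas
  }
  ca0 <- cai_eq(V0)
  s <- c(V0, cal_rates(V0, p)$m_inf, kca_gate(ca0, p)$m_inf, ca0)
  total <- 0
  repeat {
    out <- .integrate_model(unclass(p), s, 0, settle, p$dt,
                            empty, empty, empty, 0L)
    s <- out$final
    total <- total + settle
    st <- model_state(V = s[1], m_cal = s[2], m_kca = s[3], cai = s[4])
    d <- derivatives(st, p)
    if (max(abs(unlist(d))) < tol) return(st)
    if (total >= max_settle) {
      stop("no resting state: derivatives still ",
           signif(max(abs(unlist(d))), 3), " after ", total, " ms")
    }
  }
}

#' Integrate the model over a stimulus protocol
#'
#' Fixed-step integration (step `p$dt` unless overridden) of the membrane
#' equation with the operator-split scheme: synaptic conductance in closed
#' form, gates by exact exponential relaxation, V and cai by an explicit
#' midpoint update. The returned trace carries the full per-sample current
#' decomposition and the instantaneous gate steady-state targets.
#'
#' @param p a [model_parameters()] object.
#' @param proto a [build_protocol()] object.
#' @param init optional [model_state()] to start from (defaults to
#'   [initialize_rest()]); settling has already happened when it is given.
#' @param dt integration step override, ms.
#' @param record_every record every n-th step (1 = every step).
#' @return an object of class `sim_trace`: a list with `data` (data.frame
#'   with columns t, V, m_cal, m_kca, cai, g_syn, I_pas, I_VGCC, I_KCa,
#'   I_GABA, I_inj, I_sum, m_inf_cal, m_inf_kca), `params`, `protocol`,
#'   `dt`, and the initial `rest` state.
#' @examples
#' p <- model_parameters(gbar_cal = 0, gbar_kca = 0)
#' proto <- build_protocol(list(current_step(50, 100, density = 1e-3)),
#'                         duration = 300, area = p$area)
#' tr <- simulate(p, proto)
#' max(tr$data$V) - p$E_pas  # ~ (1e-3/5e-5) * (1 - exp(-100/20)) = 19.87 mV
#' @export
simulate <- function(p, proto, init = NULL, dt = p$dt, record_every = 1L) {
  stopifnot(inherits(p, "model_parameters"),
            inherits(proto, "stimulus_protocol"))
  if (is.null(init)) init <- initialize_rest(p)
  s0 <- c(init$V, init$m_cal, init$m_kca, init$cai)
  out <- .integrate_model(unclass(p), s0, 0, proto$duration, dt,
                          proto$steps, proto$ipsps, proto$ipsgs,
                          as.integer(record_every))
  rec <- out$record
  df <- data.frame(t = rec[, 1], V = rec[, 2], m_cal = rec[, 3],
                   m_kca = rec[, 4], cai = rec[, 5], g_syn = rec[, 6])
  cur <- membrane_currents(df, p, I_inj = rec[, 7])
  df <- cbind(df, as.data.frame(cur))
  df$m_inf_cal <- cal_rates(df$V, p)$m_inf
  df$m_inf_kca <- kca_gate(df$cai, p)$m_inf
  structure(list(data = df, params = p, protocol = proto, dt = dt,
                 rest = init),
            class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("<sim_trace> %d samples, dt = %g ms, V in [%.2f, %.2f] mV\n",
              nrow(x$data), x$dt, min(x$data$V), max(x$data$V)))
  invisible(x)
}

#' End of the plateau-inducing stimulus
#'
#' The protocol-clock time at which the last current step ends; plateau
#' duration is measured from this offset.
#'
#' @param proto a `stimulus_protocol` (or a `sim_trace`).
#' @return time, ms; `NA` if the protocol has no current step.
#' @export
stimulus_offset <- function(proto) {
  if (inherits(proto, "sim_trace")) proto <- proto$protocol
  if (nrow(proto$steps) == 0) return(NA_real_)
  max(proto$steps[, "onset"] + proto$steps[, "duration"])
}

#' Compare the fixed-step trace against reference integrations
#'
#' Reruns the protocol with (a) the same scheme at `dt/refine` and (b)
#' optionally `deSolve::lsoda` on the exact right-hand side, and reports the
#' maximum deviations of V and cai at the coarse sample times. Used as the
#' numerical-accuracy oracle for the fixed-step scheme.
#'
#' @param p a [model_parameters()] object.
#' @param proto a [build_protocol()] object.
#' @param refine refinement factor for the fine fixed-step rerun.
#' @param lsoda also run the adaptive reference (slower).
#' @param init optional starting [model_state()].
#' @return list with `max_dV` (mV), `max_dcai` (mM) against the refined run,
#'   and if `lsoda = TRUE` also `max_dV_lsoda`, `max_dcai_lsoda`.
#' @export
verify_integrator <- function(p, proto, refine = 100, lsoda = FALSE,
                              init = NULL) {
  if (is.null(init)) init <- initialize_rest(p)
  coarse <- simulate(p, proto, init = init)
  fine <- simulate(p, proto, init = init, dt = p$dt / refine,
                   record_every = as.integer(refine))
  n <- min(nrow(coarse$data), nrow(fine$data))
  res <- list(max_dV = max(abs(coarse$data$V[1:n] - fine$data$V[1:n])),
              max_dcai = max(abs(coarse$data$cai[1:n] - fine$data$cai[1:n])))
  if (lsoda) {
    ref <- simulate_lsoda(p, proto, init = init, times = coarse$data$t)
    res$max_dV_lsoda <- max(abs(coarse$data$V - ref$V))
    res$max_dcai_lsoda <- max(abs(coarse$data$cai - ref$cai))
  }
  res
}

#' Adaptive-step reference integration (deSolve)
#'
#' Independent reference trajectory computed with `deSolve::lsoda` directly
#' on the R-level [derivatives()] right-hand side, with stimulus
#' discontinuities declared as event times. Far slower than [simulate()];
#' used only for verification.
#'
#' @inheritParams verify_integrator
#' @param times output times, ms.
#' @return data.frame with columns t, V, m_cal, m_kca, cai.
#' @export
simulate_lsoda <- function(p, proto, init = NULL, times = NULL) {
  if (is.null(init)) init <- initialize_rest(p)
  if (is.null(times)) times <- seq(0, proto$duration, by = p$dt)
  rhs <- function(t, y, parms) {
    st <- list(V = y[1], m_cal = y[2], m_kca = y[3], cai = max(y[4], 0),
               g_syn = protocol_conductance(proto, t))
    d <- derivatives(st, p, I_inj = protocol_current(proto, t))
    list(c(d$dV, d$dm_cal, d$dm_kca, d$dcai))
  }
  breaks <- sort(unique(c(proto$steps[, 1],
                          proto$steps[, 1] + proto$steps[, 2],
                          proto$ipsps[, 1], proto$ipsgs[, 1])))
  tout <- sort(unique(c(times, breaks[breaks <= max(times) & breaks >= 0])))
  y0 <- c(init$V, init$m_cal, init$m_kca, init$cai)
  sol <- deSolve::lsoda(y0, tout, rhs, parms = NULL,
                        rtol = 1e-9, atol = c(1e-9, 1e-12, 1e-12, 1e-14))
  sol <- sol[match(times, sol[, 1]), ]
  data.frame(t = sol[, 1], V = sol[, 2], m_cal = sol[, 3],
             m_kca = sol[, 4], cai = sol[, 5])
}
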