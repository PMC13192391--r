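#' Quasi-steady-state membrane current
#'
#' Total membrane current at voltage V under steady-state conditions: the
#' VGCC activation gate at `m_inf(V)`, the SK gate and the Ca2+ inactivation
#' at the given (frozen) cai. This reduces the I = 0 problem to one variable
#' in V at each instant of the plateau, with cai playing the role of the
#' slow parameter.
#'
#' @param V membrane potential, mV (vectorised).
#' @param cai frozen intracellular Ca2+, mM.
#' @param p a [model_parameters()] object.
#' @param g_syn synaptic conductance, uS.
#' @return current density, mA/cm2.
#' @export
steady_state_current <- function(V, cai, p, g_syn = 0) {
  m <- cal_rates(V, p)$m_inf
  mk <- kca_gate(cai, p)$m_inf
  h <- h_cal(cai, p)
  p$g_pas * (V - p$E_pas) +
    p$gbar_cal * m * h^2 * ghk_flux(V, cai, p$cao, p$temperature, p$F, p$R_gas) +
    p$gbar_kca * mk^3 * (V - p$E_K) +
    g_syn * 1e-6 * (V - p$E_GABA) / p$area
}

#' Solve the steady-state I = 0 equation for V
#'
#' Finds every root of [steady_state_current()] in a voltage range by a
#' dense-grid sign-change scan followed by bisection refinement, and labels
#' stability from the local current slope: since `dV/dt = -I/Cm`, a root is
#' stable iff `dI/dV > 0` (repelling otherwise).
#'
#' @inheritParams steady_state_current
#' @param V_range search range, mV.
#' @param grid_step scan resolution, mV.
#' @param refine_tol bisection tolerance on the root, mV.
#' @return data.frame with columns `V` (sorted) and `stability`
#'   (`"stable"` / `"repelling"`); zero rows when no root lies in range.
#' @export
solve_fixed_points <- function(cai, p, g_syn = 0, V_range = c(-100, 20),
                               grid_step = 0.01, refine_tol = 1e-6) {
  Vg <- seq(V_range[1], V_range[2], by = grid_step)
  I <- steady_state_current(Vg, cai, p, g_syn)
  sg <- sign(I)
  idx <- which(sg[-1] * sg[-length(sg)] < 0)
  exact <- which(I == 0)
  roots <- Vg[exact]
  for (i in idx) {
    lo <- Vg[i]; hi <- Vg[i + 1]
    flo <- I[i]
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      fm <- steady_state_current(mid, cai, p, g_syn)
      if (fm == 0) { lo <- hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- sort(unique(roots))
  if (!length(roots)) {
    return(data.frame(V = numeric(0), stability = character(0)))
  }
  eps <- 1e-4
  slope <- vapply(roots, function(v) {
    (steady_state_current(v + eps, cai, p, g_syn) -
       steady_state_current(v - eps, cai, p, g_syn)) / (2 * eps)
  }, 0)
  data.frame(V = roots,
             stability = ifelse(slope > 0, "stable", "repelling"))
}

#' Track fixed-point branches along a simulated plateau
#'
#' Runs [solve_fixed_points()] at subsampled time points using each
#' instant's cai, then links roots across time into branches by nearest-V
#' continuation (capped jump). Within the plateau range (V above rest +
#' `plateau_margin`), the stable branch is the near-stable point tracked by
#' V and the repelling branch is the termination threshold; branch
#' disappearance (a fold) ends a branch and is not an error.
#'
#' @param trace a [simulate()] trace containing a plateau.
#' @param p a [model_parameters()] object.
#' @param stride time between evaluations, ms.
#' @param window optional `(t0, t1)` restriction, ms.
#' @param jump_cap maximum V step linking a branch across evaluations, mV.
#' @param plateau_margin plateau range is V > rest + this margin, mV.
#' @return data.frame of class `fixed_point_branches`: `t`, `cai`, `V`,
#'   `stability`, `branch` (integer id), `in_plateau_range` (logical).
#' @export
track_branches <- function(trace, p, stride = 2, window = NULL,
                           jump_cap = 5, plateau_margin = 15) {
  d <- trace$data
  if (is.null(window)) window <- range(d$t)
  tt <- d$t[d$t >= window[1] & d$t <= window[2]]
  keep <- tt[seq(1, length(tt), by = max(1L, round(stride / trace$dt)))]
  rest <- trace$rest$V
  rows <- list()
  branch_v <- numeric(0)   # last V per open branch
  next_id <- 1L
  for (t0 in keep) {
    i <- which.min(abs(d$t - t0))
    fp <- solve_fixed_points(d$cai[i], p)
    ids <- integer(nrow(fp))
    used <- rep(FALSE, length(branch_v))
    if (nrow(fp)) {
      for (j in seq_len(nrow(fp))) {
        if (length(branch_v)) {
          dist <- abs(branch_v - fp$V[j])
          dist[used] <- Inf
          k <- which.min(dist)
          if (length(k) && is.finite(dist[k]) && dist[k] <= jump_cap) {
            ids[j] <- k; used[k] <- TRUE; branch_v[k] <- fp$V[j]
            next
          }
        }
        branch_v <- c(branch_v, fp$V[j])
        used <- c(used, TRUE)
        ids[j] <- length(branch_v)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        t = t0, cai = d$cai[i], V = fp$V, stability = fp$stability,
        branch = ids, in_plateau_range = fp$V > rest + plateau_margin)
    }
    # branches not matched at this time stay dormant; a later point within
    # the jump cap may resume them, otherwise they are simply ended
  }
  res <- do.call(rbind, rows)
  class(res) <- c("fixed_point_branches", class(res))
  res
}

#' I-V trajectory over a time window
#'
#' Orders the (V, I_sum) path of a trace over a window and reports whether
#' the path crosses the I = 0 line with a slope reversal (the signature of
#' an encounter with the repelling point: subthreshold IPSPs cross and turn
#' back, suprathreshold ones approach without crossing before the final
#' outward excursion).
#'
#' @param trace a [simulate()] trace.
#' @param window `(t0, t1)` on the trace clock, ms.
#' @param i_eps currents smaller than this are treated as "on the line"
#'   when the window starts at rest, mA/cm2.
#' @return list `path` (data.frame t, V, I_sum), `crossed` (logical:
#'   crossing with V-slope reversal), `crossings` (data.frame t, V at sign
#'   changes), `reversed` (logical: V slope reverses inside the window).
#' @export
iv_trajectory <- function(trace, window, i_eps = 1e-9) {
  d <- trace$data
  if (window[1] < min(d$t) || window[2] > max(d$t)) stop("window outside trace")
  seg <- d[d$t >= window[1] & d$t <= window[2], c("t", "V", "I_sum")]
  I <- seg$I_sum
  sg <- sign(I)
  idx <- which(sg[-1] * sg[-length(sg)] < 0)
  crossings <- data.frame(t = seg$t[idx], V = seg$V[idx])
  dV <- diff(seg$V)
  reversed <- any(dV > 1e-12) && any(dV < -1e-12)
  list(path = seg, crossed = nrow(crossings) > 0 && reversed,
       crossings = crossings, reversed = reversed)
}

#' Gate lag relative to the steady-state target
#'
#' Per-sample difference between each activation gate and its instantaneous
#' steady-state value: the VGCC lag `m_cal - m_inf(V)` is the mechanism
#' that lets fast IPSPs reach hyperpolarized voltages without terminating
#' the plateau (m stays high while V drops, transiently boosting the
#' inward Ca2+ current).
#'
#' @param trace a [simulate()] trace.
#' @param window optional `(t0, t1)` for the summary, ms (defaults to the
#'   whole trace).
#' @return data.frame `t`, `lag_cal`, `lag_kca`, with attributes
#'   `max_lag_cal` and `max_lag_kca` (maximum absolute lag in the window).
#' @export
gate_lag_analysis <- function(trace, window = NULL) {
  d <- trace$data
  out <- data.frame(t = d$t,
                    lag_cal = d$m_cal - d$m_inf_cal,
                    lag_kca = d$m_kca - d$m_inf_kca)
  if (is.null(window)) window <- range(d$t)
  w <- out[out$t >= window[1] & out$t <= window[2], ]
  attr(out, "max_lag_cal") <- max(abs(w$lag_cal))
  attr(out, "max_lag_kca") <- max(abs(w$lag_kca))
  out
}

#' Dynamic termination threshold versus IPSP speed
#'
#' For each converged threshold pair, the estimated termination threshold
#' is the most hyperpolarized V reached during the just-subthreshold IPSP,
#' and the IPSP maximum |dV/dt| is measured from the just-suprathreshold
#' IPSP. Fast approaches collapse the threshold to more hyperpolarized
#' values.
#'
#' @param pairs list of [find_termination_threshold()] results (or lists
#'   with `sub_trace`, `supra_trace`, `control`, `ipsg_onset`, `tau_syn`).
#' @param window feature window after IPSG onset, ms.
#' @return data.frame with one row per pair: `tau_syn`, `max_dVdt`
#'   (mV/ms, suprathreshold), `threshold_V` (mV, subthreshold minimum).
#' @export
estimate_dynamic_threshold <- function(pairs, window = 50) {
  rows <- lapply(pairs, function(pr) {
    if (is.null(pr$sub_trace) || is.null(pr$supra_trace)) {
      stop("pair without sub/supra traces (non-bracketing)")
    }
    if (!is.null(pr$verdict_sub) &&
        (isTRUE(pr$verdict_sub$terminated) || !isTRUE(pr$verdict_supra$terminated))) {
      stop("non-bracketing pair: verdicts do not straddle the threshold")
    }
    onset_abs <- pr$control$onset + pr$ipsg_onset
    sub <- measure_ipsp_features(pr$sub_trace, onset_abs, window)
    supra <- measure_ipsp_features(pr$supra_trace, onset_abs, window)
    data.frame(tau_syn = if (is.null(pr$tau_syn)) NA_real_ else pr$tau_syn,
               max_dVdt = supra$max_dVdt, threshold_V = sub$min_V)
  })
  do.call(rbind, rows)
}
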