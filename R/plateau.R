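#' Plateau-detection configuration
#'
#' Operational definitions used by [detect_plateau()] and
#' [classify_termination()].
#'
#' @param ref_delay delay after stimulus offset at which the plateau
#'   reference voltage is read, ms.
#' @param persist minimum time V must stay above the half-repolarization
#'   level beyond offset to count as a plateau, ms.
#' @param outlast regenerative requirement: V must additionally stay above
#'   the half level for this long beyond offset (three membrane time
#'   constants), so stimulus-inflated passive tails never qualify, ms.
#' @param min_elev minimum elevation of the reference voltage above rest,
#'   mV (rejects passive afterdepolarizations).
#' @param rest_margin "back at rest" band for termination classification, mV.
#' @param term_window window after IPSG onset within which V must reach the
#'   rest band for a termination verdict, ms.
#' @param remain_frac terminated trials must retain less than this fraction
#'   of the control's post-onset remaining duration.
#' @param smooth_ms running-median width applied to V before threshold
#'   crossings are detected, ms (noise robustness; ~identity on clean
#'   traces).
#' @return a list of class `plateau_config`.
#' @export
plateau_config <- function(ref_delay = 5, persist = 20, outlast = 60,
                           min_elev = 20,
                           rest_margin = 5, term_window = 130,
                           remain_frac = 0.5, smooth_ms = 1) {
  structure(list(ref_delay = ref_delay, persist = persist, outlast = outlast,
                 min_elev = min_elev, rest_margin = rest_margin,
                 term_window = term_window, remain_frac = remain_frac,
                 smooth_ms = smooth_ms),
            class = "plateau_config")
}

#' Detect a plateau and measure its duration
#'
#' A plateau is present when, beyond the offset of the triggering current
#' step, V stays above the half-repolarization level -- the midpoint between
#' the voltage read `ref_delay` ms after offset and the resting voltage --
#' for at least `persist` ms (and, to exclude stimulus-inflated passive
#' tails, for `outlast` ms), with the reference at least `min_elev` mV
#' above rest. Duration runs from stimulus offset to the final crossing of
#' the half level -- a transient dip the plateau survives does not count as
#' the end -- and the break point is the voltage at maximal repolarization
#' speed near that crossing. Traces that never cross are flagged
#' `nonrepolarizing`.
#'
#' @param trace a [simulate()] trace whose protocol contains a current step.
#' @param cfg a [plateau_config()].
#' @return a list of class `plateau_metrics`: `plateau_present`, `onset`
#'   (stimulus offset, ms), `duration` (ms; `Inf` when nonrepolarizing),
#'   `plateau_level` (reference V, mV), `break_point_V` / `break_point_t`,
#'   `nonrepolarizing`, `rest_V`, `half_level`.
#' @export
detect_plateau <- function(trace, cfg = plateau_config()) {
  stopifnot(inherits(trace, "sim_trace"))
  off <- stimulus_offset(trace)
  if (is.na(off)) stop("protocol has no current step; no stimulus offset")
  d <- trace$data
  if (max(d$t) <= off) stop("trace ends before the stimulus offset")
  # short running-median smoothing keeps the half-crossing estimate robust
  # to recording noise (first-passage bias on the slow repolarization)
  k <- max(1L, round(cfg$smooth_ms / trace$dt))
  if (k %% 2 == 0) k <- k + 1L
  if (k > 1L && k < nrow(d)) d$V <- stats::runmed(d$V, k, endrule = "median")
  rest <- trace$rest$V
  vref <- d$V[which.min(abs(d$t - (off + cfg$ref_delay)))]
  half <- (vref + rest) / 2
  post <- d[d$t >= off, c("t", "V")]
  eligible <- post$t > off + cfg$ref_delay
  below <- which(post$V < half & eligible)
  # the crossing that defines the plateau end is the start of the FINAL
  # below-half run: a transient dip (an IPSP the plateau survives) must not
  # count as the end
  nonrep <- length(below) == 0L || post$V[nrow(post)] >= half
  if (!nonrep) {
    above_after <- which(post$V >= half & eligible)
    last_above <- if (length(above_after)) max(above_after) else 0L
    crossing <- post$t[below[below > last_above][1]]
  } else {
    crossing <- Inf
  }
  duration <- crossing - off
  first_cross <- if (length(below)) post$t[below[1]] - off else Inf
  present <- (vref >= rest + cfg$min_elev) &&
    (first_cross >= max(cfg$persist, cfg$outlast))
  bp_V <- bp_t <- NA_real_
  if (!nonrep) {
    # search near the detected end so an earlier IPSP transient cannot be
    # mistaken for the final repolarization
    seg <- post[post$t >= crossing - 30 & post$t <= crossing + 60, ]
    dv <- diff(seg$V) / diff(seg$t)
    i <- which.min(dv)
    bp_V <- seg$V[i]
    bp_t <- seg$t[i]
  }
  structure(list(plateau_present = present, onset = off,
                 duration = if (present) duration else if (nonrep) Inf else duration,
                 plateau_level = vref, break_point_V = bp_V,
                 break_point_t = bp_t,
                 nonrepolarizing = nonrep, rest_V = rest, half_level = half),
            class = "plateau_metrics")
}

#' @export
print.plateau_metrics <- function(x, ...) {
  cat(sprintf("<plateau_metrics> present: %s, duration: %s ms, level %.1f mV, break %.1f mV\n",
              x$plateau_present,
              if (is.finite(x$duration)) sprintf("%.1f", x$duration) else "Inf (nonrepolarizing)",
              x$plateau_level, x$break_point_V))
  invisible(x)
}

#' Classify an IPSG trial as terminated or not
#'
#' A trial counts as terminated only if (a) V reaches the rest band
#' (within `rest_margin` mV of rest) within `term_window` ms of the IPSG
#' onset, and (b) the plateau time remaining after onset is less than
#' `remain_frac` of the control's remaining time at the same onset. The
#' conjunction prevents the IPSP transient itself (which dips toward rest
#' and recovers) from being scored as a termination.
#'
#' @param trial a [simulate()] trace containing the IPSG.
#' @param control [detect_plateau()] metrics of the matching no-IPSG trace.
#' @param ipsg_onset IPSG onset relative to the stimulus offset, ms.
#' @param cfg a [plateau_config()].
#' @return list `terminated` (logical) and `termination_time` (ms after
#'   IPSG onset; `NA` when not terminated).
#' @export
classify_termination <- function(trial, control, ipsg_onset,
                                 cfg = plateau_config()) {
  stopifnot(inherits(control, "plateau_metrics"))
  if (!control$plateau_present) stop("control trace has no plateau")
  if (ipsg_onset < 0 || ipsg_onset >= control$duration) {
    stop("ipsg_onset lies outside the control plateau")
  }
  m <- detect_plateau(trial, cfg)
  off <- control$onset
  t_on <- off + ipsg_onset
  d <- trial$data
  win <- d[d$t >= t_on & d$t <= t_on + cfg$term_window, ]
  at_rest <- which(win$V <= control$rest_V + cfg$rest_margin)
  reached <- length(at_rest) > 0L
  remain_trial <- m$duration - ipsg_onset
  remain_ctrl <- control$duration - ipsg_onset
  collapsed <- is.finite(remain_trial) &&
    remain_trial < cfg$remain_frac * remain_ctrl
  terminated <- reached && collapsed
  list(terminated = terminated,
       termination_time = if (terminated) win$t[at_rest[1]] - t_on else NA_real_,
       trial_duration = m$duration)
}

#' Find the just-suprathreshold plateau-inducing current step
#'
#' Doubles a seed current-step density until the response qualifies as a
#' plateau under [detect_plateau()], mirroring just-suprathreshold current
#' injection.
#'
#' @param p a [model_parameters()] object.
#' @param rest optional settled [model_state()] (computed if missing).
#' @param onset,width step onset and width, ms.
#' @param seed starting density, mA/cm2.
#' @param duration simulated time, ms.
#' @param max_doublings give up after this many doublings.
#' @param cfg a [plateau_config()].
#' @return list `proto` (the protocol), `amplitude` (density, mA/cm2),
#'   `metrics` (control [detect_plateau()] result), `trace`, `rest`.
#' @export
find_plateau_step <- function(p, rest = NULL, onset = 20, width = 50,
                              seed = 1e-4, duration = 1500,
                              max_doublings = 14, cfg = plateau_config()) {
  if (is.null(rest)) rest <- initialize_rest(p)
  amp <- seed
  for (k in seq_len(max_doublings)) {
    proto <- build_protocol(list(current_step(onset, width, density = amp)),
                            duration = duration, area = p$area)
    tr <- tryCatch(simulate(p, proto, init = rest), error = function(e) NULL)
    if (!is.null(tr)) {
      m <- detect_plateau(tr, cfg)
      if (m$plateau_present) {
        return(list(proto = proto, amplitude = amp, metrics = m,
                    trace = tr, rest = rest))
      }
    }
    amp <- amp * 2
  }
  stop("no plateau evoked within ", max_doublings, " doublings of the seed step")
}

#' All-or-none termination threshold by bisection
#'
#' Doubles the IPSG peak conductance from a seed until a terminating
#' amplitude is found, then bisects the bracket to a relative tolerance.
#'
#' @param p a [model_parameters()] object.
#' @param plateau_proto no-IPSG protocol that evokes the control plateau.
#' @param ipsg_onset IPSG onset after stimulus offset, ms.
#' @param tau_syn IPSG decay time constant, ms.
#' @param seed_g starting conductance, uS.
#' @param rel_tol relative bracket tolerance on g.
#' @param max_doublings abort ("unterminable") beyond this many doublings.
#' @param rest optional settled state.
#' @param cfg a [plateau_config()].
#' @param runner optional replacement evaluation function `g -> list(trace,
#'   verdict)` (testing seam; the default runs the model and
#'   [classify_termination()]).
#' @return list of class `threshold_result`: `g_star` (uS, the terminating
#'   bracket end), `bracket` `(sub, supra)`, `rel_tol`, `sub_trace`,
#'   `supra_trace`, `verdict_sub`, `verdict_supra`, `control`, `ipsg_onset`,
#'   `tau_syn`.
#' @export
find_termination_threshold <- function(p, plateau_proto, ipsg_onset,
                                       tau_syn = 5, seed_g = 1e-5,
                                       rel_tol = 0.005, max_doublings = 30,
                                       rest = NULL, cfg = plateau_config(),
                                       runner = NULL) {
  if (is.null(runner)) {
    if (is.null(rest)) rest <- initialize_rest(p)
    control_tr <- simulate(p, plateau_proto, init = rest)
    control <- detect_plateau(control_tr, cfg)
    if (!control$plateau_present) stop("no plateau without IPSG; nothing to terminate")
    off <- control$onset
    run <- function(g) {
      pr <- with_events(plateau_proto, ipsg_event(off + ipsg_onset, g, tau_syn))
      tr <- simulate(p, pr, init = rest)
      list(trace = tr, verdict = classify_termination(tr, control, ipsg_onset, cfg))
    }
  } else {
    run <- runner
    control_tr <- NULL
    control <- NULL
  }
  hi <- seed_g
  hi_run <- run(hi)
  n <- 0
  while (!hi_run$verdict$terminated) {
    n <- n + 1
    if (n > max_doublings) {
      stop("unterminable: no terminating IPSG within ", max_doublings,
           " doublings of the seed")
    }
    hi <- hi * 2
    hi_run <- run(hi)
  }
  lo <- hi / 2
  lo_run <- if (n == 0) run(0) else run(lo)
  if (n == 0) lo <- 0
  it <- 0
  while (hi - lo > rel_tol * hi && it < 60) {
    it <- it + 1
    mid <- (lo + hi) / 2
    mr <- run(mid)
    if (mr$verdict$terminated) { hi <- mid; hi_run <- mr }
    else { lo <- mid; lo_run <- mr }
  }
  structure(list(g_star = hi, bracket = c(sub = lo, supra = hi),
                 rel_tol = rel_tol,
                 sub_trace = lo_run$trace, supra_trace = hi_run$trace,
                 verdict_sub = lo_run$verdict, verdict_supra = hi_run$verdict,
                 control = control, control_trace = control_tr,
                 ipsg_onset = ipsg_onset, tau_syn = tau_syn),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> g* = %.4g uS at onset %g ms (tau %g ms), bracket [%.4g, %.4g]\n",
              x$g_star, x$ipsg_onset, x$tau_syn, x$bracket[1], x$bracket[2]))
  invisible(x)
}

#' IPSG timing sweep
#'
#' Delivers an IPSG of fixed amplitude and decay at a list of onsets along
#' the plateau and records the termination verdict at each onset. Onsets at
#' or beyond the spontaneous plateau end are marked not-applicable.
#'
#' @inheritParams find_termination_threshold
#' @param g_max IPSG peak conductance, uS.
#' @param times onsets after stimulus offset, ms.
#' @return data.frame of class `sweep_result` with columns `time`, `g_max`,
#'   `tau_syn`, `applicable`, `terminated`, `termination_time`, `duration`.
#' @export
sweep_timing <- function(p, plateau_proto, g_max, tau_syn = 5,
                         times = seq(10, 100, by = 5), rest = NULL,
                         cfg = plateau_config()) {
  stopifnot(!is.unsorted(times, strictly = TRUE))
  if (is.null(rest)) rest <- initialize_rest(p)
  control_tr <- simulate(p, plateau_proto, init = rest)
  control <- detect_plateau(control_tr, cfg)
  if (!control$plateau_present) stop("no control plateau")
  off <- control$onset
  out <- lapply(times, function(t_on) {
    if (t_on >= control$duration) {
      return(data.frame(time = t_on, g_max = g_max, tau_syn = tau_syn,
                        applicable = FALSE, terminated = NA,
                        termination_time = NA_real_, duration = NA_real_))
    }
    pr <- with_events(plateau_proto, ipsg_event(off + t_on, g_max, tau_syn))
    tr <- simulate(p, pr, init = rest)
    v <- classify_termination(tr, control, t_on, cfg)
    data.frame(time = t_on, g_max = g_max, tau_syn = tau_syn,
               applicable = TRUE, terminated = v$terminated,
               termination_time = v$termination_time,
               duration = v$trial_duration)
  })
  res <- do.call(rbind, out)
  attr(res, "control_duration") <- control$duration
  class(res) <- c("sweep_result", class(res))
  res
}

#' IPSG amplitude-by-decay-tau sweep
#'
#' Explores the IPSG parameter plane at a fixed onset and records which
#' (amplitude, tau) pairs terminate the plateau.
#'
#' @inheritParams find_termination_threshold
#' @param amp_grid increasing IPSG amplitudes, uS.
#' @param tau_grid increasing decay time constants, ms.
#' @param onset IPSG onset after stimulus offset, ms.
#' @return data.frame of class `sweep_result`, one row per grid cell, with
#'   columns `g_max`, `tau_syn`, `terminated`, `termination_time`,
#'   `duration`.
#' @export
sweep_amp_tau <- function(p, plateau_proto, amp_grid, tau_grid, onset = 50,
                          rest = NULL, cfg = plateau_config()) {
  stopifnot(!is.unsorted(amp_grid, strictly = TRUE),
            !is.unsorted(tau_grid, strictly = TRUE))
  if (is.null(rest)) rest <- initialize_rest(p)
  control_tr <- simulate(p, plateau_proto, init = rest)
  control <- detect_plateau(control_tr, cfg)
  if (!control$plateau_present) stop("no control plateau")
  off <- control$onset
  cells <- expand.grid(g_max = amp_grid, tau_syn = tau_grid)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    g <- cells$g_max[i]; ts <- cells$tau_syn[i]
    if (g == 0) {
      v <- list(terminated = FALSE, termination_time = NA_real_,
                trial_duration = control$duration)
    } else {
      pr <- with_events(plateau_proto, ipsg_event(off + onset, g, ts))
      tr <- simulate(p, pr, init = rest)
      v <- classify_termination(tr, control, onset, cfg)
    }
    data.frame(g_max = g, tau_syn = ts, terminated = v$terminated,
               termination_time = v$termination_time,
               duration = v$trial_duration)
  })
  res <- do.call(rbind, out)
  attr(res, "onset") <- onset
  attr(res, "control_duration") <- control$duration
  class(res) <- c("sweep_result", class(res))
  res
}

#' Minimal terminating amplitude per decay tau
#'
#' Extracts, for each `tau_syn` in an amplitude-by-tau sweep, the smallest
#' amplitude whose cell terminated (`NA` when none did). For a monotone
#' (up-set) verdict structure this is the termination boundary of the
#' parameter plane.
#'
#' @param sweep a [sweep_amp_tau()] result (or any data.frame with columns
#'   `g_max`, `tau_syn`, `terminated`).
#' @return data.frame `tau_syn`, `g_min` sorted by `tau_syn`.
#' @export
threshold_boundary <- function(sweep) {
  d <- as.data.frame(sweep)
  taus <- sort(unique(d$tau_syn))
  g_min <- vapply(taus, function(ts) {
    g <- d$g_max[d$tau_syn == ts & d$terminated %in% TRUE]
    if (length(g)) min(g) else NA_real_
  }, 0)
  data.frame(tau_syn = taus, g_min = g_min)
}

#' IPSP waveform features
#'
#' Minimum voltage, IPSP amplitude (pre-onset V minus minimum V) and the
#' maximum hyperpolarizing rate of change within a window after an
#' IPSG/mock-IPSP onset.
#'
#' @param trace a [simulate()] trace.
#' @param onset event onset on the trace clock, ms.
#' @param window analysis window length after onset, ms.
#' @return list `min_V` (mV), `min_V_t` (ms), `ipsp_amplitude` (mV),
#'   `max_dVdt` (mV/ms, magnitude of the steepest hyperpolarizing slope).
#' @export
measure_ipsp_features <- function(trace, onset, window = 50) {
  d <- trace$data
  if (onset < min(d$t) || onset > max(d$t)) stop("onset outside trace")
  if (onset + window > max(d$t)) {
    warning("window exceeds trace; truncated")
    window <- max(d$t) - onset
  }
  pre_i <- which(d$t < onset)
  pre <- if (length(pre_i)) d$V[max(pre_i)] else d$V[1]
  win <- d[d$t >= onset & d$t <= onset + window, ]
  i_min <- which.min(win$V)
  dv <- diff(win$V) / diff(win$t)
  list(min_V = win$V[i_min], min_V_t = win$t[i_min],
       ipsp_amplitude = pre - win$V[i_min],
       max_dVdt = max(0, -min(dv)))
}
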