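#' Stimulus events
#'
#' Event constructors for [build_protocol()]. Three kinds are supported:
#' a rectangular current step, a mock IPSP (an instantaneous hyperpolarizing
#' current that decays exponentially, emulating somatic injection of an
#' IPSP-shaped waveform), and an inhibitory synaptic conductance event (IPSG:
#' instantaneous rise by `g_max`, single-exponential decay with `tau_syn`
#' toward the GABA reversal).
#'
#' Current amplitudes may be given as absolute currents in pA (`amplitude`)
#' or as densities in mA/cm2 (`density`); pA values are converted with the
#' compartment area at [build_protocol()] time. Note that absolute pA values
#' from somatic recordings do not transfer to a lone 10 um sphere (input
#' resistance in the GOhm range), so model protocols are normally specified
#' just-suprathreshold via [find_plateau_step()].
#'
#' @param onset event onset, ms (protocol clock; 0 = end of settling).
#' @param duration step duration, ms.
#' @param amplitude absolute current, pA (positive = depolarizing for steps,
#'   magnitude of the hyperpolarizing transient for mock IPSPs).
#' @param density current density, mA/cm2 (alternative to `amplitude`).
#' @param tau_decay mock-IPSP decay time constant, ms.
#' @param g_max IPSG peak conductance, uS.
#' @param tau_syn IPSG decay time constant, ms.
#' @return an event list, to be passed to [build_protocol()].
#' @name stimulus_events
NULL

#' @rdname stimulus_events
#' @export
current_step <- function(onset, duration, amplitude = NULL, density = NULL) {
  list(kind = "step", onset = onset, duration = duration,
       amplitude = amplitude, density = density)
}

#' @rdname stimulus_events
#' @export
mock_ipsp <- function(onset, amplitude = NULL, tau_decay = 30, density = NULL) {
  list(kind = "ipsp", onset = onset, amplitude = amplitude,
       density = density, tau_decay = tau_decay)
}

#' @rdname stimulus_events
#' @export
ipsg_event <- function(onset, g_max, tau_syn) {
  list(kind = "ipsg", onset = onset, g_max = g_max, tau_syn = tau_syn)
}

#' Assemble and validate a stimulus protocol
#'
#' Canonicalises a list of [stimulus_events] into matrices consumed by
#' [simulate()]: current steps and mock IPSPs as current densities (pA
#' amplitudes divided by the compartment area), IPSG events as conductance
#' jumps with exponential decay. The protocol clock starts after the settling
#' period, at t = 0.
#'
#' @param events list of events from [current_step()], [mock_ipsp()],
#'   [ipsg_event()].
#' @param duration total simulated time after settling, ms.
#' @param settle settling time before the protocol, ms.
#' @param area compartment area used for pA-to-density conversion, cm2.
#' @return an object of class `stimulus_protocol`.
#' @examples
#' proto <- build_protocol(list(current_step(100, 50, amplitude = 150)),
#'                         duration = 600)
#' proto$steps  # density ~4.77e-2 mA/cm2 for the default area
#' @export
build_protocol <- function(events = list(), duration = 1000, settle = 2000,
                           area = pi * (10e-4)^2) {
  stopifnot(duration > 0, settle >= 0, area > 0)
  if (!is.null(events$kind)) events <- list(events)  # single bare event
  to_density <- function(amplitude, density) {
    if (is.null(density) && is.null(amplitude)) {
      stop("event needs either `amplitude` (pA) or `density` (mA/cm2)")
    }
    if (!is.null(density)) density else amplitude * 1e-9 / area
  }
  steps <- ipsps <- ipsgs <- NULL
  for (ev in events) {
    if (!is.list(ev) || is.null(ev$kind)) stop("malformed event")
    if (is.null(ev$onset) || !is.finite(ev$onset) || ev$onset < 0) {
      stop("event onset must be a finite number >= 0")
    }
    if (ev$kind == "step") {
      if (ev$duration <= 0) stop("step duration must be > 0")
      steps <- rbind(steps, c(ev$onset, ev$duration,
                              to_density(ev$amplitude, ev$density)))
    } else if (ev$kind == "ipsp") {
      if (ev$tau_decay <= 0) stop("mock IPSP tau_decay must be > 0")
      amp <- to_density(ev$amplitude, ev$density)
      if (amp < 0) stop("mock IPSP amplitude is a magnitude; must be >= 0")
      ipsps <- rbind(ipsps, c(ev$onset, amp, ev$tau_decay))
    } else if (ev$kind == "ipsg") {
      if (ev$g_max < 0) stop("IPSG g_max must be >= 0")
      if (ev$tau_syn <= 0) stop("IPSG tau_syn must be > 0")
      ipsgs <- rbind(ipsgs, c(ev$onset, ev$g_max, ev$tau_syn))
    } else stop("unknown event kind: ", ev$kind)
  }
  as_mat <- function(m, cols) {
    if (is.null(m)) m <- matrix(numeric(0), 0, length(cols))
    m <- m[order(m[, 1]), , drop = FALSE]
    colnames(m) <- cols
    m
  }
  steps <- as_mat(steps, c("onset", "duration", "density"))
  ipsps <- as_mat(ipsps, c("onset", "density", "tau_decay"))
  ipsgs <- as_mat(ipsgs, c("onset", "g_max", "tau_syn"))
  if (nrow(steps) > 1) {
    ends <- steps[, "onset"] + steps[, "duration"]
    if (any(steps[-1, "onset"] < ends[-nrow(steps)])) {
      stop("overlapping current steps are not supported")
    }
  }
  structure(list(duration = duration, settle = settle, area = area,
                 steps = steps, ipsps = ipsps, ipsgs = ipsgs),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %g ms (+%g ms settle): %d step(s), %d mock IPSP(s), %d IPSG(s)\n",
              x$duration, x$settle, nrow(x$steps), nrow(x$ipsps),
              nrow(x$ipsgs)))
  invisible(x)
}

#' Add events to an existing protocol
#'
#' @param proto a `stimulus_protocol`.
#' @param ... events from the [stimulus_events] constructors.
#' @return a new validated `stimulus_protocol`.
#' @export
with_events <- function(proto, ...) {
  stopifnot(inherits(proto, "stimulus_protocol"))
  evs <- protocol_events(proto)
  build_protocol(c(evs, list(...)), duration = proto$duration,
                 settle = proto$settle, area = proto$area)
}

# back-convert a protocol's matrices into an event list (densities kept)
protocol_events <- function(proto) {
  evs <- list()
  for (i in seq_len(nrow(proto$steps))) {
    evs[[length(evs) + 1L]] <- current_step(proto$steps[i, 1],
                                            proto$steps[i, 2],
                                            density = proto$steps[i, 3])
  }
  for (i in seq_len(nrow(proto$ipsps))) {
    evs[[length(evs) + 1L]] <- mock_ipsp(proto$ipsps[i, 1],
                                         density = proto$ipsps[i, 2],
                                         tau_decay = proto$ipsps[i, 3])
  }
  for (i in seq_len(nrow(proto$ipsgs))) {
    evs[[length(evs) + 1L]] <- ipsg_event(proto$ipsgs[i, 1],
                                          proto$ipsgs[i, 2],
                                          proto$ipsgs[i, 3])
  }
  evs
}

#' Injected current and synaptic conductance of a protocol at time t
#'
#' Closed-form evaluation of the stimulus waveforms (used by the reference
#' integrators and for plotting).
#'
#' @param proto a `stimulus_protocol`.
#' @param t time(s) on the protocol clock, ms (vectorised).
#' @return `protocol_current`: injected current density, mA/cm2;
#'   `protocol_conductance`: synaptic conductance, uS.
#' @export
protocol_current <- function(proto, t) {
  I <- numeric(length(t))
  for (i in seq_len(nrow(proto$steps))) {
    on <- proto$steps[i, 1]
    I <- I + ifelse(t >= on & t < on + proto$steps[i, 2],
                    proto$steps[i, 3], 0)
  }
  for (i in seq_len(nrow(proto$ipsps))) {
    on <- proto$ipsps[i, 1]
    I <- I - ifelse(t >= on,
                    proto$ipsps[i, 2] * exp(-(t - on) / proto$ipsps[i, 3]), 0)
  }
  I
}

#' @rdname protocol_current
#' @export
protocol_conductance <- function(proto, t) {
  g <- numeric(length(t))
  for (i in seq_len(nrow(proto$ipsgs))) {
    on <- proto$ipsgs[i, 1]
    g <- g + ifelse(t >= on,
                    proto$ipsgs[i, 2] * exp(-(t - on) / proto$ipsgs[i, 3]), 0)
  }
  g
}
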