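# Shared fixtures, computed lazily once per test run.

.pk_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .pk_cache)) {
    assign(name, force(expr), envir = .pk_cache)
  }
  get(name, envir = .pk_cache)
}

fix_params <- function() cached("params", model_parameters())

fix_rest <- function() cached("rest", initialize_rest(fix_params()))

# just-suprathreshold 50 ms step at the calibrated defaults
fix_step <- function() cached("step", {
  find_plateau_step(fix_params(), rest = fix_rest())
})

# IPSG termination threshold at onset 50 ms, default tau
fix_thr50 <- function() cached("thr50", {
  fs <- fix_step()
  find_termination_threshold(fix_params(), fs$proto, ipsg_onset = 50,
                             rest = fix_rest())
})

# threshold pairs across the synaptic tau sweep (includes tau 5 = thr50)
fix_tau_pairs <- function() cached("tau_pairs", {
  fs <- fix_step()
  taus <- c(5, 10, 20, 40, 80)
  out <- lapply(taus, function(ts) {
    if (ts == 5) return(fix_thr50())
    find_termination_threshold(fix_params(), fs$proto, ipsg_onset = 50,
                               tau_syn = ts, rest = fix_rest())
  })
  names(out) <- paste0("tau", taus)
  out
})

# hand-built trace: rest -65, instantaneous plateau at -10 mV from t = 100
# to 300 ms, stimulus 100-150 ms, instant fall back to rest
fix_boxcar_trace <- function(dt = 0.1) {
  t <- seq(0, 400, by = dt)
  V <- ifelse(t >= 100 & t < 300, -10, -65)
  fake_trace(t, V, dt = dt,
             proto = build_protocol(list(current_step(100, 50, density = 1e-3)),
                                    duration = 400))
}

# wrap arbitrary (t, V) samples in a sim_trace-compatible object
fake_trace <- function(t, V, dt = t[2] - t[1], proto = NULL, rest_V = -65) {
  d <- data.frame(t = t, V = V, m_cal = 0, m_kca = 0, cai = 1e-4, g_syn = 0,
                  I_pas = 0, I_VGCC = 0, I_KCa = 0, I_GABA = 0, I_inj = 0,
                  I_sum = 0, m_inf_cal = 0, m_inf_kca = 0)
  structure(list(data = d, params = model_parameters(), protocol = proto,
                 dt = dt,
                 rest = model_state(V = rest_V, m_cal = 0, m_kca = 0,
                                    cai = 1e-4)),
            class = "sim_trace")
}
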