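test_that("plateau detection on constructed and passive traces", {
  # boxcar: rest -65, -10 mV from 100 to 300 ms, stimulus offset 150 ms
  tr <- fix_boxcar_trace()
  m <- detect_plateau(tr)
  expect_true(m$plateau_present)
  expect_false(m$nonrepolarizing)
  expect_equal(m$onset, 150)
  expect_equal(m$duration, 150, tolerance = 0.02)
  expect_lt(m$half_level, -35)  # midpoint of -10 and -65

  # passive RC decay fails the 20 ms persistence requirement
  t <- seq(0, 400, by = 0.1)
  V <- ifelse(t < 100, -65,
              ifelse(t < 150, -20, -65 + 45 * exp(-(t - 150) / 20)))
  rc <- fake_trace(t, V, proto = build_protocol(
    list(current_step(100, 50, density = 1e-3)), duration = 400))
  expect_false(detect_plateau(rc)$plateau_present)

  # never-repolarizing trace is flagged
  Vn <- ifelse(t < 100, -65, -12)
  nr <- fake_trace(t, Vn, proto = build_protocol(
    list(current_step(100, 50, density = 1e-3)), duration = 400))
  mn <- detect_plateau(nr)
  expect_true(mn$nonrepolarizing)
  expect_true(is.infinite(mn$duration))

  # a trace ending before the stimulus is rejected
  short <- fake_trace(seq(0, 90, by = 0.1), rep(-65, 901),
                      proto = build_protocol(
                        list(current_step(100, 50, density = 1e-3)),
                        duration = 400))
  expect_error(detect_plateau(short), "offset")
})

test_that("termination classification separates collapse from the IPSP transient", {
  tr <- fix_boxcar_trace()
  control <- detect_plateau(tr)
  dt <- 0.1; t <- tr$data$t

  # trial falling to rest 8 ms after an IPSG at +50 ms -> terminated
  V1 <- ifelse(t >= 100 & t < 208, -10, -65)
  trial1 <- fake_trace(t, V1, proto = tr$protocol)
  v1 <- classify_termination(trial1, control, ipsg_onset = 50)
  expect_true(v1$terminated)
  expect_equal(v1$termination_time, 8, tolerance = 0.2)

  # a 5 mV transient dip that rejoins the plateau -> not terminated
  V2 <- ifelse(t >= 100 & t < 300, -10, -65)
  V2[t >= 200 & t < 210] <- -15
  trial2 <- fake_trace(t, V2, proto = tr$protocol)
  expect_false(classify_termination(trial2, control, 50)$terminated)

  # an onset outside the plateau is rejected
  expect_error(classify_termination(trial2, control, 200), "outside")
})

test_that("bisection recovers a step-function threshold through the runner seam", {
  # stub: duration 200 ms for g < 1, immediate collapse for g >= 1
  stub <- function(g) {
    terminated <- g >= 1
    list(trace = NULL,
         verdict = list(terminated = terminated,
                        termination_time = if (terminated) 5 else NA,
                        trial_duration = if (terminated) 20 else 200))
  }
  thr <- find_termination_threshold(NULL, NULL, ipsg_onset = 50,
                                    seed_g = 0.01, runner = stub)
  expect_lt(abs(thr$g_star - 1) / 1, 0.005)
  expect_true(thr$bracket["sub"] < thr$g_star)
  expect_false(thr$verdict_sub$terminated)
  expect_true(thr$verdict_supra$terminated)

  # no terminating amplitude -> explicit unterminable diagnostic
  never <- function(g) list(trace = NULL,
                            verdict = list(terminated = FALSE,
                                           trial_duration = 200))
  expect_error(find_termination_threshold(NULL, NULL, 50, seed_g = 1e-9,
                                          max_doublings = 10, runner = never),
               "unterminable")
})

test_that("model all-or-none: sharp duration jump and verdict monotonicity in g", {
  p <- fix_params(); r <- fix_rest(); fs <- fix_step(); thr <- fix_thr50()
  ctrl <- thr$control
  off <- ctrl$onset
  dur_at <- function(g) {
    pr <- with_events(fs$proto, ipsg_event(off + 50, g, thr$tau_syn))
    detect_plateau(simulate(p, pr, init = r))$duration
  }
  gap <- dur_at(0.99 * thr$g_star) - dur_at(1.01 * thr$g_star)
  expect_gt(gap, 50)
  # verdicts at 2x and 0.5x the threshold
  run <- function(g) {
    pr <- with_events(fs$proto, ipsg_event(off + 50, g, thr$tau_syn))
    classify_termination(simulate(p, pr, init = r), ctrl, 50)$terminated
  }
  expect_true(run(2 * thr$g_star))
  expect_false(run(0.5 * thr$g_star))
})

test_that("timing sweep: early resistance and monotone verdicts", {
  p <- fix_params(); r <- fix_rest(); fs <- fix_step(); thr <- fix_thr50()
  sw <- sweep_timing(p, fs$proto, g_max = thr$g_star, tau_syn = thr$tau_syn,
                     times = c(10, 20, 50, 100), rest = r)
  expect_false(any(sw$terminated[sw$time %in% c(10, 20)]))
  expect_true(all(sw$terminated[sw$time %in% c(50, 100)]))
  v <- sw$terminated[sw$applicable]
  expect_true(all(diff(as.integer(v)) >= 0))

  # zero amplitude never terminates
  sw0 <- sweep_timing(p, fs$proto, g_max = 0, tau_syn = thr$tau_syn,
                      times = c(10, 50, 100), rest = r)
  expect_false(any(sw0$terminated[sw0$applicable]))

  # onsets beyond the spontaneous end are not applicable, not errors
  swl <- sweep_timing(p, fs$proto, g_max = thr$g_star, tau_syn = thr$tau_syn,
                      times = c(50, ceiling(thr$control$duration) + 10),
                      rest = r)
  expect_false(swl$applicable[2])
  expect_true(is.na(swl$terminated[2]))
})

test_that("amplitude x tau sweep has an up-set verdict structure", {
  # boundary extraction on a constructed monotone 3x3 table
  d <- expand.grid(g_max = c(1, 2, 3), tau_syn = c(5, 10, 20))
  d$terminated <- with(d, (tau_syn == 5 & g_max >= 3) |
                         (tau_syn == 10 & g_max >= 2) |
                         (tau_syn == 20 & g_max >= 1))
  b <- threshold_boundary(d)
  expect_equal(b$g_min, c(3, 2, 1))

  # model: small grid around the tau-5 threshold at onset 50 ms
  p <- fix_params(); r <- fix_rest(); fs <- fix_step(); thr <- fix_thr50()
  amps <- thr$g_star * c(0, 0.3, 0.8, 1.1, 1.6)
  amps[1] <- 0
  sw <- sweep_amp_tau(p, fs$proto, amp_grid = sort(amps),
                      tau_grid = c(5, 20, 80), onset = 50, rest = r)
  # amplitude-0 row never terminates
  expect_false(any(sw$terminated[sw$g_max == 0]))
  # within each tau, terminating amplitudes form an up-set
  for (ts in unique(sw$tau_syn)) {
    v <- sw$terminated[sw$tau_syn == ts][order(sw$g_max[sw$tau_syn == ts])]
    expect_true(all(diff(as.integer(v)) >= 0))
  }
  # slower tau terminates at amplitudes the fast tau cannot
  b2 <- threshold_boundary(sw)
  expect_true(all(diff(b2$g_min) <= 0))
})

test_that("IPSP feature measurement on a constructed waveform", {
  # linear fall of 10 mV over 5 ms (slope 2 mV/ms), exponential recovery
  t <- seq(0, 300, by = 0.1)
  V <- ifelse(t < 100, -20,
              ifelse(t < 105, -20 - 2 * (t - 100),
                     -30 + 10 * (1 - exp(-(t - 105) / 30))))
  tr <- fake_trace(t, V)
  f <- measure_ipsp_features(tr, onset = 100, window = 100)
  expect_equal(f$ipsp_amplitude, 10, tolerance = 0.01)
  expect_equal(f$min_V, -30, tolerance = 0.01)
  expect_equal(f$max_dVdt, 2, tolerance = 0.01)
  # flat trace has zero amplitude
  flat <- fake_trace(t, rep(-65, length(t)))
  expect_equal(measure_ipsp_features(flat, 100, 50)$ipsp_amplitude, 0)
  expect_warning(measure_ipsp_features(tr, 290, 50), "truncat")
  expect_error(measure_ipsp_features(tr, 400, 10), "outside")
})
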