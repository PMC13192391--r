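p0 <- model_parameters()

test_that("geometry and parameter validation", {
  expect_equal(p0$area, pi * (10e-4)^2, tolerance = 1e-12)
  expect_error(model_parameters(diameter = -1), "diameter")
  expect_error(model_parameters(ca_inf = 3, cao = 2), "ca_inf")
  expect_error(model_parameters(cao = 0), "cao")
  expect_error(update_parameters(p0, gbar_kal = 1), "unknown")
  p2 <- update_parameters(p0, diameter = 20)
  expect_equal(p2$area, pi * (20e-4)^2, tolerance = 1e-12)
})

test_that("VGCC rate functions match their closed forms", {
  # analytic limit of the removable singularity: u/(exp(u/3.8)-1) -> 3.8
  r <- cal_rates(-27.01, p0)
  expect_equal(r$alpha, 0.055 * 3.8, tolerance = 1e-6)
  # exponent vanishes at -63.01 mV
  expect_equal(cal_rates(-63.01, p0)$beta, 0.94, tolerance = 1e-12)
  # direct evaluation at u = -3.8
  expect_equal(cal_rates(-23.21, p0)$alpha,
               0.055 * (-3.8) / (exp(-1) - 1), tolerance = 1e-6)
  # continuity across the singularity
  expect_lt(abs(cal_rates(-27.01 + 1e-7, p0)$alpha -
                  cal_rates(-27.01, p0)$alpha), 1e-6)
  expect_error(cal_rates(NaN, p0), "finite")
  # m_inf monotone increasing on a dense grid
  V <- seq(-100, 40, by = 0.1)
  expect_true(all(diff(cal_rates(V, p0)$m_inf) > 0))
  expect_true(all(cal_rates(V, p0)$tau_m > 0))
})

test_that("GHK flux: sign, Nernst zero, continuity, monotonicity", {
  vn <- nernst_ca(1e-4, 2, 32)
  expect_equal(vn, 1e3 * 8.314 * 305.15 / (2 * 96485) * log(2 / 1e-4),
               tolerance = 1e-12)
  expect_equal(ghk_flux(vn, 1e-4, 2, 32), 0, tolerance = 1e-8)
  # z -> 0 limit: 0.001 * 2F * (cai - cao)
  expect_equal(ghk_flux(0, 1e-4, 2, 32), 1e-3 * 2 * 96485 * (1e-4 - 2),
               tolerance = 1e-9)
  expect_lt(abs(ghk_flux(1e-9, 1e-4, 2, 32) - ghk_flux(0, 1e-4, 2, 32)), 1e-6)
  expect_error(ghk_flux(0, 1e-4, -2, 32), "cao")
  # monotone increasing in V (rectifying flux), so |flux| -- the inward
  # drive -- decreases toward the unique zero at the Nernst potential,
  # cross-checked against a dense brute-force scan
  V <- seq(-100, 50, by = 0.01)
  g <- ghk_flux(V, 1e-4, 2, 32)
  expect_true(all(diff(g) > 0))
  expect_true(all(g < 0))  # Nernst ~ +130 mV is outside the scan range
  expect_true(all(diff(abs(g)) < 0))
  V2 <- seq(100, 160, by = 0.001)
  g2 <- ghk_flux(V2, 1e-4, 2, 32)
  zero_brute <- V2[which.min(abs(g2))]
  expect_lt(abs(zero_brute - vn), 0.001)
})

test_that("Ca2+-dependent inactivation h and SK gate", {
  expect_equal(h_cal(0, p0), 1)
  expect_equal(h_cal(p0$ki, p0), 0.5)
  expect_equal(h_cal(3 * p0$ki, p0), 0.25)
  expect_error(h_cal(-1e-5, p0), "cai")
  ca <- seq(0, 1, by = 1e-3)
  expect_true(all(diff(h_cal(ca, p0)) < 0))

  expect_equal(kca_gate(p0$cac, p0)$m_inf, 0.5)
  expect_equal(kca_gate(3 * p0$cac, p0)$m_inf, 0.9)
  # decided defaults: beta 0.03/ms, q10 3, 32 C vs 22 C reference
  expect_equal(kca_gate(p0$cac, p0)$tau_m, 1 / (0.03 * 2) / 3,
               tolerance = 1e-12)
  expect_true(all(diff(kca_gate(ca, p0)$m_inf) > 0))
  expect_true(all(kca_gate(ca, p0)$m_inf < 1))
  expect_error(kca_gate(-1, p0), "cai")
})

test_that("membrane currents follow the printed forms and sum exactly", {
  s <- model_state(V = p0$E_pas, m_cal = 0, m_kca = 0, cai = p0$ca_inf)
  cur <- membrane_currents(s, p0)
  expect_equal(unlist(cur), c(I_pas = 0, I_VGCC = 0, I_KCa = 0, I_GABA = 0,
                              I_inj = 0, I_sum = 0))
  # zero driving force at the GABA reversal
  s2 <- model_state(V = p0$E_GABA, m_cal = 0.1, m_kca = 0.1, cai = 1e-3,
                    g_syn = 0.01)
  expect_equal(membrane_currents(s2, p0)$I_GABA, 0)
  # direct SK evaluation: m^3 = 0.125
  p3 <- update_parameters(p0, gbar_kca = 1e-4, E_K = -90)
  s3 <- model_state(V = -10, m_cal = 0, m_kca = 0.5, cai = p0$ca_inf)
  expect_equal(membrane_currents(s3, p3)$I_KCa, 1e-4 * 0.125 * 80,
               tolerance = 1e-12)
  # identity to machine precision over many random states (vectorised)
  set.seed(11)
  n <- 1e6
  sr <- list(V = runif(n, -100, 40), m_cal = runif(n), m_kca = runif(n),
             cai = runif(n, 0, 0.5), g_syn = runif(n, 0, 0.05))
  cr <- membrane_currents(sr, p0, I_inj = runif(n, -0.01, 0.01))
  expect_identical(cr$I_sum,
                   cr$I_pas + cr$I_VGCC + cr$I_KCa + cr$I_GABA - cr$I_inj)
})

test_that("state derivatives vanish at steady state and follow first-order gates", {
  # gates at target, cai balancing drive and removal, V at a current zero
  r <- initialize_rest(p0)
  d <- derivatives(r, p0)
  expect_lt(max(abs(unlist(d))), 1e-9)
  # m_cal at m_inf has zero gate derivative
  s <- model_state(V = -30, m_cal = cal_rates(-30, p0)$m_inf, m_kca = 0.2,
                   cai = 0.01)
  expect_equal(derivatives(s, p0)$dm_cal, 0, tolerance = 1e-15)
  # without VGCC flux only removal acts on cai
  pz <- update_parameters(p0, gbar_cal = 0)
  s4 <- model_state(V = -65, m_cal = 0, m_kca = 0, cai = 2 * pz$ca_inf)
  expect_equal(derivatives(s4, pz)$dcai, -pz$ca_inf / pz$tau_r,
               tolerance = 1e-15)
  # the Ca2+ drive clamp floors influx at outward VGCC current
  pc <- update_parameters(p0, ca_drive_clamp = FALSE)
  s5 <- model_state(V = 150, m_cal = 1, m_kca = 0, cai = 0.5)
  expect_gt(membrane_currents(s5, p0)$I_VGCC, 0)   # outward at +150 mV
  expect_lt(derivatives(s5, pc)$dcai, derivatives(s5, p0)$dcai)
})
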