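#!/usr/bin/env Rscript
# IPSG amplitude x decay-tau parameter plane.
#
# The plateau is challenged at 50 ms with IPSGs spanning a log amplitude
# grid crossed with decay time constants of 5-80 ms. Slower IPSGs
# terminate at smaller amplitudes: the termination boundary amplitude is
# non-increasing in tau.

library(plateaukit)
dir.create("results", showWarnings = FALSE)

p <- model_parameters()
rest <- initialize_rest(p)
fs <- find_plateau_step(p, rest = rest)
thr <- find_termination_threshold(p, fs$proto, ipsg_onset = 50, rest = rest)

amps <- thr$g_star * 2^seq(-3.5, 1.5, by = 0.5)
taus <- c(5, 10, 20, 40, 80)
sw <- sweep_amp_tau(p, fs$proto, amp_grid = amps, tau_grid = taus,
                    onset = 50, rest = rest)
write_sweep_csv(sw, "results/amp_tau_sweep.csv")

b <- threshold_boundary(sw)
write_sweep_csv(b, "results/amp_tau_boundary.csv")
cat("termination boundary (minimal terminating amplitude, uS):\n")
print(b)
stopifnot(all(diff(b$g_min) <= 0))
cat("boundary is non-increasing in tau: slower IPSGs are more effective\n")
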