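#!/usr/bin/env Rscript
# Early resistance: IPSG timing sweep at 1x, 2x and 4x the just-threshold
# amplitude.
#
# The IPSG amplitude is fixed at the value that just terminates the plateau
# at 50 ms, then delivered every 5 ms from 10 to 100 ms after plateau
# onset. Plateaus resist inhibition early and become increasingly
# susceptible; larger amplitudes terminate earlier.

library(plateaukit)
dir.create("results", showWarnings = FALSE)

p <- model_parameters()
rest <- initialize_rest(p)
fs <- find_plateau_step(p, rest = rest)
thr <- find_termination_threshold(p, fs$proto, ipsg_onset = 50, rest = rest)

times <- seq(10, 100, by = 5)
sweeps <- lapply(c(1, 2, 4), function(mult) {
  sw <- sweep_timing(p, fs$proto, g_max = mult * thr$g_star,
                     tau_syn = thr$tau_syn, times = times, rest = rest)
  sw$amp_mult <- mult
  sw
})
all <- do.call(rbind, sweeps)
write_sweep_csv(all, "results/timing_sweep.csv")

firsts <- vapply(sweeps, function(sw)
  suppressWarnings(min(sw$time[sw$terminated %in% TRUE])), 0)
write_summary_json(list(
  g_star_uS = thr$g_star,
  earliest_termination_ms = as.list(setNames(firsts, c("x1", "x2", "x4")))
), "results/timing_sweep.json")
cat(sprintf("earliest terminating onset: 1x %g ms, 2x %g ms, 4x %g ms\n",
            firsts[1], firsts[2], firsts[3]))
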