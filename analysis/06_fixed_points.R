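#!/usr/bin/env Rscript
# Steady-state I = 0 branches and I-V trajectories.
#
# Solving the membrane equation for I = 0 with gates at steady state and
# cai frozen at each instant reveals two branches inside the plateau
# voltage range: a stable branch that V tracks (the plateau is a
# near-stable point) and a repelling branch -- the termination threshold --
# that drifts toward depolarized values as Ca2+ accumulates, explaining
# the early resistance to inhibition. Around the threshold, just-
# subthreshold IPSP trajectories cross the I = 0 line and reverse;
# just-suprathreshold ones do not come back.

library(plateaukit)
dir.create("results", showWarnings = FALSE)

p <- model_parameters()
rest <- initialize_rest(p)
fs <- find_plateau_step(p, rest = rest)
m <- fs$metrics; off <- m$onset

br <- track_branches(fs$trace, p, stride = 2,
                     window = c(off + 5, off + m$duration))
write_sweep_csv(br, "results/fixed_point_branches.csv")

inpl <- br[br$in_plateau_range, ]
cat(sprintf("branches in plateau range: %d\n",
            length(unique(inpl$branch))))
thr_br <- inpl[inpl$stability == "repelling", ]
cat(sprintf("threshold branch drifts %.1f -> %.1f mV over the plateau\n",
            thr_br$V[1], thr_br$V[nrow(thr_br)]))

thr <- find_termination_threshold(p, fs$proto, ipsg_onset = 50, rest = rest)
win <- c(off + 50, off + 80)
sub <- iv_trajectory(thr$sub_trace, win)
supra <- iv_trajectory(thr$supra_trace, win)
write_sweep_csv(sub$path, "results/iv_path_subthreshold.csv")
write_sweep_csv(supra$path, "results/iv_path_suprathreshold.csv")
cat(sprintf("subthreshold path crosses I=0 and reverses: %s\n", sub$crossed))
cat(sprintf("suprathreshold path final V: %.1f mV (no return)\n",
            supra$path$V[nrow(supra$path)]))
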