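#!/usr/bin/env Rscript
# Simulate a synthetic cohort at the online-experiment scale, with
# realistic contamination: wrong-digit reports, rare timeouts, and three
# planted chance-level participants who should fall to the accuracy
# filter downstream.
#
# Finds: 30 participants x 466 trials; star-choice rate near 50% overall
# (the cycle is symmetric) but strongly modulated within cycles.

suppressPackageStartupMessages(library(acvsadapt))
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(n_participants = 30, tau = 0.1, delta = 1.2,
                         beta = 0.15, n_practice = 2, n_main = 4,
                         n_chance_participants = 3, seed = 20260921)
st <- simulate_study(cfg)
print(st)
cat(sprintf("overall star-choice rate: %.3f\n",
            mean(st$trials$choice == "star")))

write_trials_csv(st$trials, "results/sim_trials.csv")
write.csv(st$truth$cohort, "results/sim_truth_cohort.csv", row.names = FALSE)
jsonlite::write_json(st$truth$group, "results/sim_truth_group.json",
                     auto_unbox = TRUE, digits = NA)
cat("wrote results/sim_trials.csv (+ ground-truth manifest)\n")
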