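#!/usr/bin/env Rscript
# Apply the exclusion filters to the simulated cohort.
#
# Finds: the three planted chance-level participants are exactly the
# ones whose blocks fail the 75% accuracy criterion; trial-level filters
# then remove the wrong-digit reports (~2.5%) and timeouts (~0.1%).

suppressPackageStartupMessages(library(acvsadapt))

trials <- read_trials_csv("results/sim_trials.csv")
main <- trials[trials$block_type == "main", ]

blk <- exclude_low_accuracy_blocks(main)
rep_blk <- attr(blk, "exclusion_report")
cat(sprintf("block filter: %d blocks (%.1f%% of trials) removed; participants excluded: %s\n",
            rep_blk$blocks_removed, 100 * rep_blk$fraction_removed,
            paste(rep_blk$participants_excluded, collapse = ", ")))

out <- exclude_invalid_trials(blk)
rep_tr <- attr(out, "exclusion_report")
cat(sprintf("trial filter: %d incorrect, %d over 5000 ms (%.2f%% of remaining)\n",
            rep_tr$incorrect_removed, rep_tr$slow_removed,
            100 * rep_tr$fraction_removed))

write_trials_csv(out, "results/sim_trials_clean.csv")
jsonlite::write_json(list(blocks = rep_blk, trials = rep_tr),
                     "results/exclusion_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("kept %d of %d main-block trials\n", nrow(out), nrow(main)))
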