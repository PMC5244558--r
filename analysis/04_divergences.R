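#!/usr/bin/env Rscript

# Per-worm and per-strain divergence statistics under the fitted state
# model: within- vs between-strain occurrence divergences with the
# rank-sum/FDR separation test, and each strain's occurrence and
# transition divergence from the wild-type reference.

suppressPackageStartupMessages(library(wormstates))

seed <- 26093
collection <- read_dataset("results/screen_preprocessed.csv")
model <- read_state_model("results/state_model.json")

binned <- bin_collection(collection, model)

dd <- intra_inter_divergence(binned$occurrence, binned$strains, seed = seed)
utils::write.table(
  dd[, c("worm", "strain", "delta_intra", "delta_inter")],
  "results/worm_divergences.tsv", sep = "\t", row.names = FALSE,
  quote = FALSE)
sep <- strain_separation_test(dd)
utils::write.table(sep$table, "results/strain_separation.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

aggregates <- strain_aggregates(binned)
records <- divergence_from_reference(aggregates, "N2")
utils::write.table(records[, c("strain", "delta_r", "delta_T")],
                   "results/reference_divergences.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

message(sprintf("%d/%d strains show coherent within-strain state usage (q < 0.05)",
                sep$n_significant, nrow(sep$table)))
message(sprintf("reference divergences: delta_r in [%.4f, %.4f], delta_T in [%.4f, %.4f]",
                min(records$delta_r), max(records$delta_r),
                min(records$delta_T), max(records$delta_T)))
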