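#!/usr/bin/env Rscript

# Screen for strains whose transition patterns are atypical given their
# postures: regress transition divergence on occurrence divergence across
# strains, standardize the residuals, and flag strains above the trend at
# q < 0.05. For the top strain, rank the per-state occurrence fold changes
# and reconstruct the over/under-represented postures as midline angles.

suppressPackageStartupMessages(library(wormstates))

seed <- 26093
collection <- read_dataset("results/screen_preprocessed.csv")
model <- read_state_model("results/state_model.json")
basis <- local({
  b <- jsonlite::fromJSON("results/data/screen/basis.json")
  structure(list(n_angles = b$n_angles, dims = b$dims,
                 matrix = matrix(b$matrix, b$n_angles, b$dims, byrow = TRUE)),
            class = "eigenworm_basis")
})

binned <- bin_collection(collection, model)
scr <- reference_screen(binned, "N2")
print(scr$regression)

utils::write.table(scr$records[, c("strain", "delta_r", "delta_T", "z", "q")],
                   "results/atypicality.tsv", sep = "\t", row.names = FALSE,
                   quote = FALSE)
flagged <- scr$records$strain[scr$records$atypical]
message("flagged as atypical: ",
        if (length(flagged)) paste(flagged, collapse = ", ") else "none")

top <- scr$records$strain[1]
aggregates <- scr$aggregates
fc <- state_fold_change(aggregates[[top]]$r, aggregates$N2$r,
                        top_n = min(5L, model$K %/% 2),
                        mean_frames = binned$mean_frames)
utils::write.table(cbind(strain = top, fc$table),
                   "results/fold_changes.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
angles <- t(vapply(c(fc$over, fc$under), function(k) {
  reconstruct_posture(model$means[k, ], basis)
}, numeric(basis$n_angles)))
utils::write.table(
  data.frame(state = c(fc$over, fc$under),
             direction = rep(c("over", "under"),
                             times = c(length(fc$over), length(fc$under))),
             angles),
  "results/reconstructed_postures.csv", sep = ",", row.names = FALSE,
  quote = FALSE)
message(sprintf("top strain %s: over-represented states %s, under-represented %s",
                top, paste(fc$over, collapse = " "),
                paste(fc$under, collapse = " ")))
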