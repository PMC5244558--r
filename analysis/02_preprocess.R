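#!/usr/bin/env Rscript

# Quality control, gap interpolation and downsampling for both panels.
# Worms outside the 890-910 s recording window or missing more than 40%
# of frames are dropped, then strains with fewer than five surviving
# individuals; remaining gaps are filled by linear interpolation and
# everything is brought to 5 frames per second.

suppressPackageStartupMessages(library(wormstates))

for (panel in c("screen", "dissect")) {
  collection <- read_dataset(file.path("results/data", panel, "dataset.csv"))
  pp <- preprocess(collection)
  write_exclusion_report(pp$exclusions,
                         sprintf("results/%s_exclusions.tsv", panel))
  write_dataset(pp$collection, sprintf("results/%s_preprocessed.csv", panel))
  message(sprintf("%s panel: kept %d of %d worms (%d excluded)",
                  panel, length(pp$collection$series),
                  length(collection$series), nrow(pp$exclusions)))
}
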