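#!/usr/bin/env Rscript

# Can inactivity removal plus uniform acceleration of the wild type
# explain an atypical strain? On the dissection panel, fit the state
# model and the occurrence-vs-transition trend, find the flagged strain,
# then fit the (alpha, beta) transformation whose pooled speed
# distribution best matches it, rebuild the divergences against the
# transformed (artificial) reference, and standardize them against the
# previously fitted trend (Z_a). A small |Z_a| means the strain's
# atypical transitions are explained by those two factors alone.

suppressPackageStartupMessages(library(wormstates))

seed <- 26093
collection <- read_dataset("results/dissect_preprocessed.csv")

points <- sample_frames(collection, fraction = 0.01, seed = seed,
                        k_init = 30)
model <- fit_fab_gmm(points, eps = 0.01, k_init = 30, seed = seed)
binned <- bin_collection(collection, model)
scr <- reference_screen(binned, "N2")
print(scr$regression)
flagged <- scr$records$strain[scr$records$atypical]
message("flagged as atypical: ",
        if (length(flagged)) paste(flagged, collapse = ", ") else "none")
if (!length(flagged)) quit(save = "no")

wildtype <- subset_strains(collection, "N2")$series
rows <- lapply(flagged, function(strain) {
  target <- subset_strains(collection, strain)$series
  ap <- fit_artificial_params(wildtype, target)
  res <- evaluate_reproduction(ap$series, target, model, scr$regression)
  data.frame(strain = strain, alpha = ap$alpha, beta = ap$beta, D = ap$D,
             delta_r_a = res$delta_r_a, delta_T_a = res$delta_T_a,
             z_a = res$z_a,
             original_z = scr$records$z[scr$records$strain == strain])
})
tab <- do.call(rbind, rows)
utils::write.table(tab, "results/factor_dissection.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
print(tab, digits = 3)
message(sprintf("Z_a vs original z: %s",
                paste(sprintf("%s %.2f -> %.2f", tab$strain,
                              tab$original_z, tab$z_a), collapse = "; ")))
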