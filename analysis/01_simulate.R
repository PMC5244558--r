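#!/usr/bin/env Rscript

# Build the two synthetic study collections.
#
# Screen panel (20 strains): wild-type reference, clones, mutants with
# shifted state usage (reweight) and mutants with rewired transition
# structure at matched usage (retransition) -- the material for the
# atypical-transition screen.
#
# Dissection panel (10 strains): wild-type reference plus a fast,
# never-resting mutant (and on-trend fillers), the material for asking
# whether inactivity removal plus acceleration explains an atypical
# strain.

suppressPackageStartupMessages(library(wormstates))

seed <- 26093

reweights <- function(strengths) {
  lapply(strengths, function(s)
    list(kind = "reweight", pi_stat = exp(s * c(1, 0.5, 0, -0.5, -1, 0))))
}

screen_pert <- c(list(N2 = NULL),
                 reweights(seq(0.2, 1.4, length.out = 5)),
                 list(R1 = list(kind = "retransition"),
                      R2 = list(kind = "retransition"),
                      R3 = list(kind = "retransition")),
                 replicate(11, NULL, simplify = FALSE))
names(screen_pert)[2:6] <- paste0("RW", 1:5)
names(screen_pert)[10:20] <- paste0("W", 1:11)

screen_cfg <- synthetic_config(n_strains = 20, seed = seed)
screen <- simulate_strains(screen_cfg, screen_pert)
write_collection(screen, "results/data/screen")

dissect_pert <- c(list(N2 = NULL,
                       MUT = list(kind = c("no_rest", "accelerate"),
                                  gamma = 2)),
                  reweights(seq(0.2, 1.2, length.out = 4)),
                  replicate(4, NULL, simplify = FALSE))
names(dissect_pert)[3:6] <- paste0("RW", 1:4)
names(dissect_pert)[7:10] <- paste0("W", 1:4)

dissect_cfg <- synthetic_config(n_strains = 10, seed = seed + 1)
dissect <- simulate_strains(dissect_cfg, dissect_pert)
write_collection(dissect, "results/data/dissect")

message(sprintf("screen panel: %d worms in %d strains; dissection panel: %d worms in %d strains",
                length(screen$series), screen_cfg$n_strains,
                length(dissect$series), dissect_cfg$n_strains))
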