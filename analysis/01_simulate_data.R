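#!/usr/bin/env Rscript

# Stage 1: generate every synthetic input the downstream analyses read.
# All generators are seeded, so rerunning this script reproduces the same
# files bit for bit. Outputs land under results/data/.

suppressPackageStartupMessages(library(phagechar))

seed <- 20260919L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## killing curves: phage-free control plus an eight-step MOI ladder,
## read every 30 min for 6.5 h, 5% multiplicative noise
params <- infection_params(noise_sd = 0.05, seed = seed)
mois <- 10^seq(-7, 0)
times <- seq(0, 390, by = 30)
curves <- simulate_growth_curves(params, mois = mois, times = times)
long <- do.call(rbind, c(
  list(data.frame(time_min = times, condition = "control", replicate = 1L,
                  value = curves$control_od)),
  lapply(names(curves$moi_curves), function(m)
    data.frame(time_min = times, condition = m, replicate = 1L,
               value = curves$moi_curves[[m]]))))
write.table(long, file.path(out, "killing_curves.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

## one-step growth: latent 20 min, burst 60, two bursts, 5-min sampling
os <- simulate_one_step(infection_params(latent_min = 20, burst = 60,
                                         noise_sd = 0.05, seed = seed + 1),
                        times = seq(0, 70, by = 5), n0 = 1e4)
write.table(data.frame(time_min = os$times, condition = "onestep",
                       replicate = 1L, value = os$titer),
            file.path(out, "one_step.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

## adsorption: exponential decay of free phage at 2e8 cells/mL
ads <- simulate_adsorption(p0 = 1e6, k = 3e-10, cells = 2e8,
                           times = c(0, 1, 2, 3, 4, 5, 10, 15),
                           noise_sd = 0.02, seed = seed + 2)
write.table(data.frame(time_min = ads$times, condition = "adsorption",
                       replicate = 1L, value = ads$titer),
            file.path(out, "adsorption.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

## PRF genome set: 20 genomes with a shared TAC locus (5% divergence),
## three motif-scrambled and two -1-stop negatives, 1165 nt terminal
## repeats, mixed strands
neg <- rep("none", 20)
neg[c(4, 11, 17)] <- "scramble_motif"
neg[c(7, 19)] <- "plant_minus1_stop"
gp <- make_prf_genomes(20, negatives = neg, divergence = 0.05,
                       dtr_len = 1165, seed = seed + 3,
                       strand = rep(c("+", "-"), 10))
write_genbank(gp$genomes, file.path(out, "prf_genomes.gbk"))
write.table(data.frame(genome_id = gp$truth$genome_id, orf_id = "tac_orf"),
            file.path(out, "prf_locus_map.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(gp$truth, file.path(out, "prf_truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

## defense-system table: 120 strains, 20 systems, three truly enriched
tab <- make_defense_table(120, 20, prevalence = 0.3,
                          enriched = c(sys03 = 8, sys11 = 6, sys18 = 10),
                          group_frac = 0.35, seed = seed + 4,
                          group_labels = c("O11", "non-O11"))
df <- cbind(data.frame(strain_id = tab$strain_ids, group = tab$group),
            as.data.frame(tab$matrix + 0L))
write.table(df, file.path(out, "defense_systems.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("synthetic inputs written to", out, "\n")
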