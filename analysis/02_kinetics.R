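#!/usr/bin/env Rscript

# Stage 2: phenotype quantification from the assay time series — local
# virulence and the integrated virulence index (both for the synthetic
# killing curves and for the published Adele ladder), one-step growth,
# adsorption kinetics, biofilm inhibition and stability log-reductions.

suppressPackageStartupMessages(library(phagechar))

dat <- "results/data"
out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## virulence from the synthetic killing curves
curves <- curves_from_table(read_assay_table(file.path(dat, "killing_curves.tsv")))
mois <- sort(as.numeric(names(curves$moi_curves)))
ladder <- do.call(rbind, lapply(mois, function(m) {
  lv <- local_virulence(curves, m)
  data.frame(moi = lv$moi, v = lv$v)
}))
vi_sim <- virulence_index(ladder)
write.table(ladder, file.path(out, "local_virulence.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("synthetic curves: window end %d min, virulence index %.3f\n",
            curves$window_end, vi_sim))

## the published Adele ladder integrates to the printed index
vi_ref <- virulence_index(adele_local_virulence())
cat(sprintf("published Adele ladder: virulence index %.3f (printed: 0.535)\n",
            vi_ref))

## one-step growth
os_tab <- read_assay_table(file.path(dat, "one_step.tsv"))
os <- titer_series(os_tab$time_min, os_tab$value, n0 = 1e4)
r <- one_step(os)
cat(sprintf("one-step: latent %g min, rise %g min, burst size %.1f\n",
            r$latent_min, r$rise_min, r$burst_size))

## adsorption
ad_tab <- read_assay_table(file.path(dat, "adsorption.tsv"))
ad <- adsorption(titer_series(ad_tab$time_min, ad_tab$value),
                 cell_density = 2e8)
cat(sprintf("adsorption: %.1f%% adsorbed at 5 min, %.1f%% at 15 min, k = %.2e mL/cell/min\n",
            ad$percent_adsorbed[ad$times == 5],
            ad$percent_adsorbed[ad$times == 15], ad$rate_constant))

## biofilm inhibition across an MOI gradient (crystal-violet OD means)
biofilm <- data.frame(
  moi = c(0.1, 1, 10, 100),
  inhibition = c(
    biofilm_inhibition(c(1.02, 0.98, 1.00), c(0.78, 0.75, 0.75)),
    biofilm_inhibition(c(1.02, 0.98, 1.00), c(0.60, 0.57, 0.63)),
    biofilm_inhibition(c(1.02, 0.98, 1.00), c(0.40, 0.37, 0.37)),
    biofilm_inhibition(c(1.02, 0.98, 1.00), c(0.19, 0.17, 0.18))))
write.table(biofilm, file.path(out, "biofilm_inhibition.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("biofilm inhibition rises from %.0f%% (MOI 0.1) to %.0f%% (MOI 100)\n",
            biofilm$inhibition[1], biofilm$inhibition[4]))

## thermal stability as log10 reductions from a 7.0e8 PFU/mL stock
stab <- data.frame(temperature_c = c(30, 40, 50, 60, 70),
                   titer = c(6.8e8, 6.5e8, 5.1e8, 7.0e6, 0))
red <- lapply(stab$titer, function(x) log_reduction(7.0e8, x, lod = 100))
stab$log10_reduction <- vapply(red, `[[`, numeric(1), "value")
stab$censored <- vapply(red, `[[`, logical(1), "censored")
write.table(stab, file.path(out, "thermal_stability.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("thermal: %.1f log10 drop at 60 C; >= %.1f log10 (censored) at 70 C\n",
            stab$log10_reduction[4], stab$log10_reduction[5]))

write.table(data.frame(quantity = c("virulence_index_synthetic",
                                    "virulence_index_published",
                                    "latent_min", "burst_size",
                                    "adsorbed_5min_pct", "rate_constant"),
                       value = c(vi_sim, vi_ref, r$latent_min,
                                 r$burst_size,
                                 ad$percent_adsorbed[ad$times == 5],
                                 ad$rate_constant)),
            file.path(out, "kinetics_summary.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
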