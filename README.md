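# phagechar

Phenotypic and genomic characterization of lytic bacteriophages, for
phage biologists quantifying candidate therapeutic phages: killing-curve
virulence, one-step growth, adsorption, biofilm and stability estimators;
a scanner for −1 programmed ribosomal frameshift (PRF) signals at tail
assembly chaperone (TAC) loci; whole-genome statistics (GC content,
direct-terminal-repeat borders, ORF extraction); and a defense-system
enrichment screen. Seeded synthetic-data generators provide ground truth
for every stage, so the complete analysis runs offline.

## The quantities at the core

**Virulence.** At one multiplicity of infection (MOI), local virulence
compares areas under OD curves up to the control's stationary onset *T*:

    v = 1 − A_phage / A_control,   A = ∫₀ᵀ OD(t) dt   (trapezoid rule)

The virulence index integrates v over log₁₀(MOI) and normalizes by the
maximal area, giving a number in [0, 1].

**One-step growth.** Latent period = last pre-rise sampling time (titer ≤
1.5 × baseline); plateau = first post-rise run of points within a 10%
tolerance band; burst size = plateau titer × volume ÷ phage input at t₀.

**Adsorption.** Percent adsorbed = 100 (1 − P/P₀); the rate constant k
(mL cell⁻¹ min⁻¹) is the origin-constrained slope of −ln(P/P₀) vs N·t.

**−1 PRF scan.** A TAC locus passes when the slippery motif (GTTTTT) sits
in the final 60 nt of the ORF and a −1 frameshift applied right after the
motif extends translation ≥ 200 nt past the frame-0 stop with no premature
−1-frame stop. Unique alleles across a genome set are deduplicated,
aligned (deterministic center-star over Needleman–Wunsch) and summarized
by invariant-site fraction and minimum pairwise identity.

**Enrichment.** Per defense system, a two-sided Fisher exact test (point
probability method, built from the hypergeometric distribution) on the 2×2
group × presence table, with Benjamini–Hochberg correction across the
screen at α = 0.05.

## Worked example

```r
library(phagechar)

# published local-virulence ladder of phage Adele (MOI 1e-7 .. 1)
virulence_index(adele_local_virulence())
#> [1] 0.5357143

# synthetic one-step growth with known truth: latent 20 min, burst 60
p  <- infection_params(latent_min = 20, burst = 60, noise_sd = 0, seed = 1)
os <- simulate_one_step(p, times = seq(0, 70, 10), n0 = 1e4)
one_step(os)[c("latent_min", "rise_min", "burst_size")]
#> $latent_min
#> [1] 20
#> $rise_min
#> [1] 10
#> $burst_size
#> [1] 60

# PRF survey of 6 synthetic genomes, 2 engineered negatives
neg <- c("none", "none", "scramble_motif", "plant_minus1_stop", "none", "none")
gp  <- make_prf_genomes(6, negatives = neg, seed = 42)
lm  <- setNames(rep("tac_orf", 6), sapply(gp$genomes, `[[`, "id"))
survey_locus(gp$genomes, lm)
#> LocusSurvey: 6 genome(s), 6 unique allele(s), 4/6 pass
```

The virulence index 0.536 says the phage removes ~54% of the attainable
bacterial biomass-time across seven decades of MOI; 4/6 passing genomes
are exactly the four without an engineered defect (missing motif or
planted −1-frame stop).

## The analysis

Numbered drivers under `analysis/` run the full workflow on synthetic
data and write tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R   # seeded inputs (TSV/GenBank)
Rscript analysis/02_kinetics.R        # virulence, one-step, adsorption, biofilm, stability
Rscript analysis/03_prf_scan.R        # genome stats + PRF locus survey
Rscript analysis/04_enrichment.R      # defense-system screen + host range
```

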