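---
title: "Methods: quantifying phage phenotype, frameshift conservation and defense-system enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying phage phenotype, frameshift conservation and defense-system enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagechar)
```

phagechar quantifies the phenotype of a lytic bacteriophage from bench
assay time series and interrogates its genome for a specific translational
recoding signal. This vignette describes the models and procedures, the
parameters that matter, what the synthetic-data generators emulate (and do
not), and the numerical choices made where the methodology was genuinely
open.

## Killing-curve virulence

A dynamic killing assay follows the optical density (OD) of a bacterial
culture exposed to phage across a ladder of multiplicities of infection
(MOI), alongside a phage-free control. Local virulence at one MOI is an
area ratio:

$$ v(\mathrm{MOI}) = 1 - \frac{\int_0^T \mathrm{OD}_{\mathrm{MOI}}(t)\,dt}
                             {\int_0^T \mathrm{OD}_{0}(t)\,dt}, $$

integrated by the trapezoid rule from the first reading to the endpoint
$T$, and clamped below at 0 (a culture that grows *better* with phage
would otherwise produce $v < 0$). The integrated virulence index is the
area under $v$ versus $\log_{10}(\mathrm{MOI})$, normalized by the area of
$v \equiv 1$ over the same range, so it lives in $[0, 1]$: 0 for a phage
with no effect at any MOI, 1 for complete suppression everywhere.

$T$ should be the onset of the stationary phase of the control.
`detect_window_end()` finds it as the first sampling time at which the
forward difference of the control OD falls below 5% of its maximum — a
simple rule that is robust on 30-min sampling grids; it is user-overridable
because stationary-phase onset is the one genuinely subjective choice in
this assay.

Applied to the published eight-step ladder of *Pseudomonas* phage Adele
(`adele_local_virulence()`), the index evaluates to:

```{r}
virulence_index(adele_local_virulence())
```

## One-step growth

A one-step growth experiment tracks plaque-forming units (PFU) after
synchronous low-MOI infection. The estimator works on the raw titer
series:

* **baseline** — titer at the first sampling time;
* **latent period** — the last sampling time with titer at most
  `rise_factor` (default 1.5) times baseline before the first sustained
  rise; the estimate is grid-limited by construction, matching how latent
  periods are reported (e.g. "20 min" on a 5- or 10-min grid);
* **plateau** — seeded by the first pair of consecutive post-rise points
  whose relative difference is within `plateau_tol` (default 10%), then
  extended forward while each next point stays within `plateau_tol` of the
  running plateau mean. The extension is the load-bearing numerical
  choice: with multiplicative noise of the same order as the tolerance, a
  rule that only ever averages the seeding pair estimates the plateau from
  two points and fails its accuracy target in a noticeable fraction of
  runs, whereas anchoring on the running mean averages the whole plateau
  and still terminates at a second burst (whose jump is far outside the
  band);
* **burst size** — plateau titer × culture volume ÷ phage input at $t_0$,
  i.e. infective centers are taken as the phage input, the convention used
  when burst sizes are reported as "plateau over input".

Two-burst curves — a second, slower rise after the first plateau, which
real one-step experiments of this phage family show — are handled
naturally: the plateau band breaks at the second rise, so the burst size
always refers to the first burst.

## Adsorption, biofilm, stability

Free-phage decay is summarized as the unadsorbed fraction $P(t)/P_0$ and
percent adsorbed; with a known cell density $N$ the adsorption rate
constant $k$ (mL cell$^{-1}$ min$^{-1}$) is the least-squares slope
through the origin of $-\ln(P/P_0)$ against $N t$, the exact solution for
first-order adsorption $P(t) = P_0 e^{-kNt}$.

Biofilm inhibition uses the standard crystal-violet reduction,
$100\,(\bar{c} - \bar{p})/\bar{c}$ over well means; negative values
(enhancement) are reported as-is.

Stability assays are summarized as $\log_{10}$ reductions versus a
reference titer. Treated titers below the detection limit are censored:
the value reported is the lower bound $\log_{10}(\mathrm{ref}/\mathrm{LOD})$
with `censored = TRUE`, the quantitative rendering of "complete
inactivation".

## The −1 PRF scanner

Tail assembly chaperones are produced as a short (TAC-N) and a long
(TAC-NC) isoform, the latter via a −1 programmed ribosomal frameshift at a
slippery sequence near the 3′ end of the TAC-N reading frame. The scanner
formalizes the genomic test for this signal:

1. `find_slippery()` reports exact occurrences of the motif (default the
   `GTTTTT` hexamer; the generalized heptamer is deliberately not the
   default because the hexamer is the conserved signal at these loci)
   whose start lies within the final `window_nt` (default 60) of the ORF.
   "Near the 3′ end" is not a quantified notion; 60 nt covers the
   reported sites with margin and is a parameter.
2. `minus1_extension()` models the recoding event: translation proceeds
   through the motif, then resumes one nucleotide back immediately after
   the motif's last base. Alternative slip positions shift the measured
   extension by at most 3 nt, so downstream conclusions (an extension
   threshold of 200 nt) are insensitive to this choice. A −1-frame stop
   strictly before the original stop is a premature stop (the locus fails);
   otherwise the extension is measured in nt from the start of the frame-0
   stop codon to the end of the first −1-frame stop at or beyond it.
   Scanning gives up `scan_limit_nt` (default 3000) past the ORF when no
   annotation bounds the locus.
3. `survey_locus()` runs the test across a genome set, deduplicates the
   locus alleles (case-insensitive exact identity), aligns the unique
   alleles and attaches conservation statistics. A genome "passes" when
   the motif is present, the −1 frame is stop-free, and the extension
   reaches `threshold_nt` (default 200).

Minus-strand loci are reverse-complemented before scanning, and all
results are reported on the coding strand; a locus gives identical results
on either strand (tested property).

## Alignment and conservation

The aligner is intentionally self-contained and deterministic: global
Needleman–Wunsch with a linear gap penalty (defaults match/mismatch/gap =
1/−1/−2) and a fixed traceback preference, and a center-star progressive
multiple alignment (center = sequence maximizing summed pairwise scores,
merged under "once a gap, always a gap"). Linear gaps keep the optimum
exhaustively checkable, which is how the aligner is tested. The trade-off
is explicit: a center-star alignment is not a Muscle-class MSA, so
alignment-dependent statistics (percent invariant sites, minimum pairwise
identity) are comparable across runs of this package but not reproductions
of any external aligner's figures.

Conservation statistics: an invariant column has one unique non-gap
symbol and no gaps; identity between two rows is matches over columns
where at least one row is non-gap (doubly-gapped columns excluded — the
identity denominator had to be pinned down somewhere, and this choice is
stated rather than implied).

## Enrichment screen

Defense-system presence/absence across two strain groups is tested
per-system with a two-sided Fisher exact test built from the
hypergeometric distribution, using the point-probability method (all
same-margin tables with point probability ≤ observed × (1 + 10⁻⁷) — the
tolerance factor guards against floating-point ties, and matches the
common convention of standard implementations; sidedness was an open
choice, and two-sided is the default of those implementations). The
sample (cross-product) odds ratio is attached for ranking only.
Benjamini–Hochberg adjustment is applied across the systems of one screen
(one group comparison); significance is `q < alpha` with `alpha = 0.05`.
Under a null generator (all odds ratios 1) the screen's empirical false
discovery proportion stays at or below `alpha` within Monte-Carlo error —
a tested property, not an assumption.

## Synthetic data: what it emulates, and what it does not

No raw assay data ship with this package; every pipeline stage instead
runs on seeded generators with known ground truth.

* `simulate_growth_curves()` integrates a
  susceptible/infected/resistant/phage compartment model (forward Euler,
  0.5-min step, per-step fluxes capped at the available amount so no
  compartment ever goes negative; infected cells lyse one latent period
  after infection, releasing `burst` phage). Defaults — growth rate
  0.025/min, carrying capacity 1 OD, adsorption constant 3×10⁻¹¹
  mL cell⁻¹ min⁻¹, latent 20 min, burst 60, 5% lognormal reading noise —
  were chosen once to reproduce the qualitative phenomenology of dynamic
  killing assays on this phage–host pair: a sigmoidal control,
  near-complete suppression at high MOI, graded intermediate behavior,
  low-MOI curves near the control. They are a phenomenological stand-in,
  not a fit: the model has no spatial structure, no evolved resistance,
  and its OD proxy counts infected cells at full weight, so passing
  recovery tests demonstrates correctness of the estimators under this
  model, not accuracy on any particular bench dataset.
* `simulate_one_step()` is a piecewise (baseline/rise/plateau, optional
  second burst) titer curve with lognormal noise; recovery tests use
  latent 20 min, burst 60, noise σ = 0.1, single-burst curves sampled
  every 5 min to 70 min — on a 10-min bench grid the first plateau holds
  too few points for *any* tolerance rule at this noise level, so the
  denser grid is the package's stated study condition for the recovery
  experiment.
* `simulate_adsorption()` is exact exponential decay plus noise — it
  cannot emulate the late flattening real adsorption curves show, which
  is why rate constants from real data should be fit on the early points.
* `make_prf_genomes()` plants a TAC-like locus with the motif, a stop-free
  −1 extension of at least the requested length (realized as the smallest
  frame-compatible length, reported in the truth table), divergence
  applied only where it preserves the motif/frame structure, negatives by
  motif scrambling or −1-stop planting, and optional terminal repeats.
  Divergence beyond ~0.75 per site cannot preserve the constraints and is
  rejected.
* `make_defense_table()` draws group labels and per-system presence with
  log-odds shifted by the configured odds ratio in the focal group.

Every generator is a pure function of its `seed` argument; reruns are
bit-identical.

## Degenerate inputs and tie-breaks

* GC content excludes `N`/ambiguity codes from numerator and denominator;
  an all-ambiguous sequence is an error, not 0%.
* The terminal-repeat border is the longest string border no longer than
  half the genome, found via the KMP failure chain (a plain cap would be
  wrong: a string like `ABABA` has borders 3 and 1 but none of length 2);
  a homopolymer reports exactly half its length.
* ORF extraction reports the leftmost (longest) start per stop-anchored
  frame, making output deterministic.
* Alignment traceback prefers diagonal, then the gap consuming the first
  sequence, then the second; star-MSA center ties resolve to the first
  input.
* `one_step` errors distinctly on flat series ("no burst") and on series
  that rise without settling ("unterminated rise").
* Allele deduplication sorts by descending count, then lexicographically.

## Problem sizes

The shipped analyses and tests run at deliberately modest sizes: 20-genome
locus surveys (≈600 nt loci), 200 single-genome scanner classifications,
100-replicate recovery studies, 1000-replicate null screens on 100 × 20
tables, and exhaustive oracle sweeps over all 2×2 tables with total ≤ 40
and all {A,C} sequence pairs up to length 4. These sizes give the
properties room to fail while keeping a full run in the order of a minute.

## Known limitations

* The DTR detector finds exact prefix/suffix borders on an assembled
  sequence; it does not perform read-based terminus typing, and an
  assembly that includes the repeat only once will correctly report no
  border.
* The scanner is annotation-driven: it tests the locus you point it at
  and does not discover TAC genes de novo (synteny-based recognition is
  out of scope).
* Center-star alignment quality degrades for deeply diverged allele sets;
  conservation numbers are tied to this aligner by design.
* The virulence index depends on the integration endpoint; two indices
  are comparable only when computed over the same MOI range and window
  rule.
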