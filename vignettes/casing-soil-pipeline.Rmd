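---
title: "Methods: casing-soil 16S community analysis with negative-control decontamination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: casing-soil 16S community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casecomm)
```

## The problem

Casing soil — the soil layer spread over colonized substrate to trigger
mushroom fruiting — hosts a bacterial community that changes with the
cultivation stage and is believed to matter for primordium formation. 16S
amplicon surveys of such systems face a specific obstacle: sterilized
substrate and other low-biomass samples still amplify, because bacterial
DNA is present in reagents and the laboratory environment. Left in place,
these contaminant genotypes distort every downstream community statistic.
`casecomm` packages an analysis built around that obstacle: sequencing
libraries from sterilized stage-II substrate are treated as negative
controls, and the contaminants they define are removed from all libraries
by an iterative rule-based filter before any ecology is computed.

## The decontamination model and its assumptions

The filter works on a dereplicated unique-sequence × sample count table and
applies three rules per pass, repeating passes until a fixed point:

1. *Control ratio.* Keep sequence $u$ iff some experimental library $s$
   has $\mathrm{rel}(u,s) \ge r \cdot \max_c \mathrm{rel}(u,c)$ over
   controls $c$, with $r = 10$. Sequences absent from every control are
   kept iff present anywhere experimental.
2. *Abundance floor.* Keep $u$ iff $\mathrm{rel}(u,s) \ge$ 0.1% in at
   least one experimental library.
3. *Sample retention.* Discard a sample once filtering has removed more
   than 75% of its starting reads. A sample retaining exactly 25% is kept:
   only strictly "over 75% filtered" counts as too contaminated.

Relative abundances are recomputed from the *current* (post-removal)
library sizes at each pass, while rule 3 always compares against the
*original* starting sizes — this is what makes iteration meaningful and
guarantees monotone shrinkage, hence termination in at most
(#sequences + #samples) passes. Controls never count as experimental
libraries in rules 1–2 but are themselves subject to rule 3; once a control
is discarded it stops contributing control maxima, and if every control is
gone, rule 1 degrades to presence filtering (this also makes the procedure
idempotent on its own output, which the test suite asserts). All
thresholds are inclusive ("at least") on the keep side for rules 1–2.

The implicit model is a *shared reagent contamination* model: contaminant
genotypes enter every library from a common source, strongly enriched in
low-biomass controls, at low level elsewhere. The 10× ratio assumes at
least an order-of-magnitude enrichment in controls; genuine sequences
coincidentally present in controls at high relative abundance will be lost
(a known cost of the design), and genuinely rare taxa (< 0.1% everywhere)
are removed regardless of origin — the floor deliberately trades
sensitivity for robustness to noise sequences.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `control_ratio` | 10 | fold-enrichment over controls required to keep a sequence (dimensionless) |
| `min_relabund` | 0.001 | per-library relative-abundance floor (fraction) |
| `max_filtered_fraction` | 0.75 | fraction of starting reads a sample may lose (fraction) |
| `identity` | 0.97 | OTU clustering identity threshold (fraction of alignment columns) |
| `rarefaction_depth` | 7096 | reads per sample after subsampling |
| `n_perm` | 999 | ANOSIM permutations |
| `lda_threshold` | 4.0 | log10 LDA-score cutoff for biomarkers |
| `rho_threshold`, `network_alpha` | 0.75, 0.05 | absolute Spearman rho and p cutoffs for network edges |

The first three are the decontamination constants of the procedure; the
rest are the community-analysis conventions the pipeline standardizes on.
All are exposed through `pipeline_config()` / YAML and on the individual
functions.

## What the synthetic generator emulates — and what it does not

`enumerate_design()` reproduces the 150-sample staged design: six replicate
bottles; normal casing across stages I–VII (90 samples), no-casing (24) and
sterilized-casing (36) treatments at stages V–VI; stage II sterilized
substrate (12 libraries) as negative controls. `make_stage_profiles()`
builds one relative-abundance profile per stage × compartment; casing-soil
profiles anchor a Burkholderia-like dominant taxon at 11.95 / 55.79 /
35.14 / 45.60% across stages I/V/VI/VII and a declining
Thermogemmatispora-like taxon (26.68 → 1.10%), with the remaining mass
spread by a seeded Dirichlet draw (total concentration 200 over the
unanchored taxa — chosen once as a realistic tail: most minor taxa land
around 0.3–2%, a few below the 0.1% floor). `simulate_counts()` draws each
library as a single multinomial mixing (i) the sample's stage profile,
(ii) a contaminant profile shared by *all* samples, scaled per sample by a
lognormal factor (σ = 0.3) to mimic variable contamination load, at an
expected 2% share, and (iii) 40 sample-private noise sequences at a
combined 0.2% share, each far below the 0.1% floor. Negative controls draw
from the contaminant profile only. Depths are uniform on 20,000–40,000
reads — a desk-scale echo of real per-sample ranges. Taxa are independent
random 250-mers, so pairwise identities sit near 25% and 97% clustering
recovers taxa exactly.

Because each library is one multinomial draw of its stage profile, genuine
relative abundances converge to the profile as depth grows (the suite
checks agreement within three standard errors at depth $10^5$), and
within-stage replicate variation is purely sampling noise. Real data differ
in ways the generator deliberately omits: overdispersed replicate-to-replicate
composition, chimeras and PCR bias, sequencing errors correlated along
reads, taxonomically structured sequence similarity, and contaminant
profiles that vary by batch rather than by a single lognormal amplitude.
Passing tests therefore demonstrate that the *procedures* are implemented
correctly and are recoverable under their own stated model — not that the
thresholds are optimal for any particular real dataset.

## Numerical and design choices

- **Read merging** scans all overlaps ≥ 10 bp between the forward mate and
  the reverse complement of the reverse mate, picks the overlap with the
  most matching bases among those with ≥ 90% identity (ties to the longer
  overlap), resolves mismatches by the higher phred score and assigns the
  columnwise maximum quality. The 90% identity floor is a guard against
  spurious merges; the quality rules are the common merger convention.
- **Mean-quality filter** is applied verbatim as an inclusive cutoff (mean
  ≤ 30 fails). This is strict for real MiSeq data; `qual_cutoff` is
  configurable.
- **Barcodes** are matched exactly on the forward (leading) end only,
  which is treated as canonical; no mismatch rescue.
- **Identity** is global Needleman–Wunsch (match +1, mismatch −1, linear
  gap −2) with identity = matching columns / alignment columns after
  trimming terminal-gap columns. Greedy clustering processes sequences in
  decreasing total-abundance order (ties by string), joining the first
  centroid at ≥ 97%; this is deterministic and order-invariant. For speed,
  a candidate below threshold by the upper bound
  matches/(matches+mismatches) — which gaps can only lower — skips the
  exact column count.
- **Rarefaction** is hypergeometric (without replacement), applied *after*
  clustering, since the diversity indices are defined at a common OTU-table
  depth; samples below depth are dropped with a warning.
- **Shannon** uses natural log; **ACE** uses the rare cutoff 10 and falls
  back to observed richness when no taxa are rare and to Chao1 when every
  rare taxon is a singleton (coverage zero).
- **NMDS** minimizes Kruskal stress-1 with primary tie treatment,
  best-of-20 random starts (vegan's monoMDS engine); non-convergence is
  reported, not fatal. `k` must be below the sample count.
- **ANOSIM** p-values are permutation-exact,
  $p = (1 + \#\{R^\ast \ge R\})/(1 + n_\mathrm{perm})$.
- **LEfSe-style scoring** has no subclass stage (the design has none).
  Features are screened by Kruskal–Wallis at α = 0.05 on per-million
  abundances, then scored over 30 bootstraps at 2/3 sampling: per class
  pair, a one-axis discriminant along the class-mean difference under the
  pooled within-class covariance (+1e-6 on the diagonal, unit-normalized);
  a feature's effect averages its absolute projected and raw mean
  differences, and the score is log10 of the bootstrap mean (floored at 1),
  maximized over pairs. Per-million scaling puts 4.0 on the familiar
  scale. Degenerate covariances fall back to the raw difference direction.
- **Network** correlations are computed on relative abundances of the
  rarefied table; the p threshold is applied without multiple-testing
  correction by default (a BH flag exists). Edge thresholds are symmetric:
  rho ≥ 0.75 for positive and rho ≤ −0.75 for negative associations, each
  additionally requiring p < 0.05.
- **Ties and determinism.** Every ranking used for ordering (dereplication
  columns, clustering order, top-k OTUs) breaks ties lexicographically;
  every random operation takes a seed derived from one master seed, so two
  runs with the same configuration produce byte-identical outputs.

## Test problem sizes

The suite validates the full 150-sample design at depths 20,000–40,000 for
the decontamination-recovery property (ten seeds), and smaller
configurations elsewhere: 2,000–3,000-read libraries with 20 taxa for
end-to-end runs, 10 × 10 tables against a straight-line oracle for the
decontamination rules, 10,000-replicate null simulations for the Welch and
Kruskal–Wallis calibrations and 1,000 for ANOSIM (199 permutations each),
and 100 null datasets of 40 samples × 20 OTUs for the network
false-positive rate. These sizes were chosen to make the statistical
assertions sharp at interactive runtimes.

## Known limitations

- The decontamination is rule-based, not model-based: it does not estimate
  contamination probabilities (as frequency/prevalence mixture models do)
  and cannot rescue genuine taxa that happen to dominate controls.
- Greedy centroid clustering is one of several reasonable de novo OTU
  definitions; no equivalence with any specific external tool is claimed.
- The ANOSIM and NMDS wrappers inherit vegan's semantics; with very few
  samples per group the permutation p floor is coarse.
- LDA effect sizes on features with singular within-class covariance rely
  on the regularized or raw-difference fallback; scores for collinear
  feature sets should be read comparatively, not as precise magnitudes.
- Taxonomic assignment is out of scope; biomarker and network nodes are
  OTUs (or any taxon-collapsed table the caller provides).
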