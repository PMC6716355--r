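# casecomm

**Casing-soil 16S community analysis with iterative negative-control
decontamination.**

`casecomm` is an R package for analysing 16S rRNA amplicon surveys of
mushroom casing soil — the soil layer placed over colonized substrate to
induce fruiting — across cultivation stages. It is aimed at microbiome
analysts who need a tested, reproducible version of a pipeline in which the
central and least standard step is a four-step decontamination of
unique-sequence tables against sterilized negative-control libraries, the
situation that arises when sequencing low-biomass or sterilized samples
whose reagent DNA still amplifies.

## The core procedure

After paired reads are merged (minimum 10 bp overlap), quality-filtered
(length ≥ 200 bp, mean phred > 30, no ambiguous bases), demultiplexed by
exact 6-bp barcode + primer match and dereplicated into a unique-sequence ×
sample count table, decontamination iterates three rules to a fixed point:

1. **Control-ratio rule.** A unique sequence *u* is kept iff some
   experimental library *s* satisfies
   rel(u, s) ≥ 10 × max over controls *c* of rel(u, c),
   where rel(·) are relative abundances against *current* library sizes.
2. **Abundance floor.** *u* is kept iff rel(u, s) ≥ 0.1% in at least one
   experimental library.
3. **Sample retention.** A sample is discarded when the filtering has
   removed more than 75% of its *starting* reads (retaining exactly 25% is
   kept).
4. Steps 1–3 are repeated on the reduced table until a full pass removes
   nothing.

Downstream, the retained sequences are clustered into OTUs by
abundance-sorted greedy centroid clustering at 97% global-alignment
identity, rarefied without replacement to a common depth (7,096 reads by
default), and summarized with Shannon and ACE indices,
Hellinger-transformed Bray-Curtis dissimilarities, NMDS + ANOSIM,
Kruskal-Wallis + LDA-effect-size biomarker discovery (log10 score
threshold 4.0), and a signed Spearman co-occurrence network over the top-20
OTUs (|rho| ≥ 0.75, p < 0.05).

A synthetic-data generator reproduces the study design this pipeline was
built around — 150 samples over six stages, three casing treatments, six
replicates, with stage II sterilized-substrate libraries acting as negative
controls — including a shared reagent-style contaminant profile and
sub-0.1% private noise sequences, with per-sequence ground-truth labels so
every stage of the pipeline can be validated end to end.

## Worked example

```r
library(casecomm)
res <- run_pipeline(pipeline_config(master_seed = 1, outdir = "run1"))

res$table
#> uniqueseq_table: 150 samples x 4273 unique sequences (12 controls)
#>   total reads: 4,467,620

res$decontam$report
#> decontam_report: 2 iteration(s); 138 samples retained; 4,014,631 of 4,467,620 reads (89.86%)
#>   iter 1: -10 seqs (step1), -4213 seqs (step2), -12 samples (step3); reads 4,467,620 -> 4,014,631
#>   iter 2: -0 seqs (step1), -0 seqs (step2), -0 samples (step3); reads 4,014,631 -> 4,014,631
```

The 10 shared contaminant sequences fall to the control-ratio rule, 4,213
private noise sequences to the 0.1% floor, and all 12 negative controls —
left with nothing but contaminant reads — are discarded by the sample-
retention rule; a second pass confirms the fixed point. Clustering the
survivors recovers exactly the 50 planted taxa as OTUs:

```r
res$otu
#> otu_tab: 138 samples x 50 OTUs
res$ordination$anosim
#> $R
#> [1] 1
#> $p
#> [1] 0.001
res$network
#>      otu_a    otu_b        rho            p     sign
#> 1 OTU_0001 OTU_0005 -0.8052044 1.153335e-32 negative
#> 2 OTU_0003 OTU_0015  0.8605132 1.152899e-41 positive
#> 3 OTU_0005 OTU_0006 -0.8298928 2.805647e-36 negative
```

ANOSIM R = 1 (p = 0.001) says casing-soil communities are perfectly
rank-separated across stages, as expected under the generator's
stage-specific profiles; the network edges reflect abundance trade-offs
among the dominant planted taxa. Every stage also writes a TSV/JSON
artifact and a `manifest.json` with seeds, parameters and read accounting
into the output directory.

Individual steps are ordinary functions (`run_decontam()`,
`greedy_cluster()`, `rarefy_table()`, `alpha_diversity()`, `bray_curtis()`,
`nmds()`, `anosim_test()`, `run_lefse()`, `build_network()`, ...) and can
be applied to your own dereplicated tables, read in with
`read_seqtab_tsv()` and `read_metadata_tsv()`.

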