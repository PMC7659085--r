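# ohnorhythm

Diurnal rhythm detection in organ RNA-seq time courses and
functional-divergence classification of teleost-genome-duplication (TGD)
gene duplicates.

## The scientific problem

Teleost fish genomes retain a few percent of their genes as duplicate pairs
("ohnologs") from the whole-genome duplication ~375 Mya, while most genes
resolved back to single copies ("singletons", 1:1 with a non-duplicated
outgroup such as spotted gar). One measurable axis along which duplicates
can diverge is the daily expression rhythm: in an organ sampled around the
clock, does one copy cycle and the other not (sub-/neo-functionalization),
do both cycle with different peak times, or do both keep the identical
rhythm? `ohnorhythm` implements the complete analysis chain for this
question:

* **expression** — cpm normalisation (`cpm = counts / library size × 10⁶`),
  replicate averaging, relative expression (each timepoint divided by the
  daily mean), and the expressed-gene filter (cpm > 1 at ≥ 2 of 8
  timepoints);
* **rhythm** — a from-scratch nonparametric umbrella rank test: for every
  hypothesised (peak, trough) timepoint pair on the circular 24 h clock,
  the statistic sums Mann-Whitney U concordance counts over all ordered
  group pairs of the rising arc and of the falling arc
  (Jonckheere–Terpstra construction, ties ½); per-hypothesis permutation
  p-values (exact by enumeration for ≤ 10 observations, seeded Monte-Carlo
  otherwise) are Bonferroni-combined, and a gene is called cyclic at
  p < 0.01. Peak Zt, peak shape (circular hours from peak to minimum) and
  amplitude (max − min relative expression) describe each rhythm;
* **homology** — ohnolog pairs (2:1 to gar) via the five-filter chain
  (duplication-ancestor screen, single shared gar ortholog, gene
  multiplicity, anchored chromosomes, ≥ 5 Mbp tandem separation) and
  singletons (1:1) via the four-exclusion chain, from Biomart-style
  tables; plus the synteny co-linearity score
  `Score = #orthologs / 2n` over ±n-gene windows;
* **divergence** — intra-organ (`ONE_CYCLIC`, `BOTH_CYCLIC_DIFFERENT`,
  `BOTH_CYCLIC_SAME`) and inter-organ (`ONE_CYCLIC_MULTI`,
  `DIFFERENT_BY_ORGAN`, `SYNCHRONIZED_MULTI`) classification of cyclic
  pairs, multi-organ singleton classification, and summary count tables;
* **ncounter** — NanoString nCounter validation-platform normalisation
  (positive-control scaling with 0.3–3 qualification, housekeeping
  geometric-mean normalisation, negative-control background subtraction);
* **synthetic data** — seeded negative-binomial simulators of the full
  design (9 organs × 8 Zt × 2 replicates, planted cosine rhythms) and of
  homology tables with planted pairs, singletons and one decoy class per
  identification rule.

See `vignettes/methods.Rmd` for the model, its assumptions and all tunable
parameters.

## Worked example

Simulate a two-organ experiment with 20% planted cyclic genes and a matched
homology table, run the pipeline, and inspect the divergence summary:

```r
library(ohnorhythm)

cfg <- sim_config(n_genes = 200, organs = c("skin", "eye"),
                  cyclic_fraction = 0.2, amplitude_range = c(0.8, 1),
                  baseline_mean_range = c(50, 500), seed = 42)
sim <- simulate_counts(cfg)
hom <- simulate_homology(homology_sim_config(n_ohnolog_pairs = 10,
                                             n_singletons = 20, seed = 42))
# give the first count-matrix rows the homology-table gene ids so the two
# simulations describe one genome
ids <- unique(hom$table$ensembl_gene_id)
rownames(sim$counts)[seq_along(ids)] <- ids

res <- run_pipeline(sim$counts, sim$samples, homology = hom$table,
                    n_perm = 10000, seed = 42)
#> expression: 2 organs, 200 genes [0.0s]
#> rhythm[skin]: 200 expressed, 42 cyclic [1.0s]
#> rhythm[eye]: 200 expressed, 41 cyclic [0.8s]
#> homology: 10 pairs, 20 singletons; divergence: 14 calls [0.0s]

res$summary$per_organ
#>   organ expressed cyclic cyclic_percent
#> 1  skin       200     42           21.0
#> 2   eye       200     41           20.5
```

42 of 200 expressed skin genes (21.0%) are called cyclic at p < 0.01 —
close to the planted 20% because every planted rhythm here has high
amplitude (0.8–1) and the false-positive rate is below 1%. The divergence
summary tallies each recovered ohnolog pair by how its two copies divide
the cyclic pattern:

```r
dv <- res$divergence$summary
dv$table[dv$table$count > 0, ]
#>                   scope              category count percent
#> 1           intra_organ            ONE_CYCLIC     3      75
#> 2           intra_organ BOTH_CYCLIC_DIFFERENT     1      25
#> 5           inter_organ    DIFFERENT_BY_ORGAN     1     100
#> 7 singleton_multi_organ          SYNCHRONIZED     1      25
#> 8 singleton_multi_organ             DIFFERENT     3      75
#> 9            not_cyclic            NOT_CYCLIC     5     100

dv$n_cyclic_pairs
#> [1] 5
```

Of the 10 planted pairs, 5 have at least one cyclic copy; 4 of those 5
(80%) are confined to a single organ, and in most only one copy cycles —
the sub-/neo-functionalization signature. A per-gene query reproduces the
expression-browser table:

```r
query_gene(res, res$ohnologs$gene_a[1])$summary
#>   organ mean_cpm expressed p_value is_cyclic peak_zt peak_shape amplitude
#> 1  skin     8014      TRUE   0.935     FALSE    12.5          9     0.603
#> 2   eye     6813      TRUE   1.000     FALSE    21.5          6     0.418
```

This copy is expressed in both organs but cycles in neither (p ≫ 0.01);
its partner carries the rhythm.

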