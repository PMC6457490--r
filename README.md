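# tilebind

Binding-region calling and Rank Product differential expression for
two-colour, dye-swapped tiling microarrays.

`tilebind` is for experiments that locate the genomic targets of a
bacterial DNA-binding regulator by contrasting two strains — a deletion
mutant and the same mutant complemented with an epitope-tagged copy —
on high-density tiling arrays, with a matched two-colour transcriptomic
time course. The motivating system is a *Streptomyces* two-component
response regulator that represses three antibiotic biosynthetic gene
clusters; its binding sites show up as probe-level enrichment of
`log2(IP/mock)` in the complemented strain only, in either a
single-summit (monophasic) or an asymmetric double-summit (biphasic)
profile.

## What it computes

**ChIP branch** — per timepoint: QC flag filtering (a probe is excluded
if flagged, in both channels, in samples of both strains or in more than
two samples), dye-orientation correction, scale normalization
(`median(|x|)` equalized across arrays), dye-balanced strain averaging,
then the strain-contrast enrichment call: a probe is a *candidate* iff
its complemented-strain value exceeds its deletion-strain value in both
replicate pairs, and *enriched* iff its fold change

```
fold_change = mean(complemented) − mean(deleted)        [log2 units]
threshold   = mean(fc over candidates) + 1.0 × sd(fc over candidates)
```

exceeds the data-derived threshold (sample sd). Enriched probes within
1 kb join by single linkage; clusters of ≥ 2 probes become binding
regions, which are annotated against gene models (promoter-proximal /
gene-internal / intergenic) and classified as monophasic or biphasic
from the smoothed, background-corrected fold-change profile.

**Expression branch** — per timepoint: the same QC filter and
orientation, global median centering within array, scale normalization,
per-gene averaging of good probes over coding spans, then unpaired
two-class **Rank Product**: with the K = nA × nB pairwise differences
ranked per comparison, `RP_g = (∏_k r_gk)^(1/K)`; significance is a
permutation-estimated pfp (expected false positives per selected gene),
genes selected at `pfp < 0.15`, and selected genes counted inside
configured biosynthetic-cluster ID ranges (defaults: *act*
SCO5071–SCO5092, *cda* SCO3210–SCO3249, excluding the deleted gene
SCO3226).

**Synthetic data** — a seeded generator reproduces the design (two
strains × two dye-swapped replicates × three timepoints) with
ground-truthed spike-in binding regions and DE genes, used throughout
the tests.

## Worked example

```r
library(tilebind)

cfg <- sim_config(rng_seed = 42)          # 100 kb genome, 80 bp tiling
sim <- simulate_dataset(cfg)              # 12 spiked regions, noise sd 0.3

res <- run_chip_pipeline(sim$chip, sim$annotation, timepoints = 14)[["14h"]]
res$enrichment$threshold
#> 0.973  (398 candidate probes, 51 enriched)
res$regions[1:4, c("region_id", "start", "end", "n_probes", "shape",
                   "location_class")]
#>   region_id start   end n_probes      shape    location_class
#>  region_001  5921  6140        3 monophasic     gene_internal
#>  region_002  8561  8860        4 monophasic promoter_proximal
#>  region_003 21921 22620        5   biphasic     gene_internal
#>  region_004 29841 30140        4 monophasic     gene_internal
```

All twelve spiked centers fall inside called regions; `region_002` is
the spike placed in the shared intergenic gap of a divergent gene pair,
recovered as promoter-proximal with no overlapping gene body.

```r
ann <- sim_annotation(cfg)
sim2 <- simulate_dataset(cfg, truth_de = true_de(ann$gene_id[c(3, 40)],
                                                 14, c(2, -2)))
expr <- run_expression_pipeline(sim2$expression, sim2$annotation,
                                timepoints = 14, n_permutations = 500,
                                seed = 1,
                                gene_clusters = list(early = c("SCO1001",
                                                               "SCO1030")),
                                exclusions = character())
expr[["14h"]]$de
#> $up:   "SCO1003"    $down: "SCO1040"
attr(expr, "counts_summary")
#>  timepoint cluster direction n_genes
#>         14   early        up       1
#>         14   early      down       0
```

The two spiked DE genes (log2 effects +2 and −2) are recovered in the
correct directions at `pfp < 0.15`, and the cluster count reflects that
only `SCO1003` lies in the queried ID range.

## Documentation

The methods vignette (`vignettes/tilebind-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with units and
defaults, the permutation-null design for the Rank Product pfp, what the
synthetic generator does and does not emulate, and known limitations.
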