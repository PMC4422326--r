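# smrtbs — targeted amplicon bisulfite sequencing analysis for long reads

`smrtbs` is an R package for quantitative CpG methylation analysis from
highly multiplexed, long-read (CCS-level) amplicon bisulfite sequencing.
It covers the full analysis path from raw barcoded FASTQ to per-CpG
methylation levels, together with the design-side calculations
(equimolar pooling, CpG-island coverage) and a ground-truth read
simulator that replaces the wet lab for testing.

## Who it is for

Labs running targeted bisulfite assays on long-read platforms: barcoded
amplicons of ~0.6–1.5 kb spanning whole CpG islands, multiplexed across
samples, sequenced to ~100X as high-accuracy consensus reads. The same
machinery works for any amplicon bisulfite design with per-sample
barcodes and universal primers.

## What it computes

For each CpG site *s* of an amplicon, the methylation level is estimated
from filtered reads as

```
level(s) = n_METH(s) / (n_METH(s) + n_UNMETH(s))
```

where a read contributes METH if it retains C at a CpG (or G at the
paired position on the bottom strand) and UNMETH if it shows the
converted base; ambiguous evidence is excluded and sites with informative
depth < 10X are dropped. Upstream of this sit:

* **Demultiplexing** by 18-bp barcodes with Levenshtein edit distance ≤ 2
  (indels included), both orientations tested, ties and end-barcode
  conflicts left unassigned; barcodes and universal primers trimmed;
  reads must exceed 50 bp after trimming.
* **Bisulfite-aware alignment**: four candidates per amplicon (read ×
  reverse complement against C→T top / G→A bottom converted references)
  in collapsed three-letter space, semi-global with affine gaps;
  methylation is read back from the original bases.
* **Per-read filters**: conversion rate over non-CpG cytosines
  (`CONVERTED/(CONVERTED+RETAINED)`, pass at ≥ 0.95) and clonal
  PCR-artifact removal (reads with identical CpG *and* non-CpG patterns
  across the amplicon collapse to one representative).
* **Statistics**: replicate pairwise Pearson r and per-site SD (n−1),
  cross-platform site-level comparison, and the equimolar pooling formula
  `V_i = M·L_i / (n·C_i·ΣL)`.

## Worked example

Simulate a triplicate experiment over three CpG islands (low,
intermediate, high methylation; 700 bp, 24 CpGs each) at ~100X and run
the pipeline:

```r
library(smrtbs)
set.seed(11)
prof <- island_profiles(length = 700, n_cpg = 24)
man  <- sim_manifest(c("rep1", "rep2", "rep3"))
cfg  <- sim_config(prof$refs, prof$levels, man, n_reads = 100, seed = 11)
sim  <- simulate_dataset(cfg)

res  <- run_pipeline(setNames(sim$reads$sequence, sim$reads$read_id),
                     cfg$refs, man)

res$filter_reports[["rep1.intermediate"]]
#> filter_report: 100 reads in; 16 below conversion threshold; 0 clonal removed; 84 pass
#> mean conversion rate: 0.9670 before, 0.9714 after filtering

head(res$profiles[["rep1.intermediate"]]$sites, 5)
#>   pos      level depth n_meth n_unmeth n_ambig
#> 1  28 0.05952381    84      5       79       0
#> 2  56 0.20238095    84     17       67       0
#> 3  84 0.48809524    84     41       43       0
#> 4 112 0.76190476    84     64       20       0
#> 5 140 0.97619048    84     82        2       0

replicate_stats(res$profiles[paste(man$sample_id, "intermediate", sep = ".")])
#> replicate_set intermediate: 3 replicates, 24 common sites
#>   pairwise Pearson r: 0.983 +/- 0.005
#>   per-site SD: median 0.0341
```

The filter report shows the two read filters at work (16/100 reads fell
below the 95% conversion threshold at simulated efficiency 0.97, raising
the mean conversion rate from 96.7% to 97.1%). The recovered site levels
track the simulated truth (0, 0.25, 0.5, 0.75, 1 cycling across sites)
within binomial sampling error at 84X, and the triplicates agree at
r ≈ 0.98 with a median per-site SD of 0.034.

Bench-side, the pooling calculation for two 800 bp amplicons at
50 ng/µL, 500 ng total:

```r
pooling_volumes(500, c(800, 800), 50, n_samples = 1)
#>   length concentration volume molar_share
#> 1    800            50      5         0.5
#> 2    800            50      5         0.5
```

A thin CLI over the same functions is installed at
`system.file("scripts", "smrtbs", package = "smrtbs")` with subcommands
`demux`, `run`, `simulate`, `islands`, and `pool`.

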