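# sgribo

Quantifying stress-granule condensation in single cells and classifying
translational regulation from paired RNA-seq/Ribo-seq — with a synthetic-data
generator that makes every stage testable against known ground truth.

## The problem

Stress granules (SGs) are cytoplasmic condensates of mRNA and RNA-binding
proteins that form when translation arrests under stress; G3BP proteins
nucleate them. Studying how SG condensation feeds back on gene expression
requires two quantitative pipelines that are usually assembled ad hoc:

1. **Imaging**: from two-channel fluorescence microscopy (nuclear stain +
   fluorescent reporter), segment nuclei, grow single-cell regions from
   them, detect punctate foci, and report per-cell and per-condition
   statistics — the percentage of cells with foci, and foci count/area per
   cell, as mean ± SEM across replicates.
2. **Sequencing**: from paired RNA-seq and ribosome-profiling count
   matrices, decide per gene whether a perturbation changed its mRNA
   abundance, its ribosome occupancy, its translation efficiency (TE), or
   whether an mRNA change was translationally *buffered* — then ask which
   gene sets are enriched among the changes.

`sgribo` implements both, plus melt-curve melting-temperature estimation
for the accompanying protein-biophysics assays, for R users comfortable
with Bioconductor idioms (`SummarizedExperiment` in, data frames out).

## Models and statistics

* **Foci detection**: Otsu nuclear thresholding; seeded-propagation cell
  segmentation (CellProfiler's algorithm, via EBImage); white top-hat
  speckle enhancement with a disk element; eccentricity filter — foci with
  ellipse-equivalent eccentricity `< 0.875` (from second central moments)
  are kept.
* **Counts**: negative binomial, `Var = μ + αμ²`. Median-of-ratios size
  factors; per-gene NB GLM Wald tests with a mean-based local dispersion
  trend and empirical-Bayes moderation; TE as the `condition:assay`
  interaction coefficient with one shared dispersion per gene;
  normal-prior LFC shrinkage; BH correction throughout.
* **Classification** (baseMean > 20 in both assays): `Buffering` = RNA
  q < 0.01, Ribo q ≥ 0.05; `Ribo ocp` = Ribo q < 0.05; `RNA abundance` =
  both assays q < 0.05, concordant signs; `TE` = TE q < 0.05. Multi-label
  flags plus one canonical label (precedence RNA abundance > Buffering >
  TE > Ribo ocp).
* **Enrichment**: preranked GSEA (weighted Kolmogorov–Smirnov running sum,
  random-gene-set permutation null, 10 000 permutations by default) and
  hypergeometric over-representation against a background of genes with
  TPM > 1.
* **Tm**: first-derivative maximum of the smoothed melt curve on the
  0.2 °C instrument grid.

The methods vignette (`vignettes/sgribo-methods.Rmd`) documents every
model, default and numerical choice.

## Worked example

Simulate a field of 20 stressed cells, quantify it, then classify planted
regulatory classes from simulated paired counts:

```r
library(sgribo)
library(SummarizedExperiment)

field <- generateField(fieldSpec(nCells = 20L), seed = 1)
res <- quantifyField(nuclearChannel(field), reporterChannel(field))
head(res$cellTable, 3)
#>   cell_id foci_count total_foci_area reporter_mean has_foci
#> 1       1          1              25      589.0817     TRUE
#> 2       2          1              38      587.9509     TRUE
#> 3       3          2              42      588.9987     TRUE
```

Each row is one segmented cell: how many eccentricity-filtered foci it
carries, their summed area in px², and its mean reporter intensity (the
expression-matching control). Planted counts next:

```r
design <- countDesign(nGenes = 1000L,
                      classes = c(TE_UP = 50L, BUFFERING_UP = 50L),
                      effectLfc = 2, baselineMean = 200, dispersion = 0.05)
se   <- generateCounts(design)
cnt  <- assay(se, "counts"); cd <- colData(se)
rna  <- nbWaldTest(cnt[, cd$assay == "RNA"],  cd$condition[cd$assay == "RNA"])
ribo <- nbWaldTest(cnt[, cd$assay == "RIBO"], cd$condition[cd$assay == "RIBO"])
te   <- teInteractionTest(cnt[, cd$assay == "RNA"], cnt[, cd$assay == "RIBO"],
                          cd$condition[cd$assay == "RNA"],
                          cd$condition[cd$assay == "RIBO"])
table(truth = rowData(se)$class, called = classifyGenes(rna, ribo, te)$label)
#>               called
#> truth          Buffering up  NS Ribo ocp down TE down TE up
#>   BUFFERING_UP           50   0             0       0     0
#>   NULL                    0 890             3       2     5
#>   TE_UP                   0   0             0       0    50
```

All 50 planted TE-up and all 50 buffering-up genes are recovered; 10 of
900 null genes (1.1%) pick up a spurious label. And a melt curve:

```r
meltCurveTm(generateMeltCurve(55, noiseSd = 20, seed = 1))
#> Tm estimate: 55.0 C (window 5, 349 derivative points)
```

`runPipeline()` chains all stages (simulate → segment/quantify →
DE/TE/classify → GSEA/GO → Tm) from one config and seed, writing TSV/TIFF
outputs and a JSON manifest with parameters and content hashes; reruns are
byte-identical.

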