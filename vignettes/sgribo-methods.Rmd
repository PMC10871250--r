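---
title: "Methods: stress-granule quantification and translational-regulation classification"
author: "sgribo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress-granule quantification and translational-regulation classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`sgribo` implements two analyses around the biology of stress-granule (SG)
condensation: (i) per-cell quantification of G3BP-type reporter foci from
two-channel fluorescence microscopy, and (ii) classification of
translational regulation from paired RNA-seq and ribosome-profiling
(Ribo-seq) count matrices, with preranked gene-set enrichment and
over-representation analysis downstream. A third, smaller component
estimates protein melting temperatures from differential scanning
fluorimetry curves. Every stage is exercised end to end on synthetic data
with known ground truth, generated by the package itself, so the whole
pipeline is testable without any external download.

# The imaging pipeline

## What the synthetic fields emulate

`generateField()` renders fields of adherent cells the way a 20x
spinning-disk image of U-2OS-like cells presents them to a segmentation
pipeline: a nuclear-stain channel with bright disks, and a reporter channel
in which the cytoplasm is bright, the nucleus is dimmer (0.6 of the
cytoplasmic level), and condensed foci are small bright ellipses. Foci are
rasterized hard-edged and then blurred with a sigma = 0.5 px Gaussian to
emulate optics while keeping the analytic pixel-count area usable as ground
truth; Gaussian read noise (default sd 25 photons against a focus amplitude
of 1500) is added last. Cells are placed by rejection sampling with
non-overlapping cell disks; foci are sampled inside each cell's cytoplasmic
annulus with Poisson counts (default mean 3) and a fixed minor/major axis
ratio (default 0.85, eccentricity 0.53).

The generator deliberately does **not** model a realistic point-spread
function, photobleaching, cell motility between frames, intensity gradients
within compartments, or out-of-focus light. Tests passing on these fields
therefore demonstrate correctness of the measurement logic (segmentation,
assignment, filtering, statistics), not robustness to every optical
artifact of real microscopy.

Time courses (`generateTimecourse()`) keep cell positions fixed across
timepoints and populate foci only inside the condensation window
(defaults 30-150 min), emulating transient granule assembly and
disassembly under acute arsenite- or thapsigargin-type stress.

## Segmentation and quantification

* **Otsu thresholding** (`otsuThreshold()`): 256 equal-width bins over the
  observed intensity range; the cut maximizing the between-class variance
  $w_1 w_2 (\mu_1 - \mu_2)^2$; ties resolve to the lower cut. A constant
  image is a degenerate input and raises an error so the caller decides the
  fallback.
* **Nuclei** (`segmentNuclei()`): Otsu foreground, hole filling,
  8-connected labeling, area gate (default 50 px^2 minimum). Two nuclei
  joined by even a one-pixel bridge merge into one object; this is a
  documented limitation of threshold-based nuclear segmentation.
* **Cells** (`segmentCells()`): seeded propagation from nuclear labels
  across the Otsu foreground of the reporter channel (the CellProfiler
  propagation algorithm, via `EBImage::propagate`). The `regularization`
  weight (default 0.05) trades local intensity differences against
  geometric distance; with uniform intensity it reduces to a distance
  partition, so two equidistant seeds split a uniform region at the
  perpendicular bisector.
* **Foci** (`detectFoci()`): white top-hat with a disk structuring element.
  The element radius defaults to 6 px, about twice the expected focus
  radius, which suppresses anything wider than the element (cell bodies,
  nuclei) while passing puncta. Grayscale morphology operates on a [0, 1]
  rescale of the image; because opening commutes with affine rescaling the
  top-hat is mapped back to photon units exactly, so manual thresholds are
  specified in the image's own units. Otsu or manual thresholding, then an
  area floor (default 5 px^2).
* **Eccentricity filter** (`filterFoci()`): ellipse-equivalent eccentricity
  from second central moments (with the 1/12 px^2 finite-pixel correction);
  foci with eccentricity strictly below 0.875 are kept, removing elongated
  segmentation artifacts. The threshold is strict (a focus at exactly 0.875
  is removed) and raising it can only grow the retained set.
* **Assignment** (`assignAndSummarize()`): a focus belongs to the cell
  label under its intensity-weighted centroid; centroids on background are
  tallied as unassigned rather than silently dropped.
* **Summaries** (`summarizeCondition()`): a cell "has foci" when its
  retained focus count is >= 1 (the cutoff is not defined more finely by
  the source imaging literature, so the weakest sensible definition is
  used). Percentages and per-cell means are computed per replicate and then
  averaged; SEM = sd/sqrt(N) across replicate-level values, which is the
  "mean +- SEM across replicates" convention of the imaging figures this
  mirrors. QC flags mark conditions with fewer than 3 replicates or fewer
  than 100 cells in any replicate.
* **Group comparison** (`compareConditions()`): two-sided Mann-Whitney on
  pooled per-cell values against a reference condition, with the
  conventional star tiers (p < 0.05/0.01/0.001/0.0001). Pooling cells is an
  interpretation — the alternative of testing replicate means is too weak
  at N = 3 — and is logged as such here.
* **Expression matching** (`checkExpressionDeviation()`): conditions whose
  median reporter intensity deviates from the reference median by more than
  25% (strictly) are flagged, the standard control against expression-level
  confounds when comparing condensation phenotypes.

# The count pipeline

## Model

Counts are negative binomial with $\mathrm{Var} = \mu + \alpha \mu^2$ (the
DESeq2 parameterization). `generateCounts()` draws
$K_{gs} \sim \mathrm{NB}(s_s\, q_g\, 2^{\beta_g x_s}, \alpha_g)$ where
$x_s$ indicates the stressed condition and $\beta_g$ encodes the planted
class: TE genes shift only ribosome occupancy, buffering genes shift only
mRNA abundance, RNA-abundance genes shift both concordantly, and
occupancy-only genes shift the Ribo assay. The noiseless mean matrix is
returned beside the counts so class semantics are checkable exactly.

## Normalization and dispersion

`sizeFactorsMoR()` is the median-of-ratios estimator. It assumes that most
genes are unchanged around the median; heavily one-sided regulation shifts
the reference and biases fold changes toward zero (the usual composition
caveat), which is why recovery checks in the test-suite use balanced
up/down designs.

`estimateDispersionsNB()` combines (i) per-design-cell method-of-moments
estimates $\hat\alpha_g = \sum_j (n_j-1)(v_j - m_j \bar{s^{-1}}_j) \big/
\sum_j (n_j-1) m_j^2$ on normalized counts, (ii) a mean-based local
(loess, degree 1, span 0.3) regression of the *unclamped* estimates on log
mean — fitting on the log scale or after clamping at zero would
systematically underestimate the trend because the estimates are heavily
right-skewed at n = 3 — and (iii) empirical-Bayes shrinkage toward the
trend with a per-gene weight
$w_g = V_g / (V_g + \hat\tau^2)$, where
$V_g \approx 2(\alpha_{\mathrm{trend}} + \bar{s^{-1}}/\mu_g)^2/\mathrm{df}$
is the expected sampling variance of the moment estimator and $\hat\tau^2$
the excess (biological) spread around the trend. When dispersions are
homogeneous this collapses onto the trend and keeps the downstream Wald
test close to nominal size at n = 3; genuine gene-to-gene dispersion
differences survive the shrinkage.

## Testing and classification

`nbWaldTest()` fits a per-gene NB log-linear GLM with log size factors as
offsets and the shrunken dispersions fixed, and reports log2 fold changes,
Wald z = LFC/SE, two-sided normal p, and BH-adjusted q-values; baseMean is
the mean of normalized counts over all samples. `shrinkLFC()` adds a
zero-centered normal-prior MAP (`log2FCShrunk`), with the prior variance
moment-matched to the observed LFC distribution; this is a deliberate
simplification of apeglm-style shrinkage — p-values are untouched and the
shrunken estimate is SE-monotone and never exceeds the MLE in magnitude.

`teInteractionTest()` fits condition + assay + condition:assay jointly over
both assays with assay-specific size factors and one shared dispersion per
gene (the Riborex simplification, which stabilizes small-n fits); the
interaction coefficient is the translation-efficiency log2 fold change.
Swapping the assay labels negates it exactly.

`classifyGenes()` applies the category rules: genes need RNA and Ribo
baseMean above 20; buffering up/down requires RNA q < 0.01 with the
matching sign **and** no significant ribosome-occupancy change
(Ribo q >= 0.05); Ribo-occupancy flags at Ribo q < 0.05; RNA abundance
requires q < 0.05 in both assays with concordant signs (discordant
significant pairs are flagged separately and given no canonical
direction); TE flags at TE q < 0.05. Flags are independent and multi-label.
The canonical single label resolves overlaps by the precedence
**RNA abundance > Buffering > TE > Ribo occupancy**. Ranking buffering
above TE is a considered choice: a gene whose mRNA rises while its
ribosome occupancy stays flat *necessarily* has reduced TE, so the TE flag
fires on essentially every buffered gene; "buffering" is the more specific
description of that pattern in the translational-buffering literature, and
demoting it below TE would leave the buffering category empty. Users
preferring another convention can re-derive labels from the retained
flags.

# Enrichment

`prerankedGSEA()` ranks genes by score (stable sort, ties broken by gene
id, documented because the running sum depends on order) and computes the
weighted Kolmogorov-Smirnov enrichment score: hits add
$|s|^p / \sum_{hits} |s|^p$ (default weight p = 1; p = 0 gives the classic
statistic), misses subtract $1/(N-K)$; ES is the signed extremum. The null
is built from random same-size gene sets — the only permutation scheme
available to a preranked analysis. The permutation p-value is
sign-conditional, $p = (1 + \#\{\text{same-sign } |ES_{null}| \ge
|ES|\})/(1 + \#\{\text{same-sign}\})$: conditioning the denominator on the
sign is what makes p approximately uniform under random scores (a full
$n_{perm}+1$ denominator with sign-matched counts concentrates p below
0.5), and p is bounded below by $1/(n_{perm}+1)$. NES divides ES by the
mean same-sign null magnitude; since NES normalization conventions differ
between implementations, ES and p are the comparable quantities. The
leading edge collects hit genes up to (positive ES) or after (negative ES)
the running-sum extremum.

`goOverrepresentation()` is the hypergeometric upper tail with BH
adjustment, against a background of expressed genes defined by
`buildBackground()` as TPM strictly above 1 in at least one sample;
`computeTPM()` normalizes each column to one million after dividing by
gene length.

# Melt curves

`generateMeltCurve()` produces a logistic transition on the instrument
grid (25 to 95 C in 0.2 C steps, 351 points). The default steepness of
2 per degree C gives a 2-3 degree 10-90% transition width, typical of
small-domain unfolding monitored by dye fluorescence; with the default 2%
noise this keeps the derivative peak well separated from noise-induced
local maxima. `meltCurveTm()` smooths with a centered moving average
(default window 5, odd by construction), takes central differences on the
uniform grid, requires a rising phase (a monotone-decreasing curve is a
no-transition error), and reports Tm at the derivative maximum. Constant
fluorescence offsets cancel in the derivative.

# Simulation design and problem sizes

The statistical checks run at sizes chosen to finish in minutes while
leaving no ambiguity about the property under test: 10 fields of 20 cells
for segmentation recovery; 2000 genes, 3 vs 3, dispersion 0.1 for the
type-I check; 2000 genes with 100-gene planted classes at |LFC| = 2,
baseline mean 200, dispersion 0.05 for class recovery; 200 permutation
repeats for the GSEA null; 50 curves for Tm recovery.

Two simulations use smaller dispersions, chosen from a delta-method power
analysis before the tests were run, not calibrated afterwards: the sd of
the TE interaction estimate in log2 units is approximately
$\sqrt{\sum_{cells} (1/\mu + \alpha)/n} / \ln 2$, which at
$\alpha = 0.05$, n = 3 is about 0.38 — no correct implementation could
then place 90% of pure-abundance genes inside a +-0.2 band. The TE-null
check therefore runs near the Poisson limit ($\alpha = 0.001$, sd about
0.09) where the +-0.2 band is a real test of the interaction model rather
than of luck, and the LFC-recovery check uses $\alpha = 0.01$ for the same
reason at its +-0.3 band.

# Numerical conventions

* Coordinates are 1-based (row, col) in the R convention; connected
  components are 8-connected.
* One RNG stream per generator call, restored afterwards; a single
  pipeline seed fans out to per-stage child seeds through a stage-name
  hash, so stages rerun independently and reproducibly. Rerunning
  `runPipeline()` with the same config and seed reproduces every output
  byte for byte (images are written as 16-bit TIFF after rounding to
  integer photon levels).
* Dispersions are floored at 1e-8; all-zero genes carry NA statistics and
  are excluded from classification by the baseMean filter.
* Every threshold actually applied (eccentricity, baseMean, q-value
  cutoffs, TPM background) is echoed to the run log and stored in the
  manifest.

# Known limitations

* Threshold-based nuclear segmentation merges touching nuclei; propagation
  then treats them as one cell.
* The manual-threshold and rescale-factor values of the original imaging
  pipelines are not published; defaults here are this package's own.
* `shrinkLFC()` uses a normal prior, not a heavy-tailed one; strong true
  effects are shrunk slightly more than apeglm would.
* Median-of-ratios normalization assumes mostly-unchanged genes; strongly
  one-sided regulation biases fold changes toward zero.
* The NB Wald test uses normal p-values; at n = 3 its size is controlled
  through the dispersion moderation described above, not through a
  t-correction.
* GSEA NES values are implementation-specific; compare ES and p across
  tools, not NES.
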