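---
title: "Models and methods behind loopscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind loopscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopscape)
```

loopscape implements the computational core of a chromosome-conformation
study: building and normalizing Hi-C contact matrices, quantifying A/B
compartments, calling punctate long-range interactions with a
donut-filter local background, aggregate peak and TAD analysis with
shifted-region controls, Capture-C viewpoint normalization, spike-in
calibration of count tables, and single-cell DNA-FISH contact
probabilities. Every stage can be exercised on synthetic data with
planted ground truth, so the package's guarantees are tested end to end
without any external download.

This vignette explains the models, the tunable parameters and their
defaults, what the generators do and do not emulate, and the design
choices made where the procedure was genuinely open.

## The synthetic contact-matrix generator

The generator is the study-condition definition, not a convenience. For
an off-diagonal pixel $(i, j)$ of a binned cis matrix the expected count
is

$$\lambda_{ij} = C\,|i-j|^{\alpha}\,\bigl(1 + \rho\, e_i e_j\bigr)\,
  t_{ij}\, \ell_{ij},$$

where $\alpha < 0$ is the distance-decay exponent (default $-1$; the
exponent of real data varies by condition and is not pinned by this
package — $-1$ is the classic fractal-globule reference slope),
$e \in [-1, 1]^n$ is the planted compartment vector with coupling
$\rho \in [0, 1)$ (multiplicative so that $\lambda$ stays positive and
the O/E correlation matrix is a checkerboard), $t_{ij}$ is a constant
TAD boost (default 2) for pixels with both bins in the same TAD, and
$\ell_{ij}$ is the loop fold for pixels inside a planted loop's
footprint. $C$ is set so the expected total count equals the requested
depth. Counts are Poisson, drawn once per pixel and mirrored; the
diagonal is excluded from sampling and from every downstream statistic.

Loops carry a `loop_width` (odd, in bins): a width of 5 at 10 kb gives a
focal enrichment the size of the central 50 kb window that aggregate
peak analysis scores, emulating the extent of real focal peaks; width 1
at 100 kb is a single calling-resolution pixel. The GC track is a
monotone function of the compartment sign plus noise
($0.41 + 0.03\,e_i + \varepsilon$), so eigenvector orientation by GC is
decidable by construction — in real data GC is only a proxy and can
locally disagree.

What the generator does **not** emulate: fragment-level biases
(GC/mappability coverage bias is absent, so balancing corrects only
sampling noise), trans contacts, loop networks with shared anchors,
unmappable regions, and polymer physics (no loop extrusion dynamics).
Passing tests therefore demonstrate correctness of the *computations*
under a faithful Poisson sampling model, not robustness to every
artifact of real libraries.

Distance distributions for FISH are a two-component mixture: contacts
are folded-normal around 0 (scale 50 nm), background is normal truncated
at zero by resampling (mean 700 nm, SD 150 nm — typical inter-domain
distances for loci hundreds of kilobases apart in ESC nuclei), and the
calibration distribution emulates two-color measurements of one probe
(73 ± 38 nm). Truncation resamples rather than reflects because physical
distances are non-negative and reflection would distort the mode.

The spike-in generator models the essential confound: each library is
sequenced to a fixed depth while target and spike-in material compete
for reads. A global 2-fold depletion of the target leaves the target
read total nearly unchanged and doubles the spike share, which is why
naive library-size normalization reports no change and spike-in
calibration recovers the planted shift.

## Hi-C core

Valid-pair filtering applies, in order: MAPQ ≥ 30 on both mates; PCR
duplicates (identical 5′ positions and strands of both mates — the
standard convention, since "duplicate" is not otherwise defined);
self-ligated fragments; reads more than 5 kb from the nearest
restriction site of their fragment; and religation products,
operationalized as adjacent-fragment pairs with opposite strand
orientation. Each stage's removals are counted and reported, and the
categories always sum to input minus output.

Matrices are binned at 10 kb (0-based half-open bins), masked at bins
with fewer than 10% of the median fragment count (strict `<`; a
`coverage` mode masks on row sums instead, since "number of fragments
per bin" could be read either way), and balanced per chromosome with
Knight–Ruiz scaling. The balancing target row sum is the mean unmasked
raw row sum rather than 1 — only ratios matter downstream and this keeps
counts on an interpretable scale. The KR Newton iteration falls back to
Sinkhorn-style iterative proportional fitting when it fails to converge
(logged); the symmetric scaling of a positive matrix is unique, so both
routes agree, and the test suite checks the implementation against an
independently coded Sinkhorn oracle to 1e-6. Unmasked all-zero rows are
auto-masked with a warning.

The O/E transform divides each pixel by the mean over unmasked pixels at
its distance; pixels with zero expected become `NA` and are excluded.
The contact-probability curve reports, per log-spaced distance bin, both
the total contact fraction (`prob`, summing to 1) and the normalized
per-distance mean (`density`), whose log-log slope estimates the decay
exponent.

## Compartments

O/E matrices at 500 kb are converted to Pearson correlation matrices;
each row's own diagonal entry is excluded (self-correlation inflates
structure), zero-variance rows are dropped and reported. The compartment
vector is the eigenvector of the largest algebraic eigenvalue — "first
eigenvector" is otherwise ambiguous — with ties broken by magnitude then
index. The sign is oriented so the GC-richer side is positive (A).
Compartmentalization strength is the mean absolute off-diagonal
correlation, in $[0, 1]$.

One caveat discovered while validating: a strictly periodic planted
compartment pattern makes the correlation matrix near-circulant, whose
leading eigenpair is a degenerate Fourier pair — an arbitrary rotation
of which need not align with the blocks. The pipeline therefore plants
aperiodic blocks (0.5–2.5 Mb), as real genomes do.

## Loop calling

For each pixel at least $w + 1$ bins off the diagonal, four local
neighborhoods are evaluated — donut annulus between radii $p$ and $w$
excluding the center cross, 3-wide horizontal and vertical stripes, and
the lower-left quadrant — each as
$\hat\lambda = \frac{\sum \text{obs}}{\sum \text{exp}} \cdot
\text{exp}(i,j)$ with the distance-decay expectation. All region sums
decompose into axis-aligned box sums over summed-area tables, so the
whole matrix is scored in one vectorized pass; the geometry is verified
exactly against an enumeration oracle for all $(p, w) \le 5$. Defaults
$p = 1$, $w = 5$ at the working resolution.

P-values are upper-tail Poisson probabilities, corrected by
Benjamini–Hochberg within $\lambda$-chunks
($\lambda \in [2^{k/3}, 2^{(k+1)/3})$; plain BH by flag). Calls must
pass four criteria: donut enrichment ≥ 2.25, donut FDR ≤ 0.05, FDR ≤ 0.1
in the other three neighborhoods, and ≥ 29 observed contacts. The count
criterion makes calls depth-dependent by design, which is why statistics
are computed on raw counts; significant pixels are merged by 8-connected
adjacency (a minimal dedup — no clustering procedure is otherwise
specified) with the maximum-observed pixel as summit.

## Aggregate analyses

APA extracts 500 kb windows at 10 kb around each cis anchor pair
(midpoint bins; pairs closer than 250 kb excluded) on raw matrices and
divides elementwise by the mean of 100 control windows, shifted along
the diagonal by a shared offset drawn uniformly from ±[100 kb, 1 Mb]
and rejected if it overlaps the true window — the shared offset
preserves separation exactly, which the implementation can record for
auditing. The center score is the 10%-trimmed mean of the central 5 × 5
pixels ("trimmed mean" without a fraction; 10% per tail is the common
default). Pairs are split into five equal-size distance quantiles,
remainder to the proximal groups. Aggregate TADs extract each TAD plus
one-TAD-length flanks from O/E, rescale by nearest-neighbor resampling,
and average; the central third is the TAD body.

Signal enrichment at paired anchors is the mean of source and sink
signal divided by the same statistic over 1000 distance- and
chromosome-matched random pairs.

## Capture-C

PRPP is exactly $N/\mathrm{cov} \times n_{\mathrm{prom}} \times 100$ per
fragment (×1000 for display, mPRPP), which makes profiles exactly
depth-invariant when counts scale with coverage. The interaction scorer
is a documented stand-in behind the standard "score ≥ 5" interface: a
log-log linear fit of count against fragment distance (top 1% of
fragments excluded so true peaks do not inflate the background) gives a
Poisson expectation, and the score is $-\log_{10}$ of the upper tail.
Significant fragments merge while closer than 10 fragments (strict,
index-wise — the unit is restriction fragments, not bp); summits prefer
the control sample and break ties toward the viewpoint. Aggregate
profiles normalize every condition to the control summit PRPP before
averaging within distance groups; the window half-width is exposed as
`window_frags` since only figure axes imply it.

## Calibration

Spike-in factors are $f_i \propto g_i / S_i$ — inverse spike totals
corrected by the gDNA mixing ratio (normalized to its cross-sample mean,
since only relative mixing is identified) — rescaled so the largest
factor is 1. Subsampling is deterministic scaling by default (identical
expectation, zero added variance); binomial thinning is available for
strict random-subsampling semantics. Expression is log2(RPKM + 0.01)
with replicates pooled by summing normalized counts before RPKM; ChIP
counts per peak use union-overlap counting and log10(count + 8). The
differential-expression contract fixes inputs, thresholds
(p-adj < 0.05 and fold change > 1.5, both strict) and outputs around a
pluggable per-gene test; the default is a Welch t-test on log2
normalized counts with BH correction — a stand-in, since the negative
binomial GLM machinery of dedicated DE tools is out of scope here.

## FISH

Spot sub-volumes are saturated beyond 96.5% of their maximum intensity
(suppressing isolated bright voxels; the saturation level is computed
per sub-volume, as the procedure operates on individual image regions),
thresholded at 90% of the processed maximum, and reduced to an
intensity-weighted centroid on the anisotropic voxel grid (64.5 × 64.5
× 150 nm typical). Weighting uses the clipped intensities above
threshold; an unweighted mask centroid is available by flag. Chromatic
offsets are estimated as mean displacements on multicolor beads and
subtracted. The contact threshold is mean + 3 SD of the calibration
distances — 187 nm for the 73 ± 38 nm reference — and contact
probability is the fraction of pairs strictly below threshold with a
Wilson 95% CI.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen to make the statistical guarantees sharp while completing in
minutes on one core: 120–200 bins at 100 kb for loop-caller calibration
(depth $10^6$–$10^7$), 450–600 bins at 10 kb for APA (depth up to
$10^7$), 60–100 bins at 500 kb for compartments, 2000 genes for
calibration, 400 alleles × 200 seeds for FISH coverage, and a 20 Mb
synthetic chromosome at depth $2 \times 10^6$ for the end-to-end
pipeline. Balancing tolerance is 1e-6 on the row-sum CV; Poisson tails
are computed exactly; all generators are pure functions of their seed,
and the pipeline report is byte-identical across reruns under one seed.

## Known limitations

Only cis matrices are analyzed (trans matrices are built but unused);
multi-resolution loop-call merging is not implemented; the Capture-C
scorer and the DE test are deliberate stand-ins behind stable
interfaces; no fragment-level coverage bias is simulated, so balancing
is exercised against sampling noise rather than systematic bias; and
image segmentation covers single-spot sub-volumes, not nucleus-scale
segmentation.
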