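---
title: "Classifying parent-of-origin expression bias and segmenting nuclear compartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying parent-of-origin expression bias and segmenting nuclear compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintr)
```

## The problem

In a cross between two genetically distinct parents, sequencing reads
covering strain-distinguishing SNPs can be assigned to the maternal or
paternal genome. For each gene, the **maternal ratio**

$$p_m = \frac{\text{maternal reads}}{\text{maternal reads} + \text{paternal reads}}$$

ranges from 0 (only paternal reads) to 1 (only maternal reads), with
0.5 the Mendelian expectation of equal biallelic contribution. In
bryophyte embryos (the system this package emulates), transcription is
overwhelmingly maternal while the repressive chromatin mark H3K27me3 is
deposited on paternal alleles; calling these biases genome-wide, from
RNA-seq and CUT&RUN allele count tables, is the statistical core of
this package. A companion imaging stack quantifies the corresponding
nuclear organization: one to three dense heterochromatic compartments
per embryonic nucleus, visible as elevated DAPI and antibody signal.

## The classification procedure

Given a table of per-gene, per-replicate maternal/paternal counts
(fractional expected counts are allowed), `classify_imprinting()` runs:

1. **Per-replicate exact binomial tests.** For each gene and replicate,
   a two-sided exact binomial test against $p_m = 0.5$. Fractional
   counts are rounded *down* before testing; ratio estimates always use
   the non-rounded counts. The two-sided p-value is the
   minimum-likelihood sum, which for the symmetric 0.5 null reduces to
   $\min(1,\,2\,P(X \le \min(k, n-k)))$ and is computed in that closed
   form. P-values are Bonferroni-corrected; a call is significant when
   the adjusted p-value is below $\alpha = 0.05$.
2. **Five-category binning.** Significant ratios are binned as maternal
   ($p_m \ge 0.95$), maternally biased ($0.65 \le p_m < 0.95$),
   unbiased ($0.35 < p_m < 0.65$), paternally biased
   ($0.05 < p_m \le 0.35$) or paternal ($p_m \le 0.05$); all
   non-significant cases are unbiased. The intervals tile $[0,1]$
   exactly, with the open/closed boundaries above.
3. **Replicate heterogeneity.** Each gene is tested for heterogeneity
   of its maternal/paternal split across replicates with a G-test
   ($G = 2\sum O \ln(O/E)$, expected counts from pooled margins, no
   Williams correction, $\chi^2_{r-1}$ reference). Genes without
   significant heterogeneity ($p > 0.05$, unadjusted) are kept
   automatically; heterogeneous genes are kept only when every
   replicate agrees in both its significance call and its category.
4. **Pooling and final call.** For kept genes, counts are pooled across
   replicates and a final exact test is run on the (floored) pooled
   counts, Bonferroni-corrected over the kept-gene family. The final
   reported ratio is the pooled non-rounded ratio in RNA mode; in
   CUT&RUN mode it is the *mean of the per-replicate ratios* (the one
   mode difference), while final significance still comes from the
   pooled test.

Upstream of classification, two filters remove unreliable genes:
RNA-seq keeps genes with $\ge 50$ reads summed over all replicates
(boundary inclusive), CUT&RUN keeps genes with $> 10$ reads in *every*
replicate (strict). Pure-parent control samples remove genes whose
maternal control is not fully maternal ($p_m < 0.95$) or whose paternal
control is not fully paternal ($p_m > 0.05$), in each case only when
the control measured at least 5 reads for that gene. The depth filter
runs before the control filter; the manifest records the order.

```{r classify-demo}
counts <- data.frame(
  gene_id = rep("MpGENE1", 2), replicate = c("rep01", "rep02"),
  maternal_count = c(100, 98), paternal_count = c(0, 2),
  sample_role = "embryo", assay = "rna")
classify_imprinting(counts)$results
```

### Statistical design choices

Several conventions are genuinely open and fixed here as follows:

* **Bonferroni families.** Per-replicate tests are corrected within the
  family of genes testable in that replicate; final pooled tests within
  the family of kept genes. This per-stage reading is the most
  conservative consistent choice and is echoed in the run manifest.
* **Unanimity rule inputs.** The rescue rule for heterogeneous genes
  compares Bonferroni-*adjusted* significance calls and the categories
  derived from them, matching how significance is used everywhere else
  in the procedure.
* **Rounding in the G-test.** The round-down rule is stated for the
  binomial test; we apply the same flooring in the G-test for
  consistency, and drop replicates whose floored total is zero
  (reducing the degrees of freedom). Genes with fewer than two usable
  replicates are treated as non-heterogeneous and flagged.
* **Boundary effect-size bands.** Cohen's $d$ bands (no effect < 0.2,
  small < 0.5, medium < 0.8, large otherwise) leave the cutpoints
  themselves unclassified; boundaries are assigned to the larger band.
* **Category boundaries.** Ties follow the quoted closed/open
  intervals exactly: $p_m = 0.65$ is maternally biased, $p_m = 0.35$
  paternally biased.

## The synthetic count generator

`simulate_allele_counts()` emulates the statistical structure the
procedure assumes, with known ground truth:

* A gene's category is drawn from a five-way mixture. Defaults encode
  the study conditions: wild type (0.25, 0.73, 0.02, 0, 0) with 11
  RNA-seq replicates; `mutant_category_mix()` gives
  (0.15, 0.47, 0.30, 0.08, 0) with 17 replicates; CUT&RUN designs use 2
  replicates.
* The true ratio is uniform inside a trimmed sub-interval of its
  category (`default_ratio_bounds()`), e.g. maternal genes draw from
  [0.96, 1]. Trimming keeps truths identifiable at realistic depth;
  the margins (0.01–0.03 from each boundary) were chosen once as the
  smallest offsets a deeply sequenced gene can be resolved across.
* Depth per gene × replicate is negative-binomial (mean 500, size 5 by
  default), matching the heavy-tailed coverage of informative SNPs; no
  per-gene depth distributions are published for the emulated study, so
  these are conventions, not estimates.
* Allele draws are binomial, or beta-binomial with intra-class
  correlation `overdispersion_rho` (the Beta mean equals the true
  ratio and concentration $1/\rho - 1$, so $\rho = 0$ reduces exactly
  to the binomial).
* `simulate_parental_controls()` emits pure-parent samples whose
  maternal fraction is $1 - \text{contamination}$ (symmetrically for
  the paternal control), flagging contaminated genes in ground truth.

What simulations do *not* model: mapping bias between parental genomes,
SNP-density variation along genes, reference bias after N-masking, and
correlated depth across replicates. Passing recovery tests therefore
demonstrates correctness of the statistical machinery under its own
assumptions, not robustness to those upstream artifacts.

## Chromatin enrichment and peak association

Per-gene chromatin-profiling counts are normalized to 1× genome
coverage (`normalize_1x()`: raw × genome size / total aligned bases,
the RPGC convention), with `arcsinh_transform()` as the display
transform (linear near 0, logarithmic for large values). A peak
associates with a gene when their overlap covers at least 50% of the
*peak's* length, boundary inclusive; one peak may associate with
several genes and strand is ignored (`associate_peaks()`, built on
GenomicRanges; BED input is 0-based half-open). The
regulation-vs-peak-overlap contingency test is a Pearson $\chi^2$ with
one degree of freedom and, by default, no Yates correction
(`chisq_overlap_test(correct = FALSE)`), matching the unqualified
$\chi^2$ convention; the correction is a flag.

## Nucleus segmentation

`segment_nucleus()` implements adaptive-threshold segmentation of the
DAPI channel:

1. 20 equally spaced thresholds spanning the 2nd–99.8th intensity
   percentiles (operationalizing "clearly too low" to "clearly too
   high" robustly against hot pixels — both the count and the
   percentile bounds are arguments).
2. For each threshold, the area of the maximum intensity projection of
   the 3D mask; the resulting size curve falls rapidly, crosses a wide
   plateau where only the nucleus survives, and decays in a tail.
3. Plateau detection on the absolute neighbor differences: a
   difference-threshold $d_{thr}$ starts at 1/10 of the mean difference
   and doubles until the longest run of consecutive differences
   $\le d_{thr}$ exceeds 6 (i.e. at least 7); the selected segmentation
   is the middle of that plateau, with even-length runs taking the
   lower-middle index and ties between runs going to the first.
4. 3D thresholding at the selected intensity, hole filling
   (6-connected background components not reaching the volume border),
   binary closing with a radius-1 ball, and retention of the largest
   26-connected component.

Two numerical notes. The doubling schedule is a choice — only the
starting value is prescribed by the method being implemented — and is
exposed via `growth`. And because the differences are absolute, any
monotone curve of at least 8 points eventually qualifies (at
$d_{thr} \ge \max d$ the whole curve is one run), so plateau failure is
only reported for curves too short to host a qualifying run; a
decaying tail of small absolute differences is genuinely treated as a
plateau at low size.

## Foci segmentation

`segment_foci()` clusters the intensities of the voxels inside the
nucleus with 1-D k-means in $k \in \{2,3,4\}$ classes; for
single-valued data the class boundaries (midpoints of adjacent sorted
centers) define $k-1$ thresholds, and the foci mask is the volume
thresholded at the highest one. Components are filtered: only foci
bigger than 20% of the nucleus size are kept.

* **Size convention.** Sizes are measured on maximum-intensity
  projections by default (`size_measure = "projection"`), the same
  convention the nucleus size curve uses. This keeps the method's two
  headline numbers mutually consistent — compartments can cover ~10%
  of the nucleus in volume terms while each passes a 20%-of-nucleus
  size filter — and makes 1–3 disjoint foci with per-focus fractions
  above 0.2 geometrically realizable (three disjoint convex bodies of
  ≥22% of the nucleus *volume* each cannot be packed into an
  ellipsoid). A `"voxels"` measure is available.
* **Deterministic k-means.** A specialized 1-D Lloyd routine is used:
  centers initialize at the $(2i-1)/2k$ intensity quantiles, ties go
  to the lowest-index center, and empty clusters (which arise in
  noise-free synthetic volumes with few distinct intensities) are
  reseeded at the costliest points. No random seed is involved, so
  segmentations are bit-reproducible.
* **Adjustment loop** (`adjust_foci()`). When fewer foci than expected
  are found, the intensity threshold and the size fraction are both
  multiplied by a coefficient (default 0.9, capped at 25 iterations)
  until the target count is reached; when too many or oversized foci
  are found, classification in 4 classes is used, which raises the
  highest threshold and shrinks the foci. The coefficient value and
  cap are package defaults — the emulated method names a coefficient
  without stating it. Failure raises a condition carrying the best
  attempt. The original workflow's manual mask corrections are replaced
  by accepting an externally supplied mask wherever a segmentation
  object is expected.

`overlap_fractions()` reports the intensity-weighted share of channel
signal inside the foci, the binary share of a signal domain's area
inside the foci, the share of foci area inside the signal domain
(missing, not zero, when the foci mask is empty), and the fraction of
the nucleus covered by foci.

## The synthetic image generator

`simulate_nucleus_image()` rasterizes an ellipsoidal nucleus (default
semi-axes 12×24×24 voxels in a 34×64×64 stack) and places 0–3
flattened ellipsoidal foci inside the eroded nucleus by rejection
sampling, stratified along z and pairwise separated by at least two
voxels so each focus stays its own 26-connected component. Channel
intensities (DAPI background/nucleus/focus 20/180/230; antibody
20/60/180) get additive Gaussian noise clipped at zero — the simplest
model with a directly controllable signal-to-noise ratio; the defaults
put the nucleus edge at SNR 16 and foci at SNR 12, and validation
tests run down to SNR 5–8. Geometry limits are honest limits of the
generator: three foci are placeable only for per-focus projected
fractions up to about 0.26, and infeasible requests fail with a
placement error rather than overlapping foci.

Known limitations of the imaging stack: with *no* true focus present,
k-means thresholding still produces a top class, and percolating noise
voxels can pass the size filter — the emulated workflow resolved such
cases by visual inspection, and this package leaves specificity at
zero foci to the caller (e.g. via `adjust_foci()` targets or intensity
priors). Real deconvolved stacks also show anisotropic blur and
intensity gradients that the additive-noise model does not produce.

## Problem sizes and verification

The test suite regenerates everything it checks: exact-test p-values
are compared against exhaustive pmf enumeration for all totals up to
30; plateau detection against an exhaustive search over all
difference-thresholds and runs on 100 random monotone curves; the full
classification pipeline against ground truth on 2,000 simulated genes
× 11 replicates at mean depth 500 (category proportions recovered
within ±3 points, per-gene accuracy ≥ 95%); the wild-type vs mutant
contrast on the two default mixtures (mutant mean $p_m$ lower, Cohen's
$|d| > 0.8$); and segmentation on 20 simulated nuclei (nucleus IoU
≥ 0.9, exact focus counts, per-focus volume within 10%). These sizes
were chosen as the smallest at which the mixture proportions and
segmentation errors stabilize well inside their tolerance bands.
`scripts/acceptance.R` recomputes the same quantities from scratch for
any seed.
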