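---
title: "Quantifying the EMT continuum: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the EMT continuum: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emtspectrum)
```

This vignette documents the statistical model behind `emt_spectrum()`, the
design of the synthetic-data generator used to validate it, and the
numerical and boundary conventions the implementation commits to. It makes
no empirical claims beyond what the package's test suite and
`scripts/acceptance.R` compute.

## The model

The epithelial-to-mesenchymal transition (EMT) is treated as a continuum:
each cancer cell occupies a position between a fully epithelial and a fully
mesenchymal transcriptional program, and most tumour cells sit in hybrid
(partial-EMT) states that co-express parts of both. The quantification
turns a cells × genes count matrix and a two-arm gene signature
(epithelial arm $E$, mesenchymal arm $M$) into phenotype calls:

1. **Quality control.** A cell is kept if its number of detected genes
   (genes with at least one count) lies in $[200, 5000]$, both bounds
   inclusive, and its mitochondrial count fraction is at most $0.10$;
   cells strictly above 10% mitochondrial content are removed.
   Mitochondrial genes are identified by name prefix (`"MT-"` by default).
2. **Normalization and scaling.** Counts are depth-normalized to a common
   target sum per cell ($10^4$), `log1p`-transformed, and each gene is
   z-scored across cells. Genes with zero variance scale to all-zero
   columns rather than `NaN`. (This depth/log/z pipeline stands in for
   variance-stabilizing normalizations such as regularized NB regression;
   it preserves the property the score needs — a per-gene reference point
   at the population mean.)
3. **Cancer-cell selection** (optional, `select_cancer_cells()`). Cells
   are kept if their mean scaled expression over supplied epithelial
   markers exceeds a threshold, or if a lineage-tracing label (e.g. a YFP
   reporter) marks them — OR semantics, so lineage-traced mesenchymal
   cells that have shut down epithelial markers are not lost. The default
   of `emt_spectrum()` is `select = "none"` because its intended input is
   an already-enriched cancer population; marker-based selection applied
   to a pure cancer population would systematically discard mesenchymal
   cells.
4. **Diffusion smoothing.** Dropout makes per-cell signature expression
   sparse and noisy. A MAGIC-style Markov operator is built on the
   signature submatrix of the scaled data: Euclidean kNN with $k = 15$,
   adaptive kernel $a_{ij} = \exp\!\left(-(d_{ij}/\sigma_i)^{\alpha}\right)$
   with $\alpha = 2$ and $\sigma_i$ the distance to cell $i$'s $k$-th
   neighbour, $a_{ii} = 1$, symmetrization $(A + A^\top)/2$,
   row-normalization to a transition matrix $P$, and smoothing
   $X_s = P^t X$ with diffusion time $t = 3$. Small $t$ shares
   information along the phenotypic manifold without collapsing it toward
   the global mean (the $t \to \infty$ limit is the stationary average,
   an identity the test suite checks against an eigen-decomposition
   oracle).
5. **Clustering.** A shared-nearest-neighbour graph ($k = 20$,
   neighbourhoods include the cell itself, Jaccard edge weights, edges
   below $1/15$ pruned) is partitioned by Louvain modularity. The
   resolution is chosen from a grid ($0.25, 0.5, 1, 2$) as the smallest
   resolution whose partition reaches a within-cluster expression
   consistency of 0.9 (pooled mean pairwise Pearson correlation of cells
   within a cluster); if none reaches it, the maximum-consistency
   resolution is used. Preferring the smallest adequate resolution avoids
   shattering a continuum into micro-clusters.
6. **Scoring.** For a set of cells $C$ and a signature arm $G$, the
   positive fraction is the proportion of entries of the smoothed scaled
   matrix over $C \times G$ that are strictly greater than zero — i.e.
   above the gene's population mean. With $\mathrm{EPI}$ and
   $\mathrm{MES}$ the positive fractions of the two arms and a pseudocount
   $\epsilon = 10^{-6}$,
   $$\mathrm{score} = \log_2\frac{\mathrm{EPI} + \epsilon}{\mathrm{MES} + \epsilon}.$$
   A cluster is **Epithelial** if score $\ge 1.5$, **Mesenchymal** if
   score $\le -1.5$, **Partial-EMT** strictly in between; both boundaries
   are inclusive toward the extreme classes. Clusters are relabelled in
   decreasing score order, phenotype proportions are cell-weighted
   percentages, and whole samples are classified by pooling their cells
   and scoring the pool with the same cutoffs (or, optionally, by
   per-cell plurality).

### Assumptions

- The signature's two arms discriminate the programs in the tissue at
  hand; genes absent from the matrix are dropped (reported as the
  discovered count), but both arms must remain non-empty.
- Z-scoring is done on the analysed population, so "positive" means
  above *this population's* mean — scores are comparable within a fit,
  not across independently scaled datasets.
- Diffusion assumes phenotypic neighbours in signature space are
  biological neighbours; heavy batch structure violates this and should
  be handled upstream.

## Companion tissue-level measures

**Weighted pathology score.** A specimen composition (percentages over
normal, PanIN, well/moderately/poorly differentiated PDAC, necrosis; sum
at most 100) is scored by summing fixed weights for categories whose
percentage *strictly* exceeds a threshold: normal > 5% → 1, PanIN > 30%
→ 2, well+moderate PDAC > 30% → 4, poor PDAC > 5% → 5, necrosis > 5%
→ 6; maximum 18. An all-PanIN specimen scores 2. The strict inequalities
mean a category sitting exactly at its threshold does not contribute.

**Spatial statistics.** For marked points in a rectangular window $W$,
the bivariate Ripley function is estimated as
$$\hat K(r) = \frac{|W|}{n_1 n_2} \sum_{i \in \text{from}} \sum_{j \in \text{to}} w_{ij}\, \mathbf 1[d_{ij} \le r],$$
with either no edge correction or the translation correction
$w_{ij} = |W| / \big((a - |\Delta x|)(b - |\Delta y|)\big)$. The
variance-stabilized $L(r) = \sqrt{\hat K(r)/\pi}$ equals $r$ under
complete spatial randomness (CSR); infiltration is summarized by the
trapezoidal area under $L$ on a uniform grid of 40 radii in
$(0, 20\,\mu m]$, the contact scale. Radii are capped at half the
shorter window side. The default edge correction is `"none"`: at the
problem sizes used in the tests (50–100 points per mark in a
$1000 \times 1000\,\mu m$ window, $r \le 20\,\mu m$) the boundary bias
is negligible relative to Monte-Carlo noise; `"translation"` is
available and brute-force verified. The test suite certifies CSR
calibration of $\hat K(r)$ against $\pi r^2$ for both corrections; note
that mean $L(r)$ itself sits below $r$ at radii where $\hat K$ is mostly
zero, because the square root is concave (Jensen's inequality), so
calibration claims are made on the $K$ scale.

## The synthetic-data generator

`simulate_emt_population()` exists so that the full pipeline can be
validated against known ground truth. Each cell draws a latent EMT
coordinate $u \in [0, 1]$ from one of three bands — epithelial
$U(0, 0.25)$, partial $U(0.35, 0.65)$, mesenchymal $U(0.75, 1)$ — with
mixture weights $(0.4, 0.35, 0.25)$ by default. Gene expression weights
follow logistic profiles in $u$ between a low of $0.2$ and a high of
$1.8$ with slope $0.04$. Crossing points are placed in two waves per arm:
half of the epithelial genes switch off in $U(0.26, 0.34)$ and half in
$U(0.66, 0.74)$ (mesenchymal genes mirror this, switching on). The gaps
between the latent bands therefore contain all crossings, and each band
sits on a flat plateau of the expected E/M score: epithelial cells
express (nearly) all epithelial and no mesenchymal genes, partial cells
express the "early" half of *both* programs — the hybrid co-expression
that defines partial EMT — and mesenchymal cells the reverse of
epithelial. On unsmoothed scaled data the expected positive fractions on
each plateau put the scores near $+3$, $0$ and $-3$, well clear of the
$\pm 1.5$ boundaries (diffusion smoothing sharpens the sign patterns and
pushes the extreme clusters further out, to the pseudocount bound when
one arm's positive fraction reaches zero), so recovery failures indicate
pipeline defects rather than borderline truth.

Counts are negative-binomial (dispersion `size = 2`) around
$\mu_{cg} \propto$ weight, scaled to a per-cell depth drawn lognormally
(median 2000, `sdlog = 0.3`), with independent Bernoulli dropout
(rate 0.3) and a mitochondrial block (`"MT-"` genes, 5% of depth) so QC
has something to act on. Defaults: 3000 cells, 60 + 60 signature genes,
400 background genes (enough that the 200-detected-gene QC floor is
attainable under dropout), 10 mitochondrial genes.

What the generator does **not** emulate: batch effects, ambient RNA,
doublets, cell-cycle structure, gene–gene correlation beyond the shared
latent coordinate, UMI saturation, or any non-EMT cell types (hence
`select = "none"` by default). It is a validation instrument, not a
tissue simulator.

`simulate_histology()` produces composition tables (including an
`"all-panin"` template) and `simulate_point_pattern()` produces marked
point patterns under CSR, attraction (T cells placed near cancer cells
with displacement scale 20 μm) or exclusion (rejection sampling away
from cancer cells), used to verify the ordering
attraction > CSR > exclusion of the L-curve AUC.

## Numerical choices and conventions

- **Positivity is strict** (`> 0`): a cell exactly at a gene's mean does
  not count as expressing it.
- **Classification boundaries are inclusive** toward EPI and MES;
  `classify_em_score()` is the single authority, used by cluster, cell
  and sample classification alike.
- **Pseudocount $10^{-6}$** bounds the score at roughly $\pm 19.9$ when
  one arm's positive fraction is exactly zero, instead of $\pm\infty$.
- **QC boundaries are inclusive** at 200 and 5000 detected genes and at
  10% mitochondrial content (removal strictly above).
- **Pathology thresholds are strict** (`>`), matching the score's
  worked examples (all-PanIN = 2).
- **Determinism.** `emt_spectrum()` sorts cells by id before any
  computation, so results are invariant under permutation of input rows;
  Louvain runs under the supplied seed; kNN ties break by index. Pipeline
  reruns with the same config are bit-identical, which the test suite
  checks.
- **Problem sizes used in validation** (computed by the tests, not
  asserted from literature): ground-truth recovery on 3000-cell
  populations over five seeds (phenotype percentages within 5 points,
  per-cell accuracy ≥ 95%); diffusion identities on ≤ 100 cells against
  dense brute-force and eigen-decomposition oracles; CSR calibration of
  $L(r) - r$ over 100 simulations within 3 Monte-Carlo standard errors;
  K-function equality with a double-loop oracle at $10^{-10}$.

## Limitations

- The score compares positive *fractions*, not magnitudes; two clusters
  with different expression strength but equal sign patterns score
  identically.
- Resolution selection optimizes within-cluster consistency, not
  phenotype purity; on data without cluster structure the continuum is
  still partitioned.
- The pooled sample rule can call a genuinely mixed sample Partial-EMT;
  the plurality rule is provided as a sensitivity check.
- Edge correction `"none"` is appropriate only when the contact radius is
  small relative to the window; use `"translation"` otherwise.
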