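# emtspectrum

Pancreatic-cancer cells do not sit at two poles of the
epithelial-to-mesenchymal transition (EMT); they occupy a continuum of
states, with most cells in hybrid, partial-EMT configurations that
co-express parts of both programs. `emtspectrum` quantifies that continuum
from single-cell RNA-seq counts and bundles the two companion tissue-level
measures used alongside it: a weighted histopathology score for specimen
composition tables, and bivariate Ripley K/L-function statistics for T-cell
infiltration around cancer cells in multiplexed-imaging coordinates.

The package is aimed at computational biologists analysing tumour scRNA-seq
(human or mouse) who want a transparent, testable implementation of
signature-based EMT staging, and at methodologists who need a synthetic
single-cell benchmark with known EMT ground truth.

## The method

Given a cells × genes count matrix and an EMT gene signature with an
epithelial arm *E* and a mesenchymal arm *M*:

1. **QC** — keep cells with 200 ≤ detected genes ≤ 5000 and a
   mitochondrial count fraction ≤ 10% (cells strictly above 10% are
   removed).
2. **Normalize and scale** — per-cell depth normalization, `log1p`, then
   per-gene z-scoring ("scaled data").
3. **Select cancer cells** — by mean scaled epithelial-marker expression
   and/or a lineage-tracing (e.g. YFP) flag; skipped for pre-enriched
   input.
4. **Diffusion smoothing** — a MAGIC-style Markov operator built on the
   signature expression: adaptive kNN kernel
   `exp(-(d/σᵢ)^α)` (σᵢ = distance to the k-th neighbour), symmetrized,
   row-normalized, and raised to diffusion time *t* (defaults k = 15,
   α = 2, t = 3).
5. **Cluster** — shared-nearest-neighbour graph, Louvain modularity at a
   resolution chosen from a grid by within-cluster expression consistency.
6. **Score** — per cluster, the positive fractions
   EPI = P(scaled value > 0) over the epithelial arm and MES over the
   mesenchymal arm give the E/M score

   ```
   score = Log2(EPI / MES)
   ```

   classified as **Epithelial ≥ 1.5**, **Mesenchymal ≤ −1.5**, and
   **Partial-EMT** strictly in between. Clusters are relabelled in
   decreasing score order (1 = most epithelial), and cell-weighted
   phenotype percentages and per-sample classifications are reported.

The weighted pathology score sums fixed weights for histology categories
whose percentage strictly exceeds a threshold: normal > 5% → 1,
PanIN > 30% → 2, well+moderately differentiated PDAC > 30% → 4,
poorly differentiated PDAC > 5% → 5, necrosis > 5% → 6 (maximum 18).

The spatial module estimates the bivariate
`K(r) = |W|/(n₁n₂) · Σᵢⱼ wᵢⱼ 1[dᵢⱼ ≤ r]`, its variance-stabilized
`L(r) = √(K/π)` (equal to r under complete spatial randomness), the
trapezoidal AUC of L up to a contact radius (20 μm by default), and
per-cell neighbour counts within that radius.

A synthetic-data module generates negative-binomial counts with dropout
along a latent EMT axis (with partial-EMT cells co-expressing half of each
arm), histology tables, and marked point patterns with tunable
attraction/exclusion — so the whole pipeline is testable end to end with
known ground truth.

## Worked example

```r
library(emtspectrum)

pop <- simulate_emt_population(n_cells = 800, seed = 1)
fit <- emt_spectrum(pop$counts, pop$signature, seed = 1)
fit
#> emt_spectrum fit: 793 cells, 3 clusters (resolution 0.25)
#> phenotypes: EPI 39.8%, PEMT 35.4%, MES 24.7%
coef(fit)
#>           1           2           3 
#>  13.1924877  -0.1557355 -19.9309565
```

The generating mixture was 40% epithelial / 35% partial / 25% mesenchymal
(39.7 / 35.6 / 24.7 among the 793 cells passing QC); the fit recovers
three clusters — strongly positive (epithelial: essentially all
epithelial-arm entries positive after smoothing), near zero (partial:
balanced co-expression of both arms) and strongly negative (mesenchymal;
−19.93 is the pseudocount-bounded score when the epithelial positive
fraction is exactly zero) — with phenotype percentages within 0.2 points
of the truth. `summary(fit)` prints the full cluster table and per-sample
calls; `plot(fit)` draws the score spectrum with the ±1.5 boundaries.

Histology and spatial statistics:

```r
weighted_pathology_score(c(normal = 10, panin = 40, pdac_well = 20,
                           pdac_moderate = 20, pdac_poor = 6, necrosis = 4))
#> [1] 12
l_auc(simulate_point_pattern(50, 50, interaction = "attraction", seed = 1))$auc
#> [1] 506.4074
```

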