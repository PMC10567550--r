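---
title: "Models and methods: trajectory reversal, regulons, tissue stiffness and actin networks"
author: "epiRewind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

After a skin wound, terminally differentiated epidermal cells of the
Gata6 lineage (sebaceous duct and upper hair follicle) can re-enter the
stem-cell compartment. The central quantitative question is whether this
dedifferentiation is the forward differentiation program run backwards,
or a distinct wound-specific path. epiRewind implements the computational
machinery needed to answer it on lineage-resolved single-cell RNA-seq
data, together with the biophysical read-outs (AFM stiffness maps, actin
network metrics) that characterize the altered niche — all exercisable on
synthetic data with planted ground truth.

# The reversal statistic

Two populations are gated on a stem-cell marker (default `Lrig1`, in
log-normalized units, strict inequalities):

* **differentiating**: lineage-negative cells from unwounded skin
  (timepoint 0) with marker expression `< 1` — cells that have left the
  stem state and are moving towards the differentiated fate;
* **dedifferentiating**: lineage-positive cells from wounds
  (timepoint > 0) with marker expression `> 1` — formerly differentiated
  cells that have re-acquired the stem marker.

Genes are restricted to the most variable quarter of the transcriptome
(the same proportion a 5,000-gene cut represents on a full mouse
transcriptome), tested for differential expression between the
populations with a two-sided Wilcoxon rank-sum test and
Benjamini–Hochberg adjustment, and the per-gene median log-normalized
expression is computed in each population. The headline statistic is the
Pearson correlation `R` of these median pairs (Spearman is reported
alongside; the two are close on this data). A loess curve (tricube local
linear, span 0.75) is fitted through the scatter for display; `R` is
computed on the raw medians, not the fitted values. A strongly negative
`R` means genes high in forward differentiation are low in
dedifferentiation and vice versa — the signature of trajectory reversal.
Significance comes from a permutation null: population labels are
reshuffled over the pooled cells and the entire statistic (HVG selection,
DE, medians, correlation) is recomputed, giving
`p = (1 + #{|R_perm| >= |R_obs|}) / (n_perm + 1)`.

Retention of DE genes defaults to adjusted p < 0.05 with the
min.pct ≥ 0.25 and |log fold change| ≥ 0.25 gates; setting the adjusted-p
threshold to 1 disables significance filtering (used for permutation
calibration, where the permuted populations carry no signal).

# The single-cell core

The pre-processing stages mirror a standard Seurat-style workflow:

| stage | method | defaults |
|---|---|---|
| cell filter | detected genes (count > 0) ≥ threshold | 200 (strict "fewer than" removal) |
| normalization | size factor = total / median(total); `log1p(count / sf)` | natural log |
| batch correction | parametric empirical-Bayes location/scale (ComBat algorithm) | per-gene grand mean restored exactly |
| HVG | dispersion (var/mean) z-scored within 20 mean bins | top 5,000 |
| PCA | genes centred and unit-scaled; optional per-gene covariate regression | 15 PCs |
| clustering | KNN graph + Louvain modularity | k = 20, resolution 0.5 |
| DE | rank-sum, exact enumeration when both groups ≤ 10 cells; tie-corrected normal approximation with continuity correction otherwise | min.pct 0.25, |lfc| 0.25, BH |

Numerical notes:

* The batch-correction shrinkage follows the standard fixed-point
  iteration for the normal/inverse-gamma empirical-Bayes model. A final
  re-centring step restores each gene's grand mean exactly; canonical
  ComBat preserves it only approximately, and downstream stages here
  assume it.
* The resolution parameter is on igraph's modularity scale. Macro
  structure on small toy data resolves around 0.2–0.3; the pipeline
  default of 0.5 matches the convention for epidermal cell-state
  granularity on real-scale data.
* Signature scores use the bin-matched control scheme (mean expression
  of the gene set minus mean of expression-matched controls, 25 bins,
  100 controls per gene). This replaces reference-atlas anchor transfer,
  which needs an external atlas; it plays the same role of a per-cell
  gene-set score.

# Trajectory, pseudotime kernel, trends and modules

Pseudotemporal ordering is run on lineage-positive cells, in a
low-dimensional trajectory space (the top 5 PCs of the 15-PC embedding).
The backbone is a deliberately simple principal graph: seeded k-means
centroids (12 by default) joined by a Euclidean minimum spanning tree.
Fitting the tree in the full 15-dimensional space makes centroid-centroid
distances noise-dominated at Smart-seq2 cell numbers and can scramble the
backbone, which is why the trajectory space is reduced; five components
retain the differentiation axis with headroom for branch structure.

Pseudotime is the tree geodesic from the root node plus a local
projection of each cell onto its node's incident edges, min–max scaled to
[0, 1]. The root is the node with the highest mean differentiated-state
score (by default `Gata6 − Lrig1` expression), i.e. the trajectory is
rooted in the differentiated state so dedifferentiation runs forward,
matching rooting at the control cluster in practice. An explicit root
node can be supplied instead.

The directed transition matrix follows the pseudotime-kernel idea:
Gaussian similarities on a KNN graph (k = 15), with edges running
backward in pseudotime damped by `exp(-max(0, t_i - t_j) / sigma)` and
rows normalized. The damping is soft — no edge is removed, so the chain
stays connected. `sigma` defaults to one fifth of the median absolute
neighbour pseudotime step: a typical backward step is damped by about
`e^-5`, while steps below the pseudotime resolution stay essentially
undamped. Defining `sigma` as the raw neighbourhood spread instead leaves
typical backward steps damped by only ~`e^-1`, which removes the
directional character the kernel exists to provide.

Gene trends are per-gene loess fits (degree 1, span 0.3) on a fixed
100-point pseudotime grid; modules are Louvain communities of a gene–gene
KNN graph built on z-scored trend vectors. Three archetypes — monotone
up, monotone down, transient — are what the module stage must separate,
and the synthetic generator plants exactly those shapes.

# Regulon enrichment

TF→target edges are read in the TRRUST 4-column dialect. Per module and
TF, enrichment is the hypergeometric upper tail of the module/regulon
overlap against the background of trend-fitted genes, BH-adjusted across
TFs. The published analysis style pairs a lenient q cutoff (q < 0.5) with
a second, tool-specific score threshold (> 0.9) whose definition is not
public; epiRewind implements that second filter as the normalized rank of
the Haldane-corrected odds ratio, clearly non-canonical and fully
configurable. Enrichment is monotone: adding a true target of a TF to a
module never increases that TF's p-value.

# AFM: force curves to stiffness maps

Internally everything is SI (m, N, Pa); reporting is in kPa. A force
curve is piezo position `z` and calibrated deflection `d`; force is
`F = k d` (spring constant 0.25 N/m by default) and indentation is
`delta = (z - z0) - d`, the standard correction for cantilever bending.
The spherical contact model

`F = 4 E sqrt(R) delta^(3/2) / (3 (1 - nu^2))`

with `nu = 0.5` (incompressible tissue) and `R = 2.5 um` (a 5-um sphere)
linearizes to a straight line of `F` against `delta^(3/2)` through the
origin; the least-squares slope `m` gives
`E = 3 m (1 - nu^2) / (4 sqrt(R))`. Only points with force between 20%
and 80% of the curve maximum (inclusive) enter the fit, which suppresses
both contact-region ambiguity and deep-indentation substrate effects.

The contact point is a free parameter: a coarse scan over sample
positions plus golden-section refinement minimizes the residual sum of
squares of the linearized fit, with the baseline offset recomputed for
each candidate as the median force of that candidate's pre-contact
segment. (Estimating the baseline once from a fixed low-force quantile
instead selects the most-negative-noise samples and biases the contact
point systematically early — about 4 sample spacings at SNR 20, versus
about 0.5 with the per-candidate baseline.) A curve whose best fit does
not improve on the flat baseline-only model by at least 10% in RSS is
flagged "no contact".

QC mirrors practice: fits are rejected for r² < 0.9, a no-contact flag,
or modulus above a cap (default 1 MPa — substrate artefacts read as
unphysically stiff tissue). Accepted fits assemble into a gridded map
(default 24 × 24 over 40 × 40 um) with a mask for excluded positions such
as hair shafts; regions are compared with a two-tailed Mann–Whitney test,
exact for samples of at most 8.

The generator solves the implicit cantilever/contact balance
`k d = F_hertz((z - z0) - d)` by Newton iteration to machine precision,
so the generator→fitter round trip recovers the planted modulus to
relative error below 1e-6 and any residual error in applications is
attributable to noise, not the solver.

# Actin network metrics

Masks are binary images (nonzero = foreground). Total length first thins
the mask to a one-pixel skeleton (Zhang–Suen thinning, implemented here
because no installed package provides 2-D skeletonization) and then sums
adjacency steps: orthogonal = 1 px, diagonal = sqrt(2) px, skipping a
diagonal step when its two pixels already share an orthogonal skeleton
neighbour — this removes the corner double-count and makes a straight
101-pixel line exactly 100 um at 1 um/px. Gliding-box lacunarity slides
an r × r window at stride 1 and reports
`Lambda(r) = var(mass) / mean(mass)^2 + 1` with population variance, the
standard gliding-box definition: 1 for homogeneous patterns, larger for
gappier ones. Box sizes default to {2, 4, 8, 16} capped by the image; the
published macro's internal box choice is not documented, so absolute
lacunarity values are reported in arbitrary units and only contrasts are
meaningful.

# The synthetic generator: what it emulates, and what it does not

The generator reproduces the study design: 684 cells across four
timepoints (days 0, 6, 9, 11), two batches per timepoint, lineage-positive
and lineage-negative cells, with a 2,000-gene reduced transcriptome (a
deliberate simulation-scale choice; the architecture, not the gene count,
carries the signal). Each cell has a latent differentiation coordinate
`z` in [0, 1] (0 = Lrig1-like stem state, 1 = Gata6-like differentiated
state):

* unwounded lineage-positive cells are differentiated,
  `z = 0.8 + 0.2 Beta(2, 2)`;
* lineage-negative cells are a basal/suprabasal mixture: 65% basal
  stem-like `Beta(2, 8)` plus 35% suprabasal differentiating
  `0.5 + 0.5 Beta(2, 2)` — the Lrig1-low differentiating gate selects
  this suprabasal tail, at a gate yield (~15–20 of 60 unwounded
  lineage-negative cells) matching the scale observed in practice;
* wounded lineage-positive cells start from the unwounded distribution
  and are displaced towards the stem state by
  `reversal_strength × max(0, t - 5) × Beta(4, 2)` with
  `reversal_strength = 0.25`/day: dedifferentiation has a ~5-day onset
  latency, so day 6 resembles day 0 while days 9 and 11 are strongly
  reversed. With `reversal_strength = 0` every wounded cell keeps
  `z ≥ 0.8`.

Counts are negative binomial with a shared inverse-dispersion (size 2,
Smart-seq2-like overdispersion), log-mean
`baseline + effect × f(z) + batch shift`, and a lognormal(0, 0.3)
per-cell library factor. Five compartment programs (uHF, SD, IFE, OB,
SG; 25–40 genes each, ~3 natural-log units — epidermal compartment
markers are near-binary) carry the three trend archetypes; 30
wound-response genes are induced in wounded skin in proportion to
`(1 - z)`, the way activation keratins rise as cells lose their
differentiated identity — by design wounding adds no axis of variation
orthogonal to the differentiation coordinate. The gate markers `Lrig1`
(down) and `Gata6` (up) are on/off (7 log units) with baselines
calibrated so the log-normalized gate threshold of 1 crosses the latent
axis at z = 0.6 and 0.4 respectively; this keeps basal cells firmly
inside the Lrig1-high gate despite count noise. The Itga6 sort gate is
annotated from the latent state with a 4% flip rate, emulating sorting
purity.

What the generator does **not** emulate: doublets and ambient RNA,
gene–gene correlation beyond the planted programs, read-level phenomena
(the counts are drawn, not aligned), realistic library-size heterogeneity
across plates, or biological heterogeneity within compartments. Passing
recovery tests on this data therefore demonstrates that the pipeline's
inference machinery is correct and calibrated under the planted model —
not that it would be robust to every artefact of real Smart-seq2 data.

All randomness flows through explicit integer seeds; one global seed
deterministically spawns per-stage seeds, so a full pipeline run is
byte-identical under a fixed configuration.

# Problem sizes and runtime choices

Default analyses use the full 684-cell, 2,000-gene cohort; the
permutation test uses 99 permutations; null-calibration experiments in
the test-suite use 19 permutations per replicate across 50 replicates
(the mean of a uniform p-value is insensitive to the permutation count);
trend fitting covers the top 300 variable genes; the stiffness map is the
full 24 × 24 grid with 200–400 samples per curve. These sizes keep a
complete synthetic run under a minute on a laptop-class machine while
leaving every statistical property testable.

# Known limitations

* The principal graph is a tree over k-means centroids: adequate for the
  single dominant trajectory here, not for cyclic or disconnected
  topologies.
* The reversal `R` depends on the gate marker's dynamic range; markers
  with shallow dynamic range blur the populations and attenuate `R`
  towards zero (the direction of the bias is conservative).
* The second regulon filter is a documented stand-in for an unpublished
  score, and absolute stiffness values depend on the instrument's own
  contact-point conventions — both are flagged configurable rather than
  canonical.
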