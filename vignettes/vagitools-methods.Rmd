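---
title: "Methods and design of the vagitools pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the vagitools pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagitools)
```

# Scope

`vagitools` chains the statistical machinery used in population-scale
vaginal-microbiome studies: feature-table filtering and rarefaction,
alpha/beta diversity with permutation tests, covariate-adjusted per-taxon
association, SparCC correlation networks, NMF-based community typing
("Vagitypes") with Yue–Clayton θ classification, counterfactual mediation,
and Firth-penalized outcome models. Everything runs on plain count tables
plus typed metadata; a seeded synthetic-cohort generator supplies data with
known ground truth for verification. Upstream read processing (denoising,
contaminant removal, batch correction, taxonomy assignment, tree building)
is out of scope: the package starts from an annotated count table.

# The synthetic cohort generator

The generator emulates the statistical structure that the downstream stages
assume, not raw sequencing:

* **Community types.** Each sample draws a type from a categorical law
  (default five types: *L. crispatus*-, *L. iners*-, *G. vaginalis*- and
  *U. parvum*-dominated plus a diverse anaerobe-rich type), then a
  composition from that type's Dirichlet concentration profile, then
  multinomial counts at a read depth drawn from a lognormal truncated to
  [48,000, 100,000] with median ≈ 79,000 — matching the depth range of
  modern amplicon runs without modeling run chemistry.
* **Core species.** The four core species carry a moderate baseline
  concentration in every profile, so they are near-ubiquitous (> 90%
  prevalence) while most panel taxa stay sporadic. One commensal
  (*M. hominis*, the mediation target) keeps a larger baseline so its log
  abundance is informative in every sample; it is therefore a fifth
  ubiquitous taxon in the default cohort.
* **Planted age–diversity effect.** Older age flattens the Dirichlet
  profile through a concentration exponent (`alpha^tilt`,
  `tilt = exp(-0.35 * age_shannon * z_age)`). A flatter profile raises
  Shannon diversity monotonically while preserving sparsity — unlike mixing
  with a uniform floor, which would make every taxon ubiquitous and destroy
  the core/non-core contrast.
* **Planted mediation chain.** Parity is an integer mediator
  (`round(2 + a·z_age + e)`, unit noise, clipped at zero) and the target
  taxon's log₂ relative abundance is shifted by exactly
  `b·(parity − mean) + c′·z_age`; the remaining taxa are rescaled so the
  composition stays normalized. Applying the effect exactly on the log₂
  relative-abundance scale (rather than multiplying and renormalizing)
  avoids an attenuation of roughly the taxon's abundance share, which would
  otherwise bias mediation recovery. Coefficients are on the z-scale of
  age, so analyses standardize age before mediation.
* **Nugent score.** A monotone function of *Lactobacillus* depletion,
  `round(10·(1 − lacto)) ± 1` discrete noise clipped to 0–10, with the
  standard classes normal (0–3), intermediate (4–6), BV (7–10). This
  reproduces the diversity↔Nugent association without a cytology model.
* **Outcomes.** Live birth follows a Bernoulli logit model on community
  type, standardized age and BMI, and embryos transferred. Clinical
  pregnancy is forced to 1 whenever live birth occurred and is drawn from
  its own logit model otherwise; this enforces the nesting of the two
  outcomes while keeping the marginal live-birth rate exactly equal to its
  linear predictor (a zero linear predictor gives a 50% rate).
* **Seeding.** All randomness flows from one root seed through
  `split_seed(seed, stage)` (a deterministic stage-name hash), so any stage
  can be reproduced in isolation and identical specs yield byte-identical
  outputs.

What the generator does **not** emulate: batch effects, contamination,
taxonomic misassignment, overdispersion beyond the Dirichlet, longitudinal
dynamics, or realistic phylogenetic signal (the tree is random). Passing
tests demonstrate correctness of the statistical machinery on data obeying
the stated model, not robustness to those artifacts.

# Numerical and statistical choices

**Filtering and rarefaction.** The count-sum (≥ 50) and prevalence (≥ 1%)
filters are evaluated simultaneously on the original table; whether one
should precede the other is ambiguous in common practice, and the
simultaneous rule is order-free. Rarefaction subsamples without
replacement; samples below the target depth are dropped and reported.

**Alpha diversity.** Shannon uses natural log; Simpson is the Gini–Simpson
complement 1 − Σp². Chao1 uses the classic S + F₁²/(2F₂), switching to the
bias-corrected S + F₁(F₁−1)/(2(F₂+1)) when no doubletons exist (the guard
avoids division by zero and is standard). This is why Chao1 is computed
directly rather than through `vegan::estimateR`, which always applies the
bias-corrected form.

**Beta diversity and tests.** Bray–Curtis is computed on counts, Jaccard on
presence/absence; UniFrac (via phyloseq) midpoint-roots unrooted trees for
determinism and uses the normalized weighted variant. PERMANOVA, ANOSIM,
MRPP and db-RDA delegate to vegan with raw-data permutation (vegan's
default) and p = (exceedances + 1)/(permutations + 1). db-RDA operates on
PCoA axes without negative-eigenvalue correction. FDR is adjusted within
each (method, metric) family across variables, mirroring per-analysis
adjustment; the variable screen requires FDR < 0.1 in at least three of
four methods (each supported by at least three metrics) and ADONIS
R² > 0.001. Whether beta tests should use rarefied or unrarefied counts is
left to the caller; the pipeline default is the rarefied table.

**Per-taxon association.** The response is log₂(relative abundance +
pseudocount) with a per-taxon pseudocount of half the minimum nonzero
relative abundance — a standard choice that keeps zeros finite without a
global constant. Default gates (prevalence ≥ 10%, mean relative abundance
≥ 1e-4) are configurable; nominal variables contrast against their declared
or most frequent level; ties in the top-taxa ranking break
lexicographically. The "key taxa" panel is the union of taxa with at least
one FDR-significant association across screened variables.

**SparCC.** Basis correlations are estimated from the log-ratio variance
matrix t_ij = var(log x_i/x_j) under a uniform (add-one) Dirichlet
resampling prior, solving the (D−2)·I + J linear system for basis
variances and excluding the strongest pair above |ρ| = 0.1 for up to ten
rounds; the element-wise median over 50 resampling draws is reported,
clipped to [−1, 1]. Non-positive basis-variance solutions are floored at a
tiny positive value. P-values permute each taxon's counts independently;
null fits use fewer inner draws (default 10) since the null statistic needs
less smoothing than the point estimate. At least four taxa are required —
the basis-variance system is unidentifiable below that.

**Networks.** Edge filters are strict inequalities (P < 0.01, |ρ| > 0.1).
Modularity and centralities are computed on the unweighted, sign-agnostic
filtered graph, as module maps drawn over all retained edges (including
negative ones) do. Closeness on disconnected graphs is computed within
components with component-size normalization so values stay finite and
comparable. Zi uses unweighted within-module degree (z-scored within each
module, 0 where the module's spread is zero); Pi = 1 − Σₛ(k_is/k_i)²; roles
use the 2.5/0.62 thresholds.

**NMF and rank selection.** Frobenius multiplicative updates from random
non-negative starts (best of 30 restarts by default; convergence at
relative objective change < 1e-6 or 2000 iterations). Dominant-type
assignment weights coefficient columns by the L1 mass of the corresponding
basis rows, removing the W/H scale ambiguity. Rank selection builds a
consensus matrix over restarts per k and takes the largest k before the
first cophenetic drop exceeding 0.05. When no drop exceeds the threshold —
which genuinely happens when well-separated types admit stable nested
coarsenings (merging two *Lactobacillus* types is as reproducible as
keeping them apart) — stability carries no information and the choice
falls back to the rank with the largest relative reconstruction-error
improvement over its predecessor, i.e. the last rank adding a dominant
structural component. Consensus runs use a lighter iteration cap (300)
since they need stable labels, not machine-precision convergence. The
pipeline exposes a forced-k override for reproducing a fixed number of
types.

**Vagitypes and θ.** Centroids are per-type means of key-taxon relative
abundances taken from the raw (not panel-renormalized) relative abundances;
samples are assigned to the centroid with the highest Yue–Clayton θ, exact
ties breaking by centroid order with a flag. Samples with zero mass on the
panel are "unclassifiable". Fine subtype splits are out of scope; model
serialization persists k, panel, centroids, markers and labels (not the NMF
factors), which suffices for external-cohort assignment.

**Mediation.** The counterfactual contrast is mean ± 1 sd for a continuous
treatment (0/1 for binary), averaged over arms and divided by the contrast
width so effects are per treatment unit; for linear–linear fits the ACME
then equals the product of coefficients exactly and ACME + ADE = total
effect holds as an identity. The mediator precedes the treatment in the
outcome design so a degenerate noiseless chain (mediator collinear with
treatment) resolves to full mediation rather than an aliased NA. Inference
is a nonparametric row-resampling bootstrap (percentile intervals,
two-sided p = 2·min(frac ≤ 0, frac ≥ 0)); binary mediators use logistic
models with a Firth-penalized refit under separation. The sensitivity
analysis recomputes ACME(ρ) under correlated mediator/outcome errors and
reports the grid-interpolated ρ where the ACME crosses zero (for the linear
case this crossing equals the residual correlation of the two
reduced-form regressions); if no crossing occurs on the grid, the boundary
is reported with a flag. "Sensitivity ρ > 0" is read as a positive
crossing point; the alternative "robustness direction" reading is noted as
ambiguous.

**Firth outcome models.** Newton iterations on the Jeffreys-penalized score
with step-halving guarantee a monotone penalized likelihood and finite
estimates under complete separation (the intercept-only fit reproduces the
(y + ½)/(n + 1) closed form). Confidence intervals and p-values come from
the profile penalized likelihood (bisection against the χ²(1) quantile; LR
test against zero), not Wald, so intervals remain sensible near
separation. The reference type is always named by the caller — no
automatic selection.

# Problem sizes

The test suite runs entirely on synthetic data sized for quick, stable
verification: cohorts of 50–500 samples over a 30-taxon panel; SparCC
recovery at n = 500 with 50 taxa; rank selection over 20 replicate
120-sample cohorts; calibration checks over 400 simulated null datasets
(permutation type-I error at 199 permutations; profile-CI coverage at
n = 50) and 20 bootstrap-coverage replicates at n = 500 with 500 bootstrap
draws. These sizes give binomial error bars comfortably inside the asserted
tolerances.

# Known limitations

* SparCC assumes sparse true correlation; dense strong correlation
  structures bias the basis-variance solution.
* The NMF rank fallback assumes the true number of types produces the
  dominant reconstruction-error improvement; heavily continuous (gradient)
  community structure blurs that signal, and the diagnostics table is
  returned for manual override.
* Mediation assumes no unmeasured treatment–mediator or treatment–outcome
  confounding and no exposure–mediator interaction; the sensitivity
  analysis probes only mediator–outcome error correlation.
* db-RDA ignores negative-eigenvalue corrections; for strongly non-Euclidean
  distance matrices the pseudo-F is approximate.
* Closeness normalization makes values comparable across components but not
  identical to whole-graph closeness on connected graphs of different
  sizes.
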