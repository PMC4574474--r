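---
title: "Methods: recurrent breakpoint genes and network-based stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recurrent breakpoint genes and network-based stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`breakgene` analyses somatic copy-number aberration (CNA) profiles of tumor
cohorts measured on array-CGH platforms.  Whenever the copy-number state of
a chromosome changes within a profile, a chromosomal break must have
occurred somewhere between the last probe of the old segment and the first
probe of the new one.  The package (i) extracts these CNA-associated
breakpoints from segmented, state-called profiles, (ii) tests which genes
harbor breakpoints in more tumors than chance allows, and (iii) uses the
recurrent breakpoint genes, together with a gene-mutation panel and a
protein-interaction network, to stratify patients into molecular subtypes
that can be linked to survival.  Segmentation and state calling themselves
(e.g. CBS via DNAcopy, calling via CGHcall) are upstream of the package.

# Breakpoint extraction

A breakpoint is declared at every boundary between two consecutive segments
of one chromosome, with two exclusions: the first segment of a chromosome
contributes no boundary (a telomeric "start" is not a break), and
boundaries flanked by two copy-number-neutral segments are discarded
(segmentation may split a neutral stretch without any true copy-number
change; call states, not log2 means, decide neutrality).

The break is only localized to inter-probe resolution (~17 kb on the
emulated platform), so each breakpoint carries an *uncertainty interval*
`(pos(left probe), pos(right probe)]`.  A breakpoint is attributed to every
gene whose span overlaps this interval (`mode = "interval"`); attributing it
only to the gene containing the right probe is available as
`mode = "point"`.  Interval attribution is what makes nearby genes share
breakpoint-supporting probe pairs; such genes are statistically inseparable
at probe resolution and are merged into *pools* (connected components of
the gene-probe bipartite graph), named after the alphabetically first
member with a `*` suffix.

# The recurrence test

For gene (or pool) $g$ and profile $s$, let $y_{gs} = 1$ if $s$ has at
least one breakpoint in $g$.  The test statistic is
$T_g = \sum_s y_{gs}$, the number of profiles broken in $g$.

**Step 1 — baseline probabilities.**  A pooled logistic regression over all
(testable gene, profile) pairs estimates the probability of a breakpoint
hitting $g$ in $s$ at random:
$$\operatorname{logit} p_{gs} = \beta_0 + \beta_1 \log(n^{probes}_g + 1)
  + \beta_2 \log \ell_g + \beta_3 \log(B_s + 1),$$
with $B_s$ the profile's total breakpoint count and $\ell_g$ the gene's
*probe-covered length* — the total width of the inter-probe intervals
overlapping the gene.  The covered length, not the raw bp span, is the
genomic territory within which a breakpoint is attributable to the gene at
probe resolution; using the raw span misstates the exposure of genes whose
span is small relative to the probe spacing.  Pooling profiles with their
burden as a covariate yields profile-specific baselines without fitting
hundreds of per-profile regressions on sparse events (a per-profile mode
exists behind `per_profile = TRUE`).  Genes without any associated probes
cannot show a breakpoint and are excluded (`p = 0`, untestable).  When the
fit is degenerate (no events, separation), a closed-form uniform-placement
model — each of $B_s$ breaks landing on one of $N$ boundaries uniformly —
is available as `fallback_probability_model()` and is flagged as such.

Two refinements matter for calibration:

* *Pools are scored on their union footprint.*  The baseline model is
  always fitted on individual genes; a pool's null probability is then
  predicted at the union of its members' probe counts and covered lengths.
  Fitting on pooled rows directly biases the level (pool covariates and
  member-event aggregation interact), and multiplying member-wise
  complements over-counts the shared territory.
* *A two-pass fit* (`refit = TRUE`): genes discovered in a first pass are
  excluded from the second pass's likelihood.  Recurrent genes carry real
  signal; leaving them in the baseline fit inflates the null for every
  gene and costs power.

**Step 2 — exact null and p-value.**  Under the null, $T_g$ is a sum of
independent Bernoulli$(p_{gs})$ across profiles — a Poisson-binomial
distribution, computed exactly by a dynamic-programming convolution
(compiled kernel, numerically stable at cohort scale since all quantities
are probabilities).  The p-value is the exact tail $P_0(T_g \ge t_{obs})$.

By default only *candidate* genes — those with at least one observed
breakpoint — are tested.  That is a selection on the test statistic, so in
this mode both the p-values and the null distributions handed to the FDR
step are conditioned on the selection event:
$P_0(T \ge t \mid T \ge 1) = P_0(T \ge t) / P_0(T \ge 1)$.  Without the
conditioning the selected nulls are anticonservative and the nominal FDR
level is not held.  Testing all genes with probe coverage
(`candidates = "testable"`) uses the unconditional null.

**Step 3 — discrete FDR.**  The null of $T_g$ is discrete and differs per
gene, so the uniform-p assumption behind plain Benjamini–Hochberg does not
hold.  The step-up used here evaluates, at every attainable threshold $t$,
$$\widehat{FDR}(t) = \frac{\sum_g P_0(P_g \le t)}
 {\max(1, \#\{p_g \le t\})},$$
with $P_0(P_g \le t)$ computed exactly on each gene's attainable p-value
support, and sets $q_g = \min_{t \ge p_g} \widehat{FDR}(t)$.  Ties are
processed in increasing threshold order; the reverse cumulative minimum
assigns tied hypotheses the minimal value.  When all hypotheses share one
null this reduces *exactly* to standard BH — which is why the probe-level
test (uniform breakpoint probability across probes, $p_s = B_s/N$, one
shared null) simply uses `p.adjust(..., "BH")`.  FDR < 0.1 is the
conventional significance call.  No mid-p variant is offered; the
attainable-CDF step-up is one faithful reading of a "discreteness-aware
BH-type correction", and is documented as a design decision.

# Network-based stratification

Breakpoint events of the prevalent recurrent genes (members of significant
pools observed in > 3% of samples, `prevalent_breakpoint_genes()`) are
merged with the binary mutation panel (a gene carrying both kinds of
events gets the element-wise OR, as for a tumor-suppressor hit by either
mechanism).  Samples with no event at all are dropped before clustering.

The merged events are propagated over the interaction network —
$F \leftarrow \alpha F A_{norm} + (1-\alpha) F_0$ with
$A_{norm} = D^{-1/2} A D^{-1/2}$, a contraction for $\alpha < 1$ — and each
sample's smoothed vector is quantile-normalized across samples so that
profiles with very different event burdens become comparable.

Consensus clustering then runs `n_iter` iterations (default 1000; the
recovery studies in the test-suite use 100), each subsampling 80% of
samples and genes and factorizing the sub-matrix by graph-regularized NMF:
$$\min_{W,H \ge 0} \|V - WH\|_F^2 + \lambda\, tr(H L H^\top),$$
by multiplicative updates.  $L$ is the *normalized* Laplacian
$I - D^{-1/2}AD^{-1/2}$ restricted to the factorized genes: its eigenvalues
are bounded by 2, so with the default $\lambda = 1$ the penalty lives on
the scale of the loadings regardless of network density (with the
unnormalized Laplacian the degree scale makes the penalty dominate the
reconstruction and the factorization collapses).  The objective is
non-increasing under the updates and is evaluated every 10 updates (it
costs as much as an update); convergence is the per-update relative change
dropping below `tol` (default 1e-5).  $W$ and $H$ are initialized
uniform-random per iteration, driven by the master seed, making runs fully
reproducible.  Each selected sample is assigned to the arg-max column of
its $W$ row *after* L1-normalizing columns — $WH$ is invariant to diagonal
rescaling of the factors, so raw-scale arg-max is meaningless — with ties
to the lowest index.  Co-clustering counts normalized by co-selection
counts give the sample similarity; final subtypes come from average-linkage
hierarchical clustering of $1 - similarity$ cut at $k$ (default 4).

Per-sample *gene aberration scores* are recovered from the factorization:
$R_s = C_s^{-1} \sum_i V_{is}$ with $V_i = W_i H_i$ and $C_s$ the number of
iterations selecting $s$ (never-selected samples get a zero vector and a
flag).  A streaming accumulator keeps memory bounded; storing the factors
(`store_factors = TRUE`) reproduces identical scores.  Gene-subtype
association uses two-sided Mann-Whitney U tests of a gene's scores inside
versus outside each subtype; sidedness and the optional BH adjustment
across the genes-by-subtypes grid are explicit arguments because the
original procedure specifies neither.

# Survival and enrichment

Kaplan-Meier curves, the $k$-group log-rank test, Cox proportional-hazards
for binary contrasts (the hazard-ratio method is a package decision; the
source analysis does not name one), a per-gene log-rank screen with
Bonferroni correction over the genes actually tested (genes with fewer
than `min_carriers = 5` carriers on either side are skipped with a
reason), and one- or two-sided Fisher exact enrichment tests.  Median OS
is read off the KM curve (first time survival drops to 0.5 or below), not
from raw observed times, to respect censoring.

# The synthetic cohort generator

`simulate_cohort()` emulates the *structure* of a segmented array-CGH
cohort: a uniform probe grid (default 17 kb spacing), log-normal gene
spans (median ~60 kb, so a typical gene covers a few probes and short
genes may cover none), negative-binomial per-sample breakpoint counts
(default mean 40, size 0.7 — counts spread over orders of magnitude),
planted recurrent genes hit with per-sample probability $\theta$ at a
random fully-internal probe boundary, an 8-gene mutation panel at
frequencies typical of commonly mutated colorectal-cancer genes, a
stochastic-block-model interaction network, and per-group exponential
survival with independent censoring.  Boundaries are converted to segments
with alternating neutral / non-neutral call states, so every simulated
boundary is detectable and no spurious neutral-neutral boundary exists —
`derive_breakpoints()` recovers exactly the simulated set, which is what
makes ground-truth bookkeeping exact.

Three presets define the study conditions used throughout the tests:
`"null"` (100 samples, 2,000 genes, 20,000 probes, no signal),
`"planted"` (the same plus 20 recurrent genes at $\theta = 0.08$), and
`"subtypes"` (200 samples, 1,000 network genes in 4 modules, 4 groups with
40 module-aligned driver genes each at $\theta = 0.35$ in-group versus
0.05 outside, a ~2.2-fold hazard in group 3 which also carries most MSI
samples and a mutation-enriched panel gene).  The driver count and
enrichment mirror a cohort in which ~170 prevalent breakpoint genes spread
over four subtypes drive the classification, with in/out-group prevalence
contrasts of the order reported for advanced colorectal tumors.  What the
generator deliberately does **not** emulate: probe-level log2 noise and
real segmentation artefacts, correlated breakpoint hotspots beyond the
planted genes, biological MSI effects on breakpoint burden, and
non-exponential survival.  Passing tests therefore demonstrate the
statistical machinery under the generative assumptions of the null model,
not robustness to real-array artefacts.

# Numerical choices and degenerate inputs

* Poisson-binomial: plain DP in doubles; no rescaling needed since all
  terms are probabilities; pmf sums to 1 within 1e-10 at cohort size.
* Tail vectors are clipped at 0 against rounding in reverse cumulative
  sums.
* Multiplicative NMF updates add 1e-10 to denominators; all-zero
  subsamples in consensus iterations are skipped with a warning.
* Propagation iterates to `max |F' - F| <= tol` (default 1e-6, cap 2000
  iterations) and is exact against the closed-form linear solve on small
  graphs.
* Empty profiles, cohorts without breakpoints, degenerate 2x2 margins,
  subtypes with fewer than two samples, and genes without carriers all
  take explicit, documented paths (error, `p = 1`, `NA` column, or skip
  reason) rather than propagating NaNs.

# Problem sizes

The shipped test-suite exercises the full chain at desk scale: calibration
at 100 samples x 2,000 genes x 20,000 probes over 25 replicates,
stratification at 200 samples x 1,000 network genes with 100 consensus
iterations, and survival machinery at n = 1,000.  A full-cohort
(352-sample, 168,823-probe) analysis runs through the identical code path;
`inst/scripts/reproduce-gse63216.md` documents how to obtain those inputs.

# Known limitations

* Breakpoint-to-gene attribution at interval resolution cannot separate
  pool members; pools are the honest unit of inference.
* The logistic baseline absorbs covariate effects only; systematic
  hotspot structure beyond the three covariates (e.g. fragile sites)
  inflates apparent recurrence by design — that is the discovery target,
  not a bug, but it means q-values are calibrated against the covariate
  null only.
* Mann-Whitney p-values for gene-subtype association are computed on
  scores derived from the same factorization that defined the subtypes;
  they rank genes within the analysis and are not population-level
  inference.
* The structural-variant type (deletion, inversion, translocation) is not
  identifiable from copy-number data and is never reported.
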