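---
title: "Phylogenetic-scale decomposition of host-microbiome associations: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic-scale decomposition of host-microbiome associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronosym)
```

This vignette is the package's own account of the models it implements, the
defaults it chooses where the design was genuinely open, and what its
synthetic validation does and does not establish.

## 1. Slicing and the BDTT profile

Every node of the bacterial tree is assigned a *depth*: the maximum path
length down to any descendant leaf. Leaves have depth 0; on an ultrametric
tree the root depth equals the tree height. A slice at depth `t` assigns
each leaf to the clade rooted at the unique ancestor `v` with
`depth(v) <= t < depth(parent(v))`. Defining depth tipward (rather than as
distance from the root) keeps slicing well defined when branch lengths are
expected substitutions per site rather than time; a node whose depth equals
`t` exactly roots its own clade, which makes `t = 0` the leaf partition.

Collapsing the host × sequence table into these clades conserves per-host
totals exactly. The default slice grid is 40 evenly spaced depths from 0 to
the tree height; `slice_depths(tree, breakpoints = TRUE)` instead returns
the distinct node depths, between which every slice quantity is piecewise
constant.

**The UniFrac identity.** Take one slice per interval between consecutive
distinct node depths, weighted by the interval width `w_t`. Writing `U_t`
for the number of slice clades present in exactly one of two hosts and
`S_t` for the number present in at least one,

\[
\frac{\sum_t w_t\,U_t}{\sum_t w_t\,S_t} \;=\; \text{unweighted UniFrac},
\]

because on an ultrametric tree the clade cut by a slice interval is in
one-to-one correspondence with the branch crossing it, and the interval
widths sum to the branch lengths. The suite asserts this to 1e-10 on 100
random trees. On non-ultrametric trees the identity holds with branch
lengths replaced by depth differences; the package slices such trees
without claiming the stricter identity.

Presence for all unweighted metrics means count ≥ 1; no relative-abundance
floor is applied. Rarefaction (`rarefy()`) is available for the
abundance-weighted Bray–Curtis profile and before presence/absence
modelling, where unequal sampling depth would otherwise bias occupancy.

## 2. Distance-matrix inference

`mrm()` regresses the unfolded strict lower triangle of the response on the
predictors and reports the coefficient of determination; with one predictor
this equals the squared Pearson Mantel statistic (asserted to 1e-12 and
cross-checked against `vegan::mantel`). Two distinct nulls are exposed, as
they answer different questions:

* the **test** permutes the rows and columns of the response jointly and
  reports `p = (1 + #{permuted R² ≥ observed}) / (n_perm + 1)` (default
  `n_perm = 999`);
* the **envelope** shuffles host names in the predictor 100 times (the
  conventional count for a 95% envelope) and flags the observed R² only if
  it exceeds the 97.5% quantile.

Variance partitioning of two predictors reports
`R²_intersection = R²_A + R²_B − R²_union`.

The per-lineage screen treats each OTU's presence/absence as a two-group
factor on the host distance matrix and computes the distance-based
pseudo-F (identical to `vegan::adonis2`'s statistic, asserted to 1e-10)
with label-permutation p-values and BH-FDR across testable OTUs (present in
≥ 2 and absent from ≥ 2 hosts). The response/factor orientation — host
distances as response, presence as factor — is a deliberate choice where
the alternatives (abundance as response) would require an abundance model
the rest of the pipeline does not need. FDR level defaults to 0.05.

## 3. The gain/loss model

Each lineage's presence along the host tree is a two-state CTMC with gain
rate `g` and loss rate `l`; transition probabilities are closed-form.
Across-lineage rate variation uses two independent discrete-gamma laws
(mean-method discretisation, 4 categories each), giving 16 equally weighted
(gain, loss) multiplier pairs. The likelihood is computed by pruning with
per-node rescaling, mixed by log-sum-exp; marginal ancestral posteriors use
the up–down algorithm with category pairs weighted by their per-lineage
posterior weight. Both are verified against exhaustive enumeration of
internal states on trees of up to 6 leaves (1e-8).

Defaults and their reasons:

* **Root prior:** the chain's stationary distribution
  `P(present) = g/(g+l)`; a flat prior is available. The stationary choice
  makes the root treatment consistent with the rate estimates.
* **Fitting:** L-BFGS-B on log-parameters, 5 seeded restarts, tolerance
  1e-8 on the log-likelihood. Estimates on the search boundary raise a
  warning — all-present or fully randomised tables legitimately end there.
* **Non-homogeneous mode:** one (gain, loss) multiplier pair per branch,
  fit by coordinate ascent after the homogeneous fit. With tens of hosts
  this is heavily over-parameterised, so it is off by default and its
  output should be read as exploratory.
* **Ascertainment:** the input table only contains observed lineages; an
  optional correction divides each lineage's likelihood by
  `1 − P(absent everywhere)`. It is off by default, matching the common
  practice of conditioning implicitly on the observed roster.
* The k-state all-rates-different Mk model for discrete host traits (diet
  as carnivore/omnivore/herbivore) shares the same machinery; its k = 2
  case reproduces the gain/loss likelihood to 1e-10, and its optimum is
  checked against `ape::ace` after aligning the root conventions (ace's
  reported log-likelihood omits the flat root prior factor `1/k`).

## 4. Phylosymbiosis effect sizes

The expected ancestral community size at a host node (sum of presence
posteriors) is compared with its distribution over `n_null` independent-swap
randomisations of the presence table; the swap preserves both margins
exactly and the implementation asserts this after every run.
`SES = (observed − null mean)/null sd`, `p = (1 + #{null ≥ observed})/(n_null + 1)`,
significant when `p ≤ 0.05`. The default is 100 null tables with 50,000
swap attempts and a full model re-fit per null table; a fixed-model mode
(`refit = FALSE`) re-uses the observed rates and is several-fold faster at
the cost of ignoring rate-estimate variability under the null. `n_null` is
exposed because reasonable analyses range from 100 to 999 replicates.

Swap-chain mixing matters: null tables are generated by re-swapping the
observed matrix, so too few attempts leave them correlated with the
observation and the node tests become conservative. The calibration
experiment in the suite uses about 75 attempts per matrix cell, at which
point the rejection rate of margin-preserving null data sits at the nominal
5% (±3 percentage points over 60 replicates — a band fixed in advance from
the replicate-level Monte-Carlo error, since the ~5 node tests within a
replicate are dependent).

The SES–age regression is ordinary least squares of SES on node depth and
deliberately carries no p-value: the node values are phylogenetically
dependent, so slope and R² are descriptive. Dietary shifts at a node are
the mean omnivory-aware distance to its two children, where each node's
3-probability diet vector is collapsed by multinomial draw, recoded with
omnivory as the union {carnivore, herbivore}, scored by Sørensen and
averaged over 100 draws; a certain carnivore and a certain omnivore are
1/3 apart rather than 1.

## 5. Diet prediction

The predictor centres the presence matrix of diet-associated lineages (no
scaling: 0/1 columns have comparable variance, and scaling would inflate
rare lineages), extracts principal axes, and fits a three-class multinomial
logit on the first `m` axes for `m = 1..max_axes`, keeping the AIC-argmin
with `k = 2(m + 1)` parameters. A small L2 penalty (default 1e-6) keeps the
fit finite under perfect separation, which is the norm rather than the
exception at a few dozen hosts; AIC uses the penalised likelihood with the
unpenalised parameter count. Ancestral communities enter as posterior
probabilities — fractional community vectors project directly — with an
optional 0.5 hard-call threshold.

Diet classes come from the nine-category percentage table: plant share ≥ 90
is herbivore, ≤ 10 carnivore, otherwise omnivore. The 90% cut is a
documented package default for synthetic and user data, not a literature
value. The 0/0.5/1 score maps a probability vector onto a single
carnivory–herbivory gradient; entropy `H = −Σ p log p` (natural log)
measures call confidence, bounded by `log 3`.

Leave-one-out cross-validation rebuilds the predictor per fold. Under label
permutation its expected accuracy sits slightly *below* the majority-class
rate (removing a host depletes its own shuffled class in the training
fold), so the skill-free check is one-sided: shuffled accuracy must not
exceed chance plus binomial noise.

## 6. What the generators emulate — and what they do not

`validate_bdtt()` implements the four-step experiment: a 200-species
pure-birth tree scaled to unit height; two environmental-preference traits
evolved under Brownian motion with exponentially time-varying rate
`σ²(τ) = σ₀² e^{βτ}` (exact per-branch variance by integration); Gaussian
filtering of species into 30 sites along two gradients; and the per-slice
R² profile against each gradient's site distances. The defaults `β = −3`
(deep signal) and `β = +3` (tip signal) concentrate roughly 80% of trait
variance in the early or late half of the tree — a strong but plausible
20-fold rate change; traits are min-max rescaled to [0, 1] so the gradient
geometry (`w = 0.15` filters on a unit gradient) is meaningful for every
replicate; the second gradient is a seeded permutation of the first, making
the two filters independent. The exponential (ACDC) law is the canonical
one-parameter family for "rates that decrease (or increase) through time";
other monotone laws would place the signal similarly but are not claimed
identical. Twenty replicates recover the peak ordering in ≥ 90% of runs,
and an equal-β negative control (40 replicates, sign test) shows no
systematic ordering.

`generate_host_microbiome()` builds cohorts with known regimes: deep
bacterial clades assigned herbivore/carnivore affinities whose members
occur noisily in matching-guild hosts (horizontal, diet-filtered), and
shallow clades inheriting a single low-rate gain/loss pattern per clade
with per-leaf dropout (vertical). Diet guilds evolve under a symmetric
3-state chain on the host tree; the percentage table is Dirichlet noise
around guild-typical masses. Every generating parameter and each OTU's
regime is returned in a truth ledger, and all generators are deterministic
given their seed.

These fixtures establish that the estimators find structure they were
designed for and stay calibrated when it is absent. They do not emulate
compositionality of real sequencing counts, within-host variability,
sequencing error, tree-reconstruction uncertainty, or correlated lineages
(the gain/loss model's independence assumption is exactly true in the
generator and only approximately true in nature), so passing tests bound
implementation error, not biological generality.

## 7. Numerical choices and degenerate inputs

Problem sizes in the validation suite — 100 identity trees, 20 + 40
disparity replicates, 200 enumeration cases, 500 × 32 recovery tables, 1000
calibration simulations, a 6-host SES calibration — were chosen as the
smallest designs whose Monte-Carlo error is clearly inside the asserted
bands. Other conventions: distance matrices must be exactly symmetric with
zero diagonal (enforced, then symmetrised); a single empty community is at
distance 1 from every non-empty one and flagged, two empty communities are
an error; labels present in one input but not another are dropped to the
intersection with a warning, never silently; every stochastic function
takes a seed and restores the caller's RNG state afterwards.

Known limitations: the profile treats slices independently (no smoothing
across depths); the gain/loss model ignores abundance; the non-homogeneous
mode is unregularised; and diet classes are a coarse trichotomy by design —
the percentage table carries finer structure that only the Euclidean
distance uses.
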