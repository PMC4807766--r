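---
title: "Selecting climate-change scenarios by clustering, and what the ensemble machinery then does with them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting climate-change scenarios by clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenoset)
```

## Why subset a scenario ensemble

A climate-change scenario is one AOGCM run under one forcing trajectory,
summarized here by three regional deltas: change in mean annual temperature
(ΔTavg, °C, additive), in total annual precipitation (ΔPrec, %, relative)
and in useful precipitation — the summer-to-annual precipitation ratio —
(ΔPrat, %, relative). Ensembles of 27+ such scenarios are typical; running a
full SDM ensemble under each of them multiplies compute by the ensemble
size. `scenoset` reduces the ensemble by clustering scenarios in
standardized delta space and keeping the member nearest each cluster
centroid, weighted downstream by cluster size. The claim worth testing — and
what the test suite tests — is that the reduced, reweighted ensemble tracks
the full one.

## The selection model and its assumptions

Scenarios are points in R^p (here p = 3). Standardization to z-scores uses
the sample SD; this is a modelling choice, not a nicety — without it the
precipitation delta (SD ≈ 4.5) would dominate the temperature delta
(SD ≈ 1.3) in every distance. The consequences: the method is invariant to
the units of each delta, but *not* to adding strongly correlated variables,
which implicitly up-weight their shared gradient.

Clustering is Lloyd k-means seeded from a Ward minimum-variance tree
(the `ward.D2` criterion on Euclidean distances, so merge heights satisfy
ΔSS = h²/2). Hierarchical seeding makes the k-means starting point
deterministic and usually near-optimal; 999 additional random restarts
(each drawing k distinct scenarios as initial centroids) guard against a
poor cut. The best partition by within-group SS wins. Two numerical policies
are pinned down because they affect reproducibility:

* **Empty clusters** occasionally arise during Lloyd iterations from poor
  starts. The repair relocates the point farthest from its own centroid into
  the empty cluster (never emptying another), so a k-cluster request always
  returns k occupied clusters.
* **Seeding of randomness** is counter-based: restart r under master seed s
  uses a seed derived from (s, r) alone, so results do not depend on
  evaluation order and are bit-reproducible.

### Choosing k

The Rsq statistic (between-SS over total-SS) is profiled over k = 1..n.
Rsq(1) = 0 and Rsq(n) = 1 by definition; the profile is made monotone by
warm-starting each k with the (k−1) solution split at its widest cluster
(any residual decrease — a finite-restart artifact — is rectified to the
running maximum with a warning). The number of clusters maximizes the net
benefit

B(k) = Rsq(k) − w · (k − 1)/(k_max − 1),

ties going to the smallest k. With the default `cost_weight` w = 1 both the
benefit and the cost term run from 0 to 1 across the profile, and the rule
has a marginal reading: stop adding clusters once one more cluster buys less
explained variance than the average per-cluster cost 1/(k_max − 1). On the
packaged 27-scenario table this selects k = 6 (Rsq ≈ 0.83); the choice of
w = 1 over smaller values was deliberate — values below ≈ 0.7 chase the long
flat tail of the profile and select k in the teens, which defeats the
purpose of subsetting. The flag is exposed for users who want a different
cost–benefit trade-off.

### Representatives

Each cluster is represented by its member nearest the centroid (Euclidean,
standardized space; ties → earliest table row). Representatives are real,
citable scenarios rather than synthetic cluster averages — practitioners can
name the AOGCM/forcing they ran. The cluster size nk_j travels with the
representative and becomes its weight.

## The downstream ensemble machinery

**Change-field projection.** Future climate grids are built by superimposing
a scenario's deltas on the baseline climatology: temperature additively,
precipitation multiplicatively (1 + ΔPrec/100), and the useful-precipitation
ratio multiplicatively with clipping to [0, 1]. Clipping events are counted
and warned about; in the packaged fixtures they are rare (ratio values sit
well inside the unit interval). Scaling the ratio directly is the simplest
reading consistent with the delta units; recomputing it from separately
projected summer and annual precipitation would need monthly deltas, which
the regional delta table does not carry. Deltas are regional scalars, but a
per-cell vector is accepted through the same interface if a spatially
explicit delta field is available.

**Occurrence models.** The package deliberately ships a single reference
learner — a ridge-stabilized logistic regression (IRLS, fixed iteration cap,
convergence flag, optional quadratic terms for unimodal responses) — because
multi-algorithm SDM platforms already exist and the consensus layer only
needs per-cell probabilities with per-model AUCs. Any learner set can be
plugged in through `probability_stack()`. The split-sample protocol is 70/30
with 20 repeats, simple random by default (stratification by class is an
option, off by default, since plain random splitting is the common
protocol). AUC is computed as the tie-aware Mann–Whitney rank statistic:
exact, O(n log n), and trivially checked against pair counting.

**Consensus.** Reference-period and full-ensemble future maps weight models
by AUC and scenarios uniformly; reduced-ensemble future maps double-weight
by AUC × cluster size. The joint weights sum to 1 (asserted at 1e-12), so
consensual probabilities stay inside the per-cell envelope of the inputs.
When every cluster member's map equals its representative's, the reduced
double-weighted consensus equals the full AUC-weighted consensus exactly —
a conservation property the suite tests by construction.

**Thresholding.** maxSSS: the candidate set is the observed distinct
consensual probabilities (exact sweep, cheap at these scales, no step-grid
approximation), predicting presence where p ≥ t (presence-inclusive), ties
resolved to the smallest threshold. A 1e-9 slack protects the tie rule from
float-order noise in the sensitivity+specificity sum. The threshold is
calibrated once per species on the reference period and transferred to
future maps; per-species thresholds are never shared.

**Range change and sensitivity.** Gains and losses are percentages of
reference-period presences (gains can exceed 100%), under unlimited
dispersal only. The sensitivity analysis enumerates all C(m, q) AOGCM
subsets (always including every available forcing for a chosen AOGCM),
recomputes each subset's AUC-weighted consensus and gains/losses, and
reports per-q spreads (max − min). Above a combination cap (default 10,000)
a seeded uniform subsample by lexicographic unranking is used, so
CMIP5-scale model lists do not explode the run.

## What the synthetic fixtures emulate — and what they don't

`make_baseline_grid()` builds a lattice with a south–north temperature
gradient (14 → −2 °C, a temperate-to-boreal transect), a west–east
precipitation gradient (800 → 1300 mm) and a mild ratio gradient
(0.28 → 0.42), plus spatially correlated noise (white noise smoothed by a
3×3 box filter; default SDs 0.6 °C, 40 mm, 0.015). `make_virtual_species()`
draws presences as independent Bernoulli trials from a known logistic
response; the default species has a thermal optimum near 7 °C, moderate
moisture preferences, prevalence ≈ 0.4 and a strong signal (ensemble AUCs
above 0.85, matching the quality band real tree-species SDMs typically
reach). These defaults were chosen once as a realistic stated world and are
not tuned per test.

The fixtures do **not** emulate spatial autocorrelation in the sampling
process (presences are independent given climate), observation error,
dispersal limitation, land-use constraints, or realistic coastline/grid
geometry. A green end-to-end test therefore establishes that the ensemble
arithmetic behaves as specified on a well-behaved landscape — not that any
real species obeys the model. Conversely, the clustering half needs no
emulation at all: its complete input is the printed 27-scenario delta table,
so its headline numbers are reproduced exactly.

## Numerical choices and degenerate inputs

* Sample SD (n−1) throughout; a constant delta column is an error naming the
  variable.
* Scenario identity is the (model, forcing) pair; duplicated pairs are
  rejected at read time with the offending rows.
* Rsq is clamped to [0, 1] (between-SS can be −1e-16 at k = 1 in floats);
  within + between = total is asserted at 1e-8 relative everywhere.
* k-means ties in the assignment step go to the lowest centroid index;
  representative ties to the earliest table row; maxSSS ties to the smallest
  threshold.
* Cell tables round-trip at 17 significant digits, so written artifacts
  reload bit-identically and pipeline manifests (md5 per artifact) are
  reproducible across machines; the resolved-config copy embeds run paths
  and is excluded from cross-run identity.
* Single-scenario tables read fine but refuse standardization; single-class
  occurrence data refuse model fits, AUC and thresholds — all with
  actionable messages.

## Known limitations

Clustering operates on regional mean deltas; spatially explicit delta
fields are projected but not clustered (a spatial extension would cluster
per-cell delta patterns instead). The cost-weight default is calibrated to
the packaged ensemble's profile shape; very differently shaped profiles may
warrant a different w. The reference learner is intentionally simple; its
quadratic logistic response cannot capture interactions or skewed response
curves, which is visible as a mild optimum-recovery bias at small n.
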