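# scenoset

Objective selection of climate-change scenarios for ensemble species
distribution forecasting.

## The problem

Impact studies in climate-change ecology need climate inputs, and dozens of
climate-change scenarios (coupled atmosphere–ocean general circulation
models, AOGCMs, crossed with forcing scenarios) are available for any
region. Running a species distribution model (SDM) ensemble under every
scenario is often prohibitive, so practitioners pick one or two scenarios —
usually arbitrarily, which can misrepresent the range of plausible climate
futures. `scenoset` implements an objective alternative: cluster the
scenarios in climate-delta space and keep one representative per cluster,
then weight the downstream ensemble so the reduced set still reflects the
full ensemble's distribution.

## The method

Each scenario *s* is a point in delta space: regional changes in mean annual
temperature ΔTavg (°C, additive), total annual precipitation ΔPrec (%,
relative) and useful precipitation ΔPrat (%, relative). The selection
procedure is:

1. standardize each delta variable to z-scores (sample SD);
2. build the Euclidean distance matrix between scenarios;
3. grow a Ward minimum-variance tree and cut it into *k* groups;
4. run k-means (Lloyd) from the cut centroids, plus 999 seeded random
   restarts, keeping the partition with minimal within-group sum of squares;
5. compute Rsq = between-SS / total-SS, the variance captured by the
   partition.

Steps 3–5 are repeated for k = 1..n; the number of clusters is chosen where
the marginal Rsq gain of one more cluster drops below the average
per-cluster cost (a cost–benefit knee rule, `select_k()`). Each cluster is
then represented by its member scenario nearest the centroid, carrying the
cluster size `nk_j` as its weight.

Downstream, per-cell occurrence probabilities `x_ij` from SDM *i* under
scenario *j* are aggregated into a consensual probability

    x̄* = Σ_i Σ_j  x_ij · (AUC_i / Σ_m AUC_m) · (nk_j / Σ_p nk_p)

— double-weighted by model quality (AUC) and cluster size. Consensual
probabilities are binarized with a sensitivity+specificity–maximizing
(maxSSS) threshold calibrated on the reference period, and range change is
reported as gains/losses in % of reference-period presence cells (unlimited
dispersal). A combinatorial sensitivity analysis quantifies what arbitrary
selection costs: for every q-of-m subset of AOGCMs, the consensus
gains/losses are recomputed and their per-q spreads summarized.

## Worked example

The packaged 27-scenario delta table (9 AOGCMs × 3 SRES forcings,
`cmip3_deltas_fixture()`) reproduces the published selection:

```r
library(scenoset)
sel <- cluster_scenarios(cmip3_deltas_fixture(), k = "auto", restarts = 999,
                         rng_seed = 1)
print(sel)
#> Scenario selection: 27 scenarios -> 6 representatives
#> Rsq(k = 6) = 0.8297 (83% of variance)
#>  cluster center             model sres                   key size     weight dist_to_centroid
#>        1  CCCMA     CGCM3.1 (T47)   A2      CGCM3.1 (T47):A2    2 0.07407407        0.5437213
#>        2   GFDL             CM2.0   B1              CM2.0:B1    8 0.29629630        0.3174983
#>        3   GFDL             CM2.0  A1B             CM2.0:A1B    5 0.18518519        0.2238051
#>        4    MRI         CGCM2.3.2   A2          CGCM2.3.2:A2    6 0.22222222        0.4003754
#>        5   CCSR MIROC3.2 (Medres)  A1B MIROC3.2 (Medres):A1B    3 0.11111111        0.4384263
#>        6   IPSL               CM4  A1B               CM4:A1B    3 0.11111111        0.5082402
```

Six clusters capture 83% of the inter-scenario variance; cluster sizes run
from 2 to 8, and the representative set spans the warm/dry (MIROC3.2, CM4)
to cool/wet (CM2.0 B1 cluster) corners of the ensemble. The full synthetic
workflow — projecting a baseline landscape under every scenario with the
change-field method, fitting a split-sample SDM ensemble on a virtual
species, and comparing the 6-representative double-weighted consensus with
the full 27-scenario consensus — runs via

```r
run_pipeline(list(out_dir = "out", seed = 1, nx = 20, ny = 20,
                  repeats = 20, run_sensitivity = "true"))
```

or the CLI (`Rscript inst/cli/scenoset.R run --config run.cfg`); see
`?run_pipeline` for the stage list and the manifest format.

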