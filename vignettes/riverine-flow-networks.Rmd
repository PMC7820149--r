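---
title: "Riverine energy-flow food webs: assembly, network analysis and keystone sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Riverine energy-flow food webs: assembly, network analysis and keystone sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverena)
```

## The model

`riverena` works with snapshot, steady-state energy budgets of river
communities. A web is a set of compartments — periphyton taxa, two detritus
pools (CPOM and FPOM), macroinvertebrates and fish — each with a storage
(J/m²), a boundary input, a non-respiratory export and a respiration term
(all J/m²/yr), plus a donor-oriented matrix `F` of internal transfers:
`F[i, j]` is the energy flowing from compartment `i` to compartment `j` per
year. Steady state (inflow equals outflow at every node) is the precondition
for all matrix analyses; `steady_state_residuals()` quantifies departures and
`balance_avg2()` removes them.

Microbial compartments are not modelled: a single dominant microbial node
would swamp flow-based metrics, at the cost of underestimating total
throughflow — a standard trade-off for stream webs of this kind.

## Web assembly

`assemble_web()` turns a community survey into a balanced web:

1. Biomass per taxon is `density × individual mass × energy density`.
2. Energetic rates close the consumer identity `C = P + R + U`:
   production `P = PB·B`, respiration `R = RB·B`, consumption
   `C = (P + R)/AE`, egestion `U = (1 − AE)·C`, with `AE` the assimilation
   efficiency (assimilation/ingestion).
3. Diet flows allocate each consumer's `C` across its resources in
   proportion to resource productivity times a preference weight.
4. Demand a compartment cannot meet from local production enters as
   boundary input — invertebrate and detritus *drift* from upstream; local
   production nobody eats leaves as export (drift out, death, downstream
   processing). An optional fraction of that surplus can instead be routed
   to the CPOM pool as non-predation mortality (`mortality_to_cpom`); it is
   off by default because mortality rates would have to be invented.
5. Egested food is exported by default; `egestion_to = "FPOM"` keeps it in
   the web instead. The published webs do not pin this choice down, so both
   are exposed and the default is the one that keeps the web acyclic.
6. Detritus pools import exactly what detritivores demand beyond internal
   supply, carry a nominal storage (100 J/m² by default, visible only in
   total system storage, never in flow metrics), and respire nothing.

Producers acquire `P + R` across the boundary (photosynthesis), so assembled
webs balance *exactly* by construction; `balance_avg2()` then only has to
absorb floating-point residue, and on hand-edited or externally supplied
webs it does real work.

Diet allocation needs an "availability" for detritus, which has no
productivity. The default is the mean periphyton production of the
community, which makes preference weights the effective control; the value
is exposed as `detritus_availability`.

## Balancing

`balance_avg2()` rescales internal flows only — boundary inputs, exports and
respiration are measured or derived quantities and are held fixed. One
iteration applies an input-scaling pass (each node's internal inflow column
rescaled to match its outflow total) and an output-scaling pass (each
internal outflow row rescaled to match its inflow total) in both orders and
averages the two candidate matrices element-wise; iterations repeat until
the largest relative residual falls below `tol` (default 1e−6, far below the
precision of any field estimate) or `max_iter` (1000) is hit, in which case
the report's `converged` flag is `FALSE` rather than an error. Flows can
never become negative (scale factors are clamped at zero), and a node with
no internal flows at all but a boundary imbalance is reported as an error,
since nothing can be scaled to fix it.

## The metric suite

All metrics start from throughflow `T_i` (boundary input plus internal
inflow) and the dimensionless matrices `G = F/T_i` (rows, output-oriented)
and `G' = F/T_j` (columns, input-oriented). Rows/columns belonging to
zero-throughflow nodes are zeroed so inert compartments keep their index.

* **Flow partition.** `N = (I − G)⁻¹` sums the boundary, direct and all
  indirect pathways. With input vector `z`: total system throughflow
  `TST = z'N1`, boundary fraction `BFI = Σz/TST`, direct `DFI = z'G1/TST`,
  indirect `IFI = z'(N − I − G)1/TST`; the three sum to one. Network
  aggradation `TST/Σz` is the mean path length of a joule.
* **Homogenization.** CV(direct)/CV(integral), where CV is the sample
  standard deviation over all S² entries (zeros included) divided by their
  mean; input orientation uses (`G'`, `N'`), output uses (`G`, `N`). Both
  orientations are exposed because published tables often do not say which
  convention was used; the summary reports the input orientation.
* **Ascendency.** Computed on the flow matrix augmented with one virtual
  import row, one export column and one dissipation column. Relative
  ascendency `A/C` is base-invariant and lies in [0, 1]. Note that `A/C` is
  *not* invariant under placing two copies of a system side by side — the
  virtual compartments are shared — which is easy to verify by hand on a
  single-node system and is asserted in the tests.
* **Utility analysis.** `d_ij = (F_ij − F_ji)/T_i`; when the spectral
  radius of `D` is below one, `U = (I − D)⁻¹` and `Y = diag(T)·U`. Flow
  synergism is `ΣY⁺/|ΣY⁻|`, flow mutualism the count ratio of positive to
  negative entries of `Y` (exact zeros excluded; with no negative entries
  both are `Inf`). The sign-count variant on dimensionless `U` is exposed
  as `mutualism_U`. The power series does not converge for every real or
  simulated web — spectral radii sit close to one whenever a single
  consumer dominates a resource's fate — so non-convergence is flagged
  (`convergent = FALSE`) and the two metrics reported as `NA`, never
  extrapolated.
* **Environ centrality.** A node's share of the row sums of `N` (output)
  and of the column sums of `N'` (input), averaged (AEC). Each vector sums
  to one, so AEC compares across webs of different size.

## Keystone Sensitivity Index

For one trait category, a web's KSI is the AEC-weighted mean sensitivity
score over its macroinvertebrates:

KSI = Σₘ scoreₘ·AECₘ / Σₘ AECₘ.

Categorical traits score 3/2/1 (higher = more sensitive): body form
cylindrical/flattened/streamlined, locomotion crawler/swimmer/
burrower-sessile, respiration gills-aerial/tegument/plastron, dispersal
low/moderate/high; the fifth category uses each taxon's Macroinvertebrate
Community Index (MCI) organic-enrichment score verbatim. AEC is taken from
the full web — the ratio restricts the sums to invertebrates, so no
re-normalization is needed, and the index is invariant to rescaling AEC.
Taxa without trait data are excluded from both sums rather than imputed
(imputing a middle score would fabricate data); the excluded AEC mass is
reported as `coverage`.

## Gradient regressions

`fit_regression()` fits ordinary least squares in four forms — linear,
log-log, log-linear, quadratic (`y ~ x + x²` on the raw scale, the simplest
reading of a "quadratic" relationship) — reporting R², the overall F and its
two-sided p-value. Natural logs are used throughout; R² and F are
base-invariant, and for single-predictor fits R² is symmetric in which
variable is called the response, so the conventional choice (metric as
response, DIN as predictor) is harmless. KSI columns are fitted linearly on
Box-Cox-transformed DIN; `boxcox_transform()` maximizes the normal profile
log-likelihood `−n/2·log σ̂²(λ) + (λ−1)Σlog x` over a λ grid from −2 to 2 in
steps of 0.05. No multiple-testing correction is applied across the fifteen
fits. The packaged `manawatu_gradient()` table carries the twelve-site
DIN/DRP/TST surface these fits are checked against.

## The synthetic generator

`generate_gradient_study()` emulates a twelve-site enrichment gradient so
the whole chain — community → web → metrics → KSI → regression — can be
exercised without field data. Design choices, fixed once:

* **Gradient.** DIN log-spaced over 0.02–0.90 mg/L (the observed range
  spans ~1.7 orders of magnitude, so log spacing is the natural design);
  DRP follows DIN on the log scale with lognormal noise. Richness is
  uniform on 33–67 taxa; guild proportions default to 20% periphyton,
  65% invertebrates, 15% fish, plus the two detritus pools.
* **Energetics.** Periphyton uses the annual P/B of 35 and R/B of
  0.03/day × 365 = 10.95/yr; invertebrate and fish rates are lognormal
  around field-typical annual ratios, with assimilation efficiencies by
  feeding role (detritivores lowest, predators highest).
* **Enrichment enters mechanistically**, never by writing metric values:
  community biomass scales as `DIN^β_TST` (default 0.5) times a lognormal
  site effect (σ = 0.3 on the log scale); invertebrate R/B shifts with
  `β_RB·log DIN` (default 0.15, energy-inefficient taxa under enrichment);
  the probability of a cylindrical body form shifts with `β_trait·log DIN`
  on the log-odds scale (default 0.8). Because assembly is linear in
  biomass, scaling every density by a factor scales TST by the same
  factor, which is what makes `β_TST` identifiable from the log-log fit.
* **Diets** follow functional feeding groups with productivity-
  proportional shares: grazers link to the whole periphyton pool,
  collectors to both detritus pools, invertebrate predators to about half
  the non-predatory invertebrates, fish to a broad invertebrate subset;
  preference weights are flat-Dirichlet draws.

For parameter-recovery experiments the generator is run with `β_RB = 0` so
the biomass effect is the only term moving `log TST` with `log DIN` — with a
respiration shift active, the fitted slope estimates the combined effect and
coverage of `β_TST` alone would be meaningless. The cheap
`metrics = "tst"` path stops after assembly, which keeps a 100-study
coverage experiment and a 500-study null calibration to a few minutes; the
tests and the acceptance script use 12 sites per study, 100 coverage
replicates and 500 null replicates.

What the generator does **not** emulate: temporal dynamics, floods and
hypoxia, microbial loops, spatial structure within a reach, or empirically
calibrated diet matrices. Passing tests on synthetic webs therefore
demonstrate the internal consistency of the pipeline and the recoverability
of imposed effects — not that any ecological conclusion about real rivers
follows.

## Numerical notes and limitations

* Matrix inversions use dense `solve()`; webs here are well below 100
  nodes, where this is exact and fast. Singularity of `I − G` is reported
  with the offending spectral radius.
* The flow partition requires positive total boundary input; an all-zero
  web is an error, not a NaN.
* Balanced-web conservation (`Σinput = Σexport + Σrespiration`) holds to
  1e−6 relative and is asserted in the tests.
* Utility non-convergence is a property of the web, not a bug; expect it
  when one consumer dominates a resource. Metrics that depend on it are
  `NA` and downstream regressions simply lose those sites.
* KSI values are bounded by the score range of the scored taxa
  (weighted-mean bounds); a web with no scored invertebrates is an error.
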