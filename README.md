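# riverena

Ecological network analysis (ENA) for riverine energy-flow food webs.

Nutrient enrichment reshapes stream communities, but its effect on
*emergent* food-web properties — how much energy moves, through how many
steps, how constrained the flows are, and whether the web's most influential
species are also its most disturbance-sensitive — is hard to read off a
species list. `riverena` is for freshwater ecologists who have community
survey data (taxon densities, individual masses, energetic rates, diet
links) across a nutrient gradient and want to turn it into mass-balanced
energy-flow networks and a reproducible statistical analysis of how web
function changes with enrichment.

## What it computes

Given a web with boundary inputs `z`, internal flows `F` (J/m²/yr, donor
rows) and throughflows `T`, the package computes, per web:

* **Flow partition** — with `G = F/T_i` and `N = (I − G)⁻¹`:
  total system throughflow `TST = Σ T_i`, respiration and export totals,
  network aggradation `TST/Σz`, and the boundary/direct/indirect split
  `BFI + DFI + IFI = 1`, where `IFI = z′(N − I − G)1 / TST` is the share of
  activity arising through intermediaries (trophic cascades).
* **Homogenization** — CV(direct matrix)/CV(integral matrix), input or
  output orientation.
* **Relative ascendency** — `A/C` on the boundary-augmented flow matrix,
  `A = Σ T_ij log₂(T_ij T·· / T_i· T_·j)`, `C = −Σ T_ij log₂(T_ij/T··)`.
* **Utility analysis** — `D` with `d_ij = (F_ij − F_ji)/T_i`,
  `U = (I − D)⁻¹`, `Y = diag(T)U`; flow synergism `ΣY⁺/|ΣY⁻|` and flow
  mutualism (positive:negative sign count of `Y`).
* **Average environ centrality (AEC)** — each node's share of integral
  input+output flow involvement; sums to one per web.
* **Keystone Sensitivity Indices** — AEC-weighted mean of trait sensitivity
  scores over macroinvertebrates (`KSI = Σₘ sₘAECₘ / Σₘ AECₘ`) for body
  form, locomotion, respiration mode, dispersal and MCI
  organic-enrichment scores.

Around that core: CSV I/O for node/flow/survey/diet/trait tables, an
AVG2-style iterative flow-scaling balancer, survey-to-web assembly using the
consumer identity `C = P + R + U` with productivity-proportional diets and
drift-import balancing, gradient regressions (linear, log-log, log-linear,
quadratic, Box-Cox linear), and a seeded synthetic-study generator that
emulates a 12-site enrichment gradient mechanistically.

## Worked example

```r
library(riverena)

# the packaged 12-site Manawatu gradient: does throughflow rise with DIN?
tab <- manawatu_gradient()
fit_regression(tab$DIN, tab$TST, "log_log")
#> gradient_fit [log_log]: R2 = 0.575, F(1,10) = 13.542, p = 0.004246
```

Total system throughflow increases significantly with dissolved inorganic
nitrogen: the log-log fit explains 58% of the between-site variance.

```r
# a two-compartment toy web: A gets 100 J/m2/yr at the boundary, passes 50 to B
net <- flow_network(
  nodes = data.frame(name = c("A", "B"), living = TRUE, storage = c(200, 100),
                     input = c(100, 0), export = c(20, 10),
                     respiration = c(30, 40)),
  flows = matrix(c(0, 50, 0, 0), 2, 2, byrow = TRUE))
ena_summary(net)
#> ena_summary (ten web-level metrics):
#>      TST     Resp  Exports   NetAgg      IFI HmgInput   RelAsc      TSS
#> 150.0000  70.0000  30.0000   1.5000   0.0000   3.0000   0.5025 300.0000
#>  MutFlow  SynFlow
#>   3.0000   4.0000
```

150 J/m²/yr of activity, a mean path length of 1.5 compartments, no
indirect flow (a two-node chain has none), and three positive utility
relationships for every negative one.

```r
# a full synthetic gradient study: 12 webs, ten metrics, five KSIs, 15 fits
study <- generate_gradient_study(synthetic_config(seed = 1))
fits <- run_gradient_analysis(study$gradient)
head(fits[, 1:7], 4)
#>    metric    form           r2            F df1 df2           p
#> 1     TST log_log 6.156292e-01 1.601654e+01   1  10 0.002509949
#> 2    Resp log_log 6.093860e-01 1.560072e+01   1  10 0.002731279
#> 3 Exports log_log 5.887668e-01 1.431710e+01   1  10 0.003579614
#> 4  NetAgg  linear 1.462932e-05 1.462953e-04   1  10 0.990587519
```

A command-line front end for shell pipelines
(`simulate | assemble | check | balance | metrics | ksi | gradient`) is
installed at `system.file("scripts", "riverena.R", package = "riverena")`.

See the vignette (`vignettes/riverine-flow-networks.Rmd`) for the model,
the balancing scheme, every metric's definition and the generator's design.

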