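# lipidtraffic

Network analysis of lipidomics profiles measured across tissue
compartments. The package is aimed at lipidomics and metabolic-programming
studies that profile the same individuals' liver, serum, CNS, heart and
adipose pools and ask not just *how much* of each lipid is present, but
*where it travels*.

The organism is modelled as a transport network: an origin (liver, the
site of de novo lipogenesis), a hub (serum) and termini (CNS, heart,
adipose). Two analyses run over it:

* **Switch Analysis** — each lipid variable (sum-composition species such
  as `TG(52:5)`) is reduced to present/absent per compartment using the
  rule *signal > 0 in ≥ 50 % of a phenotype group's samples*, then
  categorised as **A** (present in all compartments), **B** (present at
  both endpoints of an axis, e.g. `LS` = liver→serum) or **U** (present in
  one compartment and none of its neighbours). Phenotypes are compared per
  axis with the Jaccard–Tanimoto coefficient
  `J = |X ∩ Y| / |X ∪ Y|` and a resampling p-value
  `p = P(J' ≤ J_obs)` under a null that redraws both lists as uniform
  random subsets of their union with the observed sizes. Variables
  *re-routed* from one axis to another between phenotypes are detected and
  exported as routing diagrams (DOT/GraphML).
* **Abundance Analysis** — per variable and compartment, the margin change
  `x̄_E − x̄_C` with a Student's *t*-test against the dependence-corrected
  threshold `α/√N` (0.0021 for N = 586 at α = 0.05), and the
  error-normalised fold change
  `ENFC = log10(x̄_E/x̄_C) / sqrt((a² + b²)/2)`,
  with `a`, `b` the group standard deviations.

A seeded synthetic-data generator with planted re-routings and abundance
effects makes every stage testable without any external dataset.

## Worked example

Simulate a neonatal-shaped (F1N) dataset in which one variable is moved
from the serum–heart axis (control phenotype) to the serum–brain axis
(experimental phenotype), then recover it:

```r
library(lipidtraffic)

cfg <- scenario_config(
  network = "F1N", dropout = 0, seed = 202, n_samples = 6, n_variables = 60,
  planted_reroutes = list(list(variable = "auto",
                               from_axis = "SH", to_axis = "SB")))
g   <- generate(cfg)
pm  <- detect_presence(g$table, cfg$network$nodes)
rep <- switch_report(pm, cfg$network, "NP-NC", "LP-HC")
rep$comparisons
#>  axis n_control n_experimental         J p
#>    LS        34             34 1.0000000 1
#>    SB        35             36 0.9722222 1
#>    SH        36             35 0.9722222 1
find_rerouted(rep, "SH", "SB")
#> [1] "TG(41:3)"
```

Reading the comparison table: the liver–serum axis (`LS`) is identical in
the two phenotypes (J = 1). The serum–brain (`SB`) and serum–heart (`SH`)
axes each differ by exactly one variable out of ~36 (J = 35/36 ≈ 0.97),
and the p of 1 says a difference this small is entirely compatible with
chance relabelling of the shared universe. `find_rerouted()` identifies
the planted variable `TG(41:3)`: on `SH` only in the control group, on
`SB` only in the experimental group — a re-routing of traffic from heart
to brain.

The quantitative strand works the same way:

```r
ab <- abundance_report(g$table, cfg$network, "NP-NC", "LP-HC")
attr(ab, "threshold")        # alpha / sqrt(60) here
subset(ab, significant)      # margin, t p-value, ENFC per flagged row
```

End-to-end runners (`run_switch()`, `run_abundance()`) write the category
tables, axis comparisons, ENFC matrix, routing graphs and a config echo to
an output directory; the same flows are scriptable from a shell via

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","lta.R",package="lipidtraffic"))')" \
    switch --input data.csv --network F1N \
    --control NP-NC --experimental LP-HC --out rundir
```

## Documentation

`vignettes/lipid-traffic-analysis.Rmd` describes the model, its
assumptions, the tunable parameters, the synthetic-data noise model and
the design decisions in detail.
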