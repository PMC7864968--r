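---
title: "Lipid Traffic Analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lipid Traffic Analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidtraffic)
```

## The model

Lipid metabolism is systemic: species synthesised in the liver travel
through the serum to tissues that use them for structure (CNS), oxidation
(heart) or storage (adipose). `lipidtraffic` models this as a transport
network — an origin (liver), a hub (serum) and termini — and analyses a
lipidomics profile measured in each compartment from two complementary
perspectives.

**Switch Analysis (binary).** Each lipid variable (a species at
sum-composition resolution, e.g. `TG(52:5)`) is reduced to present/absent
per compartment and categorised:

* **A** — present in *all* compartments (ubiquitous);
* **B** — present in both endpoints of an *axis* (an adjacent compartment
  pair, labelled with directional letter codes such as `LS` =
  liver→serum), and not ubiquitous;
* **U** — present in a compartment and in *none of its neighbours*.

Per axis, the variable lists of two phenotypes are compared with the
Jaccard–Tanimoto coefficient \(J = |X \cap Y| / |X \cup Y|\) and a
resampling p-value: both lists are redrawn as uniformly random subsets of
the universe (by default \(X \cup Y\)) with the observed sizes, and
\(p = P(J' \le J_{\mathrm{obs}})\) — the probability that a difference at
least as large as the one seen arises by chance. A *re-routed* variable is
one that travels axis 1 in the control phenotype only and axis 2 in the
experimental phenotype only, the two axes sharing the hub.

**Abundance Analysis (quantitative).** Per variable and compartment, with
\(\bar x_C, \bar x_E\) the group means and \(a, b\) the group sample
standard deviations:

* margin change \(= \bar x_E - \bar x_C\), interpreted with a two-sample
  Student's *t*-test against a dependence-corrected threshold
  \(\alpha / \sqrt{N}\) for \(N\) variables (0.0021 for \(N = 586\) at
  \(\alpha = 0.05\));
* error-normalised fold change
  \(\mathrm{ENFC} = \log_{10}(\bar x_E / \bar x_C) \big/
  \sqrt{(a^2 + b^2)/2}\).

The ENFC mixes a log-ratio numerator with a raw-scale error denominator.
It is implemented exactly as defined — fidelity to the published statistic
over dimensional tidiness — and should be read as a signal-to-noise-scaled
effect size, not a pure fold change.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_fraction` | 0.5 | detection rule: signal > 0 in ≥ 50 % of a group's samples; evaluated on the exact fraction (3 of 5 passes, 2 of 5 does not) |
| `include_a` | `TRUE` | count ubiquitous variables as travelling every axis in comparisons; `FALSE` compares B-type lists only |
| `alpha`, `correction` | 0.05, `"sqrt"` | per-test threshold \(\alpha/\sqrt N\); `"bonferroni"` (\(\alpha/N\)) available |
| `welch` | `FALSE` | the classical equal-variance Student test is the default; Welch behind a flag |
| `p_method`, `draws`, `seed` | `"exact"`, 10⁴ | Jaccard p-value route; Monte-Carlo needs an explicit seed |

Presence for the switch sets is evaluated *within each phenotype*
(`categorize(pooled = FALSE)`); pooled (either-phenotype) presence, the
rule used for overall detection, is exposed via `pooled = TRUE`.

## Numerical choices

* The exact p-value route uses the fact that under the random-subset null
  the coefficient depends only on the intersection size, which is
  hypergeometric; the sum over intersection sizes equals full enumeration
  of subset pairs at any universe size (the test suite verifies this
  against a brute-force enumerator). Monte-Carlo redraws subsets
  explicitly and is retained as an independent route.
* Jaccard comparisons of `J' <= J_obs` use a 10⁻¹² tolerance to absorb
  floating-point noise in the rational coefficients; exact p-values are
  clamped to [0, 1].
* Two empty lists have no defined coefficient: `jaccard()` returns `NA`
  with a warning, never 0 or 1.
* Degenerate t-tests (zero variance in both groups) take the limit: p = 1
  when the means agree, 0 otherwise; groups with fewer than two samples
  give `NA` p with the margin still reported.
* ENFC is `NA` with a recorded reason when either group mean is
  non-positive or the pooled SD is zero.
* Signal correction rescales each sample to per-mille over the
  non-standard columns, errors on all-zero samples by name, and is
  idempotent.

## Design choices where the design was open

* **B excludes A; U permits non-adjacent co-presence.** B-sets are
  axis-shared variables *minus* the ubiquitous set, and a variable in, say,
  liver and brain only (non-adjacent) is U in both: the "not its
  neighbours" rule is applied literally, since nothing else constrains
  non-adjacent co-presence. The categorisation then provably partitions
  coverage: every present variable is A, in ≥ 1 B-set or in ≥ 1 U-set.
* **Comparison tail.** \(P(J' \le J_{\mathrm{obs}})\) treats dissimilarity
  at least as large as observed as the chance event; this reproduces the
  worked subset example (J = 0.67 with p = 1) exactly.
* **Axis membership includes A.** Ubiquitous variables demonstrably reach
  both endpoints of every axis, so comparisons include them by default;
  since published axis counts cannot be audited without the original
  dataset, the B-only convention is one flag away.
* **√N correction.** The 586 → 0.0021 pair pins the rule to
  \(\alpha/\sqrt N\); Bonferroni is offered but is not the default because
  it contradicts that pair.
* **Ionisation modes** are analysed in separate blocks end to end; the
  mode column defaults to `"positive"` when absent. For adipose, washed
  (PW) data should back negative-mode analyses and untreated data
  positive-mode ones — the `(PW)` suffix parses into a provenance flag,
  not a separate variable identity.

## What the synthetic generator emulates — and what it does not

`scenario_config()`/`generate()` produce two-phenotype, multi-compartment
datasets: 8 samples per (compartment, phenotype), ~300 variables drawn
from the common lipid classes with class-level abundance offsets (TGs
dominate the positive-mode signal), log-normal multiplicative noise
(`sdlog = 0.3`, ≈ 30 % CV — typical of semi-quantitative direct-infusion
lipidomics), a 5 % per-value detection dropout, and per-mille signal
correction. Category membership (A/B/U at 0.5/0.3/0.2), planted
re-routings and planted fold-change effects are all recorded in a
ground-truth manifest.

The generator does *not* simulate mass spectra, isotopes, ionisation
physics, isobaric overlap, batch effects or sample-level correlation
structure. Passing recovery tests therefore demonstrates the *set logic
and statistics* are correct under the stated noise model; they say nothing
about peak-processing artefacts in real data. One consequence the tests do
surface: per-mille closure means a large planted increase in one variable
slightly depresses all others in that compartment, which can produce
secondary low-p flags at very low noise — a property of compositional
data, not an artefact of the implementation.

## Problem sizes used in the checks

The test suite exercises: the A/B/U partition invariants on 1,000 random
presence patterns across the three preset networks; exact-vs-Monte-Carlo
agreement of the resampling p-value (10⁴ draws, 3 binomial SE) on every
(universe ≤ 6, |X|, |Y|) combination; exact recovery of planted
re-routings and 10-fold planted effects (noise 0.1, n = 8) across 20
seeded scenarios; and the null false-positive rate at 1,000 null
variables against the corrected threshold within 3 binomial SE. These
sizes keep each property statistically meaningful while the whole suite
runs in well under a minute per file.

## Known limitations

* Only sum-composition identity is modelled: no sn-positions, chains,
  adducts or mass computation.
* The network carries topology only; no kinetics or flux inference —
  presence is an average over the sampled developmental window.
* Only hub-mediated axes are considered; non-adjacent relationships enter
  solely through the U category.
* The t-test route assumes approximately normal per-mille abundances
  within groups; heavily zero-inflated variables should be interpreted via
  the Switch Analysis instead.

## A worked run

```{r, eval = FALSE}
cfg <- scenario_config(
  network = "F1N", dropout = 0, seed = 202, n_samples = 6, n_variables = 60,
  planted_reroutes = list(list(variable = "auto",
                               from_axis = "SH", to_axis = "SB")))
g <- generate(cfg)
pm <- detect_presence(g$table, cfg$network$nodes)
rep <- switch_report(pm, cfg$network, "NP-NC", "LP-HC")
rep$comparisons
find_rerouted(rep, "SH", "SB")   # recovers the planted variable
```
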