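# rabswitch

Automated structural identification of kinetic models of the **Rab5–Rab7
conversion switch** in early endocytosis.

During endosome maturation the membrane identity converts from
Rab5-dominated to Rab7-dominated. Each Rab GTPase cycles between a passive
GDP-bound concentration (`r5`, `r7`) and an active GTP-bound concentration
(`R5`, `R7`), with GDI-controlled membrane fluxes and GEF/GAP-catalyzed
(de)activation:

    dr5/dt = K1 − (k1 + GEF5)·r5 + GAP5·R5      dR5/dt = GEF5·r5 − GAP5·R5
    dr7/dt = K2 − (k2 + GEF7)·r7 + GAP7·R7      dR7/dt = GEF7·r7 − GAP7·R7

The functional forms of the four regulatory slots (GEF5, GAP5, GEF7, GAP7)
are unknown; a declarative library of alternative rate laws
(Michaelis–Menten, sigmoidal, exchange inhibition, linear, intrinsic; 3 × 3
× 7 × 2 choices) spans **126 candidate model structures**. Only two noisy
fluorescence channels are observed — scaled totals `K·(r5+R5)` and
`K·(r7+R7)` — so least-squares error alone barely discriminates among
candidates. The package implements the full identification pipeline for
this setting:

* **Model space** — enumerate and compile all candidate structures
  (`enumerate_structures()`, `build_structure()`, `compile_rhs()`).
* **Simulation** — stiff-capable integration of any candidate with a
  compiled right-hand side (`simulate_structure()`, `observe()`).
* **Selection criteria** — the relative error `E` (1 = mean-baseline),
  the hidden-state correlation criterion `R`, the switch-time displacement
  `X`, and their trade-off combinations `RX, ER, EX, ERX` (weight `alpha`)
  and `EC, ERC, EXC, ERXC` (complexity weight `beta`).
* **Parameter estimation** — Differential Evolution rand/1/bin
  (population 81, `F = 0.942`, `Cr = 0.915`, budget = 20,000 evaluations
  per parameter), reproducible by seed (`fit_structure()`, `fit_all()`).
* **Ranking and plateaus** — error profiles, the 10% plateau heuristic for
  sets of mutually indistinguishable models, bistability-group statistics
  and rate-law frequency tables (`rank_models()`, `plateau_length()`,
  `group_stats()`, `component_frequencies()`).
* **Practical identifiability** — bootstrap refitting on noise-perturbed
  data with percentile confidence intervals, estimate correlation matrices
  and bound-pileup flags (`bootstrap_identify()`).
* **Synthetic data** — seeded ground-truth scenarios with the statistical
  signature of the experimental series (`default_switch_scenario()`,
  `generate_dataset()`), so the whole pipeline is testable offline.

Results are tibbles; fitted objects have `tidy()`/`glance()` methods and
every result type has an `autoplot()`.

## Worked example

Generate a synthetic switch dataset, fit a handful of candidate structures
under the combined criterion `ERX` (alpha = 0.5), and rank them:

```r
library(rabswitch)

spec <- default_switch_scenario(n = 301, noise_level = 0.05, seed = 1)
gen  <- generate_dataset(spec)
attr(gen$dataset, "t_s")
#> [1] 132

# the true structure (id 73) plus seven competitors
cands <- enumerate_structures(constraints = list(
  gef5 = c(1, 2), gap5 = c(1, 3), gef7 = 2, gap7 = c(1, 2)))
fits <- fit_all(cands, gen$dataset,
                criterion = criterion_config("ERX", alpha = 0.5),
                de = de_config(budget_multiplier = 300), master_seed = 1)

scores  <- score_models(fits, gen$dataset, alpha = 0.5)
profile <- rank_models(scores, "ERX")
profile[, c("rank", "structure_id", "gef5", "gap5", "gef7", "gap7", "value", "in_plateau")]
#> # A tibble: 8 × 8
#>    rank structure_id  gef5  gap5  gef7  gap7 value in_plateau
#>   <int>        <int> <int> <int> <int> <int> <dbl> <lgl>
#> 1     1           74     2     3     2     2 0.443 TRUE
#> 2     2           32     1     3     2     2 0.527 FALSE
#> 3     3           45     2     1     2     1 0.530 FALSE
#> 4     4           73     2     3     2     1 0.536 FALSE
#> 5     5           46     2     1     2     2 0.544 FALSE
#> 6     6            4     1     1     2     2 0.568 FALSE
#> 7     7           31     1     3     2     1 0.634 FALSE
#> 8     8            3     1     1     2     1 0.664 FALSE
attr(profile, "plateau_length")
#> [1] 1
```

`value` is the ERX criterion (smaller is better; an `E` of 1 would be the
mean-predictor baseline). The top-ranked structure differs from the truth
(id 73, ranked fourth here) only in the GAP7 slot — at this sharply reduced
budget (300 evaluations per parameter, versus the reference 20,000) the
profile mixes structural differences with optimization noise, which is
precisely why conclusions are drawn from the indistinguishability plateau
of a properly budgeted sweep rather than from a single winner. Ranks 2-5
sit within a few percent of each other; the plateau here is cut short by
the lucky leader.

Assess how well the winning structure's parameters are pinned down by data
of this quality:

```r
bs <- bootstrap_identify(spec$structure, gen$dataset, noise_level = 0.1,
                         n_replicates = 20,
                         de = de_config(budget_multiplier = 300), seed = 1)
tidy(bs)           # per-parameter mean, 95% percentile CI, bound pile-ups
summarize_identifiability(bs)$high_correlations  # confounded pairs, |r| desc
```

Measured series in the space-delimited dialect (`t Rab5 Rab7`, `#`
comments) load with `read_measurements(path, time_shift = )`, including the
828.56 s shift conventionally applied to the published aggregated series.

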