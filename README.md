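# ceatree

Decision-tree cost-utility analysis for health economics, with
deterministic and probabilistic sensitivity analysis.

`ceatree` is built for analysts who compare treatment strategies with a
decision tree: a decision root over the strategies, chance nodes whose
branch probabilities are expressions over named parameters, and terminal
nodes carrying cost (US$) and utility payoffs. The engine rolls the tree
back to expected cost and quality-adjusted life years (QALYs) per strategy
and derives the standard decision statistics:

- **ICER** — incremental cost-effectiveness ratio,
  ΔCost / ΔEffect between two strategies (with dominance flags when the
  ratio is not meaningful);
- **NMB** — net monetary benefit, λ·Effect − Cost at willingness-to-pay λ
  (US$/QALY); maximising NMB is equivalent to the "adopt if ICER < λ" rule
  whenever the comparator gains effect;
- one-way, two-way, **tornado** and **threshold** (bisection) sensitivity
  analysis on any scalar output;
- **PSA** — probabilistic sensitivity analysis with method-of-moments beta
  (probabilities, utilities) and gamma (costs) samplers, summarised as
  cost-effectiveness acceptability curves (CEAC) and a cost-effectiveness
  plane with a bivariate-normal confidence ellipse;
- linear **calibration** of free terminal payoffs to arm-level targets
  (expectations are linear in the payoffs, so calibration is an exact
  solve).

The package ships a calibrated model comparing **early anterior cruciate
ligament reconstruction (ACLR)** with **conservative treatment**
(structured rehabilitation with optional delayed ACLR) for chronic ACL
injury in Indonesia — an 18-month horizon, societal perspective, and a
WHO-CHOICE willingness-to-pay threshold of US$12,876/QALY (three times the
2021 Indonesian GDP per capita).

## Worked example

```r
library(ceatree)

model <- acl_model()   # or read_model("inst/extdata/acl_indonesia.yaml")
cea_table(evaluate_model(model), wtp = 12876)
#> <cea_table> at WTP US$12876/QALY
#> # A tibble: 2 × 8
#>   strategy                cost effect incr_cost incr_effect  icer status     nmb
#>   <chr>                  <dbl>  <dbl>     <dbl>       <dbl> <dbl> <chr>    <dbl>
#> 1 Conservative treatment  3290   0.81        NA       NA       NA referen…  7140
#> 2 Early ACLR              4266   0.86       976        0.05 19520 icer      6807
```

Conservative treatment costs US$3,290 for 0.81 QALYs; early ACLR costs
US$976 more for 0.05 extra QALYs, an ICER of about US$19,520/QALY — above
the US$12,876 threshold, so conservative treatment has the higher net
monetary benefit (7,140 vs 6,807) and is preferred at base case.

Threshold analysis on the post-ACLR utility (at what utility does early
ACLR become cost-effective?):

```r
solve_threshold(model, "u_stable_aclr", target = 12876,
                bracket = c(0.82, 0.95), output = "icer")
#> <threshold_result> u_stable_aclr = 0.8857999 (comparator cost-effective above this value; 26 iterations)
```

Probabilistic sensitivity analysis and acceptability curves:

```r
samples <- run_psa(model, draws = 5000, seed = 2022)
ceac(samples, wtp_grid = c(0, 12876, 20000, 30000))
#> # A tibble: 8 × 3
#>     wtp strategy               probability
#>   <dbl> <chr>                        <dbl>
#> 1     0 Early ACLR                  0.0164
#> 2     0 Conservative treatment      0.984
#> 3 12876 Early ACLR                  0.351
#> 4 12876 Conservative treatment      0.649
#> 5 20000 Early ACLR                  0.508
#> 6 20000 Conservative treatment      0.492
#> 7 30000 Early ACLR                  0.619
#> 8 30000 Conservative treatment      0.381
```

At the WHO-CHOICE threshold, conservative treatment is cost-effective in
about 65% of draws; early ACLR reaches 50% acceptability near
λ ≈ US$20,000/QALY and rises from there. `plot_ceac()`,
`plot_ce_plane()` and `plot_tornado()` draw the corresponding figures.

A command-line interface wraps the same functions
(`inst/cli/ceatree.R`):

```sh
Rscript inst/cli/ceatree.R evaluate --model inst/extdata/acl_indonesia.yaml --wtp 12876
Rscript inst/cli/ceatree.R psa --model inst/extdata/acl_indonesia.yaml --draws 5000 --seed 2022 --out results
```

## Model configuration

Models are YAML files with `parameters`, `tree` and `settings` keys
(schema: `inst/schema/ceatree-model-1.0.json`). Payoff and probability
expressions may use parameter names, numeric literals, `+ - * /` and
parentheses; one branch per chance node may be the keyword `complement`.
See `inst/extdata/acl_indonesia.yaml` for a complete example, and the
methods vignette (`vignettes/acl-cost-utility.Rmd`) for the model's
assumptions and design choices.
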