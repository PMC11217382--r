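# volpgg

Tools for studying collaboration as a **voluntary threshold public goods
game**: a belief-based best-response model of the one-shot game, population
predictions under Beta-distributed beliefs, a loner-externality model, a
synthetic experiment generator, finite-session mechanics, and the
statistical pipeline (bootstrap, mixed-effects regressions, ROC comparison)
used to analyse such experiments.

## The problem

Many collaborations are joined voluntarily: people choose between an
uncertain group endeavor and a safe individual alternative before groups
even form. `volpgg` models this as a threshold public goods game. Groups of
$n = 5$ members each hold an endowment $e = 10$ points and choose to
cooperate (C, invest the endowment) or defect (D, keep it); if at least $q$
members cooperate ($q \in \{2, 4, 5\}$), everyone earns the reward
$R = 30$. Under *voluntary* participation a player may instead leave (L)
for a sure $e + s = 20$ points.

A player believing each other member cooperates with probability
$\gamma$ faces expected payoffs

$$E[\pi \mid C] = R\,\Gamma_{q-1},\qquad
  E[\pi \mid D] = e + R\,\Gamma_{q},\qquad
  E[\pi \mid L] = e + s,$$

with $\Gamma_k$ the binomial upper tail over the $n - 1$ others. With
beliefs distributed $\mathrm{Beta}(\alpha, \beta)$ across the population,
integrating the best-response partition yields action shares $r_x$, the
within-group cooperation rate $p_{\mathrm{coop}} = r_C/(r_C + r_D)$, the
group success rate (binomial upper tail at $q$), and normalized
efficiencies. A loner-externality parameter $\rho \in [0,1]$ interpolates
between flexible groups that exclude loners ($\rho = 0$) and fixed
boundaries where loners count like defectors ($\rho = 1$), via
$p_{\mathrm{coop}}(\rho) = r_C/(r_C + r_D + \rho\, r_L)$.

At $q = 5$ the model's sharpest prediction: defection is strictly dominated
by leaving for every belief, so any voluntary group that forms cooperates
fully.

## Worked example

Analytic predictions for the coordination threshold under uniform beliefs:

```r
library(volpgg)
spec <- game_spec(threshold = 5, regime = "voluntary")
best_response_regions(spec)
#> # A tibble: 2 × 3
#>   lower upper action
#>   <dbl> <dbl> <chr>
#> 1 0     0.904 L
#> 2 0.904 1     C
action_shares(beta_belief(1, 1), spec)
#>        C        D        L
#> 0.096398 0.000000 0.903602
```

No belief interval makes defection a best response, so the predicted
within-group cooperation rate is 1: only confident optimists
($\gamma > (2/3)^{1/4} \approx 0.904$) opt in, and all of them cooperate.

A full synthetic experiment and its analysis:

```r
cfg <- cohort_config(design = "main", seed = 2026)
records <- elicited_belief_to_gamma(generate_cohort(cfg))
summarize_conditions(records)
#>      regime threshold rho n_C n_D n_L p_coop p_success
#> 1 mandatory         2  NA  43 148   0  0.225   0.31485
#> 2 mandatory         4  NA  88 103   0  0.461   0.14226
#> 3 mandatory         5  NA  46 145   0  0.241   0.00081
#> 4 voluntary         2  NA  21 167   3  0.112   0.09916
#> 5 voluntary         4  NA  49  56  86  0.467   0.14861
#> 6 voluntary         5  NA  17   2 172  0.895   0.57342

stat <- function(d) {
  s <- summarize_conditions(d)
  w <- tidyr::pivot_wider(s[, c("regime", "threshold", "p_coop")],
                          names_from = regime, values_from = p_coop)
  setNames(w$voluntary - w$mandatory, paste0("delta_p_coop_q", w$threshold))
}
bootstrap_ci(records, stat, B = 1000, seed = 2026)
#>         statistic    point ci_low ci_high n_iterations n_undefined
#> 1 delta_p_coop_q2 -0.11343 -0.172 -0.0518         1000           0
#> 2 delta_p_coop_q4  0.00593 -0.105  0.1210         1000           0
#> 3 delta_p_coop_q5  0.65390  0.513  0.7853         1000           0
```

The bootstrap resamples whole participants (all six of a participant's
condition rows move together) and reports percentile 95% intervals. At
$q = 5$ the voluntary regime lifts within-group cooperation by 0.65 in this
synthetic cohort — the self-selection signature. At $q = 2$ the *pure
best-response* generator shows a negative gap: the outside option also
filters out reluctant cooperators, a genuine property of the
fixed-beliefs model discussed in the methods vignette
(`vignettes/voluntary-collaboration.Rmd`).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/volpgg.R model --threshold 5 --regime voluntary --alpha 1 --beta 1 --out out/
Rscript inst/cli/volpgg.R simulate --config config.yaml --seed 7 --out out/
Rscript inst/cli/volpgg.R analyze --data out/cohort.csv --bootstrap 1000 --out out/
```

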