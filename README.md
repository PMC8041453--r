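# anchorpoint

Anchor point selection for differential item functioning (DIF) detection
between two groups of test takers under the Rasch model.

## The problem

To compare Rasch item difficulties between a reference and a focal group, the
two sets of estimates must first be placed on a common scale: the Rasch scale
has no origin, so each group's parameters are only identified up to an
additive constant. Classical practice picks a set of *anchor items* and
equates their mean across groups — but if the anchor accidentally contains
DIF items, the false alarm rate of the subsequent tests inflates.

`anchorpoint` instead selects an *anchor point*: a scale shift `c` applied to
the focal group's estimates, chosen by maximising an inequality criterion of
the item-wise absolute distances

    d_j(c) = | beta_j(g1) - beta_j(g2) - c |.

Two criteria are provided:

* the **Gini Index** of `d(c)` — maximal when a small minority of items
  carries all the DIF while the majority interlocks; bounded by `1 - 1/m`,
  and independent of the absolute DIF magnitude;
* the **CLF criterion** `-sum_j sqrt(d_j(c)^2 + eps)` from the factor-analytic
  alignment literature (with `eps = 0` by default, the simplified form
  `-sum_j d_j(c)`).

Both criteria, as functions of `c`, can attain optima only at the single-item
shifts `c = beta_j(g1) - beta_j(g2)`, so the continuous search reduces to a
sparse grid of at most `m` candidates. Items are then tested by the anchored
item-wise Wald statistic `t_j = (beta_j(g1) - beta_j(g2) - c) / se_j`,
with standard errors computed under the anchoring restriction.

Beyond the global optimum, the *criterion plot* over the whole search
interval is informative: secondary local optima correspond to alternative
alignments — item clusters that could equally be declared DIF-free, e.g. from
an unaccounted DIF-inducing secondary dimension.

Also included: three classical anchor-selection heuristics as baselines
(constant all-other, constant-four mean-p-value-threshold, iterative
forward), conditional maximum likelihood (CML) estimation with analytic
standard errors via elementary symmetric functions, and a simulation harness
for type-I-error / hit-rate experiments with additive or
secondary-dimension DIF, including label-switching scoring.

## Worked example

The classic illustration: 10 items, the fourth carries 0.75 logits of DIF.
On the true parameters:

```r
library(anchorpoint)
toy <- make_toy()                    # m = 10, item 4 shifted by +0.75
cc <- criterion_curve(toy$beta1, toy$beta2)
cc
#> Anchor point selection over [-4, 4] (2 candidate shifts, 10 items)
#>   GINI global optimum: shift = 0 (value 0.9); local optima at -0.75
#>   CLF  global optimum: shift = 0 (value -0.75)
#> Selected anchor point (gini): shift = 0
```

Both criteria put the global optimum at shift 0 — nine items interlock and
only item 4 shows DIF — and the Gini value there is `1 - 1/10 = 0.9`, its
maximum, regardless of the DIF size. The Gini curve has a secondary local
peak at `-0.75`: the alternative alignment where item 4 interlocks and the
other nine are declared DIF items. `plot(cc)` draws the criterion plot.

On simulated data the whole pipeline is one call:

```r
design <- sim_design(m = 10, n_ref = 1000, n_foc = 1000, dif_items = 4,
                     dif_size = 0.75, seed = 123, beta_range = c(-2, 2))
dat <- generate_study1(design, 1)
fit <- anchorpoint(dat, method = "gini")
fit
#> Anchor point DIF analysis (gini method)
#> Groups: reference (reference, n_used = 982) vs focal (focal, n_used = 975)
#> Selected shift c = 0.2017
#> DIF flagged at alpha = 0.05: Item4, Item7, Item10
```

Item 4 is flagged decisively (`t = -5.85`); in this particular replication
two further items are borderline false alarms — the printed `fit$curve`
shows several shallow local optima, the signature of a noisy alignment worth
inspecting. Averaged over replications the false alarm rate at this
configuration is about 1.5% (`run_simulation(design, methods = "gini",
reps = 150)`), comfortably below the nominal 5%.

Simulation experiments compare methods on identical data:

```r
run_simulation(design, methods = c("gini", "clf", "mpt4"), reps = 150)
#> DIF simulation: Study 1, 10 items, n = 1000/1000, 150 replications (plain scoring)
#>  method false_alarm_rate hit_rate   far_se hit_se reps_ok
#>    gini         0.014815        1 0.003268      0     150
#>     clf         0.007407        1 0.002271      0     150
#>    mpt4         0.038519        1 0.005358      0     150
```

## Main functions

| function | purpose |
| --- | --- |
| `rasch_cml()` | per-group CML fit: difficulties, vcov, log-likelihood |
| `criterion_curve()` | Gini/CLF curves, candidate shifts, global and local optima |
| `wald_test()`, `anchored_wald_test()` | item-wise Wald DIF tests at a shift / anchor set |
| `anchor_allother()`, `anchor_mpt()`, `anchor_forward()` | classical anchor heuristics |
| `anchorpoint()` | full pipeline: fit both groups, align, test |
| `sim_design()`, `generate_study1/2()`, `run_simulation()`, `score_run()` | simulation harness |
| `read_responses()`, `write_*()` | delimited-text / JSON input and output |

See the vignette (`vignettes/anchor-point-selection.Rmd`) for the model,
the operationalisation of the classical heuristics, and all numerical
choices.
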