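---
title: "Anchor point selection for Rasch DIF detection: models, numerics, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor point selection for Rasch DIF detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorpoint)
```

## The model and the alignment problem

The Rasch model gives person $i$ probability
$P(X_{ij} = 1) = \mathrm{logit}^{-1}(\theta_i - \beta_j)$ of solving item
$j$. Differential item functioning (DIF) means an item's difficulty differs
between a reference and a focal group after accounting for ability. Because
the latent scale has no origin, per-group difficulty estimates
$\tilde\beta_j^{(g)}$ are identified only up to a constant: before any
comparison, the focal group's scale must be shifted by some $c$, after which
the item-wise absolute distances

$$d_j(c) = \left|\tilde\beta_j^{(1)} - \tilde\beta_j^{(2)} - c\right|$$

quantify apparent DIF. Classical anchoring derives $c$ from a chosen item
set $A$ as the difference of the anchor means; this package's main method
chooses $c$ directly, as the maximiser of an *inequality* criterion of
$d(c)$ over the interval
$[\min\tilde\beta^{(1)} - \max\tilde\beta^{(2)},\;
  \max\tilde\beta^{(1)} - \min\tilde\beta^{(2)}]$,
within which the two groups' parameter ranges overlap.

Two criteria are implemented. The **Gini Index**, via the rank formula
$GI = \frac{2\sum_j r_j d_j}{m \sum_j d_j} - \frac{m+1}{m}$
(ranks ascending; the value is invariant to tie order and to positive
rescaling of $d$), is 0 for all-equal distances and $1 - 1/m$ when one item
holds everything. Maximising it prefers alignments where few items carry all
the DIF. The **CLF criterion** $-\sum_j \sqrt{d_j^2 + \epsilon}$ comes from
the factor-analytic alignment method; since the search here is grid-based,
no smoothing is needed and $\epsilon = 0$ (the simplified form
$-\sum_j d_j$) is the default, with $\epsilon$ exposed for fidelity to the
original. An inequality criterion is the right notion here — a *norm* of
$d(c)$ would confuse "many small distances" with "few large ones", which
mean opposite things for DIF screening.

Both criteria are piecewise-smooth functions of $c$ whose local and global
maxima can occur only at the single-item shifts
$c = \tilde\beta_j^{(1)} - \tilde\beta_j^{(2)}$. `criterion_curve()`
therefore evaluates the candidates exactly and uses a dense grid (default
1001 points) purely for plotting, never for selection. Candidate differences
closer than $10^{-12}$ are collapsed.

### Ties, local optima, degenerate cases

* **Global ties** (criterion values within $10^{-10}$): the candidate with
  the smaller $|c|$ is designated global and a warning is raised. Ties are
  not an edge case to paper over — with $\epsilon = 0$ the CLF is concave
  piecewise-linear and its maximiser is a *median* of the candidate
  differences, so for even $m$ the two middle candidates tie structurally.
  A tie between distant candidates signals a label-switching situation (two
  item clusters, each internally invariant) and deserves a look at the plot.
* **Local optima** are local maxima of the *continuous* criterion curve.
  They can only sit at candidates, so each non-global candidate is probed
  against the criterion value a small offset to either side ($10^{-3}$ times
  the smallest candidate gap). A neighbouring-candidate comparison would be
  wrong: in the one-DIF toy example the secondary Gini peak at $-0.75$ has a
  *lower* value (0.1) than its only neighbour (the global optimum, 0.9), yet
  it is a genuine local maximum — the curve dips between them. With
  $\epsilon = 0$ the CLF, being concave, has kinks but no secondary peaks;
  the Gini Index is where cluster structure shows up, which is one reason it
  is the default criterion. Each local optimum is reported with a
  *prominence* (its value minus the higher adjacent candidate's value;
  negative when the neighbour is the global optimum).
* **Perfect alignment** ($\sum_j d_j = 0$): the Gini Index is defined as 0
  (the no-DIF case) and a note is emitted.

## CML estimation

Per-group difficulties are estimated by conditional maximum likelihood: the
likelihood conditional on the person raw scores is free of the person
parameters, at the cost of the elementary symmetric functions (ESFs)
$\gamma_r(\epsilon)$ of the easiness parameters
$\epsilon_j = e^{-\beta_j}$. Numerical choices:

* **ESFs** use the summation algorithm with the difficulties centred first;
  the identity $\gamma_r(t\epsilon) = t^r \gamma_r(\epsilon)$ restores the
  requested scale on the log scale, so tests up to $m \approx 100$ items
  with realistic spreads are safe from overflow.
* **First- and second-order partials** (ESFs with one or two items removed)
  are computed by convolving prefix and suffix ESFs — sums of positive
  terms only. The textbook backward-removal recurrence
  $\gamma^{(j)}_r = \gamma_r - \epsilon_j \gamma^{(j)}_{r-1}$ was tried and
  rejected: its cancellation errors grow with $m$ and already stall the
  Newton iteration at 20 items (the gradient cannot get below about
  $10^{-5}$, and the inexact Hessian destroys the quadratic convergence).
* **Optimisation** is Newton–Raphson on the $m-1$ free parameters (first
  difficulty fixed internally), with analytic gradient and observed
  information $\sum_r n_r \,\mathrm{Cov}(X \mid r)$. The conditional
  likelihood is concave, so steps are damped by halving only while the
  log-likelihood is far from the optimum; once the gradient is below
  $10^{-3}$ the pure Newton step is taken, because log-likelihood
  differences are then at rounding level and a line search would stall.
  Convergence requires a maximum absolute gradient below $10^{-8}$ within
  100 iterations.
* **Extreme scores** (0 or $m$ correct) carry no conditional information and
  are dropped, reported via `n_used`; an item with no variance among the
  retained persons stops estimation with an error naming it.
* **Restrictions**: reporting defaults to sum-zero (positive variance for
  every item); `convert_restriction()` moves between sum-zero and
  first-zero, shifting the estimates by a constant and transforming the
  covariance accordingly. All downstream selections and tests are invariant
  to this choice, which the test suite verifies.

## Wald DIF tests and the variance convention

Given a shift $c$, each item is tested with
$t_j = (\tilde\beta_j^{(1)} - \tilde\beta_j^{(2)} - c)/\hat{se}_j$ against
the standard normal. The standard error convention matters more than it
looks. When $c$ derives from an anchor set $A$ (explicitly, or implicitly as
the candidate item(s) of an anchor point), the tested quantity is the
contrast $\tilde\beta_j - \overline{\tilde\beta}_A$ per group, and
$\hat{se}_j$ is computed as the variance of exactly that contrast, summed
over groups. Taking instead the bare vcov diagonals under sum-zero omits the
anchor items' own sampling variance: with a single-item anchor that omission
inflates the null type-I error from 5% to roughly 11% at $m = 20$,
$n = 250$ per group (measured with this package's own harness). With the
contrast variance the tests hold the nominal level for any anchor length,
and an item anchoring itself gets $t = 0$ by construction. The bare-shift
`wald_test(..., anchor = NULL)` keeps the diagonal convention for shifts
that correspond to no anchor set. What is *not* propagated, here as in the
anchor-selection literature generally, is the uncertainty of the selection
itself (which item ends up as the anchor).

No multiple-testing correction is applied by default — false alarm rates are
defined per item — but Bonferroni/BH-adjusted flags are available.

## The classical heuristics, operationalised

The three baselines are published as sketches; this package fixes them as
explicit, deterministic procedures (all ties break by the secondary score,
then the lower item index):

* **constant all-other** (`anchor_allother`): each item tested with all
  others as preliminary anchor; the four items with smallest $|t|$ become
  the anchor. Inherits the assumption that DIF cancels out; under unbalanced
  DIF its false alarm rate grows with the sample size, which the simulation
  suite reproduces.
* **constant four MPT** (`anchor_mpt`): all single-anchor analyses are run;
  each item collects $m - 1$ p-values; the threshold is the grand mean of
  all collected p-values; an item's score is how many of its p-values exceed
  the threshold; the top four are the anchor (ties: larger mean p-value).
* **iterative forward** (`anchor_forward`): items ranked by mean $|t|$ over
  the single-anchor analyses; the anchor grows along that ranking and stops
  as soon as it is longer than the number of currently significant
  non-anchor items.

The anchor length of four for the constant methods follows the convention of
the comparison studies this design mirrors. The mean-p-value threshold and
the exact stopping rule are this package's explicit readings of the cited
procedures; the originals leave room for interpretation, so simulation
comparisons against published numbers should be read qualitatively.

## The simulation harness

`sim_design()` fixes a scenario; defaults are chosen once as a realistic
two-group testing situation and are not tuned per experiment: item
difficulties equally spaced on $[-2.5, 2.5]$, DIF size 0.6 logits, no
impact (focal ability mean shift 0), group sizes 500, and for the
secondary-dimension study a loading of 1.0 and a group gap of 1.0 on
dimension 2 (the focal group lower, so positive gaps disadvantage the focal
group exactly as unbalanced additive DIF does).

* **Study 1 (additive DIF)**: abilities $N(0,1)$ reference,
  $N(-\mathrm{impact}, 1)$ focal; the focal group's difficulties for the DIF
  items are shifted by the DIF size — all in one direction (unbalanced) or
  alternating (balanced); responses Bernoulli under the Rasch model.
* **Study 2 (secondary dimension)**: independent bivariate normal
  abilities; all items load 1 on dimension 1, DIF items additionally load on
  dimension 2, where the groups differ; responses from the compensatory
  two-dimensional logistic model. With no secondary loadings the generator
  consumes the identical random stream as the Study-1 null case and
  reproduces it exactly — a deliberate property that makes the reduction
  testable bit-for-bit.

Every replication derives its own seed from `(seed, rep_index)`, so methods
see identical data within a replication (paired comparisons) and any single
replication can be regenerated in isolation. Rates are means of
per-replication rates with Monte-Carlo standard errors, and failed
replications are counted, never silently dropped.

**Label switching.** When a majority cluster of items shares the same DIF,
"the cluster is DIF-free" and "the complement is DIF-free" are equally valid
solutions. `score_run(..., mode = "label_switching")` scores both labelings
and keeps the one with smaller total error $FAR + (1 - HIT)$. In the
60%-DIF scenario this is the difference between a hit rate near zero and
near one for the Gini method.

**What the generator does and does not emulate.** It produces clean,
complete, unidimensional-plus-one-nuisance-dimension binary data with known
truth — exactly what is needed to measure error rates of the methods. It
does not emulate missingness, guessing or varying discrimination, local
dependence beyond the one secondary dimension, or impact/DIF correlation;
passing simulations therefore validate the statistical machinery, not
robustness to those real-data complications.

**Problem sizes used by the shipped tests.** The package's own acceptance
checks run at desk scale, chosen to keep the whole suite in a few minutes:
the null type-I-error check uses 500 replications of 20 items on $[-2, 2]$
with 250 persons per group; the unbalanced-40%-DIF pattern uses 200
replications at $n \in \{250, 500, 1000\}$ with 20 items; the 60%-DIF
label-switching comparison uses 200 replications with 10 items at $n = 500$.
The corresponding published experiments used 10,000 replications and longer
tests; `reps` scales up when more precision is wanted.

## Known limitations

* Two groups only; the sparse-grid result makes pairwise multi-group
  extensions straightforward in principle, but they are not implemented.
* Dichotomous Rasch only — one parameter per item; no 2PL/polytomous
  support, hence no alignment of discriminations or group variances.
* Missing responses are rejected, not modelled.
* CML only; the criteria themselves would apply to any consistent
  item-parameter estimates, but no other estimation route is provided.
* Anchor-selection uncertainty is not propagated into the final tests.

```{r toy}
toy <- make_toy()
cc <- criterion_curve(toy$beta1, toy$beta2)
cc
plot(cc)
```
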