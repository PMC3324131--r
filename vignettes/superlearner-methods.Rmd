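---
title: "Methods: cross-validated Super Learner analysis of resistance genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-validated Super Learner analysis of resistance genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slgeno)
```

## The estimation problem

For patient $i$, $X_i \in \{0,1\}^p$ indicates presence of each of $p$
reverse-transcriptase resistance mutations (here the ten-mutation ddI
panel) and $Y_i$ is the week-4 change in plasma HIV-1 RNA in
$\log_{10}$ copies/mL (ΔVL; negative values are reductions, i.e.
response). The target is the regression $E(Y \mid X)$, and the practical
question is which of several heterogeneous learners estimates it best
on roughly one hundred patients — a regime where in-sample fit is
dominated by overfitting and learner choice must be driven by
cross-validated risk.

## Loss functions and cross-validated risk

Two losses score a prediction vector against the observed outcomes:

* **SqE**, the mean of $(Y - \hat Y)^2$ — unbounded, scale-sensitive;
* **1 − R**, one minus the Pearson correlation of $Y$ and $\hat Y$ —
  bounded in $[0, 2]$ and invariant under positive affine maps of the
  predictions, so it scores ranking/shape rather than calibration.

$k$-fold cross-validation partitions the patients into $k$ mutually
exclusive, exhaustive folds of as nearly equal size as possible
(`make_folds()`, unstratified, seeded). Each learner is fitted on each
fold's complement and predicts the fold; the $k$ fold risks are
averaged into the cross-validated risk. Four fold schemes are studied
($k = 10, 4, 3, 2$, i.e. 90/75/66/50% training fractions); within a
run one fold assignment per $k$ is shared by every learner and loss so
that rank differences are not fold noise. Learners are ranked per
$(k, \text{loss})$; exact ties (equality after rounding to 10 decimals)
receive the mean of the positions they span, so two learners tied at
the top are both ranked 1.5.

**Numerical conventions.** A constant prediction (or outcome) vector
has no defined correlation; the package takes $R = 0$, risk 1, with a
warning. For 1 − R the default is the per-fold-then-average risk (the
average of within-fold correlations), matching the averaging wording of
the framework; a pooled variant (`pooled = TRUE`) exists for
sensitivity analysis because the original description does not say
which was used.

## The six candidate learners

Defaults are the published tuning; all stochastic learners take an
explicit seed, by default derived from the pipeline master seed plus a
stable learner-name hash so adding a candidate never perturbs the
others' randomness.

* **LM(1)** — least squares on intercept + $p$ main terms, no
  selection.
* **LM(2)** — adds all $p(p-1)/2$ two-way products (56 parameters at
  $p = 10$). At $n \approx 102$ the design is ill-conditioned or
  rank-deficient; the fit is the SVD minimum-norm least-squares
  solution — deterministic, and it reproduces the characteristic
  in-sample overfit that motivates the whole exercise.
* **CART** — binary regression tree; a split is kept only if it lowers
  training RSS by at least $cp \times$ root RSS (cp = 0.01), with a
  minimum of 5 observations per leaf (added because unrestricted leaves
  degenerate at $n \approx 100$).
* **Random forest** — 1,000 bootstrap-aggregated unpruned trees,
  $m_{try} = \lfloor p/3 \rfloor = 3$ variables sampled per node,
  prediction averaged over trees. With `bootstrap = FALSE`,
  `m_try = p`, `n_trees = 1`, it reduces exactly to an unpruned CART —
  a tested sanity bridge between the two tree implementations.
* **D/S/A** — a deterministic search over linear models whose terms are
  products of mutation indicators, by single-term deletion /
  substitution / addition moves; the best model of every size
  $0..maxsize$ ($maxsize = 2p = 20$) is recorded. On binary covariates
  $x^2 = x$, so powers are canonicalized to 1 and
  $maxsumofpow = maxorderint = 2$ jointly cap the interaction order at
  two — logged, not silently ignored. Term-subset RSS is evaluated
  through a precomputed Gram matrix with a $10^{-10}$-scale ridge for
  numerical definiteness.
* **Logic regression** — $y \approx b_0 + b_1 L(X)$ with $L$ a single
  AND/OR tree over possibly negated mutation literals, searched by
  simulated annealing over the move set {alternate leaf, alternate
  operator, grow branch, prune branch, split leaf}, $(b_0, b_1)$
  refit in closed form at every state. Schedule: geometric cooling over
  10,000 iterations, start temperature set from a 100-move pilot so
  about half of uphill moves are accepted, final temperature $10^{-6}$
  of the start (acceptance effectively zero), best-visited state kept.
  The original study fixed none of this, so the single-tree setup and
  schedule are package conventions.

**Internal size selection (D/S/A, logic regression).** Both learners
choose their size by internal 5-fold cross-validation, as the source
study states without detail. The package uses the 1-SE parsimony rule:
the smallest size whose CV risk is within one standard error of the
minimizer. A bare argmin is unstable between nested sizes — at low
noise the extra coefficient moves CV risk by far less than fold noise,
making the selected size a coin flip — whereas the 1-SE rule is the
standard remedy (cf. `rpart`, `glmnet`) and makes planted-model
recovery reproducible. Logic regression's CV also includes size 0 (the
intercept-only model), so pure-noise outcomes collapse to the trivial
model rather than a spurious one-leaf tree. Inside the CV the annealing
runs a shorter schedule (default 1,000 iterations per candidate size;
the final full-data search uses the full 10,000) — the per-size
searches are small and this keeps the learner inside a desk-scale time
budget.

## Super Learner construction

The out-of-fold predictions form the level-one matrix $Z$
($n \times L$, every entry produced by a model that never saw that
patient's fold). Two rosters are studied: SL-5 (LM(1), LM(2), random
forest, D/S/A, CART) and SL-6 (SL-5 plus logic regression).

* **Discrete Super Learner** — the learner with minimum mean
  cross-validated risk; exact ties go to the earliest learner in the
  fixed roster order (LM(1), LM(2), RF, D/S/A, CART, LogicReg) —
  deterministic and documented.
* **Weighted Super Learner** — weights on the probability simplex
  minimizing the pooled risk of $Zw$. Under SqE this is a
  non-negativity-constrained quadratic program (`quadprog`, with a
  $10^{-8}$-scale ridge so duplicate columns stay solvable; weights
  below $10^{-8}$ are zeroed and renormalized). Under 1 − R the
  objective $\mathrm{cor}(y, Zw)$ is scale-invariant and non-convex on
  the simplex; it is maximized by projected-gradient ascent from 20
  starts (the $L$ vertices, the barycenter, and seeded random simplex
  points), converging when the improvement drops below $10^{-10}$. In
  both cases the returned weights are finally compared against every
  simplex vertex and the best is kept, which makes the level-one
  dominance property (Super Learner risk ≤ every single learner's
  level-one risk, under the fitting loss and pooled functional) exact
  rather than approximate.

The SL row of a CV risk table defaults to the per-fold-averaged risk of
the weighted level-one column — the same functional as the learner
rows, and consistent with the source tables where the Super Learner row
can tie the top learner exactly. This number is optimistic about the
weight fitting (the weights saw those predictions); an honest variant
(`honest_sl_risk()`, an outer CV wrapped around the entire Super
Learner) is available behind a flag, and the tests check its risk is
no smaller on average. The source study is ambiguous about which was
reported; one of its printed Super Learner rows (SqE, six-learner
roster, clearly above the best candidate) is incompatible with
simplex-constrained fitting on shared level-one data and is not
reproduced.

## Full-dataset evaluation

Every model refitted on all data is scored by SqE, pooled 1 − R, and
$R^2$ defined as the squared Pearson correlation (not
$1 - SS_{res}/SS_{tot}$): that definition is invariant under positive
affine maps and satisfies $R^2 = (1-(1-R))^2$ whenever $R \ge 0$, the
identity the published full-model rows obey to printed precision.
Patients are classified as responders when ΔVL ≤ threshold (−0.5 or
−0.6 log₁₀ copies/mL; equality counts as response — ties are
measure-zero for continuous predictions); accuracy is the fraction of
patients whose predicted and observed status agree.

## The synthetic-data generator

Patient-level trial data are not public, so the package ships a
generator stating the published world: $n = 102$; mutation indicators
marginally Bernoulli with the ten published prevalences (48%, 34.3%,
8.8%, 26.5%, 8.8%, 18.6%, 92.2%, 27.5%, 53.9%, 24.5%); outcome
$\text{intercept} + X\beta + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$.

The study reports outcome marginals but no effect sizes, so the
packaged effects are frozen calibration constants chosen once by moment
matching, not estimates of real ddI mutation effects: $\beta = (0.30,
0.15, 0.10, 0.20, 0.40, 0.10, 0.25, 0.15, 0.30, 0.10)$ log₁₀ copies/mL
(resistance mutations attenuate the drug-induced reduction, so effects
are positive on the ΔVL scale), intercept −1.33, $\sigma = 0.735$.
These imply a marginal mean of −0.56 (the published median) and sd
≈ 0.79, hence an IQR of about (−1.09, −0.03) against the published
(−1.2, −0.14) — inside the stated tolerance; the mild left-skew of the
real IQR (midpoint −0.67 vs median −0.56) is not modelled. The
published <50 copies/mL censoring acted on RNA levels, which would
require baseline viral loads; it is emulated as a ΔVL floor at −1.53,
the ≈11% lower quantile of the uncensored marginal, matching the
reported 11% censored fraction. The floor sits below the 25% quantile,
so it does not move the median or IQR. Mutations are independent by
default; a Gaussian-copula correlation block exists because
thymidine-analogue mutations co-occur in reality, but no joint
distribution was published — correlation is a sensitivity knob, not a
calibrated fact.

What a green test therefore establishes: that the pipeline behaves
correctly on data with the trial's marginal structure — not that any
numeric table cell of the original analysis is reproduced, which would
require the non-public data. Planted-truth generators
(`generate_planted_boolean()`, `generate_planted_polynomial()`) supply
exactly recoverable models for the learner-recovery tests.

## Determinism, seeds and scaling

The pipeline is a pure function of (dataset, configuration, master
seed): fold seeds and learner seeds are derived from the master seed by
a stable string hash, RNG state is saved and restored around every
seeded block, and rerunning a configuration reproduces every file
bit-for-bit. Test and acceptance runs scale down the expensive knobs
(forest size, annealing iterations, fold lists) where the property
under test does not depend on them — e.g. level-one dominance is a
property of the weight fit, not of candidate quality — while the
printed defaults themselves are asserted by a dedicated configuration
test.

## Known limitations

* Single-tree logic regression only; multi-tree models and
  classification-mode trees/forests are out of scope.
* The 1 − R weight objective is non-convex; multi-start projected
  gradient matches an exhaustive simplex grid on small instances (a
  tested property) but carries no global guarantee at larger $L$.
* Censoring is emulated in ΔVL space (see above), not at the RNA-level
  of the assay.
* The D/S/A implementation records the best model *of size at most*
  $s$; with the tiny Gram ridge, reported RSS values are exact to
  $\sim 10^{-8}$ relative accuracy.
* Sequence-level input assumes pre-aligned amino-acid sequences;
  alignment and codon translation are out of scope. Indeterminate
  residues (gaps, X) at a pattern position are called 0 with a warning
  — absence of evidence, a convention the source did not discuss.
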