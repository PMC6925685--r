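---
title: "Weighted consensus localization: model, optimizer and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted consensus localization: model, optimizer and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locfuse)
```

## The model

Bacterial protein localization predictors are heterogeneous: they
differ in the compartments they cover, in their per-compartment skill,
and in whether they emit probabilistic scores or a single label. The
consensus model treats each of $n$ base predictors as a fixed feature
generator. Predictor $i$ contributes, per sequence, a normalized score
vector $x_i = (x_{i,1}, \dots, x_{i,m})$ over the $m$ canonical
compartments; label-only tools are one-hot encoded first, and every
vector is L1-normalized so probabilistic and label-only tools are
commensurable. The fused score for compartment $j$ is

$$S_j \;=\; \sum_{i=1}^{n} w_{i,j}\, x_{i,j},$$

and the sequence is assigned to $\arg\max_j S_j$. The weights are the
only trained quantities. Two layouts are supported: one weight per
predictor ($d = n$, the strict form of the weighted-sum rule) and one
weight per predictor and compartment ($d = n \cdot m$, the default).
The per-class layout subsumes the per-predictor one and is what makes
the method more than re-ranking: a tool that is excellent on the inner
membrane but blind to the periplasm can be trusted selectively.

Because the decision is an argmax, multiplying all weights by a
positive constant changes nothing; the weight box $[0,1]^d$ therefore
loses no generality for nonnegative weightings, and reported
"confidence" scores are simply the L1-normalized fused vector — a
monotone, rank-preserving transform, not a calibrated probability.
The second-ranked compartment is reported as a candidate alternative
location for multi-compartment proteins; no thresholded multi-label
call is made.

### Fitting by particle swarm

The training objective is plain accuracy — correct calls over
instances — which is piecewise constant in $w$, non-differentiable,
and full of plateaus. The optimizer is a particle swarm with
time-varying acceleration coefficients: each particle carries a
position $X$ (a weight vector) and velocity $V$, updated as

$$V \leftarrow \omega V' + c_1 r_1 (Pb - X') + c_2 r_2 (Pg - X'),
\qquad X \leftarrow X' + V,$$

where $Pb$ is the particle's best-known position and $Pg$ the swarm's.
Over a run of `max_calls` objective evaluations the cognitive
coefficient decays linearly $c_1: 2.5 \to 0.5$, the social coefficient
grows $c_2: 0.5 \to 2.5$, and the inertia decays
$\omega: 0.9 \to 0.4$ — exploration first, convergence on the swarm
optimum later. One *objective call* is one full-dataset accuracy
evaluation of one particle; the schedules advance on this call counter.
When an iteration budget `max_iter` is set instead, the call budget is
ignored and the schedules interpolate on iterations.

```{r schedules}
cfg <- swarm_config()
data.frame(calls = c(0, 500, 1000),
           omega = omega_at(c(0, 500, 1000), cfg),
           c1 = c1_at(c(0, 500, 1000), cfg),
           c2 = c2_at(c(0, 500, 1000), cfg))
```

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `omega_max`, `omega_min` | 0.9, 0.4 | inertia at the start / end of a run (dimensionless) |
| `c1_max`, `c1_min` | 2.5, 0.5 | cognitive coefficient, start / end |
| `c2_min`, `c2_max` | 0.5, 2.5 | social coefficient, start / end |
| `n_particles` | 25 | swarm size |
| `max_calls` | 1000 | objective-call budget and termination criterion |
| `max_iter` | unset | iteration budget; overrides `max_calls` when set |
| `lower`, `upper` | 0, 1 | per-dimension weight bounds |
| `v_max` | `upper - lower` | per-dimension velocity cap |
| `seed` | 1 | makes a run bit-reproducible |

The coefficient defaults are the widely used time-varying settings for
this swarm variant and are not worth touching; `max_calls` is the one
knob that trades fit quality for time, and 1000 calls is ample for the
committee sizes (4–10 tools) this problem presents.

## Numerical and design choices

- **Normalization.** Per-sequence L1 normalization (divide by the
  vector sum). An all-zero vector — a predictor abstaining or failing
  on a sequence — is kept all-zero so the tool contributes nothing to
  the fused sum for that sequence, rather than inventing a prior.
- **Tie-breaking.** All argmax decisions (consensus, majority vote,
  standalone predictor argmax) break ties by canonical compartment
  order, which is fixed per vocabulary. Ties and all-zero fused
  vectors are flagged `low_confidence` in the output so affected
  sequences can be audited.
- **Bound handling.** Velocities are clamped to $\pm v_{\max}$ and
  positions to the weight box after every update — standard practice;
  the capped velocity prevents divergence on the accuracy plateaus.
- **Corner seeding.** The first $n$ particles start at predictor
  corners (full weight on one tool, zero elsewhere). Since a corner
  reproduces that tool's standalone predictions exactly and the global
  best never decreases, the fitted consensus provably never
  underperforms the best individual predictor on training data. This
  makes the weaker form of the method's headline claim structural
  rather than empirical.
- **Random draws.** $r_1, r_2$ are drawn independently per dimension
  per update; a shared-draw-per-particle variant is available via
  `swarm_config(shared_draws = TRUE)`.
- **Global-best ties.** The first achiever keeps the title; strict
  improvement is required to replace it. Together with the seeded RNG
  this makes runs deterministic.
- **Fixed weights.** A configuration may pin per-tool weights; those
  dimensions are frozen (velocity zeroed) during optimization.
- **Degenerate inputs.** Empty committees in an ablation case are
  reported as an explicit untestable (`NA`) row, never fitted. Empty
  label vectors are rejected rather than returning 0/0.

### Committee ablation

The robustness protocol refits the consensus on reduced committees:
drop the single best tool, or keep only tools at-or-above / below
accuracy thresholds 0.9, 0.8, 0.7, 0.6 — nine canonical cases. Two
open choices were resolved as follows. Committee selection uses
per-predictor accuracy on the *test* split by default, which mirrors
the protocol the thresholds refer to but leaks test information into
committee membership; `select_on = "train"` is provided for a clean
variant. And each case re-optimizes weights on the reduced committee
from scratch (the stronger reading), rather than reusing
full-committee weights restricted to the survivors.

## The synthetic committee generator

Real base predictors are web services; nothing here calls them.
Instead, the generator draws labeled committees with controllable
skill structure. A predictor profile is an $m \times m$ row-stochastic
confusion matrix (row = true compartment, column = the compartment the
tool's argmax lands on; the diagonal is its expected per-class
accuracy) plus a concentration for probabilistic tools. For each
sequence and tool an emitted class is drawn from the confusion row of
the true class; label-only tools contribute its one-hot, probabilistic
tools a sharpened simplex draw — a flat Dirichlet vector mixed with
the emitted one-hot at fraction $\kappa/(1+\kappa)$, with a
deterministic swap of the top entry into the emitted slot in the rare
case the mix's argmax strays (this guarantees the argmax contract at
every $\kappa$, at the cost of a slight distortion of the score
distribution's tail). Predictor errors are independent across tools by
default; a `correlation` knob couples their correct/incorrect draws
through a shared per-sequence difficulty, because the value of fusion
degrades exactly as errors correlate and that should be testable.

`table2_like_scenario()` is the standard fixture: a generalist
(perfect on the first $m-2$ compartments, 50% on the last two), a
specialist (perfect on the last two, weak elsewhere, with errors
confined to the first $m-2$ so it rarely over-calls its specialty), a
near-random tool (30% everywhere) and a label-only tool that always
emits the second compartment — the one-class-dominant pathology real
committees exhibit. Every compartment is covered by *some* tool at
per-class accuracy 1, while the best individual tool stays near 80%
overall, so a weighted consensus has genuine headroom and the
qualitative claim — fusion strictly beats every individual — is
testable. Class priors are balanced, matching the balanced training
sets the method targets; 500 sequences is the fixture's default, large
enough that per-class accuracies are stable to a few percent.

```{r fixture}
mat <- simulate_committee(table2_like_scenario("gram_positive", seed = 1,
                                               n_sequences = 300))
report_table(per_predictor_report(mat))
fit <- fit_consensus(mat, swarm_config(max_calls = 400, seed = 1))
fit$fitness
```

### What the synthetic data does not show

The generator emulates per-class skill heterogeneity, abstentions,
label-only tools and error correlation. It does not model sequence
homology between training and test sets, class imbalance (unless
priors are set), systematic biases shared by tools trained on the same
databases, or covariate shift between organisms. Passing tests on
these fixtures therefore demonstrate the *machinery* — that the
optimizer finds weightings exploiting complementary skill — not that
any particular accuracy will be attained on real committees, which
depends entirely on the real tools' error structure.

## Problem sizes used in the test suite

The shipped tests run the optimizer at full default budget (1000
calls) on 500-sequence fixtures for the headline property checks, at
reduced budgets (50–300 calls, 8–25 particles) for structural checks
where the property holds at any budget, and validate the optimizer
against an exhaustive lattice oracle (step 0.1) on instances with 2–3
tools and at most 20 sequences, where enumeration is exact. Generator
calibration is checked at 5000 sequences against a three-standard-error
binomial band.

## Known limitations

- Confidence scores are rank-preserving normalizations, not calibrated
  probabilities; they should not be compared across committees.
- Training accuracy is the sole objective; with very small training
  sets and many weights ($n \cdot m$), the optimizer can overfit —
  prefer `weights_per = "predictor"` when labeled data is scarce.
- The swarm is a global heuristic: it matches the lattice oracle on
  small instances, but no optimality guarantee exists beyond the
  corner-seeding floor.
- Multi-location proteins receive a ranked list only; no threshold for
  calling multiple compartments is fitted.
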