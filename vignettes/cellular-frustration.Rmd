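---
title: "Cellular frustration for semi-supervised anomaly detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular frustration for semi-supervised anomaly detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfadetect)
```

## The model

cfadetect implements an immune-inspired anomaly detector built on *cellular
frustration*. A sample with $N_f$ numeric features is displayed by $N$
*presenter* agents (after optional feature replication, one presenter per
feature column). Presenter $i$ shows the signal

$$ s_i = i + \frac{x_i - x_{i,\min}}{x_{i,\max} - x_{i,\min} + \epsilon}, $$

so signals of different presenters occupy disjoint unit intervals;
$x_{i,\min}, x_{i,\max}$ are training extremes and $\epsilon$ is a
machine-epsilon-scale guard. Facing the presenters are $N$ *detector*
agents. Each detector displays a digit (1 or 2) and is connected to $C$
random presenters; for each connection it perceives the signal through a
one-sided tail test on the training empirical CDF $F_i$: with a tail side
(left/right, equiprobable) and a tail probability $v \sim U(0, v_{\max})$,
the signal is a *rare* token $r_i$ when $F_i(s_i) < v$ (left) or
$F_i(s_i) > 1 - v$ (right), and a *frequent* token $f_i$ otherwise. Values
strictly outside the training range are rare to every detector on the
matching side, whatever its $v$ — they are signals never displayed during
training. Each detector ranks its $2C$ tokens in an interaction list
(IList); each presenter ranks the two digits (subtype I prefers 1, subtype
II prefers 2).

All agents continuously pair and unpair, as in stable-marriage dynamics:
two alone agents always pair; a paired agent switches to an alone newcomer
only under strict preference; two paired agents switch only under mutual
strict preference; every break resets the pairing ages involved. One global
iteration visits all $2N$ agents in a fresh random order, each drawing one
uniform counterpart from its interaction set, and then ages every intact
pair by one. In a *frustrated* population any pairing can be destabilised
by a third agent, so no stable matching persists — `build_toy_population()`
is the minimal cyclic-preference demonstration.

## Training (repertoire education)

Training maximises frustration on normal data by editing the ILists of
detectors that pair too long. A training sample is displayed and redrawn
uniformly every $T_S$ iterations. Any detector paired for at least the
adaptive threshold $\tau_n$ is educated and unpaired; at the end of a
window of $W_\tau$ iterations with no educations, $\tau_n$ drops to the
largest pairing age seen in that window, so its trace is nonincreasing.
Two education strategies are implemented:

* **IS** (negative selection): the educable region of the IList is replaced
  by a fresh uniform permutation — a new detector from the pool;
* **AIS** (targeted swap): the token sustaining the long pairing is swapped
  with a uniformly drawn token at a strictly lower educable rank.

Rare tokens of opposite-subtype presenters are pinned ("frozen") to the
bottom ranks so the absence of a frequent signal cannot be compensated by
its rare twin. `build_repertoire()` repeats education $N_{pop}$ times with
shared connectivity and perception maps, yielding exchangeable IList sets.

Training must stay *bounded*: completely ordered ILists leave no room for
anomalies to perturb the dynamics, and detection vanishes. We observed this
directly — educating far past the stall point of $\tau_n$ ordered every
IList fully and reduced co-occurrence detection to chance. The packaged
operating point educates to the duration target $\tau_{target} = 180$
iterations, the same target used for the convergence benchmarks, which
preserves a partially ordered top (a property of the training-data
variability, not of the algorithm's patience).

## Why the targeted swap is faster: absorbing-chain theory

Education of a single list of $N$ items (two types, $N/2$ each; top $n$
positions to correct) is an absorbing Markov chain over waiting states
$W_m$ ($m$ correct items on top), education states, and the absorbed state.
From $W_m$ education triggers with probability $(n-m)/N$. Negative
selection redraws the whole list, landing on $W_m$ with binomial
probability $\binom{n}{m}/2^n$ and absorbing with $1/2^n$; the targeted
swap corrects one item at a time, moving up with probability $\tfrac12$ in
the $N \gg n$ approximation. Expected absorption times have closed forms
(`K_E_IS()`, `K_W_IS()`, `K_W_AIS()`), verified against a
fundamental-matrix solve to $10^{-9}$ relative error, and against a direct
simulator of the explicit list process (`simulate_education()`):

```{r markov}
markov_table(c(2, 4, 8), N = 100)
K_W_IS(0, 8, 100) / K_W_AIS(0, 8, 100)
```

Two simulator choices matter. The chain's binomial education outcome is
exact only if a fresh list draws its item types independently (a new
detector from a large receptor pool); permuting the same finite list would
give hypergeometric top-$n$ occupancy and disagree strongly at small $N$,
so the simulator redraws types i.i.d. for negative selection. For the
targeted swap, the simulator keeps the finite list: its correction
probability is $(N/2 - m)/(N - n)$, which approaches $\tfrac12$ as $N/n$
grows; the residual finite-$N$ bias (about 2% at $n = 8, N = 100$) is a
property of the printed approximation, not of the code. Entering education
costs one step, matching the chains' education states.

## Detection

Monitoring fills every detector slot with a uniformly drawn repertoire
member and runs $W_d$ iterations under the displayed sample, with *anergy*:
any detector pairing reaching age $\tau_A$ is terminated, both members'
survival counters increment at $\tau_A$, and the slot is refilled by a
random repertoire member. Counters give, per presenter, $c_{i,s}(\tau)$ =
contacts surviving at least $\tau$ iterations ($\tau = 0..\tau_A$); each
paired agent counts at its current age and then ages, so
$\tilde c_{i,s} = c_{i,s}(\tau_{act})/c_{i,s}(0)$ is a survival fraction in
$[0,1]$ (defined 0 when no contact formed). Calibration runs monitoring on
the normal training samples and sets the activation threshold of presenter
$i$ to the $x$-th largest $\tilde c$ over samples, $x = \lceil N_c f
\rceil$; by construction a fraction $\approx (x-1)/N_c \approx f$ of normal
samples exceed each presenter's threshold. The response of a sample is

$$ R_s = \sum_i \left(\tilde c_{i,s} - \tilde n_i\right)
         \theta\!\left(\tilde c_{i,s} - \tilde n_i\right), $$

and performance is summarised as the true-positive rate at a fixed
false-positive rate: the decision threshold is the $\lceil N \cdot FPR
\rceil$-th largest normal test response and TPR counts anomalous responses
strictly above it (`tpr_at_fpr()`, `roc_curve()`). Two counting-rule
baselines are provided: rare signals per sample at a fixed tail size
(`baseline_rare_count()`, tail 0 = outside the training range) and rare
perceptions in the detectors' ILists (`baseline_ilists_rare_count()`).

## The synthetic generator

`generate_synthetic()` emulates the three anomaly mechanisms a frustrated
detector can sense:

1. **outlier** — one feature per sample is pushed beyond the normal
   training range by `anomaly_magnitude` times the range;
2. **excess_absence** — $\lceil N_f/4 \rceil$ features are shifted into
   their 2% tails simultaneously, so more frequent signals go missing at
   once than training ever showed;
3. **broken_combination** — correlated pairs are decoupled by independently
   permuting one member over the anomalous set (marginals exactly
   preserved, co-occurrence destroyed).

Normal samples couple the declared feature pairs through a shared-quantile
mixture: with probability $\rho$ (default 0.9) the pair shares its
quantile, else it draws independently. This choice is deliberate: a
Gaussian copula at the same correlation has vanishing tail dependence, so
its pairs are correlated in the bulk while their *rare signals* — the tail
events detectors actually perceive — almost never coincide, leaving no
co-occurrence for mechanism 3 to break. Marginals are exact under both
couplings.

What the generator does not emulate: heteroscedastic or heavy-tailed
marginals, label noise, drifting distributions, and anomalies spanning many
features at once (real anomalous classes typically deviate in many
features, which is considerably easier). Passing tests on this generator
therefore show that each mechanism is detectable in isolation at the stated
scale, not that real-data accuracy is matched.

## Numerical and protocol choices

* ECDF convention: $F_i(x)$ = (training values $\le x$)/$n$,
  right-continuous; tail tests use strict inequalities. Out-of-range values
  carry a sentinel CDF just outside $[0,1]$ so they are rare at every $v$.
* $\epsilon$ = the feature range times $2^{-32}$ (with a small floor), so
  $s_i < i + 1$ holds strictly in floating point for every presenter index
  and every in-range signal stays strictly below the clip value
  $i + (1 - 2^{-33})$ used for above-range test values; below-range values
  clip to $i$. A bare machine-epsilon guard fails this: $i + (1 -
  2.2\times10^{-16})$ rounds to $i + 1$ already at $i = 1$.
* Feature replication: when $N_f \le 32$, columns are tiled the smallest
  even number of times exceeding 32 presenters. Small populations can lock
  into stable matchings; replication also spreads one anomalous feature
  over several presenters, which is what makes single-feature anomalies
  reliably detectable. At the package's desk scale, a single anomalous
  feature among 40 *unreplicated* presenters yields TPR around 0.25–0.30 at
  10% FPR — the per-presenter signal is capped by anergy redraws and by the
  presenters' two-rank preference ties — whereas an iris-scale dataset
  (4 features replicated to 40 presenters) reaches about 0.8. This is a
  property of the method worth knowing before applying it to wide data.
* Sweep order: a fresh uniform permutation of all $2N$ agents per
  iteration, avoiding systematic presenter-before-detector bias. Educated
  detectors re-enter the dynamics immediately. The per-iteration
  counterpart draw does not exclude the current partner (a self-draw fires
  no branch).
* Degenerate AIS education (partner token frozen or already at the last
  educable rank): the detector is unpaired without a swap — unpairing alone
  removes the stable pair.
* Monte-Carlo cross-validation resamples the training subset each fold
  (folds are not a partition); every fold derives its seed from one master
  seed, and all randomness flows through R's RNG (`set.seed()` reproduces
  entire runs bit-for-bit).
* Desk-scale problem sizes used throughout the tests and the acceptance
  script: $W_\tau = 2000$, $\tau_{target} = 180$, $N_{pop} = 4$,
  $W_d = 2000$, 200 normal/100 anomalous synthetic samples, 3–5 folds.
  These are the package's chosen benchmark sizes; the full-scale defaults
  ($W_\tau = W_d = 10^4$, $N_{pop} = 12$, 10 folds) remain the documented
  defaults of `run_config()`.

## Known limitations

* One-sided detectors only; two-sided perception maps are out of scope.
* The co-occurrence (mechanism 3) signal is intrinsically weak: it lives in
  the $\sim v$-probability tails of the decoupled features, so only the
  minority of anomalous samples displaying a lone tail event can score
  high. Expect TPR modestly above the counting-rule baselines, not high
  absolute rates — consistent with the mechanism's role as a
  last-line-of-defence channel.
* The adaptive threshold $\tau_n$ cannot fall below the typical
  window-maximum pairing age, so education depth saturates; pushing past
  saturation harms detection (see Training above).
* Monitoring responses are stochastic; fold-to-fold TPR spread of ±0.1 at
  the desk scale is normal and the cross-validated mean is the meaningful
  statistic.
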