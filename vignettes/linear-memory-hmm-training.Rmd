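---
title: "Linear-memory parameter training for hidden Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear-memory parameter training for hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linhmm)
```

## The model and the training problem

`linhmm` works with first-order hidden Markov models over a finite alphabet
$\mathcal{A}$, with states $S = \{0, 1, \dots, M\}$ where state $0$
(`Start`) and state $M$ (`End`) are the only silent states. A model is
defined by transition probabilities $t_{i,j}$ with
$\sum_j t_{i,j} = 1$ for every state $i$, and emission probabilities
$e_i(y)$ with $\sum_{y \in \mathcal{A}} e_i(y) = 1$ for every emitting
state. A state path $\Pi = (\pi_0, \pi_1, \dots, \pi_{L+1})$ for an
$L$-symbol sequence $X$ runs from `Start` to `End` and emits one symbol per
non-silent state, so a complete path uses $L + 1$ transitions and $L$
emissions.

All three training algorithms in this package are iterative count-based
procedures. In iteration $q$ they collect, for every training sequence,
the number of times $T_{i,j}$ each transition and $E_i(y)$ each emission
is used by some set of state paths, and re-estimate

$$ t_{i,j}^{q+1} = \frac{\sum_n T_{i,j}^q(X^n)}{\sum_{j'} \sum_n T_{i,j'}^q(X^n)},
\qquad
e_i^{q+1}(y) = \frac{\sum_n E_i^q(y, X^n)}{\sum_{y'} \sum_n E_i^q(y', X^n)}. $$

They differ only in *which* paths contribute the counts:

* **Viterbi training** uses the single best path $\Pi^*(X)$ per sequence
  and stops when the paths no longer change;
* **stochastic EM training** uses $K$ paths per sequence sampled from the
  posterior $P(\Pi \mid X)$ and stops when the log-likelihood change is
  small or after a fixed number of iterations;
* **Baum-Welch training** (the baseline) uses posterior-*expected* counts
  over all paths, with the same stopping rule.

The classical implementations are two-step: fill an $M \times L$ dynamic
programming matrix, then walk backwards through it (traceback, or
stochastic back-tracing). The point of this package is the one-pass
alternative implemented in `viterbi_counts()`, `sem_counts()` and
`expected_counts(engine = "linear")`: a single left-to-right sweep that
carries, for every *current* state $m$, the cumulative count tables
$T_{i,j}(k, m)$ and $E_i(y, k, m)$ of the (best / sampled / expected) path
prefix ending in $m$ at position $k$, alongside the dynamic-programming
values of the previous position only. At the silent `End` state the tables
are exactly the counts the two-step procedure would have produced, so the
retained memory is $O(M \cdot \#\text{coordinates})$ (times $K$ for the
sampler) — independent of the sequence length. The equivalence is exact
for Viterbi counts (integer tables, same tie-breaking), exact in
distribution for the sampler, and holds to numerical round-off for the
expected-count recursion; the test suite checks all three against their
two-step counterparts and against brute-force path enumeration at small
sizes.

## Parameter tying and the update step

Real models train far fewer numbers than they have probability
coordinates. `hmm_parameterization()` factorizes every structural
coordinate into a product of named parameters; parameters live in
*simplex blocks* whose values sum to the block's mass (the probability
remaining after fixed entries). One parameter may appear on many
coordinates (tying), and a coordinate may carry two factors (nested
schemes such as a block-switch probability times a destination-row
distribution in the CpG model). A parameter's pooled count is the sum of
raw counts over every coordinate that carries it; the update renormalizes
each block:

$$ \theta_p \leftarrow \text{mass} \cdot
   \frac{c_p + \kappa}{\sum_{p' \in \text{block}} (c_{p'} + \kappa)} $$

with pseudocount $\kappa$ (default 1) added once per block member. This is
the exact maximum-likelihood / EM update for nested multinomial
factorizations, and the pseudocounts keep rarely used parameters alive so
that training cannot terminate prematurely on a zero row. Parameters with
role `"derived"` take part in the block normalization but are not counted
as independent; `"fixed"` parameters are never touched and their mass is
excluded up front.

## The example models

Three built-in models (plus two tiny test fixtures) exercise the
machinery:

* `build_dishonest_casino()` — fair (F) and loaded (L) dice over symbols
  1–6: 8 structural transitions, 12 emissions, 12 trained values (the two
  switch probabilities F→L, L→F, and five free faces per dice).
* `build_extended_casino()` — the same game but the fair dice must be used
  in runs of three and the loaded dice in runs of two, enforced by wait
  chains F1→F2→F3 and L1→L2: 11 transitions, 30 emissions, and still 12
  trained values because the F states share one emission distribution and
  the L states another.
* `build_cpg_model()` — CpG-island detection: one state per nucleotide
  inside (+) and outside (−) an island, fully connected (80 transitions),
  with delta-function emissions that are never trained. The transition
  scheme is nested: a shared fixed End probability; one free switch
  probability per direction; one next-base conditional distribution per
  source base and block (cross-block moves reuse the destination block's
  row); and a free Start distribution. That yields 33 free parameters
  plus the one fixed End probability. Published descriptions of this
  decomposition count "33 parameters, 32 trained"; the exact split is not
  recoverable from the prose, so our scheme is documented here,
  configurable, and the 33/32 bookkeeping difference is surfaced rather
  than hidden (we train all 33).

Default generating values are package choices (no published values exist
for these examples): fair emissions uniform, loaded dice
$e_L(6) = 0.5$ and $0.1$ elsewhere, switch probabilities $0.05$ (F→L) and
$0.1$ (L→F), End probability $2/5000$ so unconditioned paths average a few
thousand symbols; the CpG model uses the classic island/background
next-base tables with switch probabilities $0.005$ and $0.0025$. All are
overridable through the builders' `true_params` argument.

## The synthetic-data generator

`simulate_sequence()` is plain ancestral simulation (follow transitions
until `End`), with a rejection budget on a maximum length.
`generate_dataset()` produces the fixed-length datasets used by the
comparison experiments; naive rejection until a path hits the target
length exactly is hopeless (acceptance probability is of order $10^{-4}$
at these lengths), so it samples from the model's *exact* conditional
path distribution given total length $L$: a backward recursion
$u_i(r) = \sum_j t_{i,j}\, u_j(r-1)$, $u_i(0) = t_{i,End}$ gives the
probability that a path leaves state $i$ and reaches `End` after exactly
$r$ more symbols, and the forward sampler reweights every transition
choice by it. The product of the reweighted choices telescopes to
$P(\Pi) \cdot t_{\pi_L, End} / P(\text{length} = L)$, i.e. exactly the
conditional law. Columns of $u$ are renormalized to dodge underflow;
only ratios enter the sampler. One child seed per record makes datasets
reproducible record by record regardless of evaluation order.

What the generator does *not* emulate: real data are not emitted by the
fitted model family. Passing recovery and comparison experiments on these
datasets demonstrates correctness of the estimators under the model's own
law — it says nothing about model misspecification, alphabet errors, or
non-stationarity in real genomic sequence.

## Numerical choices

* Viterbi scores are computed in log space (sequences of length 5000
  underflow linear space hopelessly); counts are exact small integers in
  doubles.
* Forward values are kept in *scaled linear* space (one scale factor per
  position) rather than log space, because the back-tracing ratios of the
  sampler are scale-invariant within a position pair, which keeps the
  per-cell sampling a cheap normalized draw. $\log P(X)$ is accumulated
  from the scale logs.
* Argmax ties in both Viterbi routines break toward the lowest
  previous-state index, so the one-pass and traceback procedures agree
  exactly, ties included.
* Viterbi training stops when the pooled count vector repeats exactly
  between iterations — a cheap surrogate for "the paths no longer
  change", since the one-pass algorithm never materializes paths. For
  strictness, every column of the one-pass kernel also carries a rolling
  64-bit hash of its implied traceback path; `convergence = "path_hash"`
  additionally requires all per-sequence hashes to repeat.
* The sampler draws one predecessor per (position, reachable state,
  chain). Cells with zero forward probability are skipped: their
  back-tracing distribution is undefined and no surviving table can
  descend from them.
* Degenerate inputs: empty sequences and sequences with zero likelihood
  raise explicit errors naming the offending record; a normalization
  block whose counts and pseudocounts are all zero is an error rather
  than a silent NaN.

## The evaluation harness

`decode_and_score()` Viterbi-decodes held-out sequences and scores the
per-position binary classification "label in the positive set" (loaded
states, or '+' states). Sensitivity is $TP/(TP+FN)$; *specificity* is not
uniquely defined in the literature, so both the true-negative rate
$TN/(TN+FP)$ (default) and precision $TP/(TP+FP)$ are computed, and
performance is sensitivity × specificity under the chosen convention.
Scoring is per-position, the natural unit for these segmentation-style
models. `cross_validate()` runs the three-fold scheme: two thirds of the
sequences train, one third tests, all training configurations within a
fold share one random initialization so differences reflect the
algorithms rather than the starting point, and metrics are recorded after
every iteration with mean ± sd across folds.

`parameter_distance()` measures recovery as the mean absolute difference
between trained and generating values, separately for free emission and
free transition parameters. The casino and CpG models are *invariant*
under exchanging their state blocks (F↔L, +↔−): training converges to
either of two equivalent optima depending on the random start, and the
raw distance to one fixed labeling is then a coin flip. With
`align = "symmetry"` the distance is minimized over the model's declared
label symmetries — the standard identifiability-aware convention for
mixture-type models. The builders export the symmetries; the comparison
harness uses the aligned metric.

## Local optima, and what recovery experiments can show

Random initialization draws every block from the flat Dirichlet on its
simplex. For the dishonest casino this is a harsh start: half the draws
begin with switch probabilities above one half, deep in the basin of a
well-known spurious optimum in which the two states switch rapidly and
split the emission mass rather than separating fair from loaded dice.
Baum-Welch, being deterministic, stays in whatever basin the start
selects; stochastic EM's Monte-Carlo noise does escape, but typically
only after a couple of hundred iterations with 50 pooled training
sequences (pooling over sequences averages the sampling noise away, so
escape slows as the dataset grows). Short recovery runs from flat random
starts therefore fail to reach the generating values more often than not
— not an implementation defect (the estimators initialized at the truth
stay there, and every kernel is oracle-checked) but a property of the
likelihood surface under this initialization. The package's own
experiment scripts report recovery errors per seed so the effect is
visible rather than averaged away; multiple restarts with likelihood
ranking, milder initialization, or longer stochastic EM runs are the
practical remedies.

## Problem sizes used by the shipped experiments

The test suite and the reproduction script run at desk scale, chosen so
the full battery completes in a few minutes on one core: oracle
equivalence on 200 random models (≤ 4 emitting states, alphabet ≤ 4,
length ≤ 50), brute-force enumeration at length ≤ 8, $10^5$ posterior
draws for the sampler's distributional check, recovery on 50 casino
sequences of length 1000, and the three-fold comparison on 30 sequences
of length 1000 with Viterbi, Baum-Welch and stochastic EM at
$K \in \{1, 3, 5\}$. The algorithms themselves have no such limits; the
one-pass kernels are routinely run here at length $10^4$ to demonstrate
the memory contract, and scale linearly in time.

## Known limitations

* First-order HMMs with `Start`/`End` as the only silent states; no
  higher-order models, pair-HMMs, continuous emissions, or additional
  silent states.
* One set of parameters is trained for all sequences jointly; there is no
  per-parameter memory/time trade-off — all free parameters are collected
  in one pass.
* Posterior decoding is not implemented; evaluation decodes with the
  Viterbi path.
* The backward-algorithm variant of posterior sampling (forward-direction
  back-tracing) is not implemented.
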