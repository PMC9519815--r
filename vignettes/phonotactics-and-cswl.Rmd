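---
title: "Phonotactic stimulus control and chance-offset models for cross-situational word learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phonotactic stimulus control and chance-offset models for cross-situational word learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures implemented in
`cswltools`, the choices made where the methodology was genuinely open, and
what the package's synthetic data can and cannot establish.

## 1. Positional biphone phonotactics

The phonotactic probability of a biphone $b$ at word position $p$ (1-based
index of the biphone's first segment) is the log-token-frequency weighted
proportion

$$
P(p, b) \;=\;
\frac{\sum_{w \,:\, b \text{ at } p} \log_{10} f(w)}
     {\sum_{w \,:\, \text{any biphone at } p} \log_{10} f(w)},
$$

where $f(w)$ is the corpus token frequency of word $w$. Log weighting (base
10) is used because log frequency tracks behavioural sensitivity better
than raw counts. Within each position the probabilities sum to one, which
`biphone_table()` guarantees to $10^{-9}$ and tests verify against an
independent brute-force implementation to $10^{-12}$.

Numerical choices:

* **No smoothing.** $\log_{10} 1 = 0$, so words of token frequency 1
  legally contribute zero weight, and unseen biphones score exactly 0
  (flagged on the scored word). The weighting formula is applied as stated,
  with no pseudo-counts.
* **Word-level aggregation.** A word's PP is the **sum** of its biphone
  probabilities by default (the positional-statistic convention); the mean
  is available via `aggregation = "mean"`. Published per-word values can be
  printed under either convention; only set-level *means of the printed
  per-word values* are reproduced exactly by `set_mean_pp()`, which is why
  the bundled stimulus table (`study_stimuli()`) stores the printed numbers
  rather than recomputing them — recomputation would require the original
  corpus.
* **Homophones** (same phoneme sequence, different orthography) are
  distinct entries and both contribute: the statistic is token-based.
* Phoneme strings are space-delimited everywhere, so multi-character IPA
  symbols (e.g. the affricate `d͡ʒ`) are single segments by construction.

## 2. Pseudoword search and recombination

`generate_candidates()` enumerates every sequence matching a CV template
(default CVCV) whose adjacent pairs are attested at their positions, scores
them, removes real words, and ranks by PP with a lexicographic tie-break
(reproducibility). `select_top_set()` walks down that ranking greedily; two
optional diversity constraints — a cap on shared positional biphones
between chosen words and on repeated initial phonemes — prevent the
degenerate outcome in which the "best" six words are minor variants of one
another. The pipeline default (`max_shared_biphones = 0`) mirrors the
structure of the published stimulus sets, whose six high-probability words
share no positional biphone.

`recombine_biphones()` builds the matched lower-probability set from the
PP+ material. The default mode works at the **CV-syllable** level: the 12
syllables of the PP+ words are rearranged into new orders and positions
(a word-final syllable may reappear word-initially), which is the pattern
visible in the published word lists (e.g. the final syllables of *su-te*
and *vi-ko* recombining into *ko-su*). A biphone-level mode is available
behind `mode = "biphone"`. Candidates are ranked by PP and the selected set
is the best contiguous window of six whose mean is strictly below the PP+
mean and at least `floor` (default 0.75) of it — "slightly less probable,
but still high". The window rule keeps selection deterministic; when all
candidate probabilities are equal (a fully symmetric lexicon) no window can
lower the mean and the function fails loudly rather than fabricate a
contrast. The search strategy and diversity constraints are explicit
package choices: the original stimulus-construction engine is described
only at the level of "find and concatenate biphones", so these defaults are
inferences, not reconstructions.

## 3. Trial structure

The design generator reproduces the two-set CSWL structure: 6 word–object
pairs per set, each exposed 6 times in ambiguous 2×2 trials (2 objects, 2
words, both pairs from the same set), for 36 training trials, then 24
4AFC test trials (each pair probed twice, four same-set objects, preceded
by 2 warm-up trials with everyday objects).

* **Pairing schedule.** Each label must meet its 5 set-mates and appear 6
  times. The implemented schedule is the minimal construction satisfying
  both: all $\binom{6}{2} = 15$ distinct pairings once, plus one seeded
  perfect matching (3 pairs). This is an inference — the published design
  states the constraints, not the schedule — and it implies the training
  co-occurrence matrix has diagonal 6, within-set off-diagonal at most 2
  and cross-set 0, so an ideal co-occurrence learner is provably correct.
* **Interleaving.** Default: seeded random order with at most 2 consecutive
  same-set trials (strict alternation available). The greedy sequencer uses
  a feasibility lookahead, so it never dead-ends.
* **Order/side balance.** The first-played word's referent appears on the
  left in exactly half the trials, so object position carries no
  information about word order.
* **Foils and corners.** The 3 foils come from the 5 remaining same-set
  objects by seeded balanced sampling plus a swap-repair pass (within a
  set, foil appearance counts differ by at most 1); the target's corner is
  balanced across the four screen positions. Foil choice is not described
  in the published design; balanced sampling is the package's choice.
* **Timing** is carried as metadata: 950 ms silence, ≈696 ms word, 700 ms
  pause, ≈696 ms word, 950 ms trailing pause (3 992 ms ≈ 4 s per training
  trial); the 1 s inter-trial fixation lives in the design metadata only.
* **Counterbalancing.** Version A pairs words and objects at random
  (seeded); version B keeps the word order and swaps the object blocks
  between sets, so every word keeps its set and every object changes set.

All counts and balance properties are validated by `validate_design()` and
property-tested across seeds.

## 4. What the simulator emulates — and what it does not

`simulate_cohort()` provides three response mechanisms:

* **`glmm_generative`** (default) is the generative counterpart of the
  analysis model: $P(\text{correct}) = \mathrm{logit}^{-1}(\mathrm{logit}(0.25)
  + \beta_0 + \delta\,[\text{set}=PP+] + u_p + u_s)$ with
  $u_p \sim N(0, \tau_p^2)$, $u_s \sim N(0, \tau_s^2)$; errors are uniform
  over the three foils (the model only distinguishes correct/incorrect).
  Defaults are the study conditions: $n = 30$ participants,
  $\beta_0 = \log 7.61$, $\delta = \log 1.19$, $\tau_p = \sqrt{2.35}$,
  $\tau_s = \sqrt{0.21}$ — the fitted full-dataset values — so parameter
  recovery is well-posed by construction.
* **`associative`** is a mechanism-level co-occurrence learner: counts
  accumulated over training, softmax choice over the four displayed
  objects' counts (temperature 0 = argmax), with an optional uniform lapse.
* **`guesser`** chooses uniformly (the chance anchor, 0.25).

Reaction times are lognormal (meanlog $\log 1200$ ms, sdlog 0.35 — chosen
once as realistic adult 4AFC latencies; the study reports no RT
distribution) with a contamination component: with probability 0.02
(matching the reported ~2% exclusion) the RT is replaced by a uniform draw
from 10–30 s, emulating distraction. Contaminated rows carry a ground-truth
flag so exclusion filters can be tested exactly.

None of these mechanisms is a cognitive model of human cross-situational
learning: the learners are artifact constructs that make every downstream
stage testable without data collection. Passing tests show that the
pipeline is internally consistent (the generative model is recovered by the
fitting code; an ideal learner saturates the design; chance stays at
chance) — they say nothing about how humans weigh phonotactics against
co-occurrence, and the published human odds ratios are not reproducible
without the original participant data.

## 5. The chance-offset mixed logistic models

The 4AFC chance level enters the linear predictor as a fixed **offset**
$\mathrm{logit}(0.25) = \log(1/3) \approx -1.0986$, so the intercept is the
above-chance log-odds for the reference set (PP−) and the set coefficient
is the change for PP+. This is the only reading under which the intercept
odds ratio is interpretable as above-chance odds, and the combined
above-chance odds for PP+ is the product of the two odds ratios
(`combine_odds()`).

* **Frequentist** (`fit_glmm_frequentist()`): `lme4::glmer`, Laplace
  approximation, random intercepts for participants and stimuli (the pruned
  structure that converges), Wald intervals on the log-odds scale.
  p-values are not part of the default output. Convergence problems and
  complete separation (all responses identical) are flagged, not fatal.
* **Bayesian** (`fit_glmm_bayesian()`): JAGS, same fixed effects, richer
  random structure — participant intercepts plus independent
  stimulus-within-participant deviations. This is a diagonal
  simplification of the maximal "stimulus slopes within participant"
  covariance: with 12 stimulus levels the full unstructured covariance has
  78 parameters, poorly identified from 24 binary trials per participant,
  and the diagonal form preserves the variance decomposition the derived
  statistics need. Priors are weakly informative — Normal(0, 2.5²) on
  fixed-effect log-odds, half-t(3, 0, 2.5) on random-effect SDs — and the
  SDs are sampled via the parameter-expanded construction
  $\tau = |\xi| / \sqrt{\kappa}$, $\xi \sim N(0, 2.5^2)$,
  $\kappa \sim \mathrm{Gamma}(3/2, 3/2)$, which implies exactly that
  half-t prior while avoiding the near-zero funnel that cripples Gibbs
  mixing. Convergence is judged by the split-chain potential scale
  reduction factor with threshold 1.01; with an empty dataset the function
  returns prior draws (prior-predictive mode).

Derived quantities use the latent-scale logistic residual variance
$\sigma^2 = \pi^2/3 \approx 3.29$: the intraclass correlation
$\mathrm{ICC} = \Sigma\tau / (\Sigma\tau + \sigma^2)$ and the
marginal/conditional $R^2$ decomposition with $\sigma_f^2$ the variance of
the fixed-effect predictor. The 3-SD reaction-time exclusion is a single
pass, by default pooled over all rows of a dataset variant (the published
description says only "the mean"; a per-participant scope is provided), and
it is applied independently to the full (both probes) and halved
(first-probe-only) datasets. Power for a one-sample *t*-test against
chance uses the exact noncentral *t* distribution with noncentrality
$d\sqrt{n}$.

## 6. Problem sizes and reproducibility

The test suite exercises the statistical claims at sizes chosen to keep a
full run in a few minutes on one core while leaving Monte-Carlo error well
inside the asserted bands: 100 seeds for design validity and the
ideal-learner ceiling; 500 cohorts of 12 participants for intercept
coverage and the type-I rate of the null set effect (asserted within
[0.90, 0.99] and [0.02, 0.09]); 100 cohorts of 60 participants for
parameter recovery (mean absolute bias below 0.15 logits); 20 random
lexicons of up to 20 words for oracle equivalence at $10^{-12}$. MCMC
settings in tests are reduced (2 chains, hundreds of iterations) where only
structure is asserted; default settings (3 chains, 5 000 iterations after
adaptation and burn-in) are used where convergence itself is reported.
Every stochastic function takes a seed, pipeline stages derive
deterministic sub-seeds from the global seed, and rerunning a stage with
the same configuration reproduces its artifacts byte for byte (each stage
writes a manifest with checksums).

## 7. Known limitations

* The bundled lexicon is a small synthetic toy; absolute PP values computed
  from it are illustrative, not comparable to corpus-derived values.
* Whether the printed per-word PPs are sums or means of biphone
  probabilities cannot be decided without the source corpus; only the
  printed set means are treated as ground truth.
* The Bayesian random structure is a diagonal simplification (see §5).
* Wald intervals for the set contrast can undercover slightly with only 12
  stimulus groups; the package reports intervals as computed and leaves
  profile or bootstrap alternatives to the user.
* The simulators make no claim of cognitive plausibility;
  hypothesis-testing learner variants are future work.
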