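---
title: "Uncertainty-aware referral: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware referral: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uqreferral)
```

## The problem

Deep binary classifiers for clinical screening — dementia from transcribed
picture descriptions, depression phenotypes from discharge summaries — output
point probabilities that can flip under a change of random seed, and they give
the clinician no way to tell which predictions to trust. This package
implements the two-part remedy: (i) *Bayesian* predictive-uncertainty
quantification, which turns a single probability into a distribution of
Monte-Carlo draws and summarises its spread, and (ii) *referral learning*,
in which the model predicts for the instances it is sure about and hands the
rest to a human expert, with the referral policy evaluated by referral
curves against random and oracle baselines.

## Uncertainty from Monte-Carlo predictive samples

Everything downstream consumes a `predictive_samples` object: an
$n \times T$ matrix of positive-class probabilities, one row per instance,
one column per draw. Draws may be stochastic forward passes with dropout
left on at test time (`mc_dropout_sample()`), the members of a deep
ensemble (`ensemble_sample()`, $T = M$), or posterior draws of a
variational final layer (`bbb_sample()`). For draws $p_t$ with mean
$\bar p$:

* **Predictive entropy** $\mathrm{PE} = H(\bar p)$, the entropy of the
  ensembled prediction. It measures proximity to the 0.5 decision
  threshold.
* **Expected entropy** $\mathrm{EE} = \frac1T \sum_t H(p_t)$, the mean
  per-draw entropy — an aleatoric proxy that stays high when every draw is
  itself ambivalent.
* **Mutual information** $\mathrm{MI} = \mathrm{PE} - \mathrm{EE}$, the
  spread between draws — the epistemic proxy (the BALD score). It is zero
  iff all draws agree.
* **Variation ratio** $\mathrm{VR}$: harden each draw at 0.5 and report
  the fraction outside the modal class, in $[0, 0.5]$.

The Bernoulli label variance obeys the law of total variance,
$\bar p(1-\bar p) = \mathrm{Var}_t(p_t) + \mathrm{E}_t[p_t(1-p_t)]$,
splitting total uncertainty into epistemic and aleatoric variance
components (`variance_decomposition()`).

### Numerical conventions

These choices are deliberate and tested:

* **Entropies are in bits** (base-2 logarithm), so the maximum binary
  entropy is exactly 1; every identity used is base-invariant.
* $0 \log 0 = 0$ by continuity, so degenerate draws at 0 or 1 are legal.
* **Ties at 0.5 classify as 1.** A recall-preferring rule: in screening,
  false negatives are costlier than false positives. The same rule breaks
  annotator-majority ties.
* **Epistemic variance divides by $T$** (population variance), not
  $T - 1$, so the total-variance identity holds exactly rather than
  asymptotically.
* **MI is clamped to zero** only for floating-point negatives above
  $-10^{-12}$; anything more negative raises an internal error instead of
  being silently hidden.
* **VR hardens draws at 0.5** (`sample >= 0.5` counts as class 1); with an
  even $T$ and an exact tie both classes have count $T/2$, so VR is 0.5
  with no tie-break needed.

## Reference Bayesian samplers

The bundled classifiers are deliberately small — an encoder
(`identity`, one-hidden-layer `mlp`, or mean bag-of-embeddings `boe` for
token sequences) with a dropout site feeding a single logistic head —
because their job is to *generate* sample sets for the pipeline at
CPU-seconds scale; any external classifier that can emit per-draw
probabilities plugs in through the same `predictive_samples` container.
Training is full-batch Adam on binary cross-entropy, bit-reproducible
given `(config, seed)`.

Three samplers are provided:

* **MC dropout** re-applies the training-time dropout rate at test time
  by default (rate 0.2 is the bundled default; low rates produce the
  narrow predictive distributions that make MC dropout the weakest of the
  three in practice, and `rate = 0` is the degenerate deterministic case
  in which MI, VR and epistemic variance are exactly zero).
* **Deep ensembles** train $M$ members (default 5) differing only in
  seed. Because an $M$-member VR can take at most $M + 1$ values, ensemble
  VR has a staircase granularity — visible and tested. Member diversity
  comes from random initialisation; the `init_scale` configuration knob
  controls how different the members' starting functions are, and the
  ensemble-gain tests deliberately run in a diverse regime
  (`init_scale = 12`, 30 epochs, $n = 100$ training points) where member
  test accuracies spread by several points and averaging visibly helps,
  mirroring the intra-ensemble spread seen with real clinical text models.
* **Bayes-by-backprop final layer**: only the head is Bayesian — mean-field
  Gaussians with priors $\mathcal N(0, 1)$ on weights and
  $\mathcal N(0, 10)$ on the bias (biases range wider) — while the encoder
  is co-trained deterministically through the sampled head. The ELBO
  (Bernoulli log-likelihood minus closed-form Gaussian KL) is maximised by
  Adam with one reparameterised gradient sample per step, 2,000 steps,
  learning rate $10^{-2}$ by default; the per-step ELBO trace is kept and
  a non-finite ELBO aborts with diagnostics. At test time each of the
  `mc_samples` draws (default 1,000) reconfigures the head. On separable
  2-D data with the identity encoder this is Bayesian logistic regression,
  which is what makes the direction-recovery check against the
  `glm` oracle possible.

## Multi-annotator labels and the simulated expert

Clinical corpora carry several labels per instance ("grey cases" are those
the experts disagree on). `annotation_matrix` derives, per instance, the
**majority label** (ground-truth proxy; ties to 1), the **minority label**,
and the **human uncertainty** — the variation ratio of the label vector,
e.g. labels $\{0, 0, 1\}$ give $1/3$. The simulated expert
(`simulate_human()`) predicts the minority label on disagreement instances
and the unanimous label elsewhere; scored against the majority it is wrong
exactly on the disagreement set, so its accuracy is identically
$1 - \text{disagreement rate}$ — the most pessimistic expert consistent
with the annotations (10% disagreement leaves a 90%-accurate expert).
Annotator counts may vary per instance; all metrics use each instance's
own count. Annotators are anonymous: per-rater bias models are out of
scope.

`fit_disagreement_predictor()` (a linear regressor with predictions
clipped to $[0, 0.5]$) exists because estimating human uncertainty at test
time would be the deployable version of the combined strategy; it is
flagged experimental — with realistically sparse disagreement (tens of
positive cases per corpus) it does not produce reliable estimates, which
the tests document by contrasting a planted-signal regime with a sparse
one — and the referral machinery uses ground-truth disagreement instead.

## Referral learning

`rank_for_referral()` orders instances by descending referral score with
deterministic index tie-breaks; `refer()` takes the top
$\mathrm{round}(rN)$ (rounding half away from zero, so rate 0.25 of 10
instances refers 3). The default rate grid is $\{0, 0.05, \dots, 0.95\}$.
Strategies:

* **model_uncertainty**: score is one of PE/EE/MI/VR (default PE);
* **model_minus_human**: $u_\text{model} - \alpha\, u_\text{human}$
  (default $\alpha = 1$) — the human takes cases the model finds hard but
  the annotators agreed on, and the model keeps the grey cases;
  **model_plus_human** is the variant for workflows where the human should
  see the grey cases too;
* **random**: seeded baseline;
* **optimal**: misclassified instances first — requires ground truth and
  is labelled a theoretical upper bound in every output.

Because human uncertainty *is* a variation ratio, the combined strategies
default to VR for the model side so both terms live on $[0, 0.5]$;
pairing an entropy metric against human VR is allowed but then $\alpha$
carries the scale conversion and must be set explicitly.

Two evaluation modes mirror the two labelling regimes. With a single
label per instance the human is assumed perfect, so the model is scored
on the **non-referred** instances only; at rate 1 the retained set is
empty and metrics are reported missing, and ROC-AUC is reported missing
(with a logged reason) when the retained set degenerates to one class —
the pathology behind sharp ROC-AUC declines at high referral rates. (For
`classification_metrics()` itself, a constant score is *not* an error:
the midrank rank statistic returns 0.5 for an uninformative ranker.)
With multiple labels the evaluation is **dataset-level**: model on
retained, simulated expert on referred, both against the majority labels;
human predictions on non-referred instances are never consulted (triage
semantics), and human labels enter ROC-AUC as degenerate 0/1
probabilities.

`expected_calibration_error()` is the equal-width, confidence-binned
variant with 10 bins — calibration metrics vary across the literature and
this is the most common concrete choice.

## What the synthetic generators emulate

No credentialed clinical corpus ships with (or is fetched by) this
package; the generators reproduce the *statistical structure* the methods
care about, with defaults anchored to the reference corpora: positive
fraction $255/474 \approx 0.54$ (transcript corpus; the EHR corpus
alternative is $222/813 \approx 0.27$), three annotators, 10%
disagreement.

* `make_overlap_dataset()`: two Gaussian clouds at distance 2 whose
  common standard deviation (`overlap`) sets the Bayes error — the
  aleatoric dial; an optional angular wedge (`sparsity`) is excluded from
  training by rejection and probed at test time — the epistemic dial. The
  tests verify that a variational model's MI is higher on wedge probes
  than on the dense region.
* `make_token_dataset()`: Zipf-distributed token sequences in which the
  positive class mixes in a distribution concentrated on a quarter of the
  vocabulary — the reduced-vocabulary-diversity signature; type-token
  ratios and a null case (`divergence = 0`) are generator-level tests.
* `make_annotations()`: exactly $\mathrm{round}(\text{rate} \cdot n)$
  instances get one dissenting annotator; with odd $K$ a single flip never
  moves the majority, so the majority equals the truth and the realised
  disagreement rate is exact.
* `make_predictive_samples()`: sample sets without any training. Each
  instance gets a difficulty $d \sim U(0,1)$; exactly
  $\mathrm{round}(\text{error rate} \cdot n)$ error instances are drawn
  with probability proportional to a logistic function of $d$ whose slope
  is $8 \times \text{coupling}$ and whose intercept is calibrated by root
  finding so the mean hits the target rate. Sample centres sit on the
  predicted side of 0.5 with margin shrinking in $d$ and spread growing in
  $d$, so PE and VR rise with $d$ and, when coupling is positive, with the
  error probability. Draws are clamped to $[0,1]$; a clamped row whose
  hardened mean would cross 0.5 is mirrored ($p \to 1-p$), which preserves
  the spread and keeps the realised error rate *exactly* as planted —
  without this, near-threshold rows occasionally flip and the
  `error_rate = 0` case would not give uniformly perfect accuracy.

### The complementary scenario

`make_complementary_scenario()` builds the regime where combining model
and human uncertainty should pay: model and simulated human both about
90% accurate, with errors in different places. Three regions:

| region | share | model | annotators |
|---|---|---|---|
| grey | 0.10 | uncertain, correct half the time | one dissenter (human wrong) |
| model-hard / human-easy | 0.25 | uncertain, 20% error | unanimous |
| easy | 0.65 | confident, correct | unanimous |

The two uncertain regions share one uncertainty distribution, so the
single-label strategy cannot separate them: each referred grey instance
costs $(1 - 0.5)$ expected errors while each referred model-hard instance
removes $0.2$, and the region sizes make these cancel —
$0.10 \times 0.5 = 0.25 \times 0.2$ — so the single-label dataset-level
curve is flat. Once the whole uncertain block is referred the accuracy is
pinned at exactly 0.9 (the grey share is the only error source left),
which keeps the curve flat over the entire grid. The combined score
$\mathrm{VR}_\text{model} - \mathrm{VR}_\text{human}$ ranks the
model-hard/human-easy block strictly first, so the combined strategy
climbs while the single-label one stays level. A region of
confident-correct model predictions *with* annotator disagreement is
deliberately absent from the default scenario: any such instance adds a
human error at whatever rate it happens to be referred, which would tilt
the single-label curve at high rates and destroy the flat-curve property
this scenario exists to exhibit; its scientific content (the model
covering human weakness) is carried by the grey cases the combined
strategy keeps with the model.

## What the tests do and do not show

The test suite and acceptance checks run the full pipeline at desk scale:
identity and oracle checks are exact; behavioural claims (referral
dominance under coupling, null-safety without coupling, combined-strategy
superiority, ensemble gain, the uncertainty–misclassification link, data
shrinking epistemic uncertainty) are seed-majority or paired-standard-error
assertions over 10–50 seeds, at problem sizes of 50–2,000 instances,
ensembles of 5, 20–600 training epochs/steps, and 20–1,000 Monte-Carlo
draws. These sizes are the package's chosen study conditions: large
enough for the effects to be systematic, small enough that the whole
suite runs in well under a minute of CPU.

Passing them shows the machinery is correct and that the qualitative
phenomena are reproduced *under the generators' assumptions*: planted
difficulty, Gaussian clouds, unigram token models, a single dissenting
annotator per grey case, a maximally pessimistic simulated expert. They
do not show that any particular clinical corpus has these properties, nor
reproduce numbers measured on credentialed data; transformer-scale
encoders, pre-trained embeddings, audio, calibration post-processing
(e.g. temperature scaling), surrogate-loss/learning-to-defer formulations,
annotator-identity models, and multiclass ($>2$) uncertainty metrics are
all out of scope.

## Known limitations

* The simulated expert is the *minority-label* expert — the worst expert
  consistent with the annotations. Real experts interpolate between that
  and the majority.
* The combined strategy assumes model and human uncertainties are worth
  equal weight; when their accuracies differ, $\alpha$ must carry the
  difference, and the package provides no estimator for it.
* The disagreement predictor is linear and experimental; with sparse
  disagreement it reverts to near-constant predictions.
* Referral budgets are fixed rates; cost-sensitive budgets are not
  modelled.
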