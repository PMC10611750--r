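---
title: "Volatility beliefs in a composite-stimulus reversal bandit: models, fitting, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volatility beliefs in a composite-stimulus reversal bandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the scientific question

`volbandit` studies how beliefs about environmental volatility shape reward
learning in a three-armed bandit with *composite* stimuli. On every trial
nine images (three landscapes, three vehicles, three animals) are arranged
in a 3x3 grid; the subject picks one of the three columns, each containing
one image per category, and the rows are reshuffled independently on every
trial. Exactly one image is the *target*: choosing a column that contains
it is rewarded with high probability (0.8 in the reversal task, 0.75 in the
signalled task), any other column with the complementary low probability.
Credit must therefore be assigned across the three features of the chosen
column.

Two task variants differ only in how the target changes. In the *signalled*
task the change is announced at each of five 25-trial game boundaries, so
negative feedback is never ambiguous. In the *reversal* task one continuous
125-trial game hides target changes every 20-30 trials; a non-reward can
then mean either bad luck or a reversal. That second-order ambiguity is the
scientific crux: an agent who believes the world is very volatile will
treat chance negative feedback as evidence of a reversal and abandon a
still-correct choice (a *probabilistic error*).

The package provides, as separately testable modules: the task simulators,
two families of learning agents, MAP fitting with Laplace evidence and
random-effects model comparison, the behavioural dependent variables,
trait-level statistics (Holm correction, bootstrap mediation, ICC), and a
synthetic-cohort generator that plants an anxiety -> volatility-belief ->
learning structure so the whole chain can be exercised without any external
data.

## The reinforcement-learning family

All RL variants learn one value per image, `v(f)`, initialised to 0 (at
every announced game start in the signalled task, once per session in the
reversal task). The value of a column is the mean of its three feature
values,

$$V(S_i) = \tfrac{1}{3}\sum_{d \in S_i} v(d),$$

choices are softmax in the column values with inverse temperature
$\beta > 0$, and after feedback $r \in \{0,1\}$ the chosen column's three
images move by $\alpha\,\delta$ with $\delta = r - V(S_c)$.

* `ba` (2 parameters): learning rate $\alpha$ and $\beta$.
* `baf` (3): adds a forget rate $\varphi$; the six unchosen images relax
  toward 0 by the factor $1-\varphi$ every trial.
* `bafc` (6): splits the learning rate by prediction-error valence
  ($\alpha_p$ for $\delta > 0$, $\alpha_n$ otherwise) and adds a
  confidence trace
  $\mathrm{Conf} \leftarrow \mathrm{Conf} + \gamma\,\big((2-|\delta|)/2 -
  \mathrm{Conf}\big)$ that scales the effective rates:
  $(\alpha_p + \kappa\,\mathrm{Conf})/(1+\kappa\,\mathrm{Conf})$ after
  positive surprises and $\alpha_n/(1+\kappa\,\mathrm{Conf})$ otherwise.

Two timing conventions had to be fixed where the model family leaves them
open. Confidence starts at 0.5, the attainable lower bound of its
fixed-point range $[(2-1)/2, 1]$ under binary rewards, and is *not* reset
at signalled game boundaries (only values are); within a trial the
confidence update precedes the learning-rate computation, so the current
surprise already informs the current learning rate. Both choices are
deliberate and documented here rather than hidden in code.

A property worth knowing: because all three chosen images share the single
composite prediction error while coalitions reshuffle every trial,
*individual* feature values are not confined to $[-1, 1]$ even with binary
rewards (simulations show excursions to about $\pm 2.5$ under extreme
parameters). The chosen column's composite value is always pulled into the
convex hull of its old value and the reward, and the ensemble does not
diverge; the test suite asserts exactly those two properties.

## The hidden Markov observer

The winning model family treats the target identity as a hidden state
$f_i$ over the nine images and filters a belief $\alpha_t(f_i)$ from
feedback. After a choice with outcome $r_t$, chosen features are scored
with likelihood $q$ ($r_t=1$) or $1-q$ ($r_t=0$); unchosen features with
$1-p$ ($r_t=1$) or $p$ ($r_t=0$); the belief is renormalised and then
multiplied by a transition matrix with diagonal $1-tr$ and off-diagonal
$tr/8$ — with probability $tr$ the observer expects the target to jump
uniformly to one of the eight other images. `tr` is therefore a subjective
volatility: it diffuses the belief toward uniform every trial. Choices are
probability matching: each column is chosen with probability equal to its
summed belief mass.

The augmented variant (`hmm4`) sharpens or flattens the belief before
matching. The source description calls this a multiplication of the hidden
states, but a scalar multiplication is inert under the normalisation in the
choice rule; since the parameter is explicitly meant to allow under- and
over-matching like an inverse temperature, it is implemented as an
elementwise *exponent* on the belief (range (0, 5), 1 = exact matching).

Within a trial the order is: choose from the current belief, observe,
update (emission), transition, next trial. The belief is initialised
uniform at session start and, in the signalled task, at every announced
game boundary. A floor of 1e-300 before renormalisation guards underflow.
The filter is implemented in C++ for the fitting loops; the exported R
single-step operations compose to the identical filter, and both are tested
against a brute-force enumeration over all $9^T$ target paths for short
sessions (agreement to 1e-10).

## Fitting, evidence, and model comparison

Every parameter is fitted on an unconstrained scale (logit for unit-interval
parameters, log for $\beta$ and $\kappa$, scaled logit onto (0,5) for the
exponent) under a weakly informative N(0, 3^2) prior. Subjects are fitted
by multi-restart BFGS (the prior mean plus four prior draws by default) and
the log model evidence is approximated by Laplace's method:
$\log p(y) \approx \log p(y, \hat\theta) + \tfrac{d}{2}\log 2\pi -
\tfrac12 \log \det H$. Non-positive-definite Hessians are
ridge-regularised and flagged.

The hierarchical layer is a deliberately simple empirical-Bayes loop
standing in for full variational hierarchical toolboxes: fit each subject
under each model's current prior; turn per-subject evidences into model
responsibilities; re-estimate each model's prior as the
responsibility-weighted mean/sd of the subject MAPs (sd floored at 0.1);
iterate to tolerance. Model frequencies are mean responsibilities, and
exceedance probabilities come from 1e5 Monte-Carlo draws of a Dirichlet
posterior with concentration 1 + summed responsibilities. The contract —
regularised subject fits, responsibility-weighted group estimates,
frequencies and exceedance — matches the random-effects comparison used in
the field; numerical equality with variational implementations is not
claimed.

## The synthetic cohort and what it does (and does not) emulate

`cohort_config()` freezes the study conditions: 427 subjects, one 125-trial
reversal session each, three-parameter HMM agents. Traits: Uncontrollable
Stress and State Anxiety are standard normals correlated at 0.5 (a
plausible value for these scales; only the sign matters downstream), and
seven further factor scores are independent noise, giving the nine-factor
table the trait analyses expect. The generative parameters are
logit-normal: $q \sim \mathcal{N}(0.5, 0.8^2)$ on the logit scale (mean
about 0.62 — agents *underestimate* the true 0.8 reward probability),
$p \sim \mathcal{N}(2.2, 0.8^2)$ (skewed toward 1), and
$\mathrm{logit}(tr) = -2.5 + b\,\mathrm{anxiety} + \varepsilon$ with
$b = 0.124$ and residual sd $\sqrt{1-0.124^2}$, so the marginal sd of
logit(tr) is 1 and the population anxiety-volatility correlation is
exactly 0.124. Only `tr` is trait-linked. The calibration is closed-form
rather than simulated: at any given seed the realised sample correlation
varies around 0.124 with sd about 0.05 (at the default seed it lands near
0.23).

The generator emulates the *structure* the analyses assume — a trait-linked
subjective volatility expressed through choice behaviour — not the full
texture of human data: there are no non-responses, no reaction times, no
session-order or practice effects, and the agents are exactly the model
class later fitted to them. Passing the end-to-end tests therefore shows
that the pipeline recovers a known planted mechanism; it cannot show that
the mechanism is the right account of any real cohort.

One emergent property deserves emphasis. Under probability matching, the
volatility belief changes the *level* of accuracy and the probabilistic
error rate strongly (across agents, correlations of roughly -0.5 with mean
accuracy and +0.4 with the error proportion), but leaves the session-wide
linear learning *slope* almost untouched (correlation about -0.04): agents
reach their tr-dependent plateau within the first target segment, so the
125-trial linear trend carries almost no between-subject signal. The
anxiety -> tr -> probabilistic-errors mediation is consequently recovered
robustly at n = 427, while the anxiety -> tr -> learning-slope mediation
has no effective planted mechanism in this generative world and its
acceptance check documents that fact by failing; treat it as a property of
probability-matching HMM agents, not a defect of the mediation estimator
(which recovers planted linear paths exactly in its own tests).

## Behavioural dependent variables

Accuracy codes a trial as correct when the chosen column contains the
current true target; non-responses (possible only in imported data) count
as errors. Learning models use the trial index centred on 0 (-62..62 for
125 trials). Group learning is a mixed logistic model `correct ~ trial_c`
with by-subject random intercepts and slopes (lme4); per-subject
conditional (shrunken) slopes feed the mediations. The default `nAGQ = 0`
approximation is used for cohort-scale fits — slope extraction is
insensitive to it and it keeps a 427 x 125 binary fit fast; a per-subject
ridge-penalised logistic fallback covers non-convergence.

The probabilistic-error proportion is computed per true-target segment:
after the first run of five consecutive correct choices, every later trial
in the segment where the subject chose the still-correct target and was
not rewarded is an opportunity, and it counts as a shift when the next
trial's choice column lacks that target. The criterion resets at every
reversal. Opportunities on the last pre-reversal trial are by default
judged against the first post-reversal choice (the subject cannot know the
reversal happened; switchable), and opportunities on the session's final
trial, or followed by a non-response, are dropped. Subjects with no
opportunities are flagged ineligible and excluded from trait regressions,
mirroring how low performers drop out of this measure.

## Trait statistics

`holm()` implements the step-down rule directly (rank-k threshold
$\alpha/(m+1-k)$, rejections forming a prefix of the sorted order) and is
cross-checked against `p.adjust` in the tests. `mediate()` uses the linear
structural-equation decomposition — ACME $= a\,b$, ADE $= c'$, total
$= a\,b + c'$, proportion mediated ACME/total — with percentile CIs and
p-values from a nonparametric subject-resampling bootstrap (default 10,000
resamples; the quasi-Bayesian alternative is intentionally out of scope).
`icc_two_way()` is the two-way random-effects, absolute-agreement,
single-measures intraclass correlation with the Satterthwaite confidence
interval; the flavour is a documented package choice where the family of
two-way random-effects ICCs is ambiguous.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: a zero-variance factor or
constant correlate raises an error; an all-failed fit carries a -Inf
evidence sentinel; responsibilities with no mass leave a model's prior
untouched; reversal intervals with min = max are honoured exactly. Child
seeds for every stochastic stage (sessions, restarts, bootstrap, Dirichlet
draws) derive from one master seed by a fixed hash, so any stage can be
reproduced in isolation.

The shipped tests run the pipeline at the sizes the analyses are designed
for where that is cheap (427-subject cohorts, 1000-agent recoverability,
1e5 Dirichlet draws) and at reduced but adequately powered sizes for purely
illustrative properties (e.g. 40-subject factor-GLMM checks, 400-resample
bootstrap calibration); each test states its size inline.

## Known limitations

* The empirical-Bayes loop shares the contract, not the implementation, of
  variational hierarchical inference; group-level frequencies on real data
  will differ numerically from toolbox output.
* At 125 trials and the default generative spread, the MAP estimate of
  `tr` has split-half reliability around 0.58, which caps
  generative-vs-recovered correlations near 0.76; substantially higher
  recovery figures require either longer sessions or a wider true spread
  of volatility beliefs.
* The belief-sharpening exponent of `hmm4` is only weakly identified —
  clearly the weakest of its four parameters, though not fully
  unidentifiable in the exponentiation reading implemented here.
* The signalled-task machinery is exposed and tested, but no trait-level
  conclusions are attached to it.
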