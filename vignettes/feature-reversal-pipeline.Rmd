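---
title: "Modelling feature-based reversal learning and its neural encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling feature-based reversal learning and its neural encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexshift)
```

## The task and what the package computes

`flexshift` models a two-alternative attentional set-shifting experiment.
On every trial two peripheral grating stimuli carry opposite levels on
three feature dimensions — colour, motion direction and spatial location —
and only colour predicts reward. The rewarded colour reverses without any
cue once a block has lasted at least 30 trials and performance over the
preceding 12 trials has reached 90% (a hard cap of 80 trials bounds blocks
for non-learning agents). The subject must therefore maintain a
colour-based attention set and reverse it from trial-and-error feedback.

The package provides, as composable data-frame-first functions:

* a seeded simulator for the task and a feature-value reinforcement-learning
  (RL) agent (`simulate_session()`);
* maximum-likelihood fitting of that agent and extraction of its latent
  variables — object values, choice probability, reward prediction errors
  (`fit_agent_mle()`, `compute_latents()`);
* a state-space ideal-observer estimate of the per-trial probability of a
  correct choice and the statistically defined learning trial
  (`em_learning_curve()`, `detect_learning_trial()`);
* behavioural metrics: the windowed learning criterion, averaged learning
  curves, and post-error/post-correct accuracy (EC~n~/CC~n~)
  (`criterion_learning_trial()`, `average_learning_curve()`,
  `post_outcome_accuracy()`);
* ground-truth synthetic neurons — Poisson spike trains with log-linear
  rate modulation and two-class spike waveforms
  (`generate_spike_trains()`, `generate_waveforms()`);
* narrow/broad-spiking classification from waveform metrics
  (`waveform_metrics()`, `classify_units()`);
* the encoding battery: spike-density conversion, epoch firing rates, the
  18-variable regression set, permutation comparisons between recording
  conditions, best-variable rankings with Kendall's tau, and
  interspike-interval statistics (`encode_unit()`,
  `population_compare()`, `rank_variables()`, `spiking_stats()`).

`run_report()` strings every stage together from a seeded YAML
configuration and writes TSV tables, figures and a manifest.

## The feature-value RL model

Each of the six feature levels (two colours, two motions, two locations)
carries a value $v_i$, initialised at $v_0 = 0.5$, the chance reward
expectation. An object's value is the weighted combination of its three
feature-level values,

$$V(s) = \sum_d w_d \, v_{s(d)}, \qquad \textstyle\sum_d w_d = 1,$$

with uniform weights by default. A choice between stimuli $A$ and $B$ is a
softmax draw,

$$P(A) = \frac{e^{\beta V_A}}{e^{\beta V_A} + e^{\beta V_B}},$$

and the outcome $o \in \{0, 1\}$ generates a reward prediction error
$\delta = o - V_{\text{chosen}}$ that is scaled by the learning rate
$\eta$ to update every chosen-stimulus feature level,
$v \leftarrow v + \eta\,\delta$, while the unchosen stimulus' feature
levels decay toward the initial value,
$v \leftarrow v + \gamma\,(v_0 - v)$.

Two design choices were genuinely open and are fixed as follows. The decay
target is $v_0$ rather than 0, keeping values interpretable as reward
expectations anchored at chance; and the dimension weights sum to one so
object values stay commensurate with outcomes in $[0,1]$ (with
$v_0 = 0.5$ and $\eta, \gamma \in [0,1]$ the values provably remain in
$[0,1]$; a simulation sweep asserts this in the tests). Values reset to
$v_0$ at session boundaries but persist across block reversals within a
session — reversal learning consists exactly of carrying stale colour
values into the new block. The published hybrid model this skeleton
descends from also carries a Bayesian feature-weighting component; that
component lives in an external reference and is deliberately not
reproduced — the dimension weights are the only attention-like asymmetry
here.

Fitting maximises $\sum_t \log P(\text{choice}_t)$ over
$(\eta, \beta, \gamma)$ with bounded L-BFGS-B from 10 starts (one central,
nine uniform in the bounds), ties broken first-found; the likelihood loop
is compiled (Rcpp) because the sequential value updates cannot be
vectorised. The validation study (`validate_rl_recovery()`) refits 50
simulated sessions of 24 blocks at $\eta = 0.2$, $\beta = 6$,
$\gamma = 0.15$ and measures the median absolute relative error of each
parameter; the acceptance suite requires all three below 20%.

## The ideal-observer learning curve

Learning within a block is estimated by a state-space model: a latent
random walk $x_t = x_{t-1} + \varepsilon_t$,
$\varepsilon_t \sim N(0, \sigma^2_\varepsilon)$, observed through binary
outcomes with $P(\text{correct}_t) = \mathrm{logit}^{-1}(x_t + \mu)$,
where $\mu = \mathrm{logit}(\text{chance})$ and $x_0 = 0$, so the curve
starts at chance — the anchoring is not dictated by the framework and is
fixed here by that interpretability argument. The process variance is
estimated by EM (tolerance $10^{-8}$, at most 500 iterations), one
variance per block.

The E-step is the standard Gaussian-approximation smoother, iterated: each
pass linearises the Bernoulli observations at the previous smoothed
trajectory (pseudo-observation $z_t = x_t + (y_t - p_t)/w_t$ with
precision $w_t = p_t(1-p_t)$), runs a linear Kalman forward filter and
fixed-interval (RTS) smoother, and feeds the result into the next pass;
the linearisation point is warm-started across EM iterations and iterated
to self-consistency after the variance converges, so the reported curve is
the joint posterior mode with Laplace marginal variances. A one-pass
(non-iterated) version systematically under-shoots the state magnitude
when the process variance is large; the iterated form agrees with an exact
400-bin dense-grid smoother (`em_grid_smoother()`, the test oracle) to
within 0.05 in probability on random chance-level sequences. Two details
of that comparison matter: the grid posterior is summarised by its
*median*, because the median is the only location that commutes with the
monotone link and is exactly what the Gaussian centre estimates; and the
oracle sequences are iid Bernoulli(0.5).

Two numerical choices guard known pathologies. First, on degenerate
sequences (all outcomes identical) the variance MLE diverges — the
likelihood increases without bound in $\sigma^2_\varepsilon$ — which
inflates the confidence bounds until they are useless; the M-step
therefore applies a ceiling `var_max = 0.3`, an order of magnitude above
the estimates observed on informative blocks (typically 0.01–0.15), so it
binds only in the degenerate regime. Second, in that same large-variance
regime the Gaussian approximation of the strongly skewed exact posterior
is poor (differences up to ~0.17 in probability); this is a documented
limitation, not a target of further engineering.

Confidence bounds map the Gaussian state quantiles through the link. The
*learning trial* is the first trial whose lower 95% confidence bound
exceeds chance and never drops back for the remainder of the block. The
bound is one-sided by default (the 5th percentile), the usual convention
for a "lower 95% confidence bound" in this framework; the two-sided
2.5th-percentile variant is available via `two_sided = TRUE`. The
one-sided reading also matters practically: with two-sided bounds roughly
a third of clearly learned step-change blocks end with no learning trial
at all, because the block-end bound droops below chance after late errors.

Even so, detection on the step-change validation (Bernoulli probability
jumping 0.5 to 0.9 at a known trial $k \in [8, 20]$, 40-trial blocks) has
a structural ceiling: the ML process variance of a step under a
random-walk model is large, the block-end bound is wide, and the
persistence rule voids detection whenever a late error pulls it to
chance. `validate_learning_detection()` measures the rate of learning
trials within $k \pm 5$ over all blocks and among detected blocks; the
acceptance suite asserts the stricter all-blocks form. The windowed
criterion detector has a different structural issue: at chance
performance a 10-trial window reaches 7/10 with probability 0.17, so with
late change points the criterion usually fires before the true change.
Both assertions are kept at their nominal thresholds and their outcomes
are reported as measured.

## Behavioural metrics

The criterion learning trial is the first trial $t$ with
$\text{mean}(o_t, \ldots, o_{t+9}) \ge 0.70$ — the window includes the
candidate trial itself, and the comparison is non-strict so that 7/10
counts; windows extending past the block end are not evaluated. Averaged
learning curves exclude each session's first block, average only learned
blocks, and smooth with a trailing 4-trial moving average from trial 4
onward; the standard error is computed across blocks per trial index.
EC~n~/CC~n~ analyses count, for each lag $n$, the proportion correct among
trials $n$ after every anchor trial (overlapping anchors allowed), within
block boundaries; the block phase (early: anchor in trials 1–9; late: 10
onward) restricts the anchor position, and lags with no anchors are
reported as undefined rather than zero. Condition contrasts on these
metrics use the Wilcoxon rank-sum test; mixed ANOVA on real behavioural
data is out of scope.

## Synthetic neurons and what they do (not) emulate

Ground-truth units are Poisson: within an analysis epoch the rate on
trial $t$ is
$\lambda_t = \lambda_0 \exp\!\big(\sum_v g_v\, z(v_t)\big)$ with z-scored
regressors, and $\lambda_0$ elsewhere; the log-linear form keeps rates
positive for any gain, and undefined regressor values contribute no
modulation. Rates above 500 Hz abort generation as a mis-specification
guard. The two analysis epochs follow the task: feedback 0.05–1 s after
reward delivery and attention 0.05–0.7 s after colour-cue onset.

Waveforms are a two-lobe difference-of-Gaussians (negative trough, then a
positive peak), sampled at 40 kHz and peak-aligned. Class-defining metric
targets are drawn per unit and the lobe parameters are refined against
`waveform_metrics()` until the measured metrics match the targets. The
default classes place cortical narrow-spiking units at 0.20 ms
trough-to-peak / 0.18 ms repolarization versus 0.45 / 0.38 ms for
broad-spiking units (SDs 0.03–0.05 ms), and striatal units at 0.12 ms
half-maximum peak width with a steep valley-decay slope versus 0.25 ms
and a shallow slope; the default NS fraction is 0.3, a realistic
interneuron proportion. Only these four metrics are guaranteed — the
generator makes no claim of full waveform realism, and the spike trains
have no refractoriness, bursting, drift, or latency structure. Passing
recovery tests therefore show the *pipeline* is correct on data obeying
its assumptions, not that real recordings meet those assumptions.

## Cell-type classification

Metrics are measured on amplitude-normalised waveforms after cubic-spline
upsampling to 100 kHz, with sub-sample interpolation of extrema and
threshold crossings. Repolarization time is the first post-peak return to
25% of the peak, and the valley-decay slope is measured over the first
0.1 ms after the trough; both constants are config-exposed since the
underlying study names the metrics without defining them numerically.
Classification z-scores the scheme's two metrics, projects onto the first
principal component, and partitions with 2-means (50 seeded restarts) —
the simplest reading of clustering on the first PCA component. Cluster
labels are assigned biologically: the narrower cluster (smaller
trough-to-peak duration cortically, smaller peak width striatally) is NS.
A mean silhouette on the projected scores reports cluster quality, and
zero-variance metric sets are rejected as degenerate rather than
clustered.

## The encoding battery

Spike trains are converted to spike-density functions with a Gaussian
kernel (SD 50 ms). The per-trial epoch rate is the mean of that trace
over the window, which has the closed form
$\frac{1}{|W|}\sum_{s} [\Phi(\frac{b - s}{\sigma}) - \Phi(\frac{a - s}{\sigma})]$
over spikes $s$ and window $(a, b)$ — evaluated exactly, no grid; a raw
count mode is available.

The 18 regressors comprise six binary stimulus variables (colour, motion,
location of the chosen and of the target stimulus), six outcome variables
(outcome; outcome during and after learning; previous outcome given a
correct or an error trial; error order during learning, a descending rank
over pre-learning errors), and six epoch-dependent latent variables
(feedback epoch: signed, positive, negative RPE and their
learning-restricted versions; attention epoch: choice probability and the
chosen value on rewarded/unrewarded trials, plus learning-restricted
versions). Learning-restricted regressors are defined only before the EM
learning trial of the block; a block with no learning trial counts as
entirely during learning. Undefined values exclude a trial from that
regressor's fit only.

Each (unit, epoch, variable) is fit as a separate univariate OLS
regression — the battery reports one correlation coefficient per
regression, and a neuron may have many significant regressions, which is
incompatible with a single joint fit; a joint design-matrix mode is
deliberately out of scope. Fits need at least 30 valid trials, use
$\alpha = 0.05$, and apply no multiple-testing correction across
variables (config-exposed). Condition contrasts permute condition labels
(5000 permutations by default) on the per-unit coefficients of
significant fits — unsigned contrasts use $|r|$, the positive/negative
classes subset by sign — with a two-sided add-one p value; cells with
fewer than 3 units in either group are marked untested, not zero. Per
unit, the best variable is the significant regression with the highest
$R^2$; variables are ranked by the fraction of units for which they are
best, and rankings are compared across conditions with Kendall's tau.
CV is the SD/mean of pooled within-epoch interspike intervals and LV is
$\frac{3}{n-1}\sum_i \big(\frac{I_i - I_{i+1}}{I_i + I_{i+1}}\big)^2$,
the standard local-variation convention (1 for Poisson, 0 for regular
firing); noise correlations are Pearson correlations of per-trial epoch
spike counts over shared trials.

## Validation studies and problem sizes

The validation functions (`validate_*()`) run the pipeline against known
ground truth at the sizes the test suite and `scripts/acceptance.R` use:
50 sessions × 24 blocks for parameter recovery; 100 15-trial sequences
for the smoother oracle; 500 step-change blocks for learning-trial
detection; 200 units × 400 trials (50 tuned to signed RPE at gain 0.3)
for encoding recovery; 200 power repeats (gains 0.4 vs 0.2, 30 units per
group) and 500 null repeats for the permutation test, at 1000
permutations per repeat — the 5000-permutation default applies to actual
condition comparisons; and 200 waveforms for classification. The
power/calibration repeats simulate unit coefficients at the count level
of the same log-linear rate model (Poisson counts regressed on the
z-scored variable), since per-unit correlations of epoch counts are what
the comparison consumes; spike timing within the epoch is irrelevant to
them.

## Known limitations

* The Gaussian approximation degrades when the estimated process variance
  is at its ceiling (degenerate outcome sequences); bounds there are
  indicative only.
* The learning-trial persistence rule is conservative near block ends:
  late errors in genuinely learned blocks can void detection.
* The RL model omits the Bayesian feature-weighting component of the full
  published hybrid model; fitted parameters are interpretable within the
  skeleton model only.
* Synthetic units are Poisson with epoch-constant modulation; none of the
  temporal structure of real spike trains is emulated.
* The windowed criterion detector locates the start of sustained
  performance, which at late change points is dominated by chance runs;
  its agreement with the EM learning trial is at the cohort level, not
  per block.
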