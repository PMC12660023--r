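---
title: "Latent Markov models for noninvariant measurements: models, inference, and the simulation engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent Markov models for noninvariant measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmmni)
```

## The problem

Computer-interactive assessments log several indicators for every item a
respondent works on: a response score, an interaction time, an action count.
A latent Markov model (LMM) explains such multimodal cross-sectional
time-series by a discrete latent state sequence with first-order dependence:
the subject occupies one of $S$ states at each of $J$ measurement events, and
the state generates the $K$ observed indicators at that event.

Classical LMM estimation assumes *measurement invariance* (MI): the emission
distributions depend only on the state, never on the event. For assessment
data this is rarely credible — items are deliberately built to differ in
difficulty and labor. `lmmni` implements the *measurement-noninvariant* (MNI)
variant in which every emission parameter carries an item index, together
with the matching Baum–Welch/EM machinery, Viterbi decoding, standard errors,
model-selection criteria, and a Monte Carlo engine for validating the whole
chain. The MI-constrained model is retained both as a baseline and as the
pooled special case of every update.

## Model

**Structural part.** Initial states follow a multinomial logit with state 1 as
the reference, $\pi_s \propto \exp(\beta_{0s})$, $\beta_{01} = 0$; transitions
follow row-wise multinomial logits $a_{ss'} \propto \exp(\beta_{ss'})$,
$\beta_{s1} = 0$. The chain is time-homogeneous and first order.

**Measurement part.** Given state $s$ at event $j$, the $K$ indicators are
conditionally independent (local independence) and each follows its family's
canonical model, with parameters indexed by both $j$ and $s$ under MNI and by
$s$ alone under MI:

* nominal — baseline-category multinomial logit, category 0 as reference:
  $P(Y = m) \propto \exp(\beta_{jms})$, $\beta_{j0s} = 0$;
* ordinal — adjacent-categories logit, $\log[P(m)/P(m-1)] = \eta_{jms}$,
  equivalent to the multinomial model under $\beta_m = \sum_{l \le m} \eta_l$;
* continuous — Gaussian with location $\mu_{js}$ and scale $\sigma_{js}$;
* count — Poisson with rate $\lambda_{js}$.

Internally all parameters live on an unconstrained scale (reference-fixed
logits, $\log\sigma$, $\log\lambda$), so probability vectors and positivity
constraints hold by construction; natural-scale views are derived
(`natural_parameter_table()`). Counts with heavy tails can instead be declared
continuous after a log transform at the data-preparation stage, which mirrors
common practice for action counts.

## Inference

`em_fit()` maximizes the observed-data likelihood by EM.

* **E-step.** Scaled forward–backward recursions run per subject with
  *item-specific* emission probabilities. We use per-event scaling constants
  rather than log-space recursions: at each event the emission column maximum
  is factored out, the forward vector is renormalized, and the log-likelihood
  is accumulated from the log normalizers. The recursions are compiled (Rcpp)
  since they dominate the per-iteration cost.
* **M-step.** The initial-state and transition updates are the usual
  Lagrange-constrained closed forms (posterior averages and ratios of summed
  pairwise to summed marginal posteriors). Gaussian and Poisson parameters are
  posterior-weighted moments. Discrete-indicator logits are updated per
  (item, state) block by Newton–Raphson on the expected block log-likelihood;
  blocks are separable given the posteriors. Under MI every emission update
  simply pools its sufficient statistics over items.

**Numerical safeguards.** Each Newton block is a saturated multinomial whose
optimum is the share vector of the expected counts; the iteration therefore
starts from that closed form and acts as a verification/polish step, with
step-halving on any decrease and a $10^{-6}$ ridge on singular Hessians.
Expected counts receive a relative smoothing of $10^{-10}$ so that an empty
category keeps a finite (clamped at $\pm 30$) logit instead of stalling the
iteration at the boundary. $\sigma$ is floored at $10^{-4}$ and $\lambda$ at
$10^{-6}$; a state whose posterior mass vanishes triggers a warning and a
uniform transition row rather than a hard failure.

**Starts and convergence.** The item-specific emission structure creates a
specific multimodality: because each item owns its emission parameters, the
likelihood admits solutions that relabel the states over a *segment of items*
and refit those items' parameters, at almost no likelihood cost when
transitions are sparse. Such modes can sit within a fraction of a
log-likelihood unit of the truth-consistent mode while being useless for
parameter interpretation. `em_fit()` therefore uses a portfolio of starting
points: (i) a classify-then-estimate start — $k$-means on the standardized
subject-event feature vectors, whose cluster labels are *globally* consistent
across items, with every parameter block seeded from the hard assignment;
(ii) jittered copies of it; and (iii) fully random starts (Dirichlet(1)
structural draws, quantile-split moments of an anchor indicator, jittered
marginal category frequencies) for global diversity. With `start_iter` set,
all starts run briefly and the three most promising are continued — the
usual short-run (emEM-style) strategy, used by the experiment harnesses.
The final solution is the highest final log-likelihood, with one documented
tie-break: among candidates within 5 log-likelihood units — differences with
no statistical meaning at these data sizes — a solution descended from a
label-consistent start is preferred over one from a random start, which
suppresses the segment-relabeling modes without ever referencing generating
values. Convergence requires *both* an absolute log-likelihood change below
`loglik_tol = .001` and a maximum natural-scale parameter change below
`param_tol = .005`.

**Standard errors** (`standard_errors()`) follow the observed-information
definition: the square root of the diagonal of the inverse negative Hessian of
the observed-data log-likelihood, computed by central differences
(`pracma::hessian`) on the unconstrained parameterization. A non-positive
definite Hessian is repaired by eigenvalue clipping with a warning;
coordinates without a positive repaired variance come back as `NA`. The cost
is quadratic in the parameter count, so this is meant for the final model of
moderate size, not for every replication of a simulation.

**Model selection.** `information_criteria()` reports AIC, corrected AIC
(the small-sample AICc form), BIC, and the adjusted BIC with the
$\log((n+2)/24)$ penalty. $n$ is the number of *subjects* — the independent
sampling units — not subject-events. The corrected AIC is undefined when
$n \le df + 1$, which genuinely happens for MNI models on small samples, and
is then reported as `NA`.

## Decoding

`viterbi_decode()` returns the exact maximum a posteriori state *sequence* by
the max-product recursion in log space, ties broken deterministically toward
the lowest state index. The per-event argmax of the marginal posteriors
(`posterior_states()`) is also exposed, but only as a diagnostic: it does not
maximize the joint posterior and can assemble jointly implausible paths.

## The simulation engine

`simulate_lmm()` reproduces the generating process of the validation
experiments so that every stage is testable without external data. One design
cell (`simulation_design()`) fixes:

* $S \in \{3, 5\}$ with role labels — three states: normal, noneffortful,
  plodding; five states: normal, noneffortful, struggling, efficient,
  plodding;
* initial distribution: balanced ($1/S$ each) or skewed
  ($1 - .1(S-1)$ on the normal state, $.1$ elsewhere);
* transitions: stable (stayer probability $.9$) or unstable ($.7$),
  off-diagonals equal by row normalization;
* emission shift $\delta \in \{.5, 1.0\}$ (moderate/large);
* sample size $N$; $J$ measurement events; $K = 3$ indicators
  (ordinal score with 4 categories, Gaussian log-time, Poisson action count).

The normal state sits at hyperparameters $\mu_0, \sigma_0, \lambda_0$; other
states shift $\mu$ and $\log\lambda$ by $\pm\delta$ according to their role
(noneffortful: $-\delta$ time and count; plodding and struggling: $+\delta$
both; efficient: $-\delta$ time). Ordinal adjacent-category logits are drawn
uniformly and the implied category probabilities are reordered to the state's
accuracy role (low / high / middle-peaked / as drawn for the normal state).
Under the MNI generator the ordinal draws are per item, and uniform per-item
effects (`item_range`) perturb $\mu$ and $\log\lambda$, so noninvariant data
differ per item in every channel; the MI generator draws one pooled set.
$\sigma$ is generated state- and item-invariant but always estimated freely.
Confining the noninvariance to the ordinal channel (`item_range = 0`) is
available as a sensitivity setting, but note that under it the pooled (MI)
model is exactly correct for the location and rate parameters, so
underfitting it to noninvariant data costs almost nothing — the cross-fit
contrast the package's experiments study requires noninvariance in all
channels to be a meaningful stressor.

### Defaults, and why

Several generating constants are design choices of this package:

| quantity | default | rationale |
|---|---|---|
| events $J$ | 20 | a medium-length assessment form |
| $N$ levels | 250/500/1000 ($S=3$); 500/1000/2000 ($S=5$) | small/moderate/large calibration samples; more states need more data |
| $\mu_0$ | 4.0 log-seconds | ~55 s median response time |
| $\sigma_0$ | 0.5 | typical log-time dispersion; makes $\delta$ a 1–2 SD separation |
| $\lambda_0$ | 5 actions | a plausible per-item interaction count |
| ordinal logits | $U(-1.5, 1.5)$ | category probabilities between roughly .05 and .6 |
| item effects | $U(-0.5, 0.5)$ on $\mu$, $\log\lambda$ | item-to-item variation of the same order as a moderate state shift |

What the generator does *not* emulate: skewed or zero-inflated emissions,
missing entries, covariate effects, time-varying transitions, and items that
differ in their number of response categories. Passing recovery tests under
this generator therefore validates the inferential chain under canonical
emission families, not robustness to those real-data complications.

## Evaluation machinery

* `align_state_labels()` resolves label switching by exhaustive search over
  all $S!$ permutations, minimizing the summed squared distance between
  estimated and generating parameters concatenated on their natural scales
  (probabilities, $\mu$, $\sigma$, $\lambda$). Euclidean distance is our
  choice; any sensible metric selects the same permutation in non-degenerate
  cells. Pooled MI estimates are broadcast across items before comparison
  with per-item truth.
* `bias_rmse_summary()` reports bias, absolute bias and RMSE per congeneric
  domain ($\pi$, $A$, ordinal category probabilities, $\mu$, $\sigma$,
  $\lambda$), pooling items, states, categories and replications. Reference
  levels (state 1 for $\pi$, destination 1 for $A$, category 0 for scores)
  are excluded so sum-to-one constraints cannot cancel errors.
* `state_match_rate()` is the fraction of subject-event cells whose decoded
  state equals the truth after alignment.
* `run_study()` / `crossfit_experiment()` drive the two experiment grids: the
  validation study (full factorial over $S$, initial distribution, transition
  stability, $\delta$, $N$, with the MNI generator) and the cross-fit study
  ($S = 3$, additionally crossing the generating model, fitting both MI and
  MNI to every dataset and contrasting the ill-fitting with the matching
  model).

## Problem sizes used by the shipped experiments

The packaged test-suite and the acceptance script run the harness at desk
scale, a deliberate package choice so the full chain stays conveniently
reproducible on a laptop: 2 replications per cell for the three-state grid,
1 for the five-state grid and the cross-fit grid, with eight short-run starts
(50 iterations) per fit and the three most promising continued up to 200
iterations. The
directional conclusions (larger separation and stabler chains help; underfit
hurts more than overfit and is not repaired by sample size) are stable at this
scale; the absolute summaries carry Monte Carlo noise of a few points, which
is why the tests assert them with correspondingly generous bands.

## Known limitations

* The likelihood is multimodal; multiple random starts mitigate but do not
  guarantee a global optimum, and weakly separated cells (moderate shift,
  unstable transitions, skewed initial distribution) occasionally converge to
  near-tied optima with visibly different decoded paths.
* Numerical-Hessian standard errors are accurate but $O(p^2)$ in
  log-likelihood evaluations; for the large MNI models they are practical
  only at the final fit.
* No missing-data handling: subjects must have complete $J \times K$ records.
* Covariates, random effects, higher-order or time-varying transitions, and
  non-canonical emission families are out of scope.
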