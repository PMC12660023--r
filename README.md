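# lmmni

Latent Markov models for noninvariant measurements.

`lmmni` estimates and decodes latent Markov (hidden Markov) models for the
multimodal log data produced by computer-interactive assessments — per-item
response scores, interaction times, action counts — in settings where the
items themselves have distinct measurement properties. Classical latent
Markov estimation assumes *measurement invariance* (MI): the emission
distribution of an indicator depends only on the latent state. Assessment
items are designed to differ, so this package implements the
*measurement-noninvariant* (MNI) model in which every emission parameter is
item-specific, along with the matching inference machinery. It is aimed at
psychometricians and education researchers doing transition analysis on
process data, and at methodologists studying the consequences of
(mis)specifying measurement invariance.

## Model

Subject $i$ works through $J$ items in a fixed order; at item $j$ a latent
state $C_{ij} \in \{1,\dots,S\}$ emits $K$ indicators $Y_{ijk}$. The joint
distribution is

$$P(\mathbf{y}, \mathbf{c}) \;=\; \pi_{c_1}\, b_{1 c_1}(\mathbf{y}_1)
  \prod_{j=2}^{J} a_{c_{j-1} c_j}\, b_{j c_j}(\mathbf{y}_j),$$

with multinomial-logit initial ($\pi$) and transition ($A$) models, and
per-item emission models $b_{js}$ built from canonical families under local
independence: baseline-category logits (nominal), adjacent-categories logits
(ordinal), Gaussian (continuous, e.g. log response time), Poisson (count).
Under the MI constraint the item index is dropped. Estimation is EM with
scaled forward–backward recursions (compiled), closed-form M-steps for the
structural, Gaussian and Poisson parameters, per-block Newton updates for the
discrete-indicator logits, numerical-Hessian standard errors, AIC/AICc/BIC/
adjusted-BIC model selection, and exact Viterbi decoding. A simulation and
evaluation engine (parameter generation by role-based shifts, label
alignment, bias/RMSE/match-rate summaries, cross-fit experiments) makes the
whole chain testable end to end.

## Worked example

```r
library(lmmni)

# one cell of the validation design: 3 states, stable chain, large shifts
design <- simulation_design(S = 3, init_scenario = "balanced",
                            transition_scenario = "stable",
                            delta = 1.0, N = 200, J = 10, seed = 42)
sim <- simulate_lmm(design)

fit <- em_fit(sim$data, S = 3, invariance = "MNI",
              config = em_config(n_starts = 2, seed = 7))
fit
#> lmm_fit: S = 3 , invariance = MNI , loglik = -9023.7457 , df = 188
#>   converged: TRUE after 40 iterations
#>   AIC: 18423.49  BIC: 19043.58

al  <- align_state_labels(fit$params, sim$params)   # undo label switching
dec <- viterbi_decode(sim$data, fit$params)
state_match_rate(dec$states, sim$states, al$perm)
#> [1] 0.972

bias_rmse_summary(al$aligned, sim$params)
#>          domain         bias   abs_bias       rmse  n
#> 1 category_prob -0.003359112 0.04054946 0.05545805 90
#> 2          init  0.028950845 0.02895085 0.03677648  2
#> 3        lambda  0.047642049 0.25491979 0.38038056 30
#> 4            mu -0.008897049 0.04322140 0.05151071 30
#> 5         sigma  0.009048358 0.04063311 0.04884644 30
#> 6    transition  0.004839043 0.01255441 0.01430580  6
```

The fit recovers the generating parameters closely (RMSEs on the probability
scales around .01–.06; the Poisson rates, on a scale of ≈5 actions, around
.4) and decodes 97.2% of the latent subject-item states correctly after
alignment. `standard_errors(fit, sim$data)` adds observed-information
standard errors; `information_criteria()` and the `compare` CLI subcommand
reproduce MI-vs-MNI model-selection tables; `run_study()` and
`crossfit_experiment()` drive the full factorial experiments.

A thin command-line wrapper (`inst/cli/lmmni`) exposes `simulate`, `fit`,
`decode`, `evaluate`, `compare`, `study1` and `study2` subcommands over the
same functions.

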