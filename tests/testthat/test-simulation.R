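test_that("design grids cross the factorial structure", {
  g3 <- make_design_grid("I", S = 3)
  expect_length(g3, 24)            # 2 init x 2 transition x 2 delta x 3 N
  gI <- make_design_grid("I")
  expect_length(gI, 48)            # both state dimensionalities
  gII <- make_design_grid("II")
  expect_length(gII, 48)           # generator MI/MNI x 24, S fixed at 3
  expect_true(all(vapply(gII, function(d) d$S, integer(1)) == 3L))
  expect_setequal(unique(vapply(gII, function(d) d$generator, character(1))),
                  c("MI", "MNI"))
  # N levels differ by state dimensionality
  expect_setequal(unique(vapply(g3, function(d) d$N, integer(1))),
                  c(250L, 500L, 1000L))
  g5 <- make_design_grid("I", S = 5)
  expect_setequal(unique(vapply(g5, function(d) d$N, integer(1))),
                  c(500L, 1000L, 2000L))
  # singleton overrides give a single cell
  g1 <- make_design_grid("I", S = 3, N = 500, delta = 1.0,
                         init_scenario = "balanced",
                         transition_scenario = "stable")
  expect_length(g1, 1)
})

test_that("structural scenario values follow the design", {
  d_bal <- simulation_design(S = 5, init_scenario = "balanced")
  d_skw <- simulation_design(S = 5, init_scenario = "skewed")
  p_bal <- generate_emission_parameters(d_bal)
  p_skw <- generate_emission_parameters(d_skw)
  expect_equal(init_probs(p_bal), rep(.2, 5))
  expect_equal(init_probs(p_skw), c(.6, .1, .1, .1, .1))
  d_st <- simulation_design(S = 3, transition_scenario = "stable")
  d_un <- simulation_design(S = 3, transition_scenario = "unstable")
  expect_equal(diag(transition_matrix(generate_emission_parameters(d_st))),
               rep(.9, 3))
  A_un <- transition_matrix(generate_emission_parameters(d_un))
  expect_equal(diag(A_un), rep(.7, 3))
  expect_equal(A_un[1, 2], .15)    # off-diagonals equal by row normalization
})

test_that("emission shifts follow the state roles", {
  set.seed(7)
  d <- simulation_design(S = 5, delta = 1.0, generator = "MI")
  p <- generate_emission_parameters(d)
  mu <- p$emissions[[2]]$mu[1, ]
  lam <- exp(p$emissions[[3]]$log_lambda[1, ])
  h <- d$hyper
  # roles: normal, noneffortful, struggling, efficient, plodding
  expect_equal(mu, h$mu + c(0, -1, 1, -1, 1))
  expect_equal(log(lam), log(h$lambda) + c(0, -1, 1, 0, 1))
  expect_equal(exp(p$emissions[[2]]$log_sigma[1, ]), rep(h$sigma, 5))
  # accuracy roles order the ordinal category probabilities
  probs <- function(s) adjacent_emission_probs(p$emissions[[1]]$logits[1, s, ])
  expect_true(all(diff(probs(2)) <= 0))   # noneffortful: mass on low scores
  expect_true(all(diff(probs(3)) <= 0))   # struggling: mass on low scores
  expect_true(all(diff(probs(4)) >= 0))   # efficient: mass on high scores
  expect_equal(which.max(probs(5)), 3)    # plodding: peak at a middle category
})

test_that("MNI generator varies parameters across items, MI does not", {
  set.seed(8)
  d_mni <- simulation_design(S = 3, generator = "MNI", J = 12)
  p_mni <- generate_emission_parameters(d_mni)
  expect_equal(dim(p_mni$emissions[[2]]$mu), c(12L, 3L))
  # item variation enters through the per-item ordinal draws and through
  # uniform item effects on the location and rate channels
  expect_gt(sd(p_mni$emissions[[1]]$logits[, 1, 1]), 0)
  expect_gt(sd(p_mni$emissions[[2]]$mu[, 1]), 0)
  d_mi <- simulation_design(S = 3, generator = "MI", J = 12)
  p_mi <- generate_emission_parameters(d_mi)
  expect_equal(dim(p_mi$emissions[[2]]$mu), c(1L, 3L))
  expect_equal(p_mi$invariance, "MI")
  # the item effects can be switched off for an ordinal-only sensitivity run
  d_it <- simulation_design(S = 3, generator = "MNI", J = 12,
                            hyper = list(item_range = 0))
  p_it <- generate_emission_parameters(d_it)
  expect_equal(sd(p_it$emissions[[2]]$mu[, 1]), 0)
})

test_that("state chains reproduce the stayer and initial probabilities", {
  set.seed(9)
  d <- simulation_design(S = 5, init_scenario = "skewed",
                         transition_scenario = "stable", N = 2000, J = 20)
  p <- generate_emission_parameters(d)
  states <- draw_state_sequences(p, d$N)
  # empirical stay frequency close to .9 (MC standard error ~ .002)
  stays <- mean(states[, -1] == states[, -20])
  expect_lt(abs(stays - 0.9), 3 * sqrt(.9 * .1 / (2000 * 19)))
  # empirical initial-state distribution close to (.6, .1, .1, .1, .1)
  freq <- tabulate(states[, 1], nbins = 5) / 2000
  expect_lt(max(abs(freq - c(.6, .1, .1, .1, .1))), 3 * sqrt(.6 * .4 / 2000) + .01)
  # degenerate stayer probability of one gives constant rows
  p1 <- p
  p1$transition_logits <- matrix(-800, 5, 5); diag(p1$transition_logits) <- 0
  const <- draw_state_sequences(p1, 50)
  expect_true(all(const == const[, 1]))
})

test_that("generated indicator moments match the emission parameters", {
  set.seed(10)
  d <- simulation_design(S = 3, N = 3000, J = 4, delta = 1.0)
  p <- generate_emission_parameters(d)
  states <- draw_state_sequences(p, d$N)
  data <- generate_indicator_data(states, p)
  for (j in c(1, 3)) for (s in 1:3) {
    idx <- states[, j] == s
    n_cell <- sum(idx)
    mu_js <- p$emissions[[2]]$mu[j, s]
    lam_js <- exp(p$emissions[[3]]$log_lambda[j, s])
    expect_lt(abs(mean(data$values[idx, j, 2]) - mu_js),
              4 * 0.5 / sqrt(n_cell))
    expect_lt(abs(mean(data$values[idx, j, 3]) - lam_js),
              4 * sqrt(lam_js / n_cell))
  }
})

test_that("simulation pipeline is reproducible under a fixed seed", {
  d <- simulation_design(S = 3, N = 30, J = 5, seed = 77)
  s1 <- simulate_lmm(d)
  s2 <- simulate_lmm(d)
  expect_identical(s1$data$values, s2$data$values)
  expect_identical(s1$states, s2$states)
  d2 <- simulation_design(S = 3, N = 30, J = 5, seed = 78)
  s3 <- simulate_lmm(d2)
  expect_false(identical(s1$data$values, s3$data$values))
})
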