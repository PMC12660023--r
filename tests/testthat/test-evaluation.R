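test_that("label alignment recovers identity and constructed swaps", {
  set.seed(130)
  d <- simulation_design(S = 3, seed = 42)
  truth <- generate_emission_parameters(d)
  al <- align_state_labels(truth, truth)
  expect_equal(al$perm, 1:3)
  expect_equal(al$distance, 0)
  # permuted copy: alignment must recover the permutation
  perm <- c(3, 1, 2)
  shuffled <- permute_states(truth, perm)
  al2 <- align_state_labels(shuffled, truth)
  # shuffled state k holds true state perm[k]; alignment must invert that
  expect_equal(al2$perm, order(perm))
  expect_lt(al2$distance, 1e-16)
  expect_equal(natural_parameter_table(al2$aligned), natural_parameter_table(truth),
               tolerance = 1e-10)
  # S = 1: only one permutation
  p1 <- random_params(1, 3)
  expect_equal(align_state_labels(p1, p1)$perm, 1L)
})

test_that("alignment broadcasts pooled MI estimates against per-item truth", {
  set.seed(131)
  d_mni <- simulation_design(S = 3, J = 6, generator = "MNI", seed = 9)
  truth <- generate_emission_parameters(d_mni)
  d_mi <- simulation_design(S = 3, J = 6, generator = "MI", seed = 9)
  pooled <- generate_emission_parameters(d_mi)
  al <- align_state_labels(pooled, truth)
  expect_length(al$perm, 3)
  rep_tab <- bias_rmse_summary(al$aligned, truth)
  expect_true(all(is.finite(rep_tab$rmse)))
})

test_that("bias and RMSE follow their definitions", {
  set.seed(132)
  d <- simulation_design(S = 3, J = 4, seed = 5)
  truth <- generate_emission_parameters(d)
  # exact estimates: all zeros
  r0 <- bias_rmse_summary(truth, truth)
  expect_true(all(r0$bias == 0))
  expect_true(all(r0$rmse == 0))
  # constant shift of mu: bias = abs bias = rmse = shift for that domain
  shifted <- truth
  shifted$emissions[[2]]$mu <- truth$emissions[[2]]$mu + 0.05
  r1 <- bias_rmse_summary(shifted, truth)
  expect_equal(r1$bias[r1$domain == "mu"], 0.05)
  expect_equal(r1$abs_bias[r1$domain == "mu"], 0.05)
  expect_equal(r1$rmse[r1$domain == "mu"], 0.05)
  # two replications with opposite errors: zero bias, rmse = |error|
  up <- truth; up$emissions[[2]]$mu <- truth$emissions[[2]]$mu + 0.1
  dn <- truth; dn$emissions[[2]]$mu <- truth$emissions[[2]]$mu - 0.1
  r2 <- bias_rmse_summary(list(up, dn), truth)
  expect_equal(r2$bias[r2$domain == "mu"], 0)
  expect_equal(r2$abs_bias[r2$domain == "mu"], 0.1)
  expect_equal(r2$rmse[r2$domain == "mu"], 0.1)
  # rmse^2 = bias^2 + variance across replications
  set.seed(21)
  reps <- lapply(1:6, function(r) {
    pr <- truth
    pr$emissions[[2]]$mu <- truth$emissions[[2]]$mu + rnorm(1, 0.02, 0.05)
    pr
  })
  r3 <- bias_rmse_summary(reps, truth)
  row <- r3[r3$domain == "mu", ]
  errs <- vapply(reps, function(p) p$emissions[[2]]$mu[1, 1] - truth$emissions[[2]]$mu[1, 1],
                 numeric(1))
  expect_equal(row$rmse^2, mean(errs)^2 + mean((errs - mean(errs))^2),
               tolerance = 1e-12)
})

test_that("reference levels are excluded from probability-domain summaries", {
  set.seed(133)
  d <- simulation_design(S = 3, J = 3, seed = 6)
  truth <- generate_emission_parameters(d)
  r <- bias_rmse_summary(truth, truth)
  S <- 3; J <- 3; M <- 4
  n <- setNames(r$n, r$domain)
  expect_equal(n[["init"]], S - 1L)                 # reference state dropped
  expect_equal(n[["transition"]], S * (S - 1L))     # reference destination dropped
  expect_equal(n[["category_prob"]], J * S * (M - 1L))  # category 0 dropped
  expect_equal(n[["mu"]], J * S)
})

test_that("state match rate counts aligned agreements", {
  truth <- rbind(c(1, 2), c(2, 2))
  expect_equal(state_match_rate(truth, truth), 1)
  almost <- rbind(c(1, 2), c(2, 1))
  expect_equal(state_match_rate(almost, truth), 0.75)
  # relabeled decoding with the matching permutation restores a perfect match
  relabeled <- matrix(c(3, 1, 1, 1), 2, 2)  # decoded labels under perm c(3,1,2)
  truth2 <- matrix(c(1, 2, 2, 2), 2, 2)
  expect_equal(state_match_rate(relabeled, truth2, perm = c(3, 1, 2)), 1)
  # invariant to applying one permutation to both sequences
  set.seed(99)
  dec <- matrix(sample(1:3, 40, TRUE), 8, 5)
  tr <- matrix(sample(1:3, 40, TRUE), 8, 5)
  p <- c(2, 3, 1)
  expect_equal(state_match_rate(dec, tr),
               state_match_rate(matrix(p[dec], 8, 5), matrix(p[tr], 8, 5)))
  # random guessing at S = 3 matches about a third of cells
  guess <- matrix(sample(1:3, 3000, TRUE), 100, 30)
  tru <- matrix(sample(1:3, 3000, TRUE), 100, 30)
  expect_lt(abs(state_match_rate(guess, tru) - 1 / 3), 0.04)
})

test_that("information criteria match their formulas and parameter counts", {
  ics <- information_criteria(-1000, 10, 100)
  expect_equal(ics[["AIC"]], 2020)
  expect_equal(ics[["BIC"]], 2000 + 10 * log(100))
  expect_equal(ics[["CAIC"]], 2020 + 2 * 10 * 11 / (100 - 11))
  expect_equal(ics[["ABIC"]], 2000 + 10 * log(102 / 24))
  expect_warning(ic2 <- information_criteria(-10, 10, 11), "undefined")
  expect_true(is.na(ic2[["CAIC"]]))
  # parameter counts: S=3, J=20, K=3 (ordinal M=4, gaussian, poisson)
  d <- simulation_design(S = 3, J = 20, generator = "MNI", seed = 1)
  expect_equal(n_parameters(generate_emission_parameters(d)), 368L)
  d_mi <- simulation_design(S = 3, J = 20, generator = "MI", seed = 1)
  expect_equal(n_parameters(generate_emission_parameters(d_mi)), 26L)
})

test_that("harness rows carry coherent per-replication summaries", {
  design <- simulation_design(S = 3, N = 120, J = 6, delta = 1.0,
                              transition_scenario = "stable")
  rows <- run_study_cell(design, reps = 2, models = "MNI",
                         config = em_config(n_starts = 1, max_iter = 80, seed = 3))
  expect_equal(nrow(rows), 2)
  expect_true(all(rows$match_rate > 0.5))
  expect_true(all(rows$rmse >= abs(rows$bias) - 1e-12))
  # cross-fit on a single cell yields one delta row per replication
  xf <- crossfit_experiment(list(simulation_design(S = 3, N = 100, J = 5,
                                                   generator = "MI")),
                            reps = 1,
                            config = em_config(n_starts = 1, max_iter = 60, seed = 4))
  expect_equal(nrow(xf$runs), 2)   # both models fit to the same data
  expect_equal(nrow(xf$deltas), 1)
  expect_equal(xf$deltas$d_abs_bias,
               xf$runs$abs_bias[xf$runs$model == "MNI"] -
                 xf$runs$abs_bias[xf$runs$model == "MI"])
})

test_that("penalty ordering: BIC penalizes the MNI model more than AIC", {
  sim <- small_sim(S = 3, N = 150, J = 6, generator = "MI", seed = 140,
                   transition_scenario = "stable", delta = 1.0)
  cfg <- em_config(n_starts = 1, max_iter = 80, seed = 2)
  fit_mi <- em_fit(sim$data, S = 3, invariance = "MI", config = cfg)
  fit_mni <- em_fit(sim$data, S = 3, invariance = "MNI", config = cfg)
  d_aic <- fit_mni$ics[["AIC"]] - fit_mi$ics[["AIC"]]
  d_bic <- fit_mni$ics[["BIC"]] - fit_mi$ics[["BIC"]]
  # on MI-generated data the overfitted model loses more under BIC
  expect_gt(d_bic, d_aic)
  expect_gt(d_bic, 0)
})
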