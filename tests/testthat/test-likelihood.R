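test_that("forward pass reproduces the hand-worked two-state example", {
  ex <- worked_example()
  fw <- forward_pass(ex$y, ex$params)
  # path enumeration: .6*.7*(.9*.5 + .1*.3) + .4*.2*(.2*.5 + .8*.3)
  expect_equal(exp(fw$loglik), 0.2288, tolerance = 1e-12)
  expect_equal(prod(fw$scale), 0.2288, tolerance = 1e-12)
  # scaled alpha rows normalize
  expect_equal(rowSums(fw$alpha), c(1, 1))
})

test_that("forward likelihood equals brute-force path enumeration", {
  set.seed(11)
  for (rep in 1:12) {
    S <- sample(1:3, 1); J <- sample(1:5, 1)
    params <- random_params(S, J)
    y <- random_observations(params)
    expect_equal(forward_pass(y, params)$loglik, enumerate_loglik(y, params),
                 tolerance = 1e-10)
  }
})

test_that("states marginalize out when emissions do not separate them", {
  # identical emissions across states: likelihood = product of event probs
  spec <- indicator_spec("x", "nominal", n_categories = 2L)
  logits <- array(log(1), dim = c(3, 2, 1))  # p = (.5, .5) everywhere
  params <- lmm_parameters(2, 3, list(spec), "MNI",
                           logits_from_probs(c(.3, .7)),
                           rbind(logits_from_probs(c(.6, .4)),
                                 logits_from_probs(c(.1, .9))),
                           list(list(logits = logits)))
  y <- matrix(c(0, 1, 0), ncol = 1)
  expect_equal(exp(forward_pass(y, params)$loglik), 0.125, tolerance = 1e-12)
})

test_that("backward pass satisfies the forward-backward identity", {
  ex <- worked_example()
  bw <- backward_pass(ex$y, ex$params)
  fw <- forward_pass(ex$y, ex$params)
  expect_equal(bw[2, ], c(1, 1))
  # unscaled beta_1 = (.9*.5 + .1*.3, .2*.5 + .8*.3) = (.48, .34)
  expect_equal(bw[1, ] * fw$scale[2], c(0.48, 0.34), tolerance = 1e-12)
  # sum_s alpha_j(s) beta_j(s) = 1 at every event under scaling
  expect_equal(rowSums(fw$alpha * bw), c(1, 1))
  # J = 1: beta is identically one
  p1 <- random_params(2, 1)
  expect_equal(backward_pass(random_observations(p1), p1), c(1, 1))
})

test_that("posterior marginals match path enumeration and are consistent", {
  ex <- worked_example()
  post <- posterior_marginals(ex$y, ex$params)
  # gamma_2(1) = (.189 + .008) / .2288
  expect_equal(post$gamma[2, 1], (0.189 + 0.008) / 0.2288, tolerance = 1e-10)
  expect_equal(rowSums(post$gamma), c(1, 1))
  # xi marginalizes to gamma
  expect_equal(rowSums(post$xi[1, , ]), post$gamma[1, ], tolerance = 1e-12)
  expect_equal(colSums(post$xi[1, , ]), post$gamma[2, ], tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:6) {
    S <- sample(2:3, 1); J <- sample(2:4, 1)
    params <- random_params(S, J)
    y <- random_observations(params)
    post <- posterior_marginals(y, params)
    for (j in seq_len(J)) for (s in seq_len(S))
      expect_equal(post$gamma[j, s], enumerate_gamma(y, params, j, s),
                   tolerance = 1e-10)
    for (j in seq_len(J - 1))
      expect_equal(rowSums(post$xi[j, , ]), post$gamma[j, ], tolerance = 1e-12)
  }
})

test_that("degenerate deterministic chain gives one-hot posteriors", {
  spec <- indicator_spec("x", "nominal", n_categories = 2L)
  logits <- array(0, dim = c(3, 2, 1))
  params <- lmm_parameters(2, 3, list(spec), "MNI",
                           logits_from_probs(c(1 - 1e-12, 1e-12)),
                           rbind(logits_from_probs(c(1 - 1e-12, 1e-12)),
                                 logits_from_probs(c(1e-12, 1 - 1e-12))),
                           list(list(logits = logits)))
  post <- posterior_marginals(matrix(c(0, 1, 0), ncol = 1), params)
  expect_equal(post$gamma[, 1], c(1, 1, 1), tolerance = 1e-9)
})

test_that("complete-data log-likelihood decomposes into structural and emission terms", {
  ex <- worked_example()
  # path (1,1): .6 * .7 * .9 * .5 = .189
  expect_equal(complete_data_loglik(c(1, 1), ex$y, ex$params), log(0.189),
               tolerance = 1e-12)
  # J = 1 reduces to ln pi + emission
  p1 <- random_params(2, 1)
  y1 <- random_observations(p1)
  expect_equal(complete_data_loglik(1, y1, p1),
               log(init_probs(p1))[1] + joint_emission_logprob(y1[1, ], 1, 1, p1))
  # S = 1 reduces to the pure emission log-likelihood
  ps <- random_params(1, 3)
  ys <- random_observations(ps)
  expect_equal(complete_data_loglik(c(1, 1, 1), ys, ps),
               sum(vapply(1:3, function(j)
                 joint_emission_logprob(ys[j, ], j, 1, ps), numeric(1))))
  expect_equal(complete_data_loglik(c(1, 1, 1), ys, ps),
               forward_pass(ys, ps)$loglik)
})

test_that("impossible state paths yield -Inf with a warning", {
  spec <- indicator_spec("x", "nominal", n_categories = 2L)
  logits <- array(0, dim = c(2, 2, 1))
  # a transition logit of -800 underflows to probability zero
  params <- lmm_parameters(2, 2, list(spec), "MNI",
                           c(0, -800),
                           rbind(c(0, -800), c(0, 0)),
                           list(list(logits = logits)))
  y <- matrix(c(0, 0), ncol = 1)
  expect_warning(ll <- complete_data_loglik(c(2, 1), y, params), "zero probability")
  expect_equal(ll, -Inf)
})
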