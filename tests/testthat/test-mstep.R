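test_that("structural M-step recovers relative frequencies from posteriors", {
  # one-hot posteriors: estimates are empirical frequencies
  N <- 4; J <- 3; S <- 2
  paths <- rbind(c(1, 1, 2), c(1, 2, 2), c(2, 2, 2), c(1, 1, 1))
  gamma <- array(0, dim = c(N, J, S))
  xi <- array(0, dim = c(N, J - 1, S, S))
  for (i in 1:N) for (j in 1:J) gamma[i, j, paths[i, j]] <- 1
  for (i in 1:N) for (j in 1:(J - 1)) xi[i, j, paths[i, j], paths[i, j + 1]] <- 1
  st <- mstep_structural(gamma, xi)
  expect_equal(st$init_probs, c(.75, .25))
  # transitions out of state 1: three 1->1 and two 1->2; out of state 2: three 2->2
  expect_equal(st$transition[1, ], c(3 / 5, 2 / 5))
  expect_equal(st$transition[2, ], c(0, 1))

  # averaging property of the initial-state update
  g2 <- array(0, dim = c(2, 1, 2))
  g2[1, 1, ] <- c(.6, .4); g2[2, 1, ] <- c(.8, .2)
  st2 <- mstep_structural(g2, NULL)
  expect_equal(st2$init_probs, c(.7, .3))

  # uniform posteriors give uniform estimates
  gu <- array(1 / 3, dim = c(5, 4, 3))
  xu <- array(1 / 9, dim = c(5, 3, 3, 3))
  stu <- mstep_structural(gu, xu)
  expect_equal(stu$init_probs, rep(1 / 3, 3))
  expect_equal(stu$transition, matrix(1 / 3, 3, 3))
})

test_that("gaussian M-step computes weighted moments with pooling and floors", {
  # direct weighted arithmetic on one cell
  y <- matrix(c(1, 2, 3), 3, 1)
  gamma <- array(0, dim = c(3, 1, 2))
  gamma[, 1, 1] <- c(.5, .25, .25); gamma[, 1, 2] <- c(.5, .75, .75)
  up <- mstep_gaussian(y, gamma)
  expect_equal(up$mu[1, 1], 1.75)
  expect_equal(up$sigma[1, 1]^2, 0.6875)
  # 0/1 weights give per-cell sample moments (MLE variance, denominator n)
  g01 <- array(0, dim = c(4, 1, 2))
  g01[, 1, 1] <- c(1, 1, 0, 0); g01[, 1, 2] <- c(0, 0, 1, 1)
  y4 <- matrix(c(2, 4, 10, 30), 4, 1)
  up01 <- mstep_gaussian(y4, g01)
  expect_equal(up01$mu[1, ], c(3, 20))
  expect_equal(up01$sigma[1, ], c(1, 10))
  # constant y: sigma hits the floor, mu exact
  yc <- matrix(5, 4, 1)
  upc <- mstep_gaussian(yc, g01)
  expect_equal(upc$mu[1, ], c(5, 5))
  expect_equal(upc$sigma[1, ], c(1e-4, 1e-4))
  # pooling over items equals stacking the items
  y2 <- matrix(c(1, 2, 3, 7, 8, 9), 3, 2)
  g2 <- array(runif(3 * 2 * 2), dim = c(3, 2, 2))
  pooled <- mstep_gaussian(y2, g2, pool = TRUE)
  w <- g2[, , 1]
  expect_equal(pooled$mu[1, 1], sum(w * y2) / sum(w))
})

test_that("poisson M-step is the posterior-weighted mean count", {
  y <- matrix(c(2, 4), 2, 1)
  gamma <- array(0, dim = c(2, 1, 1)); gamma[, 1, 1] <- c(.5, .5)
  expect_equal(mstep_poisson(y, gamma)$lambda[1, 1], 3)
  y2 <- matrix(c(0, 10), 2, 1)
  g2 <- array(0, dim = c(2, 1, 1)); g2[, 1, 1] <- c(.9, .1)
  expect_equal(mstep_poisson(y2, g2)$lambda[1, 1], 1.0)
  # one-hot weights give the cell mean
  g3 <- array(0, dim = c(3, 1, 2))
  g3[, 1, 1] <- c(1, 1, 0); g3[, 1, 2] <- c(0, 0, 1)
  y3 <- matrix(c(1, 3, 12), 3, 1)
  expect_equal(mstep_poisson(y3, g3)$lambda[1, ], c(2, 12))
})

test_that("newton update inverts weighted category shares", {
  # nominal closed form: logits = log shares relative to category 0
  N <- 400; M <- 4
  set.seed(61)
  y <- matrix(sample(0:3, N, replace = TRUE, prob = c(.1, .3, .3, .3)), N, 1)
  gamma <- array(1, dim = c(N, 1, 1))
  start <- array(0, dim = c(1, 1, M - 1))
  up <- mstep_categorical_newton(y, gamma, "nominal", start)
  shares <- tabulate(y + 1, nbins = M) / N
  expect_equal(up$logits[1, 1, ], log(shares[-1] / shares[1]), tolerance = 1e-7)
  # exact target: weights forming shares (.1, .3, .3, .3) -> logits (ln3, ln3, ln3)
  y2 <- matrix(0:3, 4, 1)
  g2 <- array(0, dim = c(4, 1, 1)); g2[, 1, 1] <- c(.1, .3, .3, .3)
  up2 <- mstep_categorical_newton(y2, g2, "nominal", start)
  expect_equal(up2$logits[1, 1, ], rep(log(3), 3), tolerance = 1e-7)
  # uniform shares with equal weights -> zero logits
  y3 <- matrix(0:3, 4, 1)
  g3 <- array(1, dim = c(4, 1, 1))
  up3 <- mstep_categorical_newton(y3, g3, "nominal", array(0.7, dim = c(1, 1, 3)))
  expect_equal(up3$logits[1, 1, ], rep(0, 3), tolerance = 1e-7)
})

test_that("ordinal newton fit equals the nominal fit after reparameterization", {
  set.seed(71)
  y <- matrix(sample(0:3, 200, replace = TRUE), 200, 1)
  gamma <- array(runif(200), dim = c(200, 1, 1))
  start <- array(0, dim = c(1, 1, 3))
  nom <- mstep_categorical_newton(y, gamma, "nominal", start)
  ord <- mstep_categorical_newton(y, gamma, "ordinal", start)
  # saturated per-cell case: identical fitted category probabilities
  expect_equal(cumsum(ord$logits[1, 1, ]), nom$logits[1, 1, ], tolerance = 1e-6)
})

test_that("each newton update weakly increases the expected block log-likelihood", {
  set.seed(81)
  for (rep in 1:5) {
    M <- sample(3:5, 1)
    y <- matrix(sample(0:(M - 1), 150, replace = TRUE), 150, 1)
    gamma <- array(runif(150), dim = c(150, 1, 1))
    start <- array(rnorm(M - 1), dim = c(1, 1, M - 1))
    counts <- vapply(0:(M - 1), function(m) sum(gamma[, 1, 1][y == m]), numeric(1))
    q <- function(l) sum(counts * log(adjacent_emission_probs(l)))
    up <- mstep_categorical_newton(y, gamma, "ordinal", start)
    expect_gte(q(up$logits[1, 1, ]), q(start[1, 1, ]) - 1e-10)
  }
})
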