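test_that("pseudoinverse training solves the least-squares problem", {
  set.seed(1)
  # square nonsingular: exact interpolation
  A <- matrix(rnorm(25), 5)
  eta <- sample(c(-1, 1), 5, replace = TRUE)
  rd <- train_readout(A, eta)
  expect_lt(max(abs(crossprod(rd$W, A) - eta)), 1e-10)

  # P < N, full column rank: zero residual and the normal-equations oracle
  A <- matrix(rnorm(30 * 8), 30)
  eta <- sample(c(-1, 1), 8, replace = TRUE)
  rd <- train_readout(A, eta)
  W_oracle <- A %*% solve(crossprod(A), eta)
  expect_equal(drop(rd$W), drop(W_oracle), tolerance = 1e-10)
  expect_lt(max(abs(crossprod(rd$W, A) - eta)), 1e-8)

  expect_error(train_readout(matrix(c(1, NA), 1), matrix(c(1, 1), 1)),
               "finite")
  expect_error(train_readout(matrix(1, 2, 3), matrix(1, 1, 2)), "columns")
})

test_that("pseudoinverse matches the normal-equations oracle on random full-rank instances", {
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(2:20, 1)
    p <- sample(2:20, 1)
    A <- matrix(rnorm(n * p), n)
    P <- pseudoinverse(A)
    if (n >= p) {
      expect_equal(P, solve(crossprod(A)) %*% t(A), tolerance = 1e-8)
    } else {
      expect_equal(P, t(A) %*% solve(tcrossprod(A)), tolerance = 1e-8)
    }
  }
  # rank tolerance: results insensitive to a 10x looser cutoff
  A <- matrix(rnorm(50 * 10), 50)
  expect_equal(pseudoinverse(A),
               pseudoinverse(A, tol = 10 * 60 * .Machine$double.eps),
               tolerance = 1e-10)
})

test_that("pseudoinverse agrees with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(3)
  A <- matrix(rnorm(12 * 7), 12)
  expect_equal(pseudoinverse(A), MASS::ginv(A), tolerance = 1e-9)
  # rank-deficient case
  A[, 7] <- A[, 1] + A[, 2]
  expect_equal(pseudoinverse(A), MASS::ginv(A), tolerance = 1e-8)
})

test_that("training on mean prototypes classifies those prototypes noise-free", {
  st <- trained_setup(seed = 5)
  out <- ca3_output(st$readout, st$A)
  expect_equal(generalization_error(out$codes, st$ens$labels), 0)
})

test_that("Model 1 selects the weakest readout weights", {
  W <- c(0.5, -0.1, 0.9, 0.05, -0.6, 0.2, -0.03, 1.2, 0.4, -0.25)
  expect_equal(select_turnover_model1(W, 0.3), c(2, 4, 7))
  expect_equal(select_turnover_model1(W, 0), integer(0))
  sel <- select_turnover_model1(W, 0.5)
  expect_true(min(abs(W)[-sel]) >= max(abs(W)[sel]))
  expect_error(select_turnover_model1(matrix(1, 4, 2), 0.3), "single CA3")
})

test_that("bottom-k ties break by age then index, deterministically", {
  # hand-built 6-unit case: |W| = (3, 1, 1, 1, 2, 1), pick bottom 2
  W <- c(3, 1, -1, 1, 2, -1)
  ages <- c(0L, 2L, 5L, 2L, 1L, 9L)
  # four units tie at |W| = 1; oldest first: unit 6 (age 9), then 3 (age 5)
  expect_equal(select_turnover_model1(W, 2 / 6, ages), c(3, 6))
  # without ages, ties break by index
  expect_equal(select_turnover_model1(W, 2 / 6), c(2, 3))
})

test_that("Model 2 reduces to Model 1 and is permutation invariant", {
  set.seed(6)
  W1 <- rnorm(20)
  expect_equal(select_turnover_model2(W1, 0.3),
               select_turnover_model1(W1, 0.3))

  W <- matrix(c(0.1, -0.2, 2, 0.05,
                0.3, 0.1, -1, 0.02), 4)
  # row sums of |W|: 0.4, 0.3, 3, 0.07 -> bottom 2 are units 4 and 2
  expect_equal(select_turnover_model2(W, 0.5), c(2, 4))

  perm <- sample(4)
  sel_perm <- select_turnover_model2(W[perm, ], 0.5)
  expect_setequal(perm[sel_perm], c(2, 4))
})

test_that("Model 3 probabilities follow the clipped linear transfer function", {
  layer <- init_input_weights(4, 10, seed = 7)
  W <- c(0, 0.2, 1, 5)
  st <- synaptic_turnover_model3(W, layer, slope = 2.5, seed = 8)
  expect_equal(st$p[1], 1)        # zero weight: fully unstable
  expect_equal(st$p[4], 0)        # |W| >= wbar/slope: fully stable
  expect_true(all(st$resample[1, ]))
  expect_equal(st$dead, 1L)
  expect_false(any(st$resample[4, ]))
  expect_error(synaptic_turnover_model3(W, layer, slope = -1), "positive")

  # population synapse-turnover fraction matches mean(p) (binomial oracle)
  layer2 <- init_input_weights(50, 40, seed = 9)
  W2 <- abs(rnorm(50, sd = 0.3)) + 0.01
  reps <- 100
  set.seed(10)
  fracs <- replicate(reps, {
    s <- synaptic_turnover_model3(W2, layer2, slope = 2.5)
    mean(s$resample)
  })
  p_expected <- mean(synaptic_turnover_model3(W2, layer2, slope = 2.5,
                                              seed = 11)$p)
  se <- sd(fracs) / sqrt(reps)
  expect_lt(abs(mean(fracs) - p_expected), 3 * se + 1e-3)
})

test_that("rebirth redraws only the targeted material", {
  layer <- init_input_weights(10, 8, seed = 12)
  layer$ages <- rep(3L, 10)
  before <- layer$J

  # empty selection: nothing changes
  same <- rebirth(layer)
  expect_identical(same$J, before)

  # dead units get fresh N(0,1) rows; untouched rows are bit-identical
  reborn <- rebirth(layer, dead_units = c(2, 5), seed = 13)
  expect_identical(reborn$J[-c(2, 5), ], before[-c(2, 5), ])
  expect_false(any(reborn$J[2, ] == before[2, ]))
  expect_equal(reborn$ages[c(2, 5)], c(0L, 0L))
  expect_equal(reborn$ages[1], 3L)

  # distribution of replacement weights is standard normal (KS over rebirths)
  draws <- replicate(250, rebirth(layer, dead_units = 1)$J[1, ])
  ks <- suppressWarnings(ks.test(as.vector(draws), "pnorm"))
  expect_gt(ks$p.value, 0.001)

  # partial resampling redraws values in place, positions kept
  mask <- matrix(FALSE, 10, 8)
  mask[3, c(1, 4)] <- TRUE
  part <- rebirth(layer, resample = mask, seed = 14)
  expect_false(any(part$J[3, c(1, 4)] == before[3, c(1, 4)]))
  expect_identical(part$J[3, c(2, 3, 5:8)], before[3, c(2, 3, 5:8)])

  # under partial connectivity a reborn unit gets new positions too
  sparse <- init_input_weights(6, 20, connectivity = 0.4, seed = 15)
  reb <- rebirth(sparse, dead_units = 1, seed = 16)
  expect_equal(sum(reb$mask[1, ]), 8)
  expect_true(all(reb$J[1, !reb$mask[1, ]] == 0))
})

test_that("the simulation trace is well-formed and reproducible", {
  args <- tiny_sim_args(days = 5)
  sim <- do.call(dg_simulate, args)
  expect_s3_class(sim, "dg_sim")
  expect_equal(nrow(sim$trace), 5)
  expect_equal(sim$trace$day, 0:4)
  expect_true(all(diff(sim$trace$cum_replaced) >= 0))
  expect_true(all(sim$trace$error >= 0 & sim$trace$error <= 1))

  sim2 <- do.call(dg_simulate, args)
  expect_identical(sim$trace, sim2$trace)
  expect_identical(sim$layer$J, sim2$layer$J)
})

test_that("zero turnover leaves the network and its readout unchanged", {
  sim <- dg_simulate(days = 6, M = 60, N = 80, P = 20, f = 0.1,
                     turnover_rate = 0, test_instances = 3, seed = 3)
  expect_true(all(sim$trace$n_replaced == 0))
  expect_equal(sim$trace$cum_replaced[6], 0)
  # identical network every day: activities at day 0 and final agree
  expect_identical(sim$activities_initial, sim$activities_final)
  # error fluctuates only through fresh test noise
  expect_lt(diff(range(sim$trace$error)), 0.2)
})

test_that("Model 1 replaces exactly floor(rate * N) units every day", {
  sim <- dg_simulate(days = 4, M = 40, N = 50, P = 20, f = 0.1,
                     turnover_rate = 0.3, test_instances = 2, seed = 4)
  expect_true(all(sim$trace$n_replaced == 15))
  expect_true(all(sim$trace$frac_neuron_turnover == 0.3))
})

test_that("Model 3 neuron death never exceeds synapse turnover", {
  sim <- dg_simulate(days = 10, M = 60, N = 80, P = 20, f = 0.1,
                     model = "model3", test_instances = 2, seed = 5)
  expect_true(all(sim$trace$frac_neuron_turnover <=
                    sim$trace$frac_synapse_turnover + 1e-12))
})

test_that("survival within one iteration is nondecreasing in |W|", {
  set.seed(20)
  W <- rnorm(100)
  ages <- sample(0:5, 100, replace = TRUE)
  sel1 <- select_turnover_model1(W, 0.4, ages)
  expect_true(min(abs(W)[-sel1]) >= max(abs(W)[sel1]))
  layer <- init_input_weights(100, 30, seed = 21)
  st <- synaptic_turnover_model3(W, layer, slope = 2.5, seed = 22)
  # per-unit death probability p^M is nonincreasing in |W| through p
  ord <- order(abs(W))
  expect_true(all(diff(st$p[ord]) <= 1e-12))
})

test_that("the noisy-instance training variant runs and learns the training set", {
  sim <- dg_simulate(days = 2, M = 40, N = 120, P = 10, f = 0.1,
                     train_on = "noisy", train_instances = 5,
                     test_instances = 2, seed = 6)
  expect_equal(sim$readout$trained_on, "noisy")
  expect_equal(ncol(sim$activities_final), 50)
})
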