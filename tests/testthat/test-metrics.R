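test_that("generalization error requires an exact code match", {
  lab <- matrix(c(1, -1, 1, 1, -1, 1), 3)
  expect_equal(generalization_error(lab, lab), 0)
  out <- lab
  out[3, 2] <- -out[3, 2]  # two of three bits still match
  expect_equal(generalization_error(out, lab), 0.5)

  set.seed(1)
  o <- sample(c(-1, 1), 1e4, replace = TRUE)
  l <- sample(c(-1, 1), 1e4, replace = TRUE)
  expect_lt(abs(generalization_error(o, l) - 0.5), 0.02)
})

test_that("context-bias counting and matrix forms agree exactly", {
  # endpoints
  S <- rbind(c(1, 1, -1, -1),   # active for all (+), none of (-)
             c(1, -1, 1, -1))   # equal fractions
  labels <- c(1, 1, -1, -1)
  cb <- context_bias(S, labels)
  expect_equal(cb$psi, c(1, 0))
  expect_equal(cb$f_plus, c(1, 0.5))
  expect_equal(cb$f_minus, c(0, 0.5))
  expect_error(context_bias(S, c(1, 1, 1, -1)), "equal")

  # random instance vs a direct counting oracle
  set.seed(2)
  S <- matrix(sample(c(-1, 1), 8 * 10, replace = TRUE), 8)
  labels <- rep(c(1, -1), each = 5)
  cb <- context_bias(S, labels)
  fp <- rowSums(S[, 1:5] == 1) / 5
  fm <- rowSums(S[, 6:10] == 1) / 5
  expect_equal(cb$psi, fp - fm)

  # exhaustive: all +/-1 matrices with 2 units x 4 balanced patterns
  labels <- c(1, 1, -1, -1)
  for (code in 0:255) {
    bits <- as.integer(intToBits(code))[1:8]
    S <- matrix(2 * bits - 1, 2, 4)
    cb <- context_bias(S, labels)
    expect_equal(cb$psi, as.vector(S %*% labels) / 4)
  }
})

test_that("empirical SNR matches hand arithmetic and flags zero noise", {
  # perfectly separated: signal 4, zero noise
  r <- empirical_snr(c(1, 1, -1, -1), c(1, 1, -1, -1))
  expect_equal(r$signal, 4)
  expect_equal(r$noise, 0)
  expect_true(r$infinite)
  expect_equal(r$snr, Inf)

  # printed 6-value example: h+ = (1, 2, 3), h- = (0, 1, -1)
  # means 2 and 0 -> signal 4; variances 1 and 1 -> noise 2 -> snr 2
  r <- empirical_snr(c(1, 2, 3, 0, 1, -1), c(1, 1, 1, -1, -1, -1))
  expect_equal(r$signal, 4)
  expect_equal(r$noise, 2)
  expect_equal(r$snr, 2)

  set.seed(3)
  h <- rnorm(2000)
  expect_lt(empirical_snr(h, rep(c(1, -1), 1000))$signal, 0.01)
  expect_error(empirical_snr(1:3, c(1, 1, 1)), "both classes")
})

test_that("analytic SNR matches term-by-term evaluation", {
  # single unit: f+ = 1, f- = 0, W = 1 -> signal 4, noise 0
  bias <- structure(list(psi = 1, f_plus = 1, f_minus = 0),
                    class = "context_bias")
  r <- analytic_snr(1, bias)
  expect_equal(r$signal, 4)
  expect_equal(r$noise, 0)
  expect_true(r$infinite)

  # two-unit hand-built case evaluated symbolically
  W <- c(2, -1)
  fp <- c(0.8, 0.3)
  fm <- c(0.2, 0.6)
  bias <- structure(list(psi = fp - fm, f_plus = fp, f_minus = fm),
                    class = "context_bias")
  r <- analytic_snr(W, bias)
  sig <- (2 * (2 * 0.6 + (-1) * (-0.3)))^2
  noi <- 4 * (4 * (0.8 * 0.8 + 0.2 * 0.2 - 0.36) +
                1 * (0.3 * 0.4 + 0.6 * 0.7 - 0.09))
  expect_equal(r$signal, sig)
  expect_equal(r$noise, noi)
  expect_equal(r$snr, sig / noi)
})

test_that("analytic and empirical SNR agree on a large simulated test set", {
  st <- trained_setup(seed = 4)
  set.seed(5)
  test <- noisy_instances(st$ens, instances = 100)  # 10^4 patterns
  S <- dg_activity(dg_currents(st$layer, test$patterns), st$theta)$S
  h <- ca3_output(st$readout, S)$h[1, ]
  labels <- test$labels[1, ]
  emp <- empirical_snr(h, labels)
  ana <- analytic_snr(st$readout, context_bias(S, labels))
  expect_lt(abs(ana$snr / emp$snr - 1), 0.1)

  # the cross term dropped by the large-N signal form averages to zero over
  # random readouts (it does not vanish for a trained, bias-aligned W)
  set.seed(50)
  psi <- context_bias(S, labels)$psi
  full_vs_diag <- replicate(1000, {
    W <- rnorm(length(psi))
    c((2 * sum(W * psi))^2, 4 * sum(W^2 * psi^2))
  })
  expect_lt(abs(mean(full_vs_diag[1, ]) / mean(full_vs_diag[2, ]) - 1), 0.15)
})

test_that("analytic SNR converges to the empirical value as samples grow", {
  st <- trained_setup(seed = 6)
  gap <- sapply(c(4, 20, 100), function(k) {
    test <- noisy_instances(st$ens, instances = k, seed = 100 + k)
    S <- dg_activity(dg_currents(st$layer, test$patterns), st$theta)$S
    labels <- test$labels[1, ]
    h <- ca3_output(st$readout, S)$h[1, ]
    abs(analytic_snr(st$readout, context_bias(S, labels))$snr /
          empirical_snr(h, labels)$snr - 1)
  })
  expect_lt(gap[3], 0.1)
  expect_lt(gap[3], gap[1])
})

test_that("representation diagnostics match direct averaging oracles", {
  set.seed(7)
  S <- matrix(sample(c(-1, 1), 12 * 6, replace = TRUE), 12)
  S[, 2] <- S[, 1]  # duplicate column
  ctx <- rep(1:2, each = 3)
  d <- representation_diagnostics(S, ctx)
  expect_equal(d$correlation[1, 2], 1)
  expect_equal(d$correlation, t(d$correlation))
  expect_true(all(diag(d$correlation) == 1))
  expect_equal(dim(d$pc_scores), c(2, 6))

  # within/between means against a double loop
  R <- d$correlation
  w <- c(); b <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    if (ctx[i] == ctx[j]) w <- c(w, R[i, j]) else b <- c(b, R[i, j])
  }
  expect_equal(d$within, mean(w))
  expect_equal(d$between, mean(b))

  # zero-variance column yields NA correlations
  S[, 3] <- 1
  d2 <- representation_diagnostics(S, ctx)
  expect_true(all(is.na(d2$correlation[3, -3])))
  expect_error(representation_diagnostics(S, c(1, 1, 1, 1, 1, 2)),
               "at least 2")
})

test_that("turnover accounting reproduces hand-computed quantities", {
  sim <- dg_simulate(days = 4, M = 40, N = 50, P = 20, f = 0.1,
                     turnover_rate = 0.3, test_instances = 2, seed = 8)
  acc <- turnover_accounting(sim)
  expect_equal(acc$per_day$frac_neuron_turnover, rep(0.3, 4))
  expect_equal(acc$per_day$cum_neuron_turnover, cumsum(rep(0.3, 4)))
  expect_true(all(diff(acc$per_day$cum_replaced) >= 0))
  expect_true(all(acc$per_day$cum_replaced <= 1))
  expect_equal(acc$per_day$error_reduction,
               sim$trace$error[1] - sim$trace$error)

  # survival-by-age from a hand-checked 3-day toy trace
  toy <- dg_simulate(days = 3, M = 20, N = 10, P = 4, f = 0.2,
                     turnover_rate = 0.2, test_instances = 1, seed = 9)
  acc2 <- turnover_accounting(toy)
  # day 0: all 10 units age 1, 2 replaced -> survival 8/10
  day0 <- toy$survival[toy$survival$day == 0, ]
  expect_equal(day0$n, 10)
  expect_equal(day0$survived, 8)
  # each later day has 2 newborns (age 1 at next selection), 10 units total
  expect_equal(sum(toy$survival$n[toy$survival$day == 2]), 10)
  agg <- acc2$survival_by_age
  expect_equal(sum(agg$n), 30)  # 10 units at risk on each of 3 days
  expect_equal(agg$survival, agg$survived / agg$n)
})
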