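test_that("lag + exponential fit recovers its own forward model", {
  t <- seq(0, 10, by = 0.05)
  s <- ifelse(t < 0.65, 0, 1 * (1 - exp(-1.2 * (t - 0.65))))
  fit <- fit_lag_exponential(transport_trace(t, s))
  expect_equal(fit$A, 1, tolerance = 1e-3)
  expect_equal(fit$lag, 0.65, tolerance = 1e-3)
  expect_equal(fit$lam, 1.2, tolerance = 1e-3)
  expect_lt(fit$residual_rmsd, 1e-6)
})

test_that("a pure exponential yields a lag below the grid spacing", {
  t <- seq(0, 10, by = 0.1)
  fit <- fit_lag_exponential(transport_trace(t, 1 - exp(-0.8 * t)))
  expect_lt(fit$lag, 0.1)
})

test_that("fitted lag of an Erlang trace tracks the summed time constants", {
  # the empirical lag of a 7-transition chain at 5.31 min^-1 sits below the
  # summed time constants 7/5.31 = 1.32 min: the exponential tail absorbs
  # part of the rise. The fitted value is frozen as a regression bound.
  t <- seq(0, 10, by = 0.05)
  s <- erlang_completion_curve(7, 5.31, t)
  fit <- fit_lag_exponential(transport_trace(t, s))
  expect_equal(fit$lag, 0.780, tolerance = 0.02)
  expect_gt(fit$lag, 0.4 * 7 / 5.31)
  expect_lt(fit$lag, 7 / 5.31)
})

test_that("flat traces are rejected", {
  t <- seq(0, 5, by = 0.1)
  expect_error(fit_lag_exponential(transport_trace(t, rep(0, length(t)))),
               "flat trace")
})

test_that("RMSD matches trivial closed forms and a loop oracle", {
  expect_equal(normalized_rmsd(1:10, 1:10), 0)
  expect_equal(normalized_rmsd(rep(0.6, 50), rep(0.5, 50)), 0.1)
  set.seed(11)
  a <- rnorm(100)
  b <- rnorm(100)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(normalized_rmsd(a, b), sqrt(acc / 100))
  expect_error(normalized_rmsd(1:3, 1:4), "length mismatch")
})

test_that("a singleton noiseless scan returns normalised RMSD exactly 1", {
  cond <- short_cond()
  tr <- simulate_trace(rate_params(3, 4), cond)
  sc <- scan_steps(transport_trace(tr$times, tr$signal), n_range = 3,
                   cond = cond, n_starts = 2)
  expect_equal(sc$table$normalized_rmsd, 1)
  expect_equal(sc$best_n, 3)
  expect_lt(abs(sc$table$k_step - 4) / 4, 0.01)
})

test_that("normalised RMSD profiles attain exactly 1 at their minimum", {
  cond <- short_cond()
  traces <- make_trace_dataset(rate_params(5, 4), cond, noise_sd = 0.01,
                               replicates = 4, seed = 21)
  sc <- scan_steps(traces, n_range = 3:7, cond = cond, n_starts = 2)
  expect_equal(min(sc$table$normalized_rmsd), 1)
  expect_equal(sc$table$normalized_rmsd[sc$table$n == sc$best_n], 1)
})

test_that("the n-scan recovers generating step counts and rates", {
  # parameter recovery across step counts and rates at <= 2% noise
  cond <- short_cond()
  cases <- expand.grid(n = c(3, 5, 8, 10), k = c(2.5, 5.31, 9.5))
  hits <- 0
  rel_err <- numeric(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    n_true <- cases$n[i]
    k_true <- cases$k[i]
    traces <- make_trace_dataset(rate_params(n_true, k_true), cond,
                                 noise_sd = 0.02, replicates = 6,
                                 seed = 100 + i)
    sc <- scan_steps(traces, n_range = (n_true - 2):(n_true + 2),
                     cond = cond, n_starts = 2)
    if (sc$best_n == n_true) hits <- hits + 1
    rel_err[i] <- abs(sc$best_fit$k_step - k_true) / k_true
  }
  expect_gte(hits / nrow(cases), 0.9)
  expect_lte(median(rel_err), 0.10)
})

test_that("replicate-wise fitting mode averages per-replicate parameters", {
  cond <- short_cond()
  traces <- make_trace_dataset(rate_params(4, 5), cond, noise_sd = 0.005,
                               replicates = 3, seed = 31)
  sc <- scan_steps(traces, n_range = 4, cond = cond,
                   replicate_mode = "individual", n_starts = 2)
  expect_equal(sc$best_n, 4)
  expect_equal(sc$best_fit$k_step, 5, tolerance = 0.05)
})

test_that("the variant fit recovers a null variant and leaves the native fixed", {
  cond <- short_cond()
  nat <- native_params()
  nat_copy <- unserialize(serialize(nat, NULL))
  seg <- segmented_rate_params(nat, 6, 5.31)
  traces <- make_trace_dataset(seg, cond, noise_sd = 0.01,
                               replicates = 6, seed = 41)
  vf <- fit_variant(traces, nat, n_var_range = 4:8, cond = cond, n_starts = 2)
  expect_equal(vf$best_n_var, 6)
  expect_equal(vf$k_step_var, 5.31, tolerance = 0.10)
  expect_identical(vf$native, nat_copy)  # fixed-parameter contract
})

test_that("fixed relative brightness leaves variant kinetics unbiased", {
  cond <- short_cond()
  nat <- native_params()
  seg <- segmented_rate_params(nat, 6, 6.74, brightness = 0.5)
  traces <- make_trace_dataset(seg, cond, noise_sd = 0.01,
                               replicates = 6, seed = 43)
  vf <- fit_variant(traces, nat, brightness_rel = 0.5, n_var_range = 5:7,
                    cond = cond, n_starts = 2)
  expect_equal(vf$k_step_var, 6.74, tolerance = 0.10 * 6.74)
})
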