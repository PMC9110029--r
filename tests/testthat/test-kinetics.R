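test_that("binding equilibrium matches a bisection oracle and its limits", {
  cond <- assay_conditions(substrate_conc = 2, site_conc = 0.1)
  p <- native_params()
  eq <- equilibrate_binding(p, cond)
  C_oracle <- bisect_equilibrium(2, 0.1, 0.085 / 0.96)
  expect_equal(unname(eq[["C0"]]), C_oracle, tolerance = 1e-9)
  # mass conservation
  expect_equal(unname(eq[["S"]] + eq[["C0"]]), 2)
  expect_equal(unname(eq[["Y"]] + eq[["C0"]]), 0.1)
  # equilibrium relation holds
  expect_equal(eq[["C0"]] / (eq[["S"]] * eq[["Y"]]), 0.96 / 0.085,
               tolerance = 1e-8)

  # no binding
  eq0 <- equilibrate_binding(rate_params(6, 5, k_on = 0, k_off = 0.085), cond)
  expect_equal(unname(eq0[["C0"]]), 0)
  expect_equal(unname(eq0[["S"]]), 2)
  # infinite affinity
  eq1 <- equilibrate_binding(rate_params(6, 5, k_on = 1, k_off = 0), cond)
  expect_equal(unname(eq1[["C0"]]), 0.1)
  # degenerate
  expect_error(equilibrate_binding(rate_params(6, 5, k_on = 0, k_off = 0),
                                   cond),
               "degenerate")
})

test_that("parameter constructors validate their invariants", {
  expect_error(rate_params(0, 5), "n >= 1")
  expect_error(rate_params(6, -1), "rate constants")
  expect_error(rate_params(6, 5, brightness = 0), "brightness")
  expect_error(assay_conditions(times = c(1, 2, 3)), "start at 0")
  expect_error(assay_conditions(substrate_conc = 0), "substrate_conc")
  nat <- native_params()
  expect_error(segmented_rate_params(nat, -1, 5), "n_var")
  expect_error(segmented_rate_params(nat, 3, 5, insert_after = 9),
               "outside the chain")
})

test_that("transport chain with failure and blocking off is Erlang(n+1, k_step)", {
  cond <- short_cond()
  for (n in c(1, 3, 6)) {
    p <- rate_params(n, 5.31, k_fail = 0, k_block = 0, k_off = 0)
    tr <- simulate_trace(p, cond, pre_bound = TRUE)
    er <- erlang_completion_curve(n + 1, 5.31, cond$times)
    expect_lt(max(abs(tr$signal - er)), 1e-4)
  }
})

test_that("signal starts at zero, never decreases, and conserves mass", {
  cond <- short_cond()
  p <- rate_params(4, 3, k_fail = 0.2, k_block = 0.31)
  tr <- simulate_trace(p, cond, species = TRUE)
  expect_equal(tr$signal[1], 0)
  expect_true(all(diff(tr$signal) > -1e-9))
  sp <- tr$species
  chain_cols <- c("C0", paste0("X", 1:4), "Fin", "B")
  substrate <- sp[, "S"] + rowSums(sp[, chain_cols])
  site <- sp[, "Y"] + rowSums(sp[, chain_cols])
  expect_lt(max(abs(substrate - cond$substrate_conc)), 1e-6)
  expect_lt(max(abs(site - cond$site_conc)), 1e-6)
})

test_that("blocking truncates the amplitude by the branch-probability product", {
  # with k_fail = 0 and committed substrate, completion probability is
  # (k_step / (k_step + k_block))^(n-1)
  long <- assay_conditions(t_max = 60)
  for (kb in c(0.2, 0.5, 1.0)) {
    p <- rate_params(6, 5.31, k_fail = 0, k_block = kb, k_off = 0)
    tr <- simulate_trace(p, long, pre_bound = TRUE)
    final <- tr$signal[length(tr$signal)]
    expect_equal(final, (5.31 / (5.31 + kb))^5, tolerance = 1e-5)
  }
})

test_that("final amplitude falls with k_block and rises with k_step", {
  long <- assay_conditions(t_max = 60)
  finals <- vapply(c(0, 0.31, 1), function(kb) {
    tr <- simulate_trace(rate_params(6, 5.31, k_block = kb), long)
    tr$signal[length(tr$signal)]
  }, numeric(1))
  expect_true(all(diff(finals) < 0))
  finals_k <- vapply(c(2, 5.31, 12), function(ks) {
    tr <- simulate_trace(rate_params(6, ks), long)
    tr$signal[length(tr$signal)]
  }, numeric(1))
  expect_true(all(diff(finals_k) > 0))
})

test_that("segmentation with identical parameters is purely notational", {
  cond <- short_cond()
  nat <- rate_params(6, 5.31, k_fail = 0.1)
  seg <- segmented_rate_params(nat, 6, 5.31, k_fail_var = 0.1,
                               k_block_var = 0.31)
  uni <- rate_params(12, 5.31, k_fail = 0.1)
  expect_equal(simulate_segmented_trace(seg, cond)$signal,
               simulate_trace(uni, cond)$signal, tolerance = 1e-8)
})

test_that("degenerate and fast variable segments reduce to the native trace", {
  cond <- short_cond()
  nat <- native_params()
  native_only <- simulate_trace(nat, cond)$signal
  # n_var = 0: baseline topology
  seg0 <- segmented_rate_params(nat, 0, 1)
  expect_equal(simulate_segmented_trace(seg0, cond)$signal, native_only,
               tolerance = 1e-8)
  # instantaneous variable segment
  dev <- vapply(c(1e3, 1e4), function(kv) {
    seg <- segmented_rate_params(nat, 6, kv, k_fail_var = 0, k_block_var = 0)
    max(abs(simulate_segmented_trace(seg, cond)$signal - native_only))
  }, numeric(1))
  expect_lt(dev[2], dev[1])      # converging in the limit
  expect_lt(dev[2], 5e-4)
})

test_that("Erlang completion curve has the closed form and correct mean", {
  times <- seq(0, 5, by = 0.01)
  expect_equal(erlang_completion_curve(1, 1.2, times),
               1 - exp(-1.2 * times))
  expect_equal(erlang_completion_curve(7, 5.31, 0), 0)
  expect_gt(erlang_completion_curve(7, 5.31, 100), 1 - 1e-12)
  # mean completion time by numerical integration of the survival function
  tt <- seq(0, 40, by = 1e-3)
  surv <- 1 - erlang_completion_curve(7, 5.31, tt)
  mean_t <- sum(surv) * 1e-3
  expect_equal(mean_t, 7 / 5.31, tolerance = 1e-3)
})

test_that("lag of simulated traces grows linearly with n at fixed k_step", {
  cond <- short_cond()
  ns <- 3:8
  lags <- vapply(ns, function(n) {
    tr <- simulate_trace(rate_params(n, 5.31), cond)
    fit_lag_exponential(transport_trace(tr$times, tr$signal))$lag
  }, numeric(1))
  expect_true(all(diff(lags) > 0))
  slope <- stats::coef(stats::lm(lags ~ ns))[2]
  expect_equal(unname(slope), 1 / 5.31, tolerance = 0.25)
})
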