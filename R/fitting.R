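# Trace fitting: the empirical lag + single-exponential model, and model
# selection over the number of transport steps by a normalised-RMSD scan.

#' Construct a transport trace
#'
#' One replicate's luminescence time course with construct/condition
#' metadata. Times are minutes; the signal is normalised luminescence.
#'
#' @param times Strictly increasing sample times (min).
#' @param signal Finite luminescence values, same length as `times`.
#' @param construct,condition Labels (e.g. construct "LXX", condition
#'   "IMV_BL21_pH8").
#' @param replicate Replicate index.
#' @return An object of class `transport_trace`.
#' @export
transport_trace <- function(times, signal, construct = "unknown",
                            condition = "unknown", replicate = 1L) {
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) != length(signal)) stop("times/signal length mismatch")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(!is.finite(signal))) stop("'signal' must be finite")
  structure(list(times = times, signal = signal, construct = construct,
                 condition = condition, replicate = as.integer(replicate)),
            class = "transport_trace")
}

#' @export
print.transport_trace <- function(x, ...) {
  cat(sprintf("Transport trace [%s | %s | rep %d]: %d points, t in [%.3g, %.3g] min\n",
              x$construct, x$condition, x$replicate, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Average replicate traces on their common time grid
#'
#' @param traces A list of [transport_trace()] objects sharing one time grid.
#' @return A single `transport_trace` whose signal is the pointwise mean.
#' @export
average_traces <- function(traces) {
  if (inherits(traces, "transport_trace")) return(traces)
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "transport_trace")))
  t0 <- traces[[1]]$times
  for (tr in traces)
    if (length(tr$times) != length(t0) || any(abs(tr$times - t0) > 1e-9))
      stop("traces do not share a common time grid")
  sig <- rowMeans(vapply(traces, `[[`, numeric(length(t0)), "signal"))
  transport_trace(t0, sig, construct = traces[[1]]$construct,
                  condition = traces[[1]]$condition, replicate = 0L)
}

#' Root-mean-square deviation between aligned curves
#'
#' @param model_curve,data_curve Equal-length numeric vectors.
#' @return `sqrt(mean((model - data)^2))`. Across an n-scan, normalisation
#'   divides each RMSD by the scan minimum (see [scan_steps()]).
#' @export
normalized_rmsd <- function(model_curve, data_curve) {
  if (length(model_curve) != length(data_curve))
    stop("curve length mismatch")
  sqrt(mean((model_curve - data_curve)^2))
}

#' Fit the lag + single-exponential trace model
#'
#' The empirical description of a transport trace: zero signal until a lag
#' time, then an exponential rise,
#' \deqn{s(t) = A (1 - e^{-\lambda (t - lag)}),\ t \ge lag.}
#' The lag is the minimum time required for transport and corresponds to the
#' sum of the time constants of all transport steps; \eqn{\lambda} is a
#' composite of transport, pausing and failure rates.
#'
#' Initialisation is robust for sigmoidal traces: `lag0` is the time at 10%
#' of maximum signal, `A0` the maximum, `lambda0 = 1 / (t90 - t10)`.
#'
#' @param trace A [transport_trace()] (or `simulated_trace`).
#' @return An object of class `lag_exp_fit` with fields `A`, `lag`, `lam`
#'   and `residual_rmsd`.
#' @export
fit_lag_exponential <- function(trace) {
  t <- trace$times
  s <- trace$signal
  if (diff(range(s)) < 1e-12)
    stop("flat trace: amplitude indistinguishable from 0")
  smax <- max(s)
  t10 <- t[which(s >= 0.1 * smax)[1]]
  t90 <- t[which(s >= 0.9 * smax)[1]]
  if (!is.finite(t90) || t90 <= t10) t90 <- t10 + diff(range(t)) / 10
  start <- c(A = smax, lag = t10, lam = 1 / (t90 - t10))
  resid_fun <- function(p) {
    pred <- ifelse(t < p[2], 0, p[1] * (1 - exp(-p[3] * (t - p[2]))))
    pred - s
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fun,
                            lower = c(1e-12, 0, 1e-9),
                            upper = c(Inf, max(t), Inf),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 9))
    stop("lag + exponential fit did not converge")
  p <- fit$par
  structure(list(A = unname(p[1]), lag = unname(p[2]), lam = unname(p[3]),
                 residual_rmsd = sqrt(mean(fit$fvec^2))),
            class = "lag_exp_fit")
}

#' @export
print.lag_exp_fit <- function(x, ...) {
  cat(sprintf("lag + single-exponential fit: A = %.4g, lag = %.4g min, lambda = %.4g min^-1 (RMSD %.3g)\n",
              x$A, x$lag, x$lam, x$residual_rmsd))
  invisible(x)
}

# Fit the single-segment step model at fixed n: least squares over the
# floated parameters with multi-start on k_step (log-spaced), Levenberg-
# Marquardt with box constraints. Returns NULL on total failure.
fit_single_n <- function(n, data, cond, fixed, float_k_block = FALSE,
                         brightness_fixed = NULL, n_starts = 5,
                         k_step_range = c(0.5, 50), warm_start = NULL) {
  t <- data$times
  s <- data$signal
  fit_cond <- assay_conditions(substrate_conc = cond$substrate_conc,
                               site_conc = cond$site_conc,
                               times = if (t[1] == 0) t else c(0, t))
  drop0 <- t[1] != 0
  model_signal <- function(k_step, k_fail, brightness, k_block) {
    p <- rate_params(n = n, k_step = k_step, k_fail = k_fail,
                     k_block = k_block, k_on = fixed$k_on,
                     k_off = fixed$k_off, brightness = brightness)
    sig <- simulate_trace(p, fit_cond)$signal
    if (drop0) sig[-1] else sig
  }
  free_bright <- is.null(brightness_fixed)
  resid_fun <- function(par) {
    k_step <- exp(par[["log_k_step"]])
    k_fail <- par[["k_fail"]]
    brightness <- if (free_bright) par[["brightness"]] else brightness_fixed
    k_block <- if (float_k_block) par[["k_block"]] else fixed$k_block
    out <- try(model_signal(k_step, k_fail, brightness, k_block),
               silent = TRUE)
    if (inherits(out, "try-error")) return(rep(1e3, length(s)))
    out - s
  }
  starts <- exp(seq(log(k_step_range[1]), log(k_step_range[2]),
                    length.out = n_starts))
  if (!is.null(warm_start)) starts <- unique(c(warm_start, starts))
  lower <- c(log_k_step = log(1e-3), k_fail = 0)
  upper <- c(log_k_step = log(1e3), k_fail = 1e2)
  best <- NULL
  for (ks0 in starts) {
    par0 <- c(log_k_step = log(ks0), k_fail = 0.05)
    lo <- lower; up <- upper
    if (free_bright) {
      par0 <- c(par0, brightness = max(s))
      lo <- c(lo, brightness = 1e-6); up <- c(up, brightness = 10)
    }
    if (float_k_block) {
      par0 <- c(par0, k_block = fixed$k_block)
      lo <- c(lo, k_block = 0); up <- c(up, k_block = 1e2)
    }
    fit <- try(minpack.lm::nls.lm(par = par0, fn = resid_fun,
                                  lower = lo, upper = up,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200, ftol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error") || fit$info %in% c(0, 9)) next
    rmsd <- sqrt(mean(fit$fvec^2))
    if (is.null(best) || rmsd < best$rmsd) {
      best <- list(rmsd = rmsd,
                   k_step = exp(fit$par[["log_k_step"]]),
                   k_fail = fit$par[["k_fail"]],
                   brightness = if (free_bright) fit$par[["brightness"]]
                                else brightness_fixed,
                   k_block = if (float_k_block) fit$par[["k_block"]]
                             else fixed$k_block)
    }
  }
  best
}

# Shared replicate handling: "average" fits the replicate-averaged trace,
# "individual" fits each replicate and averages the per-n RMSDs/parameters.
prepare_scan_data <- function(traces, replicate_mode) {
  if (inherits(traces, "transport_trace") ||
      inherits(traces, "simulated_trace"))
    traces <- list(traces)
  traces <- lapply(traces, function(tr) {
    if (inherits(tr, "simulated_trace"))
      transport_trace(tr$times, tr$signal)
    else tr
  })
  if (replicate_mode == "average") list(average_traces(traces)) else traces
}

#' Scan step number by normalised RMSD
#'
#' Fits the single-segment transport model at each candidate step count `n`,
#' floating `k_step`, `k_fail` and `brightness` while holding `k_block`,
#' `k_on` and `k_off` at independently determined values, and compares fits
#' through the RMSD between model and data normalised to the scan minimum.
#' The best fit is the smallest `n` within 0.1% of the minimum normalised
#' RMSD. A scan is flagged unresolved ("plateau") when the profile keeps
#' falling (or stays flat) to the end of the range and the final value is
#' within 1% of the minimum: a signature of steps too fast to count on the
#' sampling grid.
#'
#' @param traces A [transport_trace()] or list thereof.
#' @param n_range Candidate step counts (default 1:20).
#' @param fixed Named list of the fixed constants `k_block`, `k_on`,
#'   `k_off`; defaults to the standard assay values 0.31, 0.96, 0.085.
#' @param cond [assay_conditions()] describing concentrations (times are
#'   taken from the data).
#' @param replicate_mode `"average"` (default; fit the replicate-averaged
#'   trace) or `"individual"` (fit each replicate, average RMSD and
#'   parameters across replicates, with SEMs).
#' @param n_starts Multi-start count for the optimiser (log-spaced initial
#'   `k_step`).
#' @return An object of class `step_scan`: a list with `table` (data frame
#'   of n, rmsd, normalized_rmsd, k_step, k_fail, brightness, k_block),
#'   `best_n`, `best_fit`, `plateau`, and the replicate mode.
#' @export
scan_steps <- function(traces, n_range = 1:20,
                       fixed = list(k_block = 0.31, k_on = 0.96, k_off = 0.085),
                       cond = assay_conditions(),
                       replicate_mode = c("average", "individual"),
                       n_starts = 5) {
  replicate_mode <- match.arg(replicate_mode)
  stopifnot(length(n_range) >= 1L)
  fits_needed <- prepare_scan_data(traces, replicate_mode)
  rows <- vector("list", length(n_range))
  prev_k <- prev_n <- NULL
  for (j in seq_along(n_range)) {
    n <- n_range[j]
    # warm start from the previous n, rescaled so the chain's total
    # transport time (n + 1) / k_step is preserved
    warm <- if (is.null(prev_k)) NULL else prev_k * (n + 1) / (prev_n + 1)
    per_rep <- lapply(fits_needed, function(d) {
      fit_single_n(n, d, cond, fixed, n_starts = n_starts, warm_start = warm)
    })
    per_rep <- Filter(Negate(is.null), per_rep)
    if (!length(per_rep)) {
      warning("optimiser failed at n = ", n, "; flagged")
      rows[[j]] <- data.frame(n = n, rmsd = NA_real_, k_step = NA_real_,
                              k_fail = NA_real_, brightness = NA_real_,
                              k_block = fixed$k_block)
      next
    }
    agg <- function(f) mean(vapply(per_rep, `[[`, numeric(1), f))
    rows[[j]] <- data.frame(n = n, rmsd = agg("rmsd"), k_step = agg("k_step"),
                            k_fail = agg("k_fail"),
                            brightness = agg("brightness"),
                            k_block = agg("k_block"))
    prev_k <- agg("k_step")
    prev_n <- n
  }
  tab <- do.call(rbind, rows)
  finalize_scan(tab, replicate_mode)
}

finalize_scan <- function(tab, replicate_mode) {
  ok <- is.finite(tab$rmsd)
  if (!any(ok)) stop("every candidate n failed to fit")
  mn <- min(tab$rmsd[ok])
  tab$normalized_rmsd <- tab$rmsd / mn
  # smallest n within 0.1% of the minimum
  cand <- tab$n[ok & tab$normalized_rmsd <= 1 + 1e-3]
  best_n <- min(cand)
  # plateau: final value within 1% of minimum, non-increasing (up to
  # optimiser jitter) over the last 5 scanned n: no unique step count
  ordn <- order(tab$n)
  nr <- tab$normalized_rmsd[ordn]
  k <- length(nr)
  tail_idx <- seq(max(1, k - 4), k)
  plateau <- is.finite(nr[k]) && nr[k] <= 1.01 &&
    all(diff(nr[tail_idx]) <= 2e-3, na.rm = TRUE)
  best_fit <- tab[tab$n == best_n, , drop = FALSE]
  structure(list(table = tab[, c("n", "rmsd", "normalized_rmsd", "k_step",
                                 "k_fail", "brightness", "k_block")],
                 best_n = best_n, best_fit = best_fit, plateau = plateau,
                 replicate_mode = replicate_mode),
            class = "step_scan")
}

#' @export
print.step_scan <- function(x, ...) {
  cat(sprintf("Step-number scan over n = %d..%d (%s replicates)\n",
              min(x$table$n), max(x$table$n), x$replicate_mode))
  if (x$plateau) {
    cat("  normalised RMSD plateaus: no unique step count resolvable\n")
  } else {
    cat(sprintf("  best n = %d, k_step = %.4g min^-1, k_fail = %.4g min^-1, brightness = %.4g\n",
                x$best_n, x$best_fit$k_step, x$best_fit$k_fail,
                x$best_fit$brightness))
  }
  invisible(x)
}

#' Two-segment scan for a variant's step number
#'
#' Holds every native-segment parameter (initiation, the native domain and
#' the tag transport) fixed to a prior native-only fit, and scans the
#' variable segment's step count `n_var`, floating `k_step_var` and
#' `k_fail_var` (and optionally `k_block_var`). Brightness is fixed to the
#' variant's measured amplitude relative to the native construct.
#'
#' @param traces Variant traces ([transport_trace()] or list).
#' @param native [rate_params()] from the native-only fit; returned
#'   untouched.
#' @param brightness_rel Measured brightness of the variant relative to the
#'   native construct (default 1).
#' @param n_var_range Candidate variable-segment step counts.
#' @param float_k_block If TRUE, additionally float `k_block_var`.
#' @param cond,replicate_mode,n_starts As in [scan_steps()].
#' @param insert_after Chain position of the variable segment (see
#'   [segmented_rate_params()]).
#' @return An object of class `variant_fit`: the `step_scan` over `n_var`
#'   plus `native`, `brightness_rel` and the best-fit variable parameters.
#' @export
fit_variant <- function(traces, native, brightness_rel = 1,
                        n_var_range = 1:20, float_k_block = FALSE,
                        cond = assay_conditions(),
                        replicate_mode = c("average", "individual"),
                        n_starts = 5, insert_after = native$n - 1L) {
  replicate_mode <- match.arg(replicate_mode)
  stopifnot(inherits(native, "rate_params"))
  native_frozen <- unclass(native)  # contract: returned bit-identical
  fits_needed <- prepare_scan_data(traces, replicate_mode)
  rows <- vector("list", length(n_var_range))
  prev_k <- prev_n <- NULL
  for (j in seq_along(n_var_range)) {
    nv <- n_var_range[j]
    warm <- if (is.null(prev_k) || prev_n == 0) NULL else prev_k * nv / prev_n
    per_rep <- lapply(fits_needed, function(d) {
      fit_variant_n(nv, d, cond, native, brightness_rel, float_k_block,
                    n_starts, insert_after, warm_start = warm)
    })
    per_rep <- Filter(Negate(is.null), per_rep)
    if (!length(per_rep)) {
      warning("optimiser failed at n_var = ", nv, "; flagged")
      rows[[j]] <- data.frame(n = nv, rmsd = NA_real_, k_step = NA_real_,
                              k_fail = NA_real_, brightness = brightness_rel,
                              k_block = NA_real_)
      next
    }
    agg <- function(f) mean(vapply(per_rep, `[[`, numeric(1), f))
    rows[[j]] <- data.frame(n = nv, rmsd = agg("rmsd"), k_step = agg("k_step"),
                            k_fail = agg("k_fail"), brightness = brightness_rel,
                            k_block = agg("k_block"))
    prev_k <- agg("k_step")
    prev_n <- nv
  }
  scan <- finalize_scan(do.call(rbind, rows), replicate_mode)
  stopifnot(identical(unclass(native), native_frozen))
  best <- scan$best_fit
  structure(list(scan = scan, native = native,
                 brightness_rel = brightness_rel,
                 best_n_var = scan$best_n,
                 k_step_var = best$k_step, k_fail_var = best$k_fail,
                 k_block_var = best$k_block, plateau = scan$plateau),
            class = "variant_fit")
}

fit_variant_n <- function(nv, data, cond, native, brightness_rel,
                          float_k_block, n_starts, insert_after,
                          k_step_range = c(0.5, 50), warm_start = NULL) {
  t <- data$times
  s <- data$signal
  fit_cond <- assay_conditions(substrate_conc = cond$substrate_conc,
                               site_conc = cond$site_conc,
                               times = if (t[1] == 0) t else c(0, t))
  drop0 <- t[1] != 0
  resid_fun <- function(par) {
    sp <- segmented_rate_params(native, n_var = nv,
                                k_step_var = exp(par[["log_k_step"]]),
                                k_fail_var = par[["k_fail"]],
                                k_block_var = if (float_k_block)
                                  par[["k_block"]] else native$k_block,
                                brightness = brightness_rel,
                                insert_after = insert_after)
    out <- try(simulate_segmented_trace(sp, fit_cond)$signal, silent = TRUE)
    if (inherits(out, "try-error")) return(rep(1e3, length(s)))
    (if (drop0) out[-1] else out) - s
  }
  starts <- exp(seq(log(k_step_range[1]), log(k_step_range[2]),
                    length.out = n_starts))
  # a start scaled to the candidate step count keeps the segment's total
  # transport time in a plausible range even for large n_var
  starts <- unique(c(warm_start, starts, nv * native$k_step))
  starts <- starts[starts > 0]
  best <- NULL
  for (ks0 in starts) {
    par0 <- c(log_k_step = log(ks0), k_fail = 0.05)
    lo <- c(log_k_step = log(1e-3), k_fail = 0)
    up <- c(log_k_step = log(1e4), k_fail = 1e2)
    if (float_k_block) {
      par0 <- c(par0, k_block = native$k_block)
      lo <- c(lo, k_block = 0); up <- c(up, k_block = 1e2)
    }
    fit <- try(minpack.lm::nls.lm(par = par0, fn = resid_fun,
                                  lower = lo, upper = up,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200, ftol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error") || fit$info %in% c(0, 9)) next
    rmsd <- sqrt(mean(fit$fvec^2))
    if (is.null(best) || rmsd < best$rmsd) {
      best <- list(rmsd = rmsd, k_step = exp(fit$par[["log_k_step"]]),
                   k_fail = fit$par[["k_fail"]],
                   k_block = if (float_k_block) fit$par[["k_block"]]
                             else native$k_block)
    }
  }
  best
}

#' @export
print.variant_fit <- function(x, ...) {
  cat("Two-segment variant fit (native parameters fixed)\n")
  if (x$plateau) {
    cat("  normalised RMSD plateaus with n_var: step count unresolved\n")
  } else {
    cat(sprintf("  best n_var = %d, k_step_var = %.4g min^-1\n",
                x$best_n_var, x$k_step_var))
  }
  invisible(x)
}
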