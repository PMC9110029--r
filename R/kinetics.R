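# Sequential-step kinetic model of SecA/SecYEG protein translocation.
#
# The observable is luminescence from split NanoLuc: the large fragment (11S)
# is enclosed in the vesicle and the pre-protein carries the complementary
# pep86 tag, so light appears the instant the tag crosses the membrane.
# Transport is modelled as a pre-equilibrated binding step followed by an
# irreversible chain: initiation, then n equal-rate transport steps, with the
# final step producing the luminescent product. Translocating intermediates
# can additionally dissociate and restart (k_fail) or become permanently
# trapped, killing the site (k_block).

#' Kinetic parameters of the sequential transport model
#'
#' Bundles the rate constants of the step model. All times are minutes and
#' all first-order rates min^-1; `k_on` is a second-order rate in
#' uM^-1 min^-1. `k_init` defaults to `k_step`, reflecting the assumption
#' that initiation proceeds at the same rate as a transport step.
#'
#' The default fixed constants (`k_block` = 0.31 min^-1, `k_on` = 0.96
#' uM^-1 min^-1, `k_off` = 0.085 min^-1) are the independently determined
#' values used throughout the transport-assay analysis; `k_step`, `k_fail`
#' and `brightness` are the quantities normally floated during fitting.
#'
#' @param n Number of kinetic transport steps after initiation (integer
#'   >= 1). Light is produced on completion of the n-th step.
#' @param k_step Per-step transport rate (min^-1).
#' @param k_init Initiation rate (min^-1); defaults to `k_step`.
#' @param k_fail Rate at which a translocating pre-protein dissociates with
#'   the possibility of restart (min^-1); substrate and site are returned to
#'   their free pools.
#' @param k_block Rate of permanent trapping in the channel (min^-1); the
#'   site is irreversibly lost.
#' @param k_on Association rate of pre-protein and transport site
#'   (uM^-1 min^-1).
#' @param k_off Dissociation rate of the pre-initiation complex (min^-1).
#' @param brightness Luminescent signal per completed NanoLuc (dimensionless,
#'   normalised).
#' @return An object of class `rate_params`.
#' @examples
#' rate_params(n = 6, k_step = 5.31)
#' @export
rate_params <- function(n, k_step, k_init = k_step, k_fail = 0,
                        k_block = 0.31, k_on = 0.96, k_off = 0.085,
                        brightness = 1) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 1L)
  rates <- c(k_step = k_step, k_init = k_init, k_fail = k_fail,
             k_block = k_block, k_on = k_on, k_off = k_off)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0")
  if (!is.finite(brightness) || brightness <= 0)
    stop("'brightness' must be > 0")
  structure(list(n = n, k_step = k_step, k_init = k_init, k_fail = k_fail,
                 k_block = k_block, k_on = k_on, k_off = k_off,
                 brightness = brightness),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Sequential transport model parameters\n")
  cat(sprintf("  n = %d steps, k_step = %.4g min^-1 (k_init = %.4g)\n",
              x$n, x$k_step, x$k_init))
  cat(sprintf("  k_fail = %.4g, k_block = %.4g min^-1\n", x$k_fail, x$k_block))
  cat(sprintf("  binding: k_on = %.4g uM^-1 min^-1, k_off = %.4g min^-1\n",
              x$k_on, x$k_off))
  cat(sprintf("  brightness = %.4g\n", x$brightness))
  invisible(x)
}

#' Two-segment kinetic parameters for engineered substrate variants
#'
#' For substrates built from a fixed "native" portion (initiation, the first
#' native domain and the luminescent tag) and a central "variable" domain,
#' the transport chain is split in two: the native steps keep the parameters
#' of the native-only fit, while the variable segment gets its own step
#' count and rates. Used to extract step number and rate for the variable
#' domain alone while holding everything shared between constructs fixed.
#'
#' @param native A [rate_params()] object from the native-only (baseline
#'   construct) fit; its fields are never altered by downstream fitting.
#' @param n_var Number of transport steps in the variable segment (integer
#'   >= 0; 0 is the degenerate baseline topology with no inserted domain).
#' @param k_step_var,k_fail_var,k_block_var Rates (min^-1) for the variable
#'   segment's steps; failure and blocking default to the native values.
#' @param brightness Shared signal scale; defaults to the native value.
#' @param insert_after Number of native transport steps completed before the
#'   variable segment. Defaults to `native$n - 1`: the variable domain is
#'   transported before the final native transition, which represents the
#'   luminescent tag crossing.
#' @return An object of class `segmented_rate_params`.
#' @export
segmented_rate_params <- function(native, n_var, k_step_var,
                                  k_fail_var = native$k_fail,
                                  k_block_var = native$k_block,
                                  brightness = native$brightness,
                                  insert_after = native$n - 1L) {
  stopifnot(inherits(native, "rate_params"))
  n_var <- as.integer(n_var)
  if (is.na(n_var) || n_var < 0L) stop("'n_var' must be an integer >= 0")
  if (n_var > 0L) {
    vr <- c(k_step_var, k_fail_var, k_block_var)
    if (any(!is.finite(vr)) || any(vr < 0) || k_step_var <= 0)
      stop("variable-segment rates must be finite, >= 0, with k_step_var > 0")
  }
  insert_after <- as.integer(insert_after)
  if (insert_after < 0L || insert_after > native$n)
    stop("'insert_after' places the variable segment outside the chain")
  structure(list(native = native, n_var = n_var, k_step_var = k_step_var,
                 k_fail_var = k_fail_var, k_block_var = k_block_var,
                 brightness = brightness, insert_after = insert_after),
            class = "segmented_rate_params")
}

#' Assay conditions for a transport reaction
#'
#' @param substrate_conc Pre-protein concentration (uM). The default 2 uM is
#'   saturating for the standard assay.
#' @param site_conc Active translocon/11S site concentration (uM).
#' @param t_max Simulated duration (min), used when `times` is NULL.
#' @param dt Sampling interval (min); the default 0.1 min matches
#'   plate-reader cadence.
#' @param times Optional explicit sample-time vector (min), strictly
#'   increasing and starting at 0; overrides `t_max`/`dt`.
#' @return An object of class `assay_conditions`.
#' @export
assay_conditions <- function(substrate_conc = 2, site_conc = 0.1,
                             t_max = 30, dt = 0.1, times = NULL) {
  if (is.null(times)) times <- seq(0, t_max, by = dt)
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("'times' must be strictly increasing and start at 0")
  if (!is.finite(substrate_conc) || substrate_conc <= 0)
    stop("'substrate_conc' must be > 0")
  if (!is.finite(site_conc) || site_conc <= 0)
    stop("'site_conc' must be > 0")
  structure(list(substrate_conc = substrate_conc, site_conc = site_conc,
                 times = as.numeric(times)),
            class = "assay_conditions")
}

#' Pre-reaction binding equilibrium
#'
#' Before ATP addition the pre-protein and the transport sites equilibrate:
#' \eqn{[C_0]/([S][Y]) = k_{on}/k_{off}}. Solves the resulting quadratic for
#' the complex concentration, conserving substrate and site mass, with all
#' downstream species zero. Limits: no binding when `k_on = 0`; complete
#' binding of the limiting species when `k_off = 0`.
#'
#' @param params A [rate_params()] or [segmented_rate_params()] object.
#' @param cond An [assay_conditions()] object.
#' @return Named numeric vector with elements `S` (free substrate), `Y`
#'   (free sites) and `C0` (pre-initiation complex), in uM.
#' @export
equilibrate_binding <- function(params, cond) {
  if (inherits(params, "segmented_rate_params")) params <- params$native
  stopifnot(inherits(params, "rate_params"), inherits(cond, "assay_conditions"))
  S0 <- cond$substrate_conc
  Y0 <- cond$site_conc
  k_on <- params$k_on
  k_off <- params$k_off
  if (k_on == 0 && k_off == 0)
    stop("degenerate binding: k_on and k_off are both zero")
  if (k_on == 0) {
    C0 <- 0
  } else if (k_off == 0) {
    C0 <- min(S0, Y0)
  } else {
    Kd <- k_off / k_on
    # smaller root of C^2 - (S0 + Y0 + Kd) C + S0 Y0 = 0
    b <- S0 + Y0 + Kd
    C0 <- (b - sqrt(b * b - 4 * S0 * Y0)) / 2
  }
  c(S = S0 - C0, Y = Y0 - C0, C0 = C0)
}

# Integrate a general irreversible transport chain.
# r, f, b: per-intermediate step / fail / block rates (length m >= 1).
# State: S, Y, C0, X_1..X_m, Fin (luminescent), B (blocked, absorbing).
# Failure returns substrate and site to their free pools (restart with no
# memory of progress); blocking removes both permanently.
integrate_chain <- function(r, f, b, k_init, k_on, k_off, brightness,
                            cond, init, species = FALSE,
                            rtol = 1e-8, atol = 1e-10) {
  m <- length(r)
  stopifnot(m >= 1L, length(f) == m, length(b) == m)
  y0 <- c(init[["S"]], init[["Y"]], init[["C0"]], rep(0, m), 0, 0)
  exit <- r + f + b
  rhs <- function(t, y, p) {
    S <- y[1]; Y <- y[2]; C0 <- y[3]
    X <- y[4:(3 + m)]
    bind <- k_on * S * Y
    rel <- k_off * C0
    restart <- sum(f * X)
    dfree <- -bind + rel + restart
    inflow <- c(k_init * C0, r[-m] * X[-m])
    list(c(dfree, dfree,
           bind - (k_off + k_init) * C0,
           inflow - exit * X,
           r[m] * X[m],
           sum(b * X)))
  }
  out <- deSolve::lsoda(y0, cond$times, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed to converge", call. = FALSE)
  out <- unname(as.matrix(out))
  Fin <- out[, 4 + m + 1]
  # guard against tiny negative excursions at the solver tolerance
  signal <- brightness * pmax(Fin, 0) / cond$site_conc
  res <- list(times = cond$times, signal = signal)
  if (species) {
    sp <- out[, -1, drop = FALSE]
    colnames(sp) <- c("S", "Y", "C0", paste0("X", seq_len(m)), "Fin", "B")
    res$species <- sp
  }
  res
}

#' Simulate a luminescence transport trace
#'
#' Integrates the sequential-step reaction network
#' \deqn{S + Y \rightleftharpoons C_0 \rightarrow I_1 \rightarrow \dots
#'   \rightarrow I_n \rightarrow F}
#' where binding starts at equilibrium (ATP addition defines t = 0),
#' `C0 -> I1` is initiation at `k_init`, each subsequent transition proceeds
#' at `k_step`, and arrival in F (tag across the membrane, NanoLuc formed)
#' produces light. Each translocating intermediate `I_1..I_{n-1}` can also
#' dissociate and restart (`k_fail`, substrate and site recycled) or become
#' permanently trapped (`k_block`, site lost). The reported signal is
#' `brightness * [F](t) / site_conc`, so a fully converted site pool at
#' brightness 1 gives signal 1.
#'
#' @param params A [rate_params()] object.
#' @param cond An [assay_conditions()] object.
#' @param pre_bound If TRUE, start with every site in the pre-initiation
#'   complex (saturating pre-binding) instead of the binding equilibrium.
#' @param species If TRUE, return the full species-occupancy matrix.
#' @param rtol,atol Solver tolerances (stiff-capable `lsoda`).
#' @return An object of class `simulated_trace` with elements `times`,
#'   `signal` and optionally `species`.
#' @examples
#' p <- rate_params(n = 6, k_step = 5.31)
#' tr <- simulate_trace(p, assay_conditions(t_max = 10))
#' @export
simulate_trace <- function(params, cond = assay_conditions(),
                           pre_bound = FALSE, species = FALSE,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "rate_params"))
  n <- params$n
  r <- rep(params$k_step, n)
  f <- b <- rep(0, n)
  if (n > 1L) {
    f[seq_len(n - 1L)] <- params$k_fail
    b[seq_len(n - 1L)] <- params$k_block
  }
  init <- if (pre_bound) {
    c(S = cond$substrate_conc - cond$site_conc, Y = 0, C0 = cond$site_conc)
  } else {
    equilibrate_binding(params, cond)
  }
  res <- integrate_chain(r, f, b, params$k_init, params$k_on, params$k_off,
                         params$brightness, cond, init, species,
                         rtol, atol)
  structure(c(res, list(params = params, conditions = cond)),
            class = "simulated_trace")
}

#' Simulate a trace for a two-segment (variant) substrate
#'
#' Builds the concatenated chain for an engineered substrate: initiation and
#' the native steps at the native rates, with the variable segment's steps
#' (its own `k_step`, `k_fail`, `k_block`) inserted after `insert_after`
#' native steps. Light still arises on the final transition of the native
#' chain (the tag crossing). With the variable segment parameterised
#' identically to the native one, the trace is exactly that of the uniform
#' model with `n = n_native + n_var`.
#'
#' @param params A [segmented_rate_params()] object.
#' @inheritParams simulate_trace
#' @return An object of class `simulated_trace`.
#' @export
simulate_segmented_trace <- function(params, cond = assay_conditions(),
                                     pre_bound = FALSE, species = FALSE,
                                     rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "segmented_rate_params"))
  nat <- params$native
  n_nat <- nat$n
  a <- params$insert_after
  if (a > n_nat)
    stop("inconsistent construct topology: variable segment outside chain")
  nv <- params$n_var
  seg <- c(rep("nat", a), rep("var", nv), rep("nat", n_nat - a))
  m <- length(seg)
  r <- ifelse(seg == "nat", nat$k_step, params$k_step_var)
  f <- ifelse(seg == "nat", nat$k_fail, params$k_fail_var)
  b <- ifelse(seg == "nat", nat$k_block, params$k_block_var)
  # the last intermediate before the luminescent state commits: no fail/block
  f[m] <- 0
  b[m] <- 0
  init <- if (pre_bound) {
    c(S = cond$substrate_conc - cond$site_conc, Y = 0, C0 = cond$site_conc)
  } else {
    equilibrate_binding(nat, cond)
  }
  res <- integrate_chain(r, f, b, nat$k_init, nat$k_on, nat$k_off,
                         params$brightness, cond, init, species,
                         rtol, atol)
  structure(c(res, list(params = params, conditions = cond)),
            class = "simulated_trace")
}

#' @export
print.simulated_trace <- function(x, ...) {
  cat(sprintf("Simulated transport trace: %d points over %.3g min, final signal %.4g\n",
              length(x$times), max(x$times), x$signal[length(x$signal)]))
  invisible(x)
}

#' @export
as.data.frame.simulated_trace <- function(x, ...) {
  data.frame(time_min = x$times, signal = x$signal)
}

#' Completion curve of a chain of equal-rate exponential transitions
#'
#' Analytic cumulative probability that `m` sequential exponential(`k`)
#' transitions have all completed by each time; the Erlang (gamma) CDF with
#' shape `m` and rate `k`. Mean completion time is `m / k`. Serves as the
#' closed-form reference for the transport chain with failure and blocking
#' switched off.
#'
#' @param m Number of transitions (>= 1).
#' @param k Rate of each transition (min^-1, > 0).
#' @param times Times (min) at which to evaluate.
#' @return Numeric vector of completion probabilities.
#' @export
erlang_completion_curve <- function(m, k, times) {
  stopifnot(m >= 1, k > 0)
  stats::pgamma(times, shape = m, rate = k)
}

#' Read and write model parameter configuration files
#'
#' A flat YAML (or JSON) mapping with keys `n`, `k_step`, `k_init`,
#' `k_fail`, `k_block`, `k_on`, `k_off`, `brightness`,
#' `substrate_conc_uM`, `site_conc_uM`.
#'
#' @param path File path.
#' @return `read_rate_config`: a list with elements `params`
#'   ([rate_params()]) and `conditions` ([assay_conditions()]).
#' @export
read_rate_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  keys <- c("n", "k_step", "k_init", "k_fail", "k_block", "k_on", "k_off",
            "brightness", "substrate_conc_uM", "site_conc_uM")
  missing <- setdiff(keys, names(cfg))
  if (length(missing))
    stop("config is missing keys: ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(cfg), keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  params <- rate_params(n = cfg$n, k_step = cfg$k_step, k_init = cfg$k_init,
                        k_fail = cfg$k_fail, k_block = cfg$k_block,
                        k_on = cfg$k_on, k_off = cfg$k_off,
                        brightness = cfg$brightness)
  cond <- assay_conditions(substrate_conc = cfg$substrate_conc_uM,
                           site_conc = cfg$site_conc_uM)
  list(params = params, conditions = cond)
}

#' @rdname read_rate_config
#' @param params A [rate_params()] object.
#' @param cond An [assay_conditions()] object.
#' @export
write_rate_config <- function(params, cond, path) {
  stopifnot(inherits(params, "rate_params"), inherits(cond, "assay_conditions"))
  cfg <- list(n = params$n, k_step = params$k_step, k_init = params$k_init,
              k_fail = params$k_fail, k_block = params$k_block,
              k_on = params$k_on, k_off = params$k_off,
              brightness = params$brightness,
              substrate_conc_uM = cond$substrate_conc,
              site_conc_uM = cond$site_conc)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
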