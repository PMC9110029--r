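# Shared fixtures: the native best-fit parameter set and a short assay
# window that still spans trace completion at these rates.

native_params <- function(...) rate_params(n = 6, k_step = 5.31, ...)

short_cond <- function(t_max = 10) assay_conditions(t_max = t_max)

# Bisection oracle for the binding equilibrium: solves
# Kd * C = (S - C)(Y - C) independently of the quadratic formula.
bisect_equilibrium <- function(S, Y, Kd, tol = 1e-12) {
  f <- function(C) (S - C) * (Y - C) - Kd * C
  lo <- 0
  hi <- min(S, Y)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
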