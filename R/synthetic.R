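# Synthetic-data generators: model-generated luminescence trace sets with
# plate-reader-like noise, matched baseline/variant construct panels, and
# annotated proteomes with a controllable lysine/arginine secretion bias.
# Every generator is a pure function of its arguments and seed.

#' Generate a replicate set of noisy transport traces
#'
#' Forward-simulates the kinetic model and adds i.i.d. additive Gaussian
#' noise to the normalised signal of each replicate (plate-reader-like
#' noise; default SD 0.01 on a unit-amplitude trace).
#'
#' @param params A [rate_params()] or [segmented_rate_params()] object.
#' @param cond [assay_conditions()].
#' @param noise_sd Additive Gaussian noise SD on the normalised signal.
#' @param replicates Number of replicate traces.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param construct,condition_label Metadata labels stamped on each trace.
#' @return A list of [transport_trace()] objects with attribute `truth`
#'   recording the generating parameters and seed.
#' @examples
#' tr <- make_trace_dataset(rate_params(6, 5.31), replicates = 3, seed = 1)
#' @export
make_trace_dataset <- function(params, cond = assay_conditions(),
                               noise_sd = 0.01, replicates = 3L, seed = 1L,
                               construct = "synthetic",
                               condition_label = "synthetic") {
  stopifnot(noise_sd >= 0, replicates >= 1)
  clean <- if (inherits(params, "segmented_rate_params")) {
    simulate_segmented_trace(params, cond)
  } else {
    simulate_trace(params, cond)
  }
  traces <- withr::with_seed(seed, {
    lapply(seq_len(replicates), function(i) {
      transport_trace(clean$times,
                      clean$signal + stats::rnorm(length(clean$signal),
                                                  0, noise_sd),
                      construct = construct, condition = condition_label,
                      replicate = i)
    })
  })
  attr(traces, "truth") <- list(params = params, noise_sd = noise_sd,
                                replicates = replicates, seed = seed)
  traces
}

#' Specification of one localization class of a synthetic proteome
#'
#' @param n Number of proteins (>= 10).
#' @param length_mean,length_sd Mature-sequence length distribution
#'   (residues; normal, truncated below at 30).
#' @param lys_mean,lys_sd Target per-protein Lys/(Lys+Arg) fraction:
#'   normal, truncated to `[0, 1]`.
#' @param ss_mean,ss_sd Signal-peptide length distribution for secreted
#'   classes (truncated below at 15); ignored for cytosolic.
#' @return A list of class `proteome_class_spec`.
#' @export
proteome_class_spec <- function(n, length_mean = 300, length_sd = 80,
                                lys_mean = 0.5, lys_sd = 0.15,
                                ss_mean = 22, ss_sd = 3) {
  stopifnot(n >= 10, lys_mean >= 0, lys_mean <= 1, lys_sd >= 0)
  structure(list(n = as.integer(n), length_mean = length_mean,
                 length_sd = length_sd, lys_mean = lys_mean,
                 lys_sd = lys_sd, ss_mean = ss_mean, ss_sd = ss_sd),
            class = "proteome_class_spec")
}

# Background residue frequencies (positives excluded) approximating an
# average bacterial proteome composition; only the K/R statistic is
# controlled, the rest is neutral filler.
background_aa_freq <- c(
  A = 0.089, N = 0.040, D = 0.054, C = 0.012, Q = 0.044, E = 0.062,
  G = 0.074, H = 0.023, I = 0.060, L = 0.107, M = 0.028, F = 0.039,
  P = 0.044, S = 0.058, T = 0.054, W = 0.015, Y = 0.029, V = 0.071)

# Hydrophobic-core-like residue pool for synthetic signal peptides; the
# composition is independent of the mature-domain K/R bias by construction.
ss_aa_pool <- c(A = 0.20, L = 0.30, V = 0.12, I = 0.08, F = 0.08,
                S = 0.07, G = 0.06, T = 0.05, W = 0.02, M = 0.05,
                K = 0.04, R = 0.03)

#' Generate an annotated synthetic proteome
#'
#' Samples, per class, a target Lys/(Lys+Arg) fraction for each protein
#' from a truncated normal, then composes a sequence whose realised
#' fraction matches the target to within `1/(K+R)`: about 10% of mature
#' positions are positive residues, split between K and R by rounding the
#' target, with the remaining positions drawn from a fixed background
#' frequency table. Secreted (Sec/Tat) records carry a synthetic signal
#' peptide whose composition is independent of the mature-domain bias (it
#' is stripped before analysis).
#'
#' @param class_specs Named list of [proteome_class_spec()]s; names are the
#'   localization classes ("cytosolic", "Sec", "Tat").
#' @param seed Integer seed.
#' @return A list of class `synthetic_proteome` with `records` (list of
#'   [protein_record()]), `annotation` (data frame id, loc_class, ss_start,
#'   ss_end), and `truth` (the specs and seed).
#' @export
make_proteome <- function(class_specs, seed = 1L) {
  stopifnot(length(class_specs) >= 1, !is.null(names(class_specs)),
            all(names(class_specs) %in% c("cytosolic", "Sec", "Tat")))
  records <- withr::with_seed(seed, {
    recs <- list()
    for (cl in names(class_specs)) {
      spec <- class_specs[[cl]]
      stopifnot(inherits(spec, "proteome_class_spec"))
      for (i in seq_len(spec$n)) {
        L <- max(30L, round(stats::rnorm(1, spec$length_mean, spec$length_sd)))
        target <- min(1, max(0, stats::rnorm(1, spec$lys_mean, spec$lys_sd)))
        n_pos <- max(1L, round(0.10 * L))
        n_k <- round(target * n_pos)
        filler <- sample(names(background_aa_freq), L - n_pos,
                         replace = TRUE, prob = background_aa_freq)
        mature <- sample(c(rep("K", n_k), rep("R", n_pos - n_k), filler))
        id <- sprintf("SYN_%s_%04d", toupper(substr(cl, 1, 3)), i)
        if (cl == "cytosolic") {
          recs[[id]] <- protein_record(id, paste(mature, collapse = ""), cl)
        } else {
          ss_len <- max(15L, round(stats::rnorm(1, spec$ss_mean, spec$ss_sd)))
          ss <- sample(names(ss_aa_pool), ss_len, replace = TRUE,
                       prob = ss_aa_pool)
          recs[[id]] <- protein_record(
            id, paste(c(ss, mature), collapse = ""), cl,
            ss_start = 1L, ss_end = ss_len)
        }
      }
    }
    recs
  })
  annotation <- data.frame(
    id = vapply(records, `[[`, character(1), "id"),
    loc_class = vapply(records, `[[`, character(1), "loc_class"),
    ss_start = vapply(records, `[[`, integer(1), "ss_start"),
    ss_end = vapply(records, `[[`, integer(1), "ss_end"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(records = unname(records), annotation = annotation,
                 truth = list(class_specs = class_specs, seed = seed)),
            class = "synthetic_proteome")
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat(sprintf("Synthetic proteome: %d records (%s)\n", length(x$records),
              paste(names(x$truth$class_specs), collapse = ", ")))
  invisible(x)
}

#' Generate a matched baseline + variant trace panel
#'
#' Emulates the engineered-substrate experimental design: one baseline
#' (LXX-topology) trace set generated from the native single-segment model,
#' plus variant (XLX-topology) sets generated from the two-segment model
#' with distinct variable-segment parameters. A manifest records the ground
#' truth for every set.
#'
#' @param seed Integer seed.
#' @param native [rate_params()] for the baseline construct; the default is
#'   the native best fit (n = 6, k_step = 5.31 min^-1 with the standard
#'   fixed constants).
#' @param variants Named list; each element is a list with `n_var`,
#'   `k_step_var` and optional `k_fail_var`, `k_block_var`,
#'   `brightness_rel`.
#' @param cond [assay_conditions()].
#' @param noise_sd,replicates Passed to [make_trace_dataset()].
#' @return A list of class `variant_panel` with `baseline` (trace list),
#'   `variants` (named list of trace lists) and `manifest` (ground-truth
#'   parameters per set).
#' @export
make_variant_panel <- function(seed = 1L,
                               native = rate_params(6, 5.31),
                               variants = list(
                                 wt = list(n_var = 6, k_step_var = 6.74),
                                 fast = list(n_var = 12, k_step_var = 60),
                                 slow = list(n_var = 6, k_step_var = 1.9)),
                               cond = assay_conditions(),
                               noise_sd = 0.01, replicates = 3L) {
  baseline <- make_trace_dataset(native, cond, noise_sd, replicates,
                                 seed = seed, construct = "LXX")
  out <- list()
  manifest <- list(baseline = list(params = native, seed = seed))
  i <- 0L
  for (nm in names(variants)) {
    i <- i + 1L
    v <- variants[[nm]]
    sp <- segmented_rate_params(
      native, n_var = v$n_var, k_step_var = v$k_step_var,
      k_fail_var = if (is.null(v$k_fail_var)) native$k_fail else v$k_fail_var,
      k_block_var = if (is.null(v$k_block_var)) native$k_block
                    else v$k_block_var,
      brightness = if (is.null(v$brightness_rel)) native$brightness
                   else v$brightness_rel * native$brightness)
    out[[nm]] <- make_trace_dataset(sp, cond, noise_sd, replicates,
                                    seed = seed + i,
                                    construct = paste0("XLX_", nm))
    manifest[[nm]] <- list(params = sp, seed = seed + i)
  }
  structure(list(baseline = baseline, variants = out, manifest = manifest),
            class = "variant_panel")
}
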