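# Sliding-window per-residue property profiles and region averages for
# protein sequences, plus the correlation helper used to relate PMF
# stimulation to variant hydrophobicity.

#' Built-in amino-acid property scales
#'
#' Per-residue values for the three scales used in the analysis, as
#' published:
#' * `hydrophobicity` — Kyte & Doolittle (1982) hydropathy index.
#' * `helical_propensity` — Deleage & Roux (1987) alpha-helix
#'   conformational parameter.
#' * `bulkiness` — Zimmerman, Eliezer & Simha (1968) bulkiness.
#'
#' @format A named list of three named numeric vectors (one value per
#'   standard amino acid).
#' @export
aa_scales <- list(
  hydrophobicity = c(
    A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2),
  helical_propensity = c(
    A = 1.489, R = 1.224, N = 0.772, D = 0.924, C = 0.966,
    Q = 1.164, E = 1.504, G = 0.510, H = 1.003, I = 1.003,
    L = 1.236, K = 1.172, M = 1.363, F = 1.195, P = 0.492,
    S = 0.739, T = 0.785, W = 1.090, Y = 0.787, V = 0.990),
  bulkiness = c(
    A = 11.50, R = 14.28, N = 12.82, D = 11.68, C = 13.46,
    Q = 14.45, E = 13.57, G =  3.40, H = 13.69, I = 21.40,
    L = 21.40, K = 15.71, M = 16.25, F = 19.80, P = 17.43,
    S =  9.47, T = 15.77, W = 21.67, Y = 18.03, V = 21.57)
)

#' Define a property scale with its window configuration
#'
#' @param name One of `"hydrophobicity"`, `"helical_propensity"`,
#'   `"bulkiness"` (see [aa_scales]) or `"user"` with `residue_values`
#'   supplied.
#' @param residue_values Named numeric vector covering all 20 standard
#'   amino acids (required for `name = "user"`).
#' @param window Odd window width (residues); default 9.
#' @return An object of class `property_scale`.
#' @export
property_scale <- function(name = c("hydrophobicity", "helical_propensity",
                                    "bulkiness", "user"),
                           residue_values = NULL, window = 9L) {
  name <- match.arg(name)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("'window' must be odd and >= 1")
  if (name == "user") {
    if (is.null(residue_values)) stop("'user' scale needs residue_values")
  } else {
    residue_values <- aa_scales[[name]]
  }
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  if (!all(aa20 %in% names(residue_values)))
    stop("scale must cover all 20 standard amino acids")
  structure(list(name = name, residue_values = residue_values[aa20],
                 window = window),
            class = "property_scale")
}

seq_to_values <- function(seq, scale) {
  res <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(res), c(names(scale$residue_values), "X"))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  v <- unname(scale$residue_values[res])  # X -> NA, excluded from means
  v
}

#' Sliding-window property profile
#'
#' The value at position i is the unweighted mean of the scale values over
#' the window centred at i. Positions within `(window - 1)/2` of either end
#' are undefined (`NA`): no shrunken edge windows. Unknown residues (`X`)
#' are excluded from the window mean; a window with more than 20% unknowns
#' is undefined.
#'
#' @param seq Amino-acid sequence, length >= window.
#' @param scale A [property_scale()].
#' @return Data frame with columns `position`, `residue`, `value`.
#' @export
window_profile <- function(seq, scale) {
  stopifnot(inherits(scale, "property_scale"))
  v <- seq_to_values(seq, scale)
  L <- length(v)
  w <- scale$window
  if (L < w) stop("sequence shorter than the window")
  h <- (w - 1L) %/% 2L
  known <- !is.na(v)
  csum <- cumsum(c(0, ifelse(known, v, 0)))
  ccnt <- cumsum(c(0, known))
  out <- rep(NA_real_, L)
  centers <- seq(h + 1L, L - h)
  lo <- centers - h
  hi <- centers + h
  cnt <- ccnt[hi + 1L] - ccnt[lo]
  sm <- csum[hi + 1L] - csum[lo]
  val <- ifelse(w - cnt > 0.2 * w, NA_real_, sm / cnt)
  out[centers] <- val
  data.frame(position = seq_len(L),
             residue = strsplit(toupper(seq), "")[[1]],
             value = out)
}

#' Mean property value of a whole region
#'
#' Unweighted mean of the per-residue scale values over the full sequence
#' (the region-average mode: raw per-residue values, no windowing).
#' Unknown residues (`X`) are excluded.
#'
#' @inheritParams window_profile
#' @return A single numeric value.
#' @export
region_mean <- function(seq, scale) {
  stopifnot(inherits(scale, "property_scale"))
  v <- seq_to_values(seq, scale)
  if (!length(v)) stop("empty sequence")
  mean(v, na.rm = TRUE)
}

#' Pearson correlation with its least-squares line
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return List with `r`, `slope`, `intercept`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need >= 3 points")
  fit <- stats::lm(y ~ x)
  list(r = stats::cor(x, y),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}
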