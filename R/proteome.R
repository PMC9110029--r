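# Proteome-scale lysine/arginine secretion-bias analysis: per-protein
# Lys/(Lys+Arg) fractions by localization class, Sturges-rule histograms,
# single-Gaussian fits, and class comparisons.

#' A protein record with localization annotation
#'
#' @param id Accession-like identifier.
#' @param sequence Amino-acid sequence (20-letter alphabet; `X` tolerated).
#' @param loc_class Localization class: "cytosolic", "Sec" or "Tat".
#' @param ss_start,ss_end Optional 1-based inclusive signal-peptide span
#'   (secreted classes only); the span must start at 1 and leave at least
#'   one mature residue.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, loc_class,
                           ss_start = NA_integer_, ss_end = NA_integer_) {
  loc_class <- match.arg(loc_class, c("cytosolic", "Sec", "Tat"))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("empty sequence for ", id)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence))
    stop("invalid residue letters in ", id)
  has_ss <- !is.na(ss_start) || !is.na(ss_end)
  if (has_ss) {
    if (loc_class == "cytosolic")
      stop("signal-peptide span on a cytosolic record: ", id)
    if (is.na(ss_start) || is.na(ss_end) || ss_start != 1L)
      stop("signal peptide must span 1..ss_end: ", id)
    if (ss_end >= nchar(sequence))
      stop("signal peptide covers the whole sequence: ", id)
  }
  structure(list(id = id, sequence = sequence, loc_class = loc_class,
                 ss_start = if (has_ss) as.integer(ss_start) else NA_integer_,
                 ss_end = if (has_ss) as.integer(ss_end) else NA_integer_),
            class = "protein_record")
}

#' Mature sequence after signal-peptide removal
#'
#' Secreted proteins are analysed on their mature domain: the residues of
#' the annotated signal peptide are removed first. Cytosolic records are
#' returned unchanged.
#'
#' @param rec A [protein_record()].
#' @return The mature amino-acid sequence.
#' @export
mature_sequence <- function(rec) {
  stopifnot(inherits(rec, "protein_record"))
  if (rec$loc_class == "cytosolic" || is.na(rec$ss_end)) return(rec$sequence)
  if (rec$ss_end >= nchar(rec$sequence))
    stop("signal peptide exceeds sequence for ", rec$id)
  substring(rec$sequence, rec$ss_end + 1L)
}

#' Fraction of positive residues that are lysine
#'
#' `count(K) / (count(K) + count(R))` for a sequence; `NA` when the
#' sequence contains neither lysine nor arginine (the statistic is
#' undefined and such proteins are excluded from histograms).
#'
#' @param seq Amino-acid sequence (character scalar or vector).
#' @return Numeric in `[0, 1]`, or `NA` where K + R = 0.
#' @examples
#' lys_fraction("KRKR")  # 0.5
#' @export
lys_fraction <- function(seq) {
  k <- nchar(seq) - nchar(gsub("K", "", seq, fixed = TRUE))
  r <- nchar(seq) - nchar(gsub("R", "", seq, fixed = TRUE))
  ifelse(k + r == 0, NA_real_, k / (k + r))
}

#' Histogram bin count by Sturges' rule
#'
#' `1 + 3.322 * log10(n)`, rounded to the nearest integer (3.322 log10 is
#' log2, recovering Sturges' original `1 + log2 n`).
#'
#' @param n Sample size (>= 2).
#' @return Integer bin count.
#' @export
sturges_bins <- function(n) {
  stopifnot(n >= 2)
  as.integer(round(1 + 3.322 * log10(n)))
}

#' Frequency histogram of per-protein lysine fractions
#'
#' Bins span `[0, 1]` with the Sturges-rule count for the sample size;
#' bins are half-open `[a, b)` with the final bin closed, so 0 and 1 are
#' assigned deterministically. Frequencies are bin counts divided by the
#' number of defined values `n`.
#'
#' @param values Per-protein fractions; `NA`s (undefined fractions) are
#'   dropped before `n` is computed.
#' @param class_label Label carried through to plots/outputs.
#' @return An object of class `class_histogram` with `class_label`, `n`,
#'   `bin_edges`, `mids`, `counts`, `frequencies`.
#' @export
build_histogram <- function(values, class_label = "unknown") {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need >= 2 defined values")
  if (any(values < 0 | values > 1)) stop("fractions must lie in [0, 1]")
  n <- length(values)
  nb <- sturges_bins(n)
  edges <- seq(0, 1, length.out = nb + 1)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = nb)
  structure(list(class_label = class_label, n = n, bin_edges = edges,
                 mids = (edges[-1] + edges[-(nb + 1)]) / 2,
                 counts = counts, frequencies = counts / n),
            class = "class_histogram")
}

#' @export
print.class_histogram <- function(x, ...) {
  cat(sprintf("Lys/(Lys+Arg) histogram [%s]: n = %d, %d bins\n",
              x$class_label, x$n, length(x$counts)))
  invisible(x)
}

#' Fit a single Gaussian to a class histogram
#'
#' Least squares of `a * exp(-(x - mu)^2 / (2 sigma^2))` against the
#' (bin centre, frequency) pairs. Requires at least 4 occupied bins.
#'
#' @param hist A [build_histogram()] result.
#' @return An object of class `gaussian_fit` with `amplitude`, `mean`,
#'   `sd` and `residual_rmsd`.
#' @export
fit_gaussian <- function(hist) {
  stopifnot(inherits(hist, "class_histogram"))
  if (sum(hist$counts > 0) < 4)
    stop("need >= 4 occupied bins for a Gaussian fit")
  x <- hist$mids
  y <- hist$frequencies
  w <- y / sum(y)
  mu0 <- sum(w * x)
  sd0 <- max(sqrt(sum(w * (x - mu0)^2)), diff(hist$bin_edges[1:2]) / 4)
  start <- c(a = max(y), mu = mu0, s = sd0)
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) - y,
    lower = c(1e-9, 0, 1e-6), upper = c(Inf, 1, 10),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info == 0) stop("Gaussian fit did not converge")
  p <- fit$par
  structure(list(amplitude = unname(p[1]), mean = unname(p[2]),
                 sd = unname(p[3]),
                 residual_rmsd = sqrt(mean(fit$fvec^2))),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian fit: mean %.4g, sd %.4g, amplitude %.4g (RMSD %.3g)\n",
              x$mean, x$sd, x$amplitude, x$residual_rmsd))
  invisible(x)
}

#' Compare lysine-fraction distributions between two classes
#'
#' Two-tailed unequal-variance (Welch) t test on per-protein fractions by
#' default; a label-permutation test on the difference in means is offered
#' as a distribution-free alternative.
#'
#' @param values_a,values_b Per-protein fractions (NAs dropped; each class
#'   needs >= 3 defined values).
#' @param method `"welch"` (default) or `"permutation"`.
#' @param n_perm Number of label permutations for `method = "permutation"`.
#' @return A list with `statistic`, `df` (Welch only), `p_value`, `method`.
#' @export
compare_classes <- function(values_a, values_b,
                            method = c("welch", "permutation"),
                            n_perm = 1e4) {
  method <- match.arg(method)
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 3 || length(b) < 3)
    stop("each class needs >= 3 defined values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && a[1] == b[1])
    return(list(statistic = 0, df = NA_real_, p_value = 1, method = method))
  if (method == "welch") {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, method = "welch")
  } else {
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b)
    na <- length(a)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pool), na)
      if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-15)
        hits <- hits + 1L
    }
    list(statistic = obs, df = NA_real_,
         p_value = (hits + 1) / (n_perm + 1), method = "permutation")
  }
}

#' Full lysine/arginine secretion-bias pipeline
#'
#' For a set of annotated protein records: strips signal peptides, computes
#' per-protein Lys/(Lys+Arg) on the mature domain, builds a Sturges-rule
#' histogram and Gaussian fit per localization class, and tests all class
#' pairs.
#'
#' @param records List of [protein_record()]s.
#' @param classes Classes to analyse (default all present).
#' @param test Class-comparison method passed to [compare_classes()].
#' @return An object of class `lysarg_analysis`: `fractions` (data frame of
#'   id, loc_class, lys_fraction), `histograms`, `gaussians` (NULL where a
#'   fit is impossible), and `comparisons` (data frame of pairwise tests).
#' @export
lysarg_analysis <- function(records, classes = NULL,
                            test = c("welch", "permutation")) {
  test <- match.arg(test)
  stopifnot(length(records) > 0)
  fr <- data.frame(
    id = vapply(records, `[[`, character(1), "id"),
    loc_class = vapply(records, `[[`, character(1), "loc_class"),
    lys_fraction = vapply(records, function(r)
      lys_fraction(mature_sequence(r)), numeric(1)),
    stringsAsFactors = FALSE)
  if (is.null(classes)) classes <- unique(fr$loc_class)
  hists <- gauss <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    v <- fr$lys_fraction[fr$loc_class == cl]
    hists[[cl]] <- build_histogram(v, cl)
    gauss[[cl]] <- tryCatch(fit_gaussian(hists[[cl]]), error = function(e) NULL)
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  comparisons <- do.call(rbind, lapply(pairs, function(p) {
    cc <- compare_classes(fr$lys_fraction[fr$loc_class == p[1]],
                          fr$lys_fraction[fr$loc_class == p[2]],
                          method = test)
    data.frame(class_a = p[1], class_b = p[2], statistic = cc$statistic,
               p_value = cc$p_value, method = cc$method,
               stringsAsFactors = FALSE)
  }))
  structure(list(fractions = fr, histograms = hists, gaussians = gauss,
                 comparisons = comparisons),
            class = "lysarg_analysis")
}

#' @export
print.lysarg_analysis <- function(x, ...) {
  cat("Lys/(Lys+Arg) secretion-bias analysis\n")
  for (cl in names(x$histograms)) {
    h <- x$histograms[[cl]]
    m <- mean(x$fractions$lys_fraction[x$fractions$loc_class == cl],
              na.rm = TRUE)
    cat(sprintf("  %-10s n = %4d, mean fraction %.3f\n", cl, h$n, m))
  }
  if (!is.null(x$comparisons)) {
    for (i in seq_len(nrow(x$comparisons)))
      cat(sprintf("  %s vs %s: p = %.3g (%s)\n",
                  x$comparisons$class_a[i], x$comparisons$class_b[i],
                  x$comparisons$p_value[i], x$comparisons$method[i]))
  }
  invisible(x)
}
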