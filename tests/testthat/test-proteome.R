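test_that("signal peptides are stripped before analysis", {
  cyto <- protein_record("c1", "MKRAAA", "cytosolic")
  expect_equal(mature_sequence(cyto), "MKRAAA")
  sec <- protein_record("s1", paste(rep("A", 100), collapse = ""), "Sec",
                        ss_start = 1, ss_end = 22)
  expect_equal(nchar(mature_sequence(sec)), 78)
  # boundary: a single mature residue is allowed
  tat <- protein_record("t1", "AAAK", "Tat", ss_start = 1, ss_end = 3)
  expect_equal(mature_sequence(tat), "K")
  expect_error(protein_record("bad", "AAAA", "Sec", ss_start = 1, ss_end = 4),
               "whole sequence")
  expect_error(protein_record("bad2", "AAAA", "cytosolic",
                              ss_start = 1, ss_end = 2),
               "cytosolic")
})

test_that("lysine fraction counts K among positive residues", {
  expect_equal(lys_fraction("KKKK"), 1)
  expect_equal(lys_fraction("KRKR"), 0.5)
  expect_true(is.na(lys_fraction("AAAA")))
  # invariant under permutation and insertion of non-K/R residues
  set.seed(5)
  for (i in 1:10) {
    seq0 <- paste(sample(c("K", "R", "A", "G"), 40, replace = TRUE),
                  collapse = "")
    perm <- paste(sample(strsplit(seq0, "")[[1]]), collapse = "")
    padded <- paste0("GGSA", seq0, "DDEE")
    expect_identical(lys_fraction(seq0), lys_fraction(perm))
    expect_identical(lys_fraction(seq0), lys_fraction(padded))
  }
})

test_that("Sturges' rule bin counts round the log10 form", {
  expect_identical(sturges_bins(10), 4L)
  expect_identical(sturges_bins(100), 8L)
  expect_identical(sturges_bins(2), 2L)
  expect_identical(sturges_bins(500), 10L)
})

test_that("histograms bin deterministically and normalise by sample size", {
  h1 <- build_histogram(rep(0.5, 100), "point")
  expect_equal(max(h1$frequencies), 1)
  expect_equal(sum(h1$counts > 0), 1L)

  grid <- seq(0, 1, length.out = 100)
  h2 <- build_histogram(grid, "uniform")
  expect_length(h2$counts, 8L)
  expect_true(all(abs(h2$frequencies - 0.125) <= 0.01))
  expect_equal(sum(h2$frequencies), 1)

  h3 <- build_histogram(rep(c(0, 1), each = 50), "extremes")
  expect_equal(h3$frequencies[1], 0.5)
  expect_equal(h3$frequencies[length(h3$frequencies)], 0.5)

  expect_error(build_histogram(c(NA, NA, 0.5)), ">= 2 defined")
})

test_that("Gaussian fits recover generated distributions and flag misfits", {
  set.seed(9)
  draws <- rnorm(5000, 0.7, 0.05)
  draws <- draws[draws >= 0 & draws <= 1]
  g <- fit_gaussian(build_histogram(draws, "normal"))
  expect_lt(abs(g$mean - 0.7), 0.01)
  expect_lt(abs(g$sd - 0.05), 0.2 * 0.05)

  # exact Gaussian-valued bins: parameters recovered to optimizer tolerance
  h <- build_histogram(runif(200), "shape")
  h$frequencies <- 0.2 * exp(-(h$mids - 0.55)^2 / (2 * 0.08^2))
  gx <- fit_gaussian(h)
  expect_equal(gx$mean, 0.55, tolerance = 1e-6)
  expect_equal(gx$sd, 0.08, tolerance = 1e-6)
  expect_lt(gx$residual_rmsd, 1e-9)

  # symmetric two-spike data fit far worse than a unimodal sample
  spikes <- c(rnorm(2500, 0.15, 0.02), rnorm(2500, 0.85, 0.02))
  spikes <- spikes[spikes >= 0 & spikes <= 1]
  g2 <- fit_gaussian(build_histogram(spikes, "bimodal"))
  expect_gt(g2$residual_rmsd, 10 * g$residual_rmsd)
})

test_that("class comparisons agree with a permutation oracle", {
  expect_equal(compare_classes(rep(0.5, 10), rep(0.5, 10))$p_value, 1)

  set.seed(13)
  a <- rnorm(500, 0.6, 0.1)
  b <- rnorm(500, 0.7, 0.1)
  expect_lt(compare_classes(a, b)$p_value, 1e-15)

  # moderate separation, n <= 200: Welch and permutation p agree
  a2 <- rnorm(80, 0.60, 0.12)
  b2 <- rnorm(80, 0.645, 0.12)
  pw <- compare_classes(a2, b2, method = "welch")$p_value
  pp <- compare_classes(a2, b2, method = "permutation", n_perm = 1e4)$p_value
  mc_err <- 3 * sqrt(pw * (1 - pw) / 1e4)
  expect_lt(abs(pw - pp), mc_err + 0.01)
})

test_that("the pipeline recovers the class structure of a biased proteome", {
  specs <- list(
    cytosolic = proteome_class_spec(120, lys_mean = 0.50, lys_sd = 0.12),
    Sec = proteome_class_spec(120, lys_mean = 0.68, lys_sd = 0.12))
  prot <- make_proteome(specs, seed = 17)
  res <- lysarg_analysis(prot$records)
  fr <- res$fractions
  m_cyt <- mean(fr$lys_fraction[fr$loc_class == "cytosolic"], na.rm = TRUE)
  m_sec <- mean(fr$lys_fraction[fr$loc_class == "Sec"], na.rm = TRUE)
  expect_equal(m_cyt, 0.50, tolerance = 0.03)
  expect_equal(m_sec, 0.68, tolerance = 0.03)
  expect_lt(res$comparisons$p_value[1], 0.05)
  expect_identical(length(res$histograms$Sec$counts),
                   length(res$histograms$Sec$bin_edges) - 1L)
})
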