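test_that("consensus CMS requires agreement of two classifiers", {
  expect_equal(consensus_cms(cbind("CMS1", "CMS1", "CMS1")), "CMS1")
  expect_equal(consensus_cms(cbind("CMS2", "CMS2", "CMS4")), "CMS2")
  expect_equal(consensus_cms(cbind("CMS1", "CMS2", "CMS3")), "Unknown")
  # a classifier's own unknown token never votes
  expect_equal(consensus_cms(cbind("CMS3", "NOLBL", "CMS3")), "CMS3")
  expect_equal(consensus_cms(cbind("CMS3", NA, "CMS1")), "Unknown")
  # permutation invariance over all orderings
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  trip <- c("CMS4", "CMS4", "CMS2")
  for (p in perms)
    expect_equal(consensus_cms(cbind(trip[p[1]], trip[p[2]], trip[p[3]])),
                 "CMS4")
})

test_that("band carrier frequencies count overlapping events once", {
  bands <- data.frame(chrom = "chr1", start = c(0, 1e7), end = c(1e7, 2e7),
                      band = c("p1", "q1"),
                      band_id = c("chr1:p1", "chr1:q1"))
  groups <- stats::setNames(c("g1", "g1", "g2"), c("A", "B", "C"))
  none <- cnv_band_frequencies(
    data.frame(sample_id = character(), chrom = character(),
               start = numeric(), end = numeric(), call = integer()),
    bands, groups)
  expect_true(all(none$frequency == 0))
  segs <- data.frame(sample_id = c("A", "B", "C"), chrom = "chr1",
                     start = 0, end = 5e6, call = 1L)
  all_amp <- cnv_band_frequencies(segs, bands, groups)
  amp_p1 <- all_amp[all_amp$event == "amp" & all_amp$band_id == "chr1:p1", ]
  expect_equal(amp_p1$frequency[order(amp_p1$group)], c(1, 1))
  # a segment spanning two bands is a carrier on each
  span <- data.frame(sample_id = "A", chrom = "chr1", start = 5e6,
                     end = 1.5e7, call = -1L)
  del <- cnv_band_frequencies(span, bands, groups)
  del_a <- del[del$event == "del" & del$group == "g1", ]
  expect_equal(del_a$n_carriers, c(1L, 1L))
})

test_that("Fisher enrichment matches the hypergeometric oracle", {
  freqs <- data.frame(band_id = rep(c("b1", "b2", "b3"), each = 2),
                      event = "amp",
                      group = rep(c("g1", "g2"), 3),
                      n_carriers = c(10L, 20L, 15L, 5L, 0L, 0L),
                      n_group = c(20L, 40L, 20L, 20L, 20L, 40L))
  freqs$frequency <- freqs$n_carriers / freqs$n_group
  enr <- band_enrichment(freqs, "g1", "g2")
  expect_equal(enr$p_uncorrected[enr$band_id == "b1"], 1)   # 10/20 vs 20/40
  expect_equal(enr$p_uncorrected[enr$band_id == "b3"], 1)   # no carriers
  expect_equal(enr$p_uncorrected[enr$band_id == "b2"],
               fisher_oracle(15, 5, 5, 15), tolerance = 1e-12)
  expect_equal(enr$neg_log10_p, -log10(enr$p_uncorrected))
  # random spot-check against the oracle across table shapes
  set.seed(8)
  for (i in 1:50) {
    n1 <- sample(2:25, 1); n2 <- sample(2:25, 1)
    a <- sample(0:n1, 1); c_ <- sample(0:n2, 1)
    f <- data.frame(band_id = "b", event = "amp", group = c("x", "y"),
                    n_carriers = c(a, c_), n_group = c(n1, n2),
                    frequency = c(a / n1, c_ / n2))
    expect_equal(band_enrichment(f, "x", "y")$p_uncorrected,
                 fisher_oracle(a, n1 - a, c_, n2 - c_), tolerance = 1e-12)
  }
})

test_that("the metastasis GLM is calibrated and flags separation", {
  set.seed(5)
  x <- rnorm(400)
  y <- rbinom(400, 1, plogis(-1 + x))
  fit <- metastasis_glm(data.frame(ith = x), y)
  expect_equal(fit$log_odds[fit$covariate == "ith"], 1, tolerance = 0.35)
  expect_false(attr(fit, "separation"))
  # perfectly separating covariate
  sep <- suppressWarnings(
    metastasis_glm(data.frame(z = c(rnorm(20, -3), rnorm(20, 3))),
                   rep(c(0L, 1L), each = 20)))
  expect_true(attr(sep, "separation"))
  expect_true(all(is.na(sep$log_odds)))
  expect_error(metastasis_glm(data.frame(x = rnorm(30)), rep(1L, 30)),
               "single class")
  expect_error(metastasis_glm(data.frame(x = rnorm(5)), rep(0:1, len = 5)),
               "at least 10")
  expect_error(metastasis_glm(data.frame(x = rep(1, 30)),
                              rep(0:1, len = 30)), "constant")
})

test_that("burden correlations handle the log10 display scale", {
  x <- c(1, 4, 9, 16, 25)
  expect_equal(burden_correlation(x, x)$pearson_r, 1)
  expect_equal(burden_correlation(x, max(x) - x)$pearson_r, -1)
  lg <- burden_correlation(x, log10(x + 1), log_x = TRUE)
  expect_equal(lg$pearson_r, 1)
  set.seed(10)
  nul <- burden_correlation(rpois(1000, 20), rpois(1000, 20))
  expect_lt(abs(nul$pearson_r), 0.1)
  expect_warning(burden_correlation(rep(2, 5), x), "zero variance")
})

test_that("correlation matrices mask non-significant cells after BH", {
  set.seed(12)
  n <- 60
  a <- rnorm(n)
  tab <- data.frame(a = a, b = exp(a), c = rnorm(n))
  cm <- correlation_matrix(tab)
  expect_equal(unname(diag(cm$rho)), rep(1, 3))
  # monotone transform: rank correlation 1, never masked
  expect_equal(cm$rho["a", "b"], 1)
  # an independent variable is masked
  expect_true(is.na(cm$rho["a", "c"]) || abs(cm$rho_all["a", "c"]) > 0.3)
  # FDR calibration: independent variables are almost entirely masked
  masked_frac <- replicate(25, {
    m <- matrix(rnorm(50 * 10), 50, 10)
    cm <- correlation_matrix(m)
    off <- cm$rho[upper.tri(cm$rho)]
    mean(is.na(off))
  })
  expect_gte(mean(masked_frac), 0.95)
})

test_that("pro/anti cell ratios dichotomize at the cohort median", {
  cf <- matrix(c(0.2, 0.1, 0.4, 0.3,
                 0.1, 0.2, 0.4, 0.3,
                 0.25, 0.25, 0.3, 0.2,
                 0.4, 0.0, 0.3, 0.3), nrow = 4, byrow = TRUE,
               dimnames = list(paste0("S", 1:4),
                               c("myofibroblasts", "dendritic_cells",
                                 "T_cells", "B_cells")))
  pr <- prognostic_ratio(cf, pro_types = "myofibroblasts",
                         anti_types = "dendritic_cells")
  expect_equal(pr$ratio[1], (0.2 + 1e-3) / (0.1 + 1e-3))
  expect_equal(pr$ratio[3], (0.25 + 1e-3) / (0.25 + 1e-3))
  # zero anti-fraction stays finite through the pseudocount
  expect_true(is.finite(pr$ratio[4]))
  expect_equal(sort(unique(pr$group)), c("high", "low"))
  expect_error(prognostic_ratio(cf, pro_types = "nothere",
                                anti_types = "dendritic_cells"),
               "not in profile")
})
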