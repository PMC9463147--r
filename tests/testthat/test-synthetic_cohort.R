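test_that("clone trees satisfy their structural invariants", {
  tr1 <- simulate_clone_tree(1, seed = 1)
  expect_equal(tr1$n_clones, 1L)
  expect_equal(unname(tr1$clone_fraction), 1)
  expect_equal(unname(tr1$ccf), 1)
  for (s in 1:20) {
    k <- sample(2:8, 1)
    tr <- simulate_clone_tree(k, seed = s)
    expect_equal(sum(tr$clone_fraction), 1, tolerance = 1e-9)
    expect_true(all(tr$clone_fraction >= 0.05))
    expect_equal(unname(tr$ccf[1]), 1, tolerance = 1e-9)
    for (cl in tr$clones[-1])
      expect_lte(tr$ccf[cl], tr$ccf[tr$parent[cl]] + 1e-12)
  }
  expect_identical(simulate_clone_tree(5, seed = 42),
                   simulate_clone_tree(5, seed = 42))
  expect_error(simulate_clone_tree(10, min_clone_fraction = 0.2),
               "infeasible")
})

test_that("tree topologies follow their priors", {
  chain <- simulate_clone_tree(4, seed = 1, topology = "chain")
  expect_equal(unname(chain$parent[-1]), c("C1", "C2", "C3"))
  star <- simulate_clone_tree(4, seed = 1, topology = "star")
  expect_equal(unname(star$parent[-1]), rep("C1", 3))
  expect_equal(clone_lineage(chain, "C4"), c("C1", "C2", "C3", "C4"))
  expect_equal(clone_lineage(star, "C4"), c("C1", "C4"))
})

test_that("variant assignment respects the clonal bias", {
  tr <- simulate_clone_tree(3, seed = 2)
  all_clonal <- assign_variants(tr, 100, 0, panel = "G", clonal_bias = 1,
                                seed = 3)
  expect_true(all(all_clonal$clonality == "clonal"))
  single <- assign_variants(simulate_clone_tree(1, seed = 1), 50, 0,
                            panel = "G", clonal_bias = 0, seed = 3)
  expect_true(all(single$clonality == "clonal"))
  # binomial sampling check: clonal fraction ~ bias at large n
  big <- assign_variants(tr, 10000, 0, panel = "G", clonal_bias = 0.5,
                         seed = 4)
  expect_equal(mean(big$clonality == "clonal"), 0.5, tolerance = 0.02)
  expect_true(all(big$true_ccf == unname(tr$ccf[big$clone])))
  expect_true(all(big$multiplicity %in% c(1L, 2L)))
})

test_that("read counts follow the expected-VAF relation", {
  # closed-form expectations
  t1 <- data.frame(id = "v", gene = "G", true_ccf = 1, multiplicity = 1L)
  c1 <- simulate_read_counts(t1, purity = 1, mean_coverage = 1e5, seed = 1)
  expect_equal(c1$vaf, 0.5, tolerance = 0.01)
  c2 <- simulate_read_counts(t1, purity = 0.5, mean_coverage = 1e5, seed = 1)
  expect_equal(c2$vaf, 0.25, tolerance = 0.01)
  # Monte-Carlo: 10000 clonal SSMs, coverage 100, purity 0.8
  tv <- data.frame(id = paste0("v", 1:10000), gene = "G", true_ccf = 1,
                   multiplicity = 1L)
  calls <- simulate_read_counts(tv, 0.8, 100, seed = 2)
  expect_equal(mean(calls$vaf), 0.8 / 2, tolerance = 0.005)
  expect_true(all(calls$ref_depth + calls$alt_depth > 0))
  # convergence at very high coverage
  deep <- simulate_read_counts(tv[1:200, ], 0.8, 10000, seed = 3)
  expect_equal(mean(deep$vaf), 0.4, tolerance = 0.002)
  # VAF clipping warns
  t2 <- data.frame(id = "w", gene = "G", true_ccf = 1, multiplicity = 2L)
  expect_warning(simulate_read_counts(t2, 1, 100, seed = 1, tumor_cn = 1L),
                 "clipped")
})

test_that("metastasis pairs encode their seeding mode", {
  tr <- simulate_clone_tree(4, seed = 7, topology = "star")
  mono <- simulate_met_pair(tr, "monoclonal", n_private_primary = 0,
                            n_private_met = 0, seed = 8)
  expect_true(all(mono$met$id %in% mono$primary$id))
  expect_equal(length(mono$seeding_clones), 1L)
  poly <- simulate_met_pair(tr, "polyclonal", n_seeding_clones = 2,
                            n_private_primary = 0, n_private_met = 0,
                            seed = 8)
  met_clones <- setdiff(unique(poly$met$clone), "C1")
  expect_gte(length(met_clones), 2L)
  expect_identical(simulate_met_pair(tr, "polyclonal", seed = 9),
                   simulate_met_pair(tr, "polyclonal", seed = 9))
  expect_error(simulate_met_pair(simulate_clone_tree(1), "polyclonal"),
               ">= 2 non-root")
  # private variants are private
  pp <- simulate_met_pair(tr, "monoclonal", n_private_primary = 10,
                          n_private_met = 12, seed = 10)
  expect_equal(sum(grepl("^privP", pp$primary$id)), 10L)
  expect_equal(sum(grepl("^privM", pp$met$id)), 12L)
  expect_false(any(grepl("^privM", pp$primary$id)))
})

test_that("cohort simulation is reproducible and obeys its null", {
  d <- cohort_design(n_samples = 12L, seed = 3L)
  b1 <- simulate_cohort(d)
  b2 <- simulate_cohort(d)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$mutations, b2$mutations)
  dir1 <- withr::local_tempdir()
  write_cohort(b1, dir1)
  expect_true(all(file.exists(file.path(dir1,
    c("mutations.tsv", "segments.tsv", "meta.tsv", "cell_fractions.tsv",
      "expression.tsv", "truth.tsv", "panel.txt")))))
  # zeroed planted effects: gene status uncorrelated with true ITH
  d0 <- cohort_design(n_samples = 500L,
                      planted_beta = stats::setNames(rep(0, 5),
                                                     sprintf("G%02d", 1:5)),
                      seed = 9L)
  b0 <- simulate_cohort(d0)
  status <- rowSums(b0$truth[, sprintf("G%02d", 1:5)])
  expect_lt(abs(cor(status, b0$truth$true_shannon)), 0.1)
  # very negative intercept: no relapses drawn
  dneg <- cohort_design(n_samples = 40L, relapse_intercept = -30, seed = 4L)
  expect_equal(sum(simulate_cohort(dneg)$meta$relapse), 0L)
})

test_that("cohort read counts honor local copy number from segments", {
  b <- simulate_cohort(cohort_design(n_samples = 15L, seed = 21L))
  expect_equal(sort(unique(b$meta$sample_id)),
               sort(unique(b$mutations$sample_id)))
  # cell fractions are a valid composition
  expect_equal(unname(rowSums(b$cell_fractions)),
               rep(1, nrow(b$cell_fractions)), tolerance = 1e-9)
  # truth shannon is bounded by the clone-number cap
  expect_true(all(b$truth$true_shannon <= log(b$design$max_clones) + 1e-9))
  expect_true(all(b$truth$true_shannon >= 0))
})
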