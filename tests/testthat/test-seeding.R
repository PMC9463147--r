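test_that("Jaccard similarity matches set enumeration", {
  same <- jaccard_similarity(c("a", "b"), c("a", "b"))
  expect_equal(same$jsi, 1)
  disj <- jaccard_similarity(c("a", "b"), c("c", "d"))
  expect_equal(disj$jsi, 0)
  j <- jaccard_similarity(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(j$jsi, 0.5)
  expect_equal(j$n_shared, 2L)
  expect_equal(j$n_private_primary, 1L)
  expect_equal(j$n_private_met, 1L)
  # symmetry
  j2 <- jaccard_similarity(c("b", "c", "d"), c("a", "b", "c"))
  expect_equal(j2$jsi, j$jsi)
  expect_warning(und <- jaccard_similarity(character(), character()),
                 "undefined")
  expect_true(is.na(und$jsi))
})

test_that("JSI agrees with brute-force enumeration on random set pairs", {
  set.seed(7)
  for (i in 1:200) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(1:15, 1))
    brute <- sum(letters %in% a & letters %in% b) /
      sum(letters %in% a | letters %in% b)
    expect_equal(jaccard_similarity(a, b)$jsi, brute)
  }
})

test_that("seeding classification is strict at the threshold", {
  expect_equal(classify_seeding(0.5), "polyclonal")
  expect_equal(classify_seeding(0.4), "monoclonal")
  expect_equal(classify_seeding(0.0), "monoclonal")
  expect_equal(classify_seeding(0.4 + 1e-9), "polyclonal")
  expect_true(is.na(classify_seeding(NA)))
})

test_that("JSI is monotone non-increasing as private variants are added", {
  base <- paste0("v", 1:40)
  prev <- 1
  for (extra in c(5, 10, 20)) {
    j <- jaccard_similarity(c(base, paste0("p", seq_len(extra))), base)$jsi
    expect_lte(j, prev)
    prev <- j
  }
})

test_that("combined SSM+CNV JSI reduces to SSM-only without segments", {
  calls_a <- data.frame(chrom = "chr1", pos = 1:4 * 100, ref = "A",
                        alt = "T")
  calls_b <- calls_a
  no_cnv <- jsi_with_cnvs(calls_a, calls_b)
  expect_equal(no_cnv$jsi, 1)
  expect_equal(no_cnv$variant_scope, "ssm_only")
  # 4 shared SSMs + 2 disjoint CNVs each: jsi = 4/8
  seg_a <- data.frame(sample_id = "P", chrom = c("chr2", "chr3"),
                      start = c(0, 0), end = c(1e6, 1e6),
                      call = c(1L, -1L))
  seg_b <- data.frame(sample_id = "M", chrom = c("chr4", "chr5"),
                      start = c(0, 0), end = c(1e6, 1e6),
                      call = c(1L, -1L))
  mix <- jsi_with_cnvs(calls_a, calls_b, seg_a, seg_b)
  expect_equal(mix$jsi, 0.5)
  expect_equal(mix$variant_scope, "ssm_and_cnv")
  # identical segments match by reciprocal overlap: everything shared
  all_shared <- jsi_with_cnvs(calls_a, calls_b, seg_a, seg_a)
  expect_equal(all_shared$jsi, 1)
})

test_that("CNV identity needs 50% reciprocal overlap and same sign", {
  a <- data.frame(sample_id = "P", chrom = "chr1", start = 0, end = 1e6,
                  call = 1L)
  b_near <- data.frame(sample_id = "M", chrom = "chr1", start = 2e5,
                       end = 1.2e6, call = 1L)
  b_far <- data.frame(sample_id = "M", chrom = "chr1", start = 9e5,
                      end = 5e6, call = 1L)
  b_sign <- data.frame(sample_id = "M", chrom = "chr1", start = 0,
                       end = 1e6, call = -1L)
  calls <- data.frame(chrom = "chr9", pos = 1, ref = "A", alt = "T")
  expect_equal(jsi_with_cnvs(calls, calls, a, b_near)$n_shared, 2L)
  expect_equal(jsi_with_cnvs(calls, calls, a, b_far)$n_shared, 1L)
  expect_equal(jsi_with_cnvs(calls, calls, a, b_sign)$n_shared, 1L)
})

test_that("shared copy-number events require both samples on the band", {
  bands <- data.frame(chrom = c("chr8", "chr8", "chr13"),
                      start = c(0, 1e7, 0), end = c(1e7, 2e7, 1e7),
                      band = c("q24.1", "q24.2", "q14"),
                      band_id = c("chr8:q24.1", "chr8:q24.2", "chr13:q14"))
  p <- data.frame(sample_id = "P", chrom = "chr8", start = 0, end = 5e6,
                  call = 1L)
  m <- data.frame(sample_id = "M", chrom = c("chr8", "chr13"),
                  start = c(0, 0), end = c(5e6, 5e6), call = c(1L, 1L))
  ev <- shared_cnv_events(p, m, bands)
  shared <- ev[ev$shared, ]
  expect_equal(shared$band_id, "chr8:q24.1")
  expect_equal(shared$event, "amp")
  # identical segment sets: every covered band shared
  ev2 <- shared_cnv_events(m, m, bands)
  expect_true(all(ev2$shared))
  # disjoint: nothing shared
  ev3 <- shared_cnv_events(p, data.frame(sample_id = "M", chrom = "chr13",
                                         start = 0, end = 5e6, call = 1L),
                           bands)
  expect_false(any(ev3$shared))
  freq <- shared_cnv_frequencies(list(ev, ev2))
  expect_equal(freq$frequency[freq$band_id == "chr8:q24.1" &
                                freq$event == "amp"], 1)
})

test_that("polyclonal pairs score higher JSI than monoclonal ones", {
  jsis <- list(monoclonal = numeric(), polyclonal = numeric())
  for (mode in names(jsis)) {
    for (i in 1:30) {
      s <- i * 13
      tree <- simulate_clone_tree(5, min_clone_fraction = 0.15, seed = s,
                                  topology = "star")
      pair <- simulate_met_pair(tree, mode,
                                n_seeding_clones = if (mode == "monoclonal") 1L else 3L,
                                n_private_primary = 30, n_private_met = 30,
                                seed = s + 1, variants_per_clone = 30)
      pc <- simulate_read_counts(pair$primary, 0.8, 200, seed = s + 2)
      mc <- simulate_read_counts(pair$met, 0.8, 200, seed = s + 3)
      jsis[[mode]] <- c(jsis[[mode]],
                        jaccard_similarity(observed_variant_keys(pc),
                                           observed_variant_keys(mc))$jsi)
    }
  }
  wt <- wilcox.test(jsis$polyclonal, jsis$monoclonal,
                    alternative = "greater", exact = FALSE)
  expect_lt(wt$p.value, 0.01)
})

test_that("the benchmark reports the degenerate no-private regime", {
  # a metastasis seeded by the terminal clone of a linear tree with no
  # private variants is indistinguishable from its primary: JSI 1,
  # misclassified polyclonal - the harness must surface this regime
  tree <- simulate_clone_tree(2, seed = 1, topology = "chain")
  pair <- simulate_met_pair(tree, "monoclonal", n_private_primary = 0,
                            n_private_met = 0, seed = 2)
  j <- jaccard_similarity(pair$primary$id, pair$met$id)
  expect_equal(j$jsi, 1)
  expect_equal(classify_seeding(j$jsi), "polyclonal")  # known failure mode
})
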