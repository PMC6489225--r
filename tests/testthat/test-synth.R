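test_that("generated architectures classify back to the requested composition", {
  # round trip over several compositions and seeds
  comps <- list(c(V = 1L),
                c(I = 2L, IIa = 3L, IIb = 2L, IV_2 = 1L, X = 1L),
                c(IIa = 5L, IIb = 5L, III = 2L, IV_1 = 2L, IV_3 = 3L,
                  VI = 2L, VII = 1L, VIII = 1L, IX = 1L, V = 4L))
  for (seed in c(1, 7, 23)) {
    for (comp in comps) {
      recs <- generate_architectures(comp, seed = seed)
      expect_equal(length(recs), sum(comp))
      s <- classify_proteome(recs)
      expect_equal(s$class_counts[["UNCLASSIFIED"]], 0L)
      got <- c(I = s$class_counts[["I"]], IIa = s$subclass_counts[["IIa"]],
               IIb = s$subclass_counts[["IIb"]], III = s$class_counts[["III"]],
               IV_1 = s$subclass_counts[["IV_1"]],
               IV_2 = s$subclass_counts[["IV_2"]],
               IV_3 = s$subclass_counts[["IV_3"]], V = s$class_counts[["V"]],
               VI = s$class_counts[["VI"]], VII = s$class_counts[["VII"]],
               VIII = s$class_counts[["VIII"]], IX = s$class_counts[["IX"]],
               X = s$class_counts[["X"]])
      for (k in names(comp)) {
        expect_equal(got[[k]], comp[[k]],
                     info = paste("seed", seed, "class", k))
      }
    }
  }
})

test_that("generated records satisfy protein invariants and are seed-deterministic", {
  r1 <- generate_architectures("barley-table1", seed = 5)
  r2 <- generate_architectures("barley-table1", seed = 5)
  expect_identical(r1, r2)
  for (r in r1) {
    expect_gte(r$length_aa, 350)
    expect_lte(r$length_aa, 1100)
    expect_true(all(r$domains$start_aa >= 1))
    expect_true(all(r$domains$end_aa <= r$length_aa))
    expect_true(all(r$domains$start_aa <= r$domains$end_aa))
  }
})

test_that("II-b architectures keep the U-box midpoint in the N-terminal quarter", {
  recs <- generate_architectures(c(IIb = 5L), seed = 7)
  for (r in recs) {
    h <- r$domains[r$domains$label == "U_BOX", ][1, ]
    expect_lte((h$start_aa + h$end_aa) / 2, 0.25 * r$length_aa, )
  }
})

test_that("unsatisfiable composition requests are usage errors", {
  expect_error(generate_architectures(c(Va = 1L), seed = 1), "unknown class")
  expect_error(generate_architectures(c(0L), seed = 1), "named")
})

test_that("generated architecture files round trip through the annotation reader", {
  recs <- generate_architectures(c(IIa = 2L, V = 2L, X = 1L), seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_domain_annotations(recs, f)
  back <- read_domain_annotations(f, "simple_tsv")
  expect_equal(names(back), names(recs))
  for (id in names(recs)) {
    expect_equal(back[[id]]$domains[c("label", "start_aa", "end_aa")],
                 recs[[id]]$domains[c("label", "start_aa", "end_aa")])
  }
})

test_that("rate 0 evolution leaves all leaves identical to the root", {
  tree <- with_seed_local(2, ape::rtree(5))
  aln <- simulate_alignment(tree, n_columns = 40, rate = 0, seed = 6)
  d <- pairwise_pdistance(aln)
  expect_true(all(d == 0))
  expect_error(simulate_alignment(tree, 40, rate = -1, seed = 1), "rate")
})

test_that("alignment simulation is reproducible and supports NJ recovery", {
  tree <- with_seed_local(3, {
    tr <- ape::rtree(4)
    tr$edge.length <- rep(0.3, nrow(tr$edge))
    tr
  })
  a1 <- simulate_alignment(tree, n_columns = 2000, rate = 1, seed = 10)
  a2 <- simulate_alignment(tree, n_columns = 2000, rate = 1, seed = 10)
  expect_identical(a1, a2)
  recovered <- 0L
  for (s in 1:20) {
    aln <- simulate_alignment(tree, n_columns = 2000, rate = 1, seed = 500 + s)
    nj <- neighbor_joining(pairwise_pdistance(aln))
    if (same_topology(nj, tree)) recovered <- recovered + 1L
  }
  expect_gte(recovered, 19L)
})

test_that("noise-free Cq simulation recovers planted folds exactly", {
  dsn <- cq_design(c(up3 = 3, dn2 = -2, flat = 0), noise_sd = 0)
  cq <- simulate_cq_table(dsn, seed = 12)
  expect_equal(delta_delta_ct(cq, "up3")$fold, 8)
  expect_equal(delta_delta_ct(cq, "dn2")$fold, 0.25)
  expect_equal(delta_delta_ct(cq, "flat")$fold, 1)
})

test_that("planted inductions above the call threshold are called up reliably", {
  # With the up-call cutoff at fold 2, a planted fold of exactly 2 sits on the
  # threshold and an unbiased estimate clears it only about half the time, so
  # the reliable-call regime starts above the cutoff: a planted log2 fold of
  # 1.5 (fold 2.83) must be called up in >= 90% of simulations.
  up <- 0L; n <- 60L
  for (i in seq_len(n)) {
    cq <- simulate_cq_table(cq_design(c(g = 1.5), noise_sd = 0.2),
                            seed = 40000 + i)
    res <- analyze_expression(cq)
    if (call_stress_response(res)$calls$call == "up") up <- up + 1L
  }
  expect_gte(up / n, 0.9)
  # at the threshold itself the estimate still centres on the planted fold
  folds <- vapply(1:40, function(i) {
    delta_delta_ct(simulate_cq_table(cq_design(c(g = 1), noise_sd = 0.2),
                                     seed = 41000 + i), "g")$fold
  }, 0)
  expect_equal(mean(folds), 2, tolerance = 0.1)
})

test_that("simulated Cq tables round trip through the Cq reader", {
  dsn <- cq_design(c(g1 = 1.5), n_bio = 2, n_tech = 2)
  cq <- simulate_cq_table(dsn, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_cq_table(cq, f, header_comment = "seed: 3")
  back <- read_cq_table(f, reference_gene = "actin")
  expect_equal(back$cq, cq$cq, tolerance = 1e-12)
  expect_equal(back$gene, cq$gene)
})
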