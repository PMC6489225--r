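test_that("each class rule fires on its defining architecture", {
  cases <- list(
    list(rec = mk_record("p_I", 1000, list(UFD2 = c(50, 350), U_BOX = c(900, 960))),
         class = "I"),
    list(rec = mk_record("p_V", 400, list(U_BOX = c(100, 170))), class = "V"),
    list(rec = mk_record("p_III", 450, list(U_BOX = c(30, 100),
                                            CYCLOPHILIN = c(200, 380))),
         class = "III"),
    list(rec = mk_record("p_VIII", 600, list(U_BOX = c(40, 110), TPR = c(200, 300),
                                             PKC = c(350, 580))), class = "VIII"),
    list(rec = mk_record("p_VI", 500, list(U_BOX = c(20, 90), WD40 = c(300, 450))),
         class = "VI"),
    list(rec = mk_record("p_VII", 500, list(U_BOX = c(30, 100), TPR = c(250, 350))),
         class = "VII"),
    list(rec = mk_record("p_IX", 700, list(MIF4G = c(20, 250), U_BOX = c(500, 570))),
         class = "IX"),
    list(rec = mk_record("p_X", 600, list(DJ1 = c(20, 200), U_BOX = c(350, 420))),
         class = "X"))
  for (cs in cases) {
    a <- classify_protein(cs$rec)
    expect_equal(a$pub_class, cs$class, info = cs$rec$id)
    expect_true(is.na(a$subclass))
  }
})

test_that("proteins without a U-box hit are UNCLASSIFIED", {
  a <- classify_protein(mk_record("nobox", 400, list(ARM = c(100, 200))))
  expect_equal(a$pub_class, "UNCLASSIFIED")
  expect_true("no_ubox" %in% a$rationale)
})

test_that("a degenerate ARM-like region does not qualify for Class II by default", {
  rec <- mk_record("gkl", 500, list(U_BOX = c(20, 90), ARM_LIKE = c(200, 450)))
  a <- classify_protein(rec)
  expect_equal(a$pub_class, "V")
  expect_true("arm_like_not_arm" %in% a$rationale)
  # superseded grouping available by configuration
  a2 <- classify_protein(rec, pub_rule_config(arm_like_counts_as_arm = TRUE))
  expect_equal(a2$pub_class, "II")
})

test_that("the II-a/II-b split follows the U-box midpoint vs quarter-length rule", {
  center <- mk_record("c", 800, list(U_BOX = c(380, 450), ARM = c(500, 700)))
  expect_equal(classify_protein(center)$subclass, "IIa")  # midpoint 415 > 200
  nterm <- mk_record("n", 800, list(U_BOX = c(40, 110), ARM = c(300, 700)))
  expect_equal(classify_protein(nterm)$subclass, "IIb")   # midpoint 75 <= 200
  # boundary midpoint exactly 0.25L is II-b (inclusive tie rule)
  edge <- mk_record("e", 800, list(U_BOX = c(160, 240), ARM = c(400, 700)))
  expect_equal(classify_protein(edge)$subclass, "IIb")
  # start-based rule is exposed via config
  cfg <- pub_rule_config(ubox_point = "start")
  expect_equal(classify_protein(center, cfg)$subclass, "IIa")
})

test_that("multiple U-box hits use the most N-terminal one, with a trace", {
  rec <- mk_record("two_boxes", 800,
                   list(U_BOX = c(60, 130), ARM = c(500, 700)))
  rec2 <- protein_record("two_boxes", 800, domains = data.frame(
    label = c("U_BOX", "U_BOX", "ARM"),
    start_aa = c(400L, 60L, 600L), end_aa = c(470L, 130L, 700L)))
  a <- classify_protein(rec2)
  expect_equal(a$subclass, "IIb")
  expect_true("multiple_ubox_use_most_nterminal" %in% a$rationale)
  expect_equal(classify_protein(rec)$subclass, a$subclass)
})

test_that("moving the U-box toward the N-terminus can only move IIa to IIb", {
  # property: subclass is monotone in the U-box position
  for (seed in 1:20) {
    args <- with_seed_local(seed, {
      L <- sample(400:1000, 1)
      s <- sample(100:(L - 260), 1)
      list(L = L, s = s)
    })
    L <- args$L
    rec_hi <- mk_record("hi", L, list(U_BOX = c(args$s, args$s + 70),
                                      ARM = c(L - 150, L - 20)))
    rec_lo <- mk_record("lo", L, list(U_BOX = c(36, 106),
                                      ARM = c(L - 150, L - 20)))
    sub_hi <- classify_protein(rec_hi)$subclass
    sub_lo <- classify_protein(rec_lo)$subclass
    expect_false(sub_hi == "IIb" && sub_lo == "IIa",
                 info = paste("seed", seed))
  }
})

test_that("Class IV subgroups follow the kinase-domain presence pattern", {
  both <- mk_record("b", 700, list(U_BOX = c(30, 100), STK_N = c(150, 200),
                                   PKC = c(400, 650)))
  pkc <- mk_record("p", 700, list(U_BOX = c(30, 100), PKC = c(400, 650)))
  stk <- mk_record("s", 700, list(U_BOX = c(30, 100), STK_N = c(400, 650)))
  expect_equal(classify_protein(both)$subclass, "IV_1")
  expect_equal(classify_protein(pkc)$subclass, "IV_2")
  expect_equal(classify_protein(stk)$subclass, "IV_3")
})

test_that("classification is a pure function and partitions any protein set", {
  recs <- generate_architectures("barley-table1", seed = 42)
  s1 <- classify_proteome(recs)
  s2 <- classify_proteome(recs)
  expect_identical(s1$assignments, s2$assignments)
  expect_equal(sum(s1$class_counts), length(recs))
  expect_equal(s1$n_classified + s1$class_counts[["UNCLASSIFIED"]], s1$n)
  # every protein gets exactly one class
  expect_equal(nrow(s1$assignments), length(recs))
  # duplicate ids rejected
  dup <- c(recs[1], recs[1])
  expect_error(classify_proteome(dup), "duplicate protein id")
})

test_that("an all-unclassifiable set yields zero class counts", {
  recs <- list(mk_record("a", 300, list(ARM = c(50, 250))),
               mk_record("b", 300, list()))
  s <- classify_proteome(recs)
  expect_equal(s$n_classified, 0L)
  expect_equal(s$class_counts[["UNCLASSIFIED"]], 2L)
  expect_true(all(s$class_counts[setdiff(names(s$class_counts),
                                         "UNCLASSIFIED")] == 0))
})

test_that("tandem clustering chains neighbours within the gap threshold", {
  cat67 <- read_gene_catalog(barley_catalog_path())
  cl <- find_tandem_clusters(cat67, max_gap_bp = 100000)
  # frozen from a brute-force all-pairs gap scan over the catalog loci
  expect_equal(length(cl), 2L)
  members <- lapply(cl, function(x) sort(x$name))
  expect_true(list(c("HvPUB11", "HvPUB12")) %in% members)
  expect_true(list(c("HvPUB58", "HvPUB59")) %in% members)
  # gap arithmetic for the HvPUB11/12 pair: 102438361 - 102375777 = 62584
  expect_lte(102438361 - 102375777, 100000)
})

test_that("tandem clusters are order-invariant, disjoint and chromosome-local", {
  cat67 <- read_gene_catalog(barley_catalog_path())
  shuffled <- with_seed_local(7, cat67[sample(nrow(cat67)), ])
  cl1 <- find_tandem_clusters(cat67)
  cl2 <- find_tandem_clusters(shuffled)
  expect_equal(lapply(cl1, function(x) x$name), lapply(cl2, function(x) x$name))
  all_members <- unlist(lapply(cl1, function(x) x$name))
  expect_false(anyDuplicated(all_members) > 0)
  # identical coordinates on different chromosomes never cluster
  toy <- data.frame(name = c("a", "b"), chromosome = c("chr1H", "chr2H"),
                    start_bp = c(100, 100), end_bp = c(200, 200))
  expect_equal(length(find_tandem_clusters(toy, 1e9)), 0L)
})
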