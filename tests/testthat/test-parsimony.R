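mini_matrix <- function(patterns, samples) {
  # patterns: character vector like c("110", "101"), one string per mutation
  m <- vapply(strsplit(patterns, ""), as.integer, integer(length(samples)))
  m <- rbind(0L, m)
  rownames(m) <- c("germline", samples)
  colnames(m) <- paste0("m", seq_along(patterns))
  char_matrix(m)
}

test_that("character matrix reflects shared and private mutations", {
  calls <- data.frame(sample_id = c("S1", "S2", "S1", "S2"),
                      patient_id = "P", tissue_class = "carcinoma",
                      chrom = "chr1", pos = c(100, 100, 200, 300),
                      ref = "C", alt = "T", gene = "G1", effect = "missense",
                      protein_pos = 10, vaf = c(0.4, 0.4, 0.3, 0.02),
                      context = "ACA", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("S1", "S2"), patient_id = "P",
                        tissue_class = "carcinoma")
  suppressMessages(cm <- build_character_matrix(calls, samples, 0.05))
  expect_equal(sort(unname(apply(cm$mat[-1, , drop = FALSE], 2, paste,
                                 collapse = ""))),
               sort(c("11", "10")))  # sub-threshold S2 call at pos 300 dropped
  cm2 <- build_character_matrix(calls, samples, 0.01)
  expect_equal(ncol(cm2$mat), 3)
})

test_that("noise-free simulated matrix equals the truth incidence matrix", {
  sp <- simulate_patient(quiet_params(), seed = 8)
  cm <- build_character_matrix(sp$calls, sp$samples)
  truth <- sp$truth$mutations
  carriers_truth <- function(mid) {
    b <- truth$branch[truth$mutation_id == mid][1]
    sub <- sp$calls[mutation_id(sp$calls) == mid, "sample_id"]
    sort(sub)
  }
  for (mid in sample(colnames(cm$mat), 25)) {
    expect_equal(sort(rownames(cm$mat)[cm$mat[, mid] == 1]),
                 carriers_truth(mid))
  }
  expect_equal(ncol(cm$mat), nrow(truth))
})

test_that("Fitch counting matches hand-run examples", {
  cm <- mini_matrix(c("1111"), c("A", "B", "C", "D"))
  tr <- ape::read.tree(text = "(((A,B),(C,D)),germline);")
  expect_equal(fitch_score(tr, cm)$score, 1)

  # A=C=1, B=D=0 conflicts with ((A,B),(C,D)): two independent gains
  cm2 <- mini_matrix(c("1010"), c("A", "B", "C", "D"))
  st <- fitch_score(tr, cm2)
  expect_equal(st$score, 2)
  expect_equal(st$ci, 0.5)
  expect_equal(st$hi, 0.5)
})

test_that("Fitch scoring agrees with phangorn on random matrices and trees", {
  skip_if_not_installed("phangorn")
  set.seed(31)
  for (i in 1:25) {
    k <- sample(4:7, 1)
    cm <- random_char_matrix(k, 15)
    if (is.null(cm)) next
    tr <- ape::rtree(k + 1, tip.label = sample(rownames(cm$mat)), br = NULL)
    dat <- phangorn::phyDat(cm$mat[tr$tip.label, , drop = FALSE],
                            type = "USER", levels = c(0, 1))
    expect_equal(fitch_score(tr, cm)$score,
                 as.integer(phangorn::parsimony(tr, dat)))
  }
})

test_that("search returns the exhaustive optimum; compatible data give HI 0", {
  sp <- simulate_patient(quiet_params(), seed = 9)
  cm <- build_character_matrix(sp$calls, sp$samples)
  tr <- search_mp_tree(cm)
  expect_equal(tr$stats$hi, 0)
  expect_equal(rf_distance(tr, sp$truth$tree), 0)
  # total branch length equals the score
  expect_equal(sum(tr$tree$edge.length), tr$score)
})

test_that("heuristic search score equals the brute-force minimum", {
  set.seed(32)
  for (i in 1:20) {
    k <- sample(4:5, 1)
    cm <- random_char_matrix(k, 12)
    if (is.null(cm)) next
    expect_equal(search_mp_tree(cm, method = "heuristic", restarts = 5,
                                seed = i)$score,
                 brute_force_min_score(cm))
  }
})

test_that("a column conflicting with an existing split strictly increases the score", {
  set.seed(33)
  cm <- mini_matrix(c("1100", "1100", "0011"), c("A", "B", "C", "D"))
  tr <- search_mp_tree(cm)
  s0 <- tr$score
  m2 <- cbind(cm$mat, conflict = c(0L, 1L, 0L, 1L, 0L))
  tr2 <- search_mp_tree(char_matrix(m2))
  expect_gt(tr2$score, s0)
})

test_that("four identical samples collapse to zero-length internal structure", {
  cm <- mini_matrix(c("1111", "1111", "1111"), c("A", "B", "C", "D"))
  tr <- search_mp_tree(cm)
  expect_equal(tr$score, 3)
  # all change is on the trunk; branches beyond it have length zero
  internal <- tr$tree$edge[, 2] %in% seq_len(ape::Ntip(tr$tree)) == FALSE
  expect_equal(sum(tr$tree$edge.length), 3)
  expect_true(all(tr$tree$edge.length[tr$tree$edge.length > 0] == 3))
})

test_that("bootstrap support behaves at B = 1, is seeded, and saturates on clean data", {
  sp <- simulate_patient(quiet_params(
    snv_means = c(field = 50, truncal = 50, lgd_hgd = 50, hgd_carc = 50,
                  shared = 50, private = 50), poisson_counts = FALSE),
    seed = 10)
  cm <- build_character_matrix(sp$calls, sp$samples)
  b1 <- bootstrap_support(cm, B = 1, seed = 4)
  expect_true(all(b1$support %in% c(0, 100)))
  b2 <- bootstrap_support(cm, B = 20, seed = 4)
  b3 <- bootstrap_support(cm, B = 20, seed = 4)
  expect_identical(b2$support, b3$support)
  # 50 characters per branch: every clade should be recovered essentially always
  b100 <- bootstrap_support(cm, B = 100, seed = 4)
  expect_true(all(b100$support >= 95))
  expect_equal(unique(support_band(b100$support[b100$support > 95])), "")
})

test_that("bootstrap percentages are invariant under column permutation", {
  sp <- simulate_patient(quiet_params(), seed = 11)
  cm <- build_character_matrix(sp$calls, sp$samples)
  set.seed(35)
  perm <- sample(ncol(cm$mat))
  cmp <- char_matrix(cm$mat[, perm], cm$anno[perm, ])
  s1 <- bootstrap_support(cm, B = 15, seed = 6)$support
  s2 <- bootstrap_support(cmp, B = 15, seed = 6)$support
  cl1 <- attr(s1, "clades"); cl2 <- attr(s2, "clades")
  expect_equal(cl1$support[order(cl1$clade)], cl2$support[order(cl2$clade)])
})

test_that("driver annotation places mutations on gain branches and flags homoplasy", {
  cm <- mini_matrix(c("111", "100", "101"), c("CA1", "CA2", "CA3"))
  cm$anno$gene <- c("TP53", "KRAS", "APC")
  cm$anno$effect <- "missense"
  tr <- search_mp_tree(cm)
  tr <- annotate_branches(tr, cm, c("TP53", "KRAS", "APC"))
  ann <- tr$annotations
  # truncal TP53 on the trunk: child of its gain edge is ancestral to all CAs
  tp53 <- ann[ann$gene == "TP53", ]
  expect_equal(nrow(tp53), 1)
  expect_false(tp53$homoplastic)
  cl <- crcevo:::rooted_clades(tr$tree)
  expect_equal(cl[[as.character(tp53$child)]], "CA1|CA2|CA3")
  # private KRAS sits on the CA1 leaf branch
  kras <- ann[ann$gene == "KRAS", ]
  expect_equal(tr$tree$tip.label[kras$child], "CA1")
})

test_that("a doubly-gained character is annotated twice with a homoplasy flag", {
  # pattern A=C=1 with B between them on the optimal tree for the backbone
  cm <- mini_matrix(c("110", "110", "110", "011", "011", "011", "101"),
                    c("A", "B", "C"))
  cm$anno$gene <- c(rep("X", 6), "TP53")
  cm$anno$effect <- "missense"
  tr <- search_mp_tree(cm)
  tr <- annotate_branches(tr, cm, "TP53")
  expect_equal(nrow(tr$annotations), 2)
  expect_true(all(tr$annotations$homoplastic))
})

test_that("Robinson-Foulds distance matches split enumeration and phangorn", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)

  cat6 <- ape::read.tree(text = "(((((A,B),C),D),E),F);")
  bal6 <- ape::read.tree(text = "(((A,B),(C,D)),(E,F));")
  # brute-force split comparison: caterpillar splits {AB, ABC, ABCD};
  # balanced splits {AB, CD, ABCD}; shared {AB, ABCD} -> distance 1 + 1
  expect_equal(rf_distance(cat6, bal6), 2)

  skip_if_not_installed("phangorn")
  set.seed(36)
  for (i in 1:25) {
    a <- ape::rtree(7); b <- ape::rtree(7)
    expect_equal(rf_distance(a, b),
                 as.integer(phangorn::RF.dist(a, b, rooted = FALSE)))
  }
  expect_error(rf_distance(ape::rtree(4), ape::rtree(5)), "leaf sets")
})
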