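test_that("binning takes the length-weighted majority state with documented ties", {
  g <- genome_layout("chr1", 2e6, 1e6)
  # uniform diploid
  prof <- data.frame(sample_id = "S1", chrom = "chr1", start = 0, end = 2e6,
                     cn_total = 2L, cn_minor = 1L)
  b <- bin_profiles(prof, g, 5e5)
  expect_true(all(b$mat["S1", ] == 2))
  expect_equal(nrow(b$bins), 4)

  # 80% of one bin at 3, 20% at 2 -> 3
  prof2 <- data.frame(sample_id = "S1", chrom = "chr1",
                      start = c(0, 4e5), end = c(4e5, 2e6),
                      cn_total = c(3L, 2L), cn_minor = 1L)
  b2 <- bin_profiles(prof2, g, 5e5)
  expect_equal(unname(b2$mat["S1", 1]), 3L)

  # 50/50 tie between 1 and 3: both are one step from diploid; lower wins
  prof3 <- data.frame(sample_id = "S1", chrom = "chr1",
                      start = c(0, 2.5e5), end = c(2.5e5, 5e5),
                      cn_total = c(1L, 3L), cn_minor = 0L)
  b3 <- bin_profiles(prof3, g, 5e5)
  expect_equal(unname(b3$mat["S1", 1]), 1L)
})

test_that("bins uncovered in any sample are dropped from all samples", {
  g <- genome_layout("chr1", 2e6, 1e6)
  prof <- rbind(data.frame(sample_id = "S1", chrom = "chr1", start = 0,
                           end = 2e6, cn_total = 2L, cn_minor = 1L),
                data.frame(sample_id = "S2", chrom = "chr1", start = 0,
                           end = 1e6, cn_total = 3L, cn_minor = 1L))
  b <- bin_profiles(prof, g, 5e5)
  expect_equal(ncol(b$mat), 2)  # second Mb uncovered in S2
})

test_that("binning an already bin-aligned profile is idempotent", {
  set.seed(71)
  g <- genome_layout("chr1", 5e6, 2e6)
  states <- sample(0:4, 10, replace = TRUE)
  prof <- data.frame(sample_id = "S1", chrom = "chr1",
                     start = (0:9) * 5e5, end = (1:10) * 5e5,
                     cn_total = states, cn_minor = 0L)
  b1 <- bin_profiles(prof, g, 5e5)
  # rebuild a profile from the binned states and bin again
  prof2 <- data.frame(sample_id = "S1", chrom = b1$bins$chrom,
                      start = b1$bins$start, end = b1$bins$end,
                      cn_total = b1$mat["S1", ], cn_minor = 0L)
  b2 <- bin_profiles(prof2, g, 5e5)
  expect_equal(b1$mat, b2$mat)
  expect_equal(unname(b1$mat["S1", ]), states)
})

test_that("identical samples sit at zero distance; extra gains add branch length", {
  b <- random_binned(3, 40)
  b$mat[2, ] <- b$mat[3, ]  # make S1 == S2
  tr <- cna_tree(b)
  d <- ape::cophenetic.phylo(tr$tree)
  expect_equal(d["S1", "S2"], 0)

  # sample C = sample A plus a 12-bin gained block
  mat <- rbind(diploid = rep(2L, 40), A = rep(2L, 40), B = rep(2L, 40),
               C = rep(2L, 40))
  mat["B", 1:5] <- 3L                      # keep 3 distinct samples
  mat["C", 10:21] <- mat["A", 10:21] + 1L
  bb <- structure(list(bins = b$bins, mat = mat), class = "binned_cn")
  tr2 <- cna_tree(bb)
  len_of <- function(tr, tip) {
    tr$tree$edge.length[tr$tree$edge[, 2] == match(tip, tr$tree$tip.label)]
  }
  expect_equal(len_of(tr2, "C") - len_of(tr2, "A"), 12)
})

test_that("ordered Sankoff counts |a-b| steps and the star tree bounds the optimum", {
  set.seed(72)
  for (i in 1:10) {
    b <- random_binned(sample(4:5, 1), 12)
    tr <- cna_tree(b)
    # star-tree score: every sample changes independently from the root state
    cp <- crcevo:::compress_patterns(b$mat)
    star <- colSums(abs(sweep(cp$pat[-1, , drop = FALSE], 2, cp$pat[1, ])))
    expect_lte(tr$score, sum(star * cp$weights))
    # branch lengths sum to the Sankoff minimum
    expect_equal(sum(tr$tree$edge.length), tr$score)
  }
})

test_that("heuristic Sankoff search matches the exhaustive minimum", {
  set.seed(73)
  for (i in 1:10) {
    b <- random_binned(sample(4:5, 1), 10)
    e <- cna_tree(b, method = "exhaustive")
    h <- cna_tree(b, method = "heuristic", restarts = 5, seed = i)
    expect_equal(h$score, e$score)
  }
})

test_that("a 2 -> 4 jump costs two ordered changes but one unordered change", {
  mat <- rbind(diploid = rep(2L, 10), A = rep(2L, 10), B = rep(2L, 10),
               C = rep(2L, 10))
  mat["C", 1] <- 4L
  b <- structure(list(bins = data.frame(chrom = "chr1", start = (0:9) * 5e5,
                                        end = (1:10) * 5e5), mat = mat),
                 class = "binned_cn")
  expect_equal(cna_tree(b, cost = "ordered")$score, 2)
  expect_equal(cna_tree(b, cost = "unordered")$score, 1)
})

test_that("CNA bootstrap is seeded and degenerates sensibly at B = 1", {
  set.seed(74)
  b <- random_binned(4, 30)
  t1 <- cna_bootstrap(b, B = 1, seed = 2)
  expect_true(all(t1$support %in% c(0, 100)))
  t2 <- cna_bootstrap(b, B = 10, seed = 2)
  t3 <- cna_bootstrap(b, B = 10, seed = 2)
  expect_identical(t2$support, t3$support)
})

test_that("a strongly structured split earns full bootstrap support", {
  mat <- rbind(diploid = rep(2L, 60), L1 = rep(2L, 60), L2 = rep(2L, 60),
               H1 = rep(2L, 60), H2 = rep(2L, 60))
  mat[c("H1", "H2"), 1:30] <- 3L
  mat["L2", 31] <- 1L; mat["H2", 32] <- 4L
  b <- structure(list(bins = data.frame(chrom = "chr1", start = (0:59) * 5e5,
                                        end = (1:60) * 5e5), mat = mat),
                 class = "binned_cn")
  bt <- cna_bootstrap(b, B = 50, seed = 3)
  cl <- attr(bt$support, "clades")
  expect_gte(cl$support[cl$clade == "H1|H2"], 95)
})

test_that("punctuated bursts produce a high trunk-to-branch ratio", {
  burst <- sim_params(noise = FALSE,
                      cna_rates = c(arm_gain = 0, arm_loss = 0, cnloh = 0),
                      drift_bins = 5, punctuated_burst_bins = 200)
  sp <- simulate_patient(burst, seed = 75)
  b <- bin_profiles(sp$segments, synthetic_genome())
  pp <- punctuation_profile(cna_tree(b), roles_of(sp))
  expect_gt(pp$punctuation_ratio, 10)
  expect_false(pp$low_confidence)

  control <- sim_params(noise = FALSE,
                        cna_rates = c(arm_gain = 0, arm_loss = 0, cnloh = 0),
                        drift_bins = 5, punctuated_burst_bins = 0)
  sp0 <- simulate_patient(control, seed = 75)
  b0 <- bin_profiles(sp0$segments, synthetic_genome())
  pp0 <- punctuation_profile(cna_tree(b0), roles_of(sp0))
  expect_lt(pp0$punctuation_ratio, 2)
})

test_that("a single HGD/carcinoma sample is flagged low-confidence", {
  p <- sim_params(n_carcinoma = 1, n_hgd = 0, noise = FALSE,
                  punctuated_burst_bins = 50)
  sp <- simulate_patient(p, seed = 76)
  b <- bin_profiles(sp$segments, synthetic_genome())
  pp <- punctuation_profile(cna_tree(b), roles_of(sp))
  expect_true(pp$low_confidence)
  expect_equal(pp$n_clade_samples, 1)
  lgd_only <- roles_of(sp)[sp$samples$tissue_class == "LGD"]
  expect_error(punctuation_profile(cna_tree(b), lgd_only),
               "no HGD or carcinoma")
})
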