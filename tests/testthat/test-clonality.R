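three_carc_matrix <- function() {
  m <- rbind(germline = c(0L, 0L, 0L),
             MUC = c(0L, 1L, 1L),
             CA1 = c(1L, 1L, 0L),
             CA2 = c(1L, 0L, 0L),
             CA3 = c(1L, 0L, 0L))
  colnames(m) <- c("m_truncal", "m_private_muc", "m_muconly")
  char_matrix(m)
}

test_that("clonality classes follow the carcinoma presence pattern", {
  roles <- c(MUC = "normal_mucosa", CA1 = "carcinoma", CA2 = "carcinoma",
             CA3 = "carcinoma")
  rec <- classify_clonality(three_carc_matrix(), roles)
  expect_equal(rec$cancer_pattern, c("truncal", "private", NA))
  expect_equal(rec$in_mucosa, c(FALSE, TRUE, TRUE))
  expect_equal(rec$mucosa_only, c(FALSE, FALSE, TRUE))
  expect_error(classify_clonality(three_carc_matrix(), roles[-1]),
               "missing for sample")
})

test_that("every carcinoma mutation gets exactly one clonality class", {
  sp <- simulate_patient(sim_params(), seed = 41)   # noise on
  cm <- build_character_matrix(sp$calls, sp$samples)
  rec <- classify_clonality(cm, roles_of(sp))
  in_carc <- colSums(cm$mat[sp$samples$sample_id[
    sp$samples$tissue_class == "carcinoma"], , drop = FALSE]) > 0
  expect_true(all(!is.na(rec$cancer_pattern[in_carc])))
  expect_true(all(is.na(rec$cancer_pattern[!in_carc])))
  expect_true(all(rec$cancer_pattern[in_carc] %in%
                    c("truncal", "shared_subclonal", "private")))
})

test_that("noise-free classification recovers the generator's labels exactly", {
  sp <- simulate_patient(quiet_params(), seed = 42)
  cm <- build_character_matrix(sp$calls, sp$samples)
  rec <- classify_clonality(cm, roles_of(sp))
  truth <- sp$truth$mutations
  idx <- match(rec$mutation_id, truth$mutation_id)
  expect_false(anyNA(idx))
  expect_equal(rec$cancer_pattern, truth$cancer_pattern[idx])
  expect_equal(rec$in_mucosa, truth$in_mucosa[idx])
  expect_equal(rec$mucosa_only, truth$mucosa_only[idx])
})

test_that("field overlap fraction is truncal-and-mucosa over truncal", {
  rec <- data.frame(mutation_id = paste0("m", 1:25),
                    cancer_pattern = c(rep("truncal", 20), rep("private", 5)),
                    in_mucosa = c(rep(TRUE, 5), rep(FALSE, 20)),
                    mucosa_only = FALSE)
  expect_equal(field_overlap_fraction(rec), 0.25)
  rec$in_mucosa <- FALSE
  expect_equal(field_overlap_fraction(rec), 0)
  rec$cancer_pattern <- "private"
  expect_warning(expect_true(is.na(field_overlap_fraction(rec))), "undefined")

  sp <- simulate_patient(quiet_params(), seed = 43)
  cm <- build_character_matrix(sp$calls, sp$samples)
  rec <- classify_clonality(cm, roles_of(sp))
  truth <- sp$truth$mutations
  k <- sum(truth$cancer_pattern %in% "truncal" & truth$in_mucosa)
  K <- sum(truth$cancer_pattern %in% "truncal")
  expect_equal(field_overlap_fraction(rec), k / K)
})

test_that("mutation burden divides non-synonymous counts by the footprint", {
  calls <- data.frame(sample_id = "S1", patient_id = "P",
                      tissue_class = "carcinoma", chrom = "chr1",
                      pos = 1:80, ref = "C", alt = "T", gene = "G",
                      effect = c(rep("missense", 60), rep("synonymous", 20)),
                      protein_pos = 1, vaf = 0.5, context = "ACA",
                      stringsAsFactors = FALSE)
  b <- mutation_burden(calls, "S1", footprint_mb = 30)
  expect_equal(b$n_nonsyn, 60)
  expect_equal(b$snas_per_mb, 2.0)
  expect_false(b$msi_flag)
  # hypermutated: 33 SNAs/Mb clears the 10/Mb flag threshold
  b2 <- mutation_burden(calls[rep(1, 990), ], "S1", footprint_mb = 30)
  expect_equal(b2$snas_per_mb, 33)
  expect_true(b2$msi_flag)
  expect_equal(mutation_burden(calls[0, ], "S1", 30)$snas_per_mb, 0)
  expect_error(mutation_burden(calls, "S1", footprint_mb = 0), "> 0")
})

test_that("CCF estimation follows the purity/copy-number formula", {
  r <- estimate_ccf(vaf = 0.25, purity = 0.5, cn_total = 2, cn_major = 1)
  expect_equal(r$multiplicity, 1L)
  expect_equal(r$ccf, 1.0)
  expect_equal(estimate_ccf(0.5, 1, 2, 1)$ccf, 1.0)
  expect_equal(estimate_ccf(0.25, 1, 2, 1)$ccf, 0.5)
  # clonal heterozygous diploid limit: ccf = 1 for any purity
  for (p in c(0.2, 0.5, 0.8, 1)) {
    v <- p * 1 / (p * 2 + 2 * (1 - p))
    expect_equal(estimate_ccf(v, p, 2, 1)$ccf, 1, tolerance = 1e-9)
  }
  expect_error(estimate_ccf(0.5, 0, 2), "purity")
})

test_that("convergent multi-hit genes are detected at the CCF threshold", {
  calls <- data.frame(sample_id = "S1", patient_id = "P",
                      tissue_class = "carcinoma", chrom = "chr17",
                      pos = c(101, 102, 103, 201, 202),
                      ref = "C", alt = "T",
                      gene = c("TP53", "TP53", "TP53", "KRAS", "KRAS"),
                      effect = "missense", protein_pos = 1,
                      vaf = 0.5, context = "ACA",
                      ccf = c(0.9, 0.95, 0.9, 0.9, 0.3),
                      stringsAsFactors = FALSE)
  res <- convergent_genes(calls)
  expect_equal(res, c(TP53 = 3L))
  expect_equal(length(convergent_genes(calls[0, ])), 0)
})

test_that("TP53 domain classification uses the inclusive 102-292 window", {
  expect_equal(tp53_domain_class(245), "DNA_binding")
  expect_equal(tp53_domain_class(306), "other")
  expect_equal(tp53_domain_class(c(102, 292, 101, 293)),
               c("DNA_binding", "DNA_binding", "other", "other"))
})

test_that("gene frequency tables count mutated cases and pool across cohorts", {
  calls <- data.frame(sample_id = paste0("S", 1:10), patient_id = paste0("P", 1:10),
                      tissue_class = "carcinoma", chrom = "chr17", pos = 1:10,
                      ref = "C", alt = "T", gene = "TP53",
                      effect = c(rep("missense", 8), rep("synonymous", 2)),
                      protein_pos = 1, vaf = 0.5, context = "ACA",
                      stringsAsFactors = FALSE)
  tab <- gene_frequency_table(calls, n_cases = 10)
  expect_equal(tab$frequency[tab$gene == "TP53"], 0.8)
  other <- data.frame(gene = "TP53", n_mutated = 16L, n_cases = 30L,
                      frequency = 16 / 30)
  pooled <- pool_gene_frequencies(tab, other)
  expect_equal(pooled$n_mutated, 24L)
  expect_equal(pooled$n_cases, 40L)
  expect_equal(pooled$frequency, 0.6)
  expect_equal(gene_frequency_table(calls, genes = "APC", n_cases = 10)$frequency, 0)

  cmp <- compare_gene_frequencies(tab, other)
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  expect_true(all(cmp$q >= cmp$p - 1e-12))
})
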