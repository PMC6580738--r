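two_chrom_layout <- function() {
  genome_layout(c("chr1", "chr2"), c(10e6, 10e6), c(4e6, 5e6))
}

seg <- function(sample, chrom, start, end, total, minor = NA) {
  data.frame(sample_id = sample, chrom = chrom, start = start, end = end,
             cn_total = as.integer(total), cn_minor = as.integer(minor),
             stringsAsFactors = FALSE)
}

test_that("ploidy summary is the length-weighted mean with class bins", {
  g <- two_chrom_layout()
  diploid <- rbind(seg("S", "chr1", 0, 10e6, 2, 1), seg("S", "chr2", 0, 10e6, 2, 1))
  p <- ploidy_summary(diploid, g)
  expect_equal(p$psi, 2)
  expect_equal(p$ploidy_class, "near_diploid")

  tetra <- rbind(seg("S", "chr1", 0, 10e6, 4, 2), seg("S", "chr2", 0, 10e6, 4, 2))
  expect_equal(ploidy_summary(tetra, g)$ploidy_class, "near_tetraploid")

  half <- rbind(seg("S", "chr1", 0, 10e6, 2, 1), seg("S", "chr2", 0, 10e6, 4, 2))
  p3 <- ploidy_summary(half, g)
  expect_equal(p3$psi, 3)
  expect_equal(p3$ploidy_class, "near_triploid")
})

test_that("PGA separates gains/losses from copy-neutral LOH", {
  g <- two_chrom_layout()
  base <- rbind(seg("S", "chr1", 0, 10e6, 2, 1), seg("S", "chr2", 0, 10e6, 2, 1))
  r <- pga(base, g)
  expect_equal(r$pga_full, 0)

  loh <- rbind(seg("S", "chr1", 0, 10e6, 2, 0), seg("S", "chr2", 0, 10e6, 2, 0))
  r2 <- pga(loh, g)
  expect_equal(r2$pga_full, 1)
  expect_equal(r2$pga_gl, 0)

  ten <- rbind(seg("S", "chr1", 0, 2e6, 3, 1), seg("S", "chr1", 2e6, 10e6, 2, 1),
               seg("S", "chr2", 0, 10e6, 2, 1))
  r3 <- pga(ten, g)
  expect_equal(r3$pga_full, 0.10)
  expect_equal(r3$pga_gl, 0.10)
})

test_that("low-pass profiles report pga_full equal to pga_gl with a flag", {
  g <- two_chrom_layout()
  lp <- rbind(seg("S", "chr1", 0, 4e6, 3), seg("S", "chr1", 4e6, 10e6, 2),
              seg("S", "chr2", 0, 10e6, 2))
  r <- pga(lp, g)
  expect_false(r$cnloh_resolved)
  expect_equal(r$pga_full, r$pga_gl)
})

test_that("PGA and ploidy match a per-base brute-force oracle", {
  set.seed(61)
  g <- two_chrom_layout()
  for (i in 1:20) {
    rows <- list()
    for (ch in c("chr1", "chr2")) {
      cuts <- sort(sample(1:99, sample(2:5, 1))) * 1e5
      b <- c(0, cuts, 10e6)
      for (j in seq_len(length(b) - 1)) {
        tot <- sample(0:5, 1)
        rows[[length(rows) + 1]] <- seg("S", ch, b[j], b[j + 1], tot,
                                        sample(0:(tot %/% 2), 1))
      }
    }
    prof <- do.call(rbind, rows)
    r <- pga(prof, g)
    # oracle: expand to 100-kb base units and count states directly
    unit <- 1e5
    states <- unlist(lapply(seq_len(nrow(prof)), function(j) {
      n <- (prof$end[j] - prof$start[j]) / unit
      st <- if (prof$cn_total[j] > 2) "gain" else if (prof$cn_total[j] < 2) "loss"
            else if (prof$cn_minor[j] == 0) "cnLOH" else "neutral"
      rep(st, n)
    }))
    expect_equal(r$pga_full, mean(states != "neutral"), tolerance = 1e-12)
    expect_equal(r$pga_gl, mean(states %in% c("gain", "loss")), tolerance = 1e-12)
    expect_lte(r$pga_gl, r$pga_full)
    psis <- unlist(lapply(seq_len(nrow(prof)), function(j) {
      rep(prof$cn_total[j], (prof$end[j] - prof$start[j]) / unit)
    }))
    expect_equal(ploidy_summary(prof, g)$psi, mean(psis), tolerance = 1e-12)
  }
})

test_that("arm calls require the threshold fraction and respect precedence", {
  g <- two_chrom_layout()
  prof <- rbind(seg("S", "chr1", 0, 4e6, 3, 1),        # 1p fully gained
                seg("S", "chr1", 4e6, 10e6, 2, 1),     # 1q neutral
                seg("S", "chr2", 0, 2e6, 3, 1),        # 40% of 2p gained
                seg("S", "chr2", 2e6, 5e6, 2, 1),
                seg("S", "chr2", 5e6, 8e6, 2, 0),      # 60% of 2q cnLOH
                seg("S", "chr2", 8e6, 10e6, 2, 1))
  ac <- arm_calls(prof, g, 0.5)
  expect_equal(ac$call[ac$arm == "1p"], "gain")
  expect_equal(ac$fraction[ac$arm == "1p"], 1.0)
  expect_equal(ac$call[ac$arm == "2p"], "neutral")
  expect_equal(ac$call[ac$arm == "2q"], "cnLOH")
  expect_equal(ac$fraction[ac$arm == "2q"], 0.6)
  # zero-coverage arms warn and are neutral
  w <- capture_warnings(ac2 <- arm_calls(prof[1:2, ], g, 0.5))
  expect_true(all(grepl("no segment coverage", w)))
  expect_equal(ac2$call[ac2$arm == "2p"], "neutral")
})

test_that("whole-genome doubling doubles psi and never demotes a gain call", {
  set.seed(62)
  g <- two_chrom_layout()
  prof <- rbind(seg("S", "chr1", 0, 10e6, sample(1:3, 1), 1),
                seg("S", "chr2", 0, 10e6, sample(1:3, 1), 1))
  prof$cn_minor <- pmin(prof$cn_minor, prof$cn_total %/% 2)
  doubled <- prof
  doubled$cn_total <- 2L * doubled$cn_total
  doubled$cn_minor <- 2L * doubled$cn_minor
  expect_equal(ploidy_summary(doubled, g)$psi, 2 * ploidy_summary(prof, g)$psi)
  a1 <- arm_calls(prof, g); a2 <- arm_calls(doubled, g)
  expect_true(all(a2$call[a1$call == "gain"] == "gain"))
})

test_that("arm frequency comparison finds no signal between identical cohorts", {
  g <- two_chrom_layout()
  mk <- function() arm_calls(rbind(seg("S", "chr1", 0, 10e6, 3, 1),
                                   seg("S", "chr2", 0, 10e6, 1, 0)), g)
  cohort <- replicate(5, mk(), simplify = FALSE)
  cmp <- compare_arm_frequencies(cohort, cohort)
  expect_true(all(cmp$p == 1))
  expect_true(all(cmp$q == 1))
  expect_false(any(cmp$significant))
  or <- cmp$odds_ratio[cmp$hits_a > 0 & cmp$hits_a < cmp$n_a]
  expect_true(all(is.na(or) | or == 1 | is.nan(or)))
})

test_that("an injected arm enrichment is flagged at q < 0.05", {
  g <- two_chrom_layout()
  gained <- function() arm_calls(rbind(seg("S", "chr1", 0, 10e6, 3, 1),
                                       seg("S", "chr2", 0, 10e6, 2, 1)), g)
  neutral <- function() arm_calls(rbind(seg("S", "chr1", 0, 10e6, 2, 1),
                                        seg("S", "chr2", 0, 10e6, 2, 1)), g)
  a <- c(replicate(18, gained(), simplify = FALSE),
         replicate(12, neutral(), simplify = FALSE))        # 60% gained
  b <- c(replicate(18, gained(), simplify = FALSE),
         replicate(102, neutral(), simplify = FALSE))       # 15% gained
  cmp <- compare_arm_frequencies(a, b)
  hit <- cmp[cmp$arm %in% c("1p", "1q") & cmp$direction == "gain", ]
  expect_true(all(hit$significant))
})

test_that("burden by grade combines Kruskal-Wallis with pairwise Mann-Whitney", {
  same <- list(LGD = c(1, 2, 3), HGD = c(1, 2, 3), carcinoma = c(1, 2, 3))
  r <- burden_by_grade(same)
  expect_equal(r$kruskal$statistic, 0)
  expect_equal(r$kruskal$p, 1)

  r2 <- burden_by_grade(list(LGD = c(1, 2, 3), HGD = c(4, 5, 6)))
  expect_equal(r2$pairwise$p, 0.1)
  expect_equal(unname(r2$medians), c(2, 5))
  expect_error(burden_by_grade(list(a = 1)), "2 groups")
})
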