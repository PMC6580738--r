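# Per-segment copy state against the diploid-heterozygous baseline:
# gain (total > 2), loss (total < 2), cnLOH (total == 2, minor == 0),
# else neutral. Unknown minor allele (low-pass dialect) cannot resolve cnLOH.
#' @keywords internal
segment_state <- function(cn_total, cn_minor) {
  ifelse(cn_total > 2, "gain",
         ifelse(cn_total < 2, "loss",
                ifelse(!is.na(cn_minor) & cn_minor == 0, "cnLOH", "neutral")))
}

# clip a sample's segments to the autosomes of the layout
#' @keywords internal
autosome_segments <- function(segs, layout) {
  auto <- layout[layout$is_autosome, , drop = FALSE]
  segs <- segs[segs$chrom %in% auto$chrom, , drop = FALSE]
  if (nrow(segs) == 0) return(segs)
  lim <- auto$length[match(segs$chrom, auto$chrom)]
  segs$start <- pmax(segs$start, 0)
  segs$end <- pmin(segs$end, lim)
  segs[segs$start < segs$end, , drop = FALSE]
}

#' Ploidy summary for one copy-number profile
#'
#' psi is the segment-length-weighted mean total copy number over the covered
#' autosomes. Ploidy classes: near-diploid for psi in \[1.6, 2.4),
#' near-triploid in \[2.6, 3.4\], near-tetraploid in \[3.6, 4.4\], otherwise
#' `other`.
#'
#' @param profile Segment `data.frame` for one sample.
#' @param layout A `genome_layout`.
#' @return List with `psi` and `ploidy_class`.
#' @export
ploidy_summary <- function(profile, layout) {
  segs <- autosome_segments(profile, layout)
  if (nrow(segs) == 0) stop("profile covers no autosome")
  len <- segs$end - segs$start
  psi <- sum(len * segs$cn_total) / sum(len)
  cls <- if (psi >= 1.6 && psi < 2.4) "near_diploid"
         else if (psi >= 2.6 && psi <= 3.4) "near_triploid"
         else if (psi >= 3.6 && psi <= 4.4) "near_tetraploid"
         else "other"
  list(psi = psi, ploidy_class = cls)
}

#' Percent genome altered
#'
#' Fractions of the covered autosomal genome showing copy gain, copy loss or
#' copy-neutral LOH against a diploid-heterozygous baseline. `pga_full`
#' includes cnLOH; `pga_gl` counts gains and losses only. For low-pass
#' profiles (unknown minor allele) cnLOH is unresolvable, so `pga_full`
#' equals `pga_gl` and the result is flagged.
#'
#' @param profile Segment `data.frame` for one sample.
#' @param layout A `genome_layout`.
#' @return A `BurdenResult` list: `pga_full`, `pga_gl`, `by_state` (named
#'   fractions), `covered_bp`, `covered_fraction`, `cnloh_resolved`.
#' @export
pga <- function(profile, layout) {
  segs <- autosome_segments(profile, layout)
  if (nrow(segs) == 0) stop("profile covers no autosome")
  len <- segs$end - segs$start
  st <- segment_state(segs$cn_total, segs$cn_minor)
  covered <- sum(len)
  by_state <- vapply(c("gain", "loss", "cnLOH"),
                     function(s) sum(len[st == s]) / covered, numeric(1))
  genome_bp <- sum(layout$length[layout$is_autosome])
  list(pga_full = sum(by_state), pga_gl = by_state[["gain"]] + by_state[["loss"]],
       by_state = by_state, covered_bp = covered,
       covered_fraction = covered / genome_bp,
       cnloh_resolved = !all(is.na(segs$cn_minor)))
}

#' Arm-level copy-number calls
#'
#' An arm is called gained/lost when at least `arm_fraction_threshold` of its
#' length is in that state (gain/loss take precedence over cnLOH; if both a
#' gain and a loss fraction pass the threshold the larger wins, ties to
#' gain), cnLOH when the cnLOH fraction passes instead, otherwise neutral.
#' Arms with zero coverage are called neutral with a warning.
#'
#' @param profile Segment `data.frame` for one sample.
#' @param layout A `genome_layout`.
#' @param arm_fraction_threshold Minimum fraction of arm length (default 0.5).
#' @return `data.frame` with `arm`, `call`, `fraction` (of arm length in the
#'   called state) and `coverage` (fraction of arm length covered by
#'   segments).
#' @export
arm_calls <- function(profile, layout, arm_fraction_threshold = 0.5) {
  arms <- genome_arms(layout)
  segs <- autosome_segments(profile, layout)
  st <- segment_state(segs$cn_total, segs$cn_minor)
  out <- lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    idx <- which(segs$chrom == a$chrom & segs$end > a$start & segs$start < a$end)
    ov <- pmin(segs$end[idx], a$end) - pmax(segs$start[idx], a$start)
    coverage <- sum(ov) / a$length
    frac <- vapply(c("gain", "loss", "cnLOH", "neutral"),
                   function(s) sum(ov[st[idx] == s]) / a$length, numeric(1))
    if (coverage == 0) {
      warning("arm ", a$arm, " has no segment coverage; called neutral")
      return(data.frame(arm = a$arm, call = "neutral", fraction = 0,
                        coverage = 0, stringsAsFactors = FALSE))
    }
    thr <- arm_fraction_threshold
    call <- if (frac[["gain"]] >= thr || frac[["loss"]] >= thr) {
      if (frac[["gain"]] >= frac[["loss"]]) "gain" else "loss"
    } else if (frac[["cnLOH"]] >= thr) "cnLOH" else "neutral"
    data.frame(arm = a$arm, call = call, fraction = frac[[call]],
               coverage = coverage, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare arm-level event frequencies between two cohorts
#'
#' For every arm and direction (gain, loss, and cnLOH when resolved), a 2x2
#' Fisher's exact test on event counts in cohort A versus cohort B, with
#' Benjamini-Hochberg adjustment across all arm-by-direction tests.
#' Per sample, arms with less than `min_coverage` segment coverage are
#' excluded from both numerator and denominator.
#'
#' @param cohort_a,cohort_b Lists of per-sample [arm_calls()] tables.
#' @param min_coverage Minimum per-sample arm coverage (default 0.1).
#' @return `data.frame` with per-(arm, direction) counts, odds ratio, `p`,
#'   `q`, and a `significant` flag (q < 0.05).
#' @export
compare_arm_frequencies <- function(cohort_a, cohort_b, min_coverage = 0.1) {
  if (length(cohort_a) < 1 || length(cohort_b) < 1) {
    stop("both cohorts need at least one sample")
  }
  tally <- function(cohort, arm, dir) {
    hits <- 0L; total <- 0L
    for (tab in cohort) {
      row <- tab[tab$arm == arm, , drop = FALSE]
      if (nrow(row) == 0 || row$coverage[1] < min_coverage) next
      total <- total + 1L
      if (row$call[1] == dir) hits <- hits + 1L
    }
    c(hits = hits, total = total)
  }
  arms <- unique(unlist(lapply(c(cohort_a, cohort_b), `[[`, "arm")))
  dirs <- c("gain", "loss")
  if (any(unlist(lapply(c(cohort_a, cohort_b), function(t) t$call == "cnLOH")))) {
    dirs <- c(dirs, "cnLOH")
  }
  rows <- list()
  for (arm in arms) {
    for (dir in dirs) {
      ta <- tally(cohort_a, arm, dir)
      tb <- tally(cohort_b, arm, dir)
      if (ta[["total"]] == 0 || tb[["total"]] == 0) next
      ft <- fisher_exact_2x2(ta[["hits"]], ta[["total"]] - ta[["hits"]],
                             tb[["hits"]], tb[["total"]] - tb[["hits"]])
      rows[[length(rows) + 1]] <- data.frame(
        arm = arm, direction = dir,
        hits_a = ta[["hits"]], n_a = ta[["total"]],
        hits_b = tb[["hits"]], n_b = tb[["total"]],
        odds_ratio = ft$statistic, p = ft$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- !is.na(out$q) & out$q < 0.05
  rownames(out) <- NULL
  out
}

#' Copy-number burden compared across lesion grades
#'
#' Kruskal-Wallis test across all grades plus pairwise Mann-Whitney U tests
#' with Benjamini-Hochberg adjustment, preserving the supplied grade order.
#'
#' @param groups Named list (grade -> numeric vector of per-sample PGA).
#' @return List with `kruskal` (`TestResult`), `pairwise` (`data.frame` of
#'   `group_a`, `group_b`, `u`, `p`, `q`), and `medians`.
#' @export
burden_by_grade <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  kw <- kruskal_wallis(groups)
  grades <- names(groups)
  pairs <- utils::combn(length(grades), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    mw <- mann_whitney_u(groups[[i1]], groups[[i2]])
    data.frame(group_a = grades[i1], group_b = grades[i2],
               u = mw$statistic, p = mw$p, stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$q <- bh_adjust(pw$p)
  list(kruskal = kw, pairwise = pw,
       medians = vapply(groups, stats::median, numeric(1)))
}
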