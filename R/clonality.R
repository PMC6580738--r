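#' Classify mutations by clonality and mucosal field membership
#'
#' Within one patient: a mutation is `truncal` when present in every carcinoma
#' sample, `shared_subclonal` when present in at least two but not all, and
#' `private` when present in exactly one. `in_mucosa` records presence in at
#' least one non-dysplastic mucosa sample; `mucosa_only` marks mutations
#' carried by mucosa but by no carcinoma region (for which the cancer pattern
#' is undefined, `NA`).
#'
#' @param matrix A `char_matrix` for the patient.
#' @param sample_roles Named character vector mapping every sample id in the
#'   matrix to its tissue class.
#' @return `data.frame` with `mutation_id`, `cancer_pattern`, `in_mucosa`,
#'   `mucosa_only`.
#' @export
classify_clonality <- function(matrix, sample_roles) {
  mat <- matrix$mat
  samples <- rownames(mat)[-1]
  missing <- setdiff(samples, names(sample_roles))
  if (length(missing) > 0) {
    stop("tissue class missing for sample(s): ", paste(missing, collapse = ", "))
  }
  roles <- sample_roles[samples]
  carc <- samples[roles == "carcinoma"]
  muc <- samples[roles == "normal_mucosa"]
  if (length(carc) < 1) stop("need at least one carcinoma sample")
  n_in_carc <- colSums(mat[carc, , drop = FALSE])
  in_mucosa <- if (length(muc) > 0) colSums(mat[muc, , drop = FALSE]) > 0 else
    rep(FALSE, ncol(mat))
  pattern <- rep(NA_character_, ncol(mat))
  pattern[n_in_carc == length(carc)] <- "truncal"
  pattern[n_in_carc > 0 & n_in_carc < length(carc)] <-
    ifelse(n_in_carc[n_in_carc > 0 & n_in_carc < length(carc)] == 1,
           "private", "shared_subclonal")
  data.frame(mutation_id = colnames(mat), cancer_pattern = pattern,
             in_mucosa = in_mucosa, mucosa_only = in_mucosa & n_in_carc == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of truncal mutations shared with the mucosal field
#'
#' The proportion of truncal (present in all carcinoma regions) mutations
#' that are also detected in the surrounding non-dysplastic mucosa — the
#' per-patient measure of field cancerisation.
#'
#' @param records Output of [classify_clonality()].
#' @return Numeric fraction in \[0,1\]; `NA` with a warning when the patient
#'   has no truncal mutations.
#' @export
field_overlap_fraction <- function(records) {
  truncal <- records$cancer_pattern %in% "truncal"
  if (sum(truncal) == 0) {
    warning("no truncal mutations; field overlap undefined")
    return(NA_real_)
  }
  sum(records$in_mucosa[truncal]) / sum(truncal)
}

#' Per-sample mutation burden
#'
#' Non-synonymous SNA count divided by the sequenced exome footprint, with a
#' burden-based microsatellite-instability flag.
#'
#' @param calls Mutation call `data.frame`.
#' @param sample Sample id.
#' @param footprint_mb Callable exome footprint in Mb (> 0; default 34.7).
#' @param msi_threshold SNAs/Mb above which the sample is flagged
#'   hypermutated/MSI (default 10).
#' @return List with `sample_id`, `n_nonsyn`, `snas_per_mb`, `msi_flag`.
#' @export
mutation_burden <- function(calls, sample, footprint_mb = 34.7,
                            msi_threshold = 10) {
  if (footprint_mb <= 0) stop("footprint_mb must be > 0")
  sub <- calls[calls$sample_id == sample & calls$effect != "synonymous", ,
               drop = FALSE]
  n <- nrow(sub)
  rate <- n / footprint_mb
  list(sample_id = sample, n_nonsyn = n, snas_per_mb = rate,
       msi_flag = rate >= msi_threshold)
}

#' Cancer cell fraction from VAF, purity and local copy number
#'
#' Multiplicity is estimated as
#' round(vaf * (purity * cn_total + 2(1 - purity)) / purity), clamped to
#' \[1, max(cn_major, 1)\]; the CCF is then
#' vaf * (purity * cn_total + 2(1 - purity)) / (purity * multiplicity).
#' The reported `ccf` is capped at 1; the raw value is retained in `ccf_raw`.
#'
#' @param vaf Variant allele fraction(s) in \[0,1\].
#' @param purity Sample purity in (0,1\].
#' @param cn_total Total copy number at the locus (>= 1).
#' @param cn_major Major allele copy number (defaults to `cn_total - 1`,
#'   floored at 1).
#' @return `data.frame` with `multiplicity`, `ccf`, `ccf_raw`.
#' @export
estimate_ccf <- function(vaf, purity, cn_total, cn_major = NULL) {
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0,1]")
  if (any(cn_total < 1)) stop("cn_total must be >= 1")
  if (is.null(cn_major)) cn_major <- pmax(cn_total - 1, 1)
  denom <- purity * cn_total + 2 * (1 - purity)
  mult <- pmin(pmax(round(vaf * denom / purity), 1), pmax(cn_major, 1))
  ccf_raw <- vaf * denom / (purity * mult)
  data.frame(multiplicity = as.integer(mult), ccf = pmin(ccf_raw, 1),
             ccf_raw = ccf_raw)
}

#' Detect convergent multi-hit genes
#'
#' Genes carrying two or more distinct near-clonal non-synonymous mutations
#' (CCF at or above `ccf_threshold`) — the pattern expected under convergent
#' selection for loss of a tumour suppressor.
#'
#' @param calls Mutation call `data.frame` with a `ccf` column.
#' @param ccf_threshold Near-clonal cut-off (default 0.8).
#' @return Named integer vector: per flagged gene, the count of distinct
#'   qualifying mutations. Empty when nothing qualifies.
#' @export
convergent_genes <- function(calls, ccf_threshold = 0.8) {
  if (nrow(calls) == 0) return(setNames(integer(0), character(0)))
  sub <- calls[!is.na(calls$gene) & calls$gene != "" &
               calls$effect != "synonymous" &
               !is.na(calls$ccf) & calls$ccf >= ccf_threshold, , drop = FALSE]
  if (nrow(sub) == 0) return(setNames(integer(0), character(0)))
  ids <- unique(data.frame(gene = sub$gene, id = mutation_id(sub)))
  counts <- table(ids$gene)
  res <- counts[counts >= 2]
  setNames(as.integer(res), names(res))
}

#' TP53 functional domain classification
#'
#' The p53 DNA-binding domain spans amino acids 102-292 (inclusive).
#'
#' @param protein_pos Integer codon position(s).
#' @return Character vector, `"DNA_binding"` or `"other"` (`NA` in, `NA` out).
#' @export
tp53_domain_class <- function(protein_pos) {
  ifelse(is.na(protein_pos), NA_character_,
         ifelse(protein_pos >= 102 & protein_pos <= 292, "DNA_binding", "other"))
}

#' Per-gene mutated-case frequency table
#'
#' A case counts as mutated in a gene when it carries at least one
#' non-synonymous call in that gene.
#'
#' @param cohort_calls Mutation call `data.frame` for a cohort.
#' @param genes Genes to tabulate (default: all genes seen).
#' @param n_cases Total cases in the cohort (default: number of distinct
#'   `patient_id`s in `cohort_calls`).
#' @return `data.frame` with `gene`, `n_mutated`, `n_cases`, `frequency`.
#' @export
gene_frequency_table <- function(cohort_calls, genes = NULL, n_cases = NULL) {
  if (is.null(n_cases)) n_cases <- length(unique(cohort_calls$patient_id))
  sub <- cohort_calls[cohort_calls$effect != "synonymous" &
                      !is.na(cohort_calls$gene) & cohort_calls$gene != "", ,
                      drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(sub$gene))
  n_mut <- vapply(genes, function(g) {
    length(unique(sub$patient_id[sub$gene == g]))
  }, integer(1))
  data.frame(gene = genes, n_mutated = unname(n_mut), n_cases = n_cases,
             frequency = unname(n_mut) / n_cases, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pool gene frequency tables across cohorts
#'
#' Meta-analysis pooling: numerators and denominators are summed per gene.
#'
#' @param ... Two or more outputs of [gene_frequency_table()].
#' @return Pooled frequency table over the union of genes.
#' @export
pool_gene_frequencies <- function(...) {
  tabs <- list(...)
  genes <- sort(unique(unlist(lapply(tabs, `[[`, "gene"))))
  n_mut <- n_cases <- setNames(numeric(length(genes)), genes)
  for (tab in tabs) {
    idx <- match(tab$gene, genes)
    n_mut[idx] <- n_mut[idx] + tab$n_mutated
    n_cases <- n_cases + tab$n_cases[1]
  }
  data.frame(gene = genes, n_mutated = as.integer(n_mut),
             n_cases = as.integer(n_cases), frequency = n_mut / n_cases,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare per-gene mutation frequencies between two cohorts
#'
#' Per gene, a 2x2 Fisher's exact test of mutated/wild-type cases in cohort A
#' versus cohort B, with Benjamini-Hochberg adjustment across genes.
#'
#' @param tab_a,tab_b Outputs of [gene_frequency_table()] (or pooled tables).
#' @return `data.frame` with per-gene counts, frequencies, odds ratio, `p`
#'   and `q`.
#' @export
compare_gene_frequencies <- function(tab_a, tab_b) {
  genes <- sort(union(tab_a$gene, tab_b$gene))
  ga <- tab_a[match(genes, tab_a$gene), ]
  gb <- tab_b[match(genes, tab_b$gene), ]
  na_cases <- max(tab_a$n_cases); nb_cases <- max(tab_b$n_cases)
  xa <- ifelse(is.na(ga$n_mutated), 0L, ga$n_mutated)
  xb <- ifelse(is.na(gb$n_mutated), 0L, gb$n_mutated)
  res <- lapply(seq_along(genes), function(i) {
    fisher_exact_2x2(xa[i], na_cases - xa[i], xb[i], nb_cases - xb[i])
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  data.frame(gene = genes, mutated_a = xa, cases_a = na_cases,
             mutated_b = xb, cases_b = nb_cases,
             freq_a = xa / na_cases, freq_b = xb / nb_cases,
             odds_ratio = vapply(res, `[[`, numeric(1), "statistic"),
             p = p, q = bh_adjust(p), row.names = NULL,
             stringsAsFactors = FALSE)
}
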