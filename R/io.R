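TISSUE_CLASSES <- c("blood", "normal_mucosa", "LGD", "HGD", "carcinoma")
EFFECT_CLASSES <- c("missense", "nonsense", "frameshift", "splice",
                    "synonymous", "other")
MUTATION_COLS <- c("sample_id", "patient_id", "tissue_class", "chrom", "pos",
                   "ref", "alt", "gene", "effect", "protein_pos", "vaf",
                   "context")

#' Mutation identifier used to match calls across samples
#'
#' @param calls Mutation call `data.frame`.
#' @return Character vector `chrom:pos:ref:alt`.
#' @export
mutation_id <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

.parse_error <- function(line, msg) {
  stop(sprintf("parse error at line %d: %s", line, msg), call. = FALSE)
}

#' Read a multiregion mutation table
#'
#' Tab-separated, one row per mutation call in one sample, with required
#' header columns `sample_id, patient_id, tissue_class, chrom, pos, ref, alt,
#' gene, effect, protein_pos, vaf, context`. Every row is validated: VAF in
#' \[0,1\], ref != alt, tissue/effect classes from the fixed vocabularies, and
#' for single-base substitutions a 3-mer context whose middle base matches the
#' reference allele. Duplicate (sample, chrom, pos, alt) rows are rejected.
#'
#' @param path File path.
#' @return A list with `calls` (validated `data.frame`, one row per call) and
#'   `samples` (deduplicated `data.frame` of `sample_id`, `patient_id`,
#'   `tissue_class`).
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  missing <- setdiff(MUTATION_COLS, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[MUTATION_COLS]
  df$pos <- suppressWarnings(as.numeric(df$pos))
  df$protein_pos <- suppressWarnings(as.numeric(df$protein_pos))
  vaf_chr <- df$vaf
  df$vaf <- suppressWarnings(as.numeric(df$vaf))
  for (i in seq_len(nrow(df))) {
    ln <- i + 1L  # header is line 1
    if (is.na(df$pos[i]) || df$pos[i] < 1) .parse_error(ln, "malformed position")
    if (is.na(df$vaf[i]) && !is.na(vaf_chr[i])) .parse_error(ln, "malformed VAF")
    if (is.na(df$vaf[i]) || df$vaf[i] < 0 || df$vaf[i] > 1) {
      .parse_error(ln, sprintf("VAF '%s' outside [0,1]", vaf_chr[i]))
    }
    if (is.na(df$ref[i]) || is.na(df$alt[i]) || df$ref[i] == df$alt[i]) {
      .parse_error(ln, "ref and alt must differ")
    }
    if (!df$tissue_class[i] %in% TISSUE_CLASSES) {
      .parse_error(ln, paste0("unknown tissue_class '", df$tissue_class[i], "'"))
    }
    if (!df$effect[i] %in% EFFECT_CLASSES) {
      .parse_error(ln, paste0("unknown effect '", df$effect[i], "'"))
    }
    is_snv <- nchar(df$ref[i]) == 1L && nchar(df$alt[i]) == 1L
    if (!is.na(df$context[i])) {
      if (nchar(df$context[i]) != 3L) .parse_error(ln, "context must be a 3-mer")
      if (is_snv && substr(df$context[i], 2, 2) != df$ref[i]) {
        .parse_error(ln, "context middle base must equal ref")
      }
    }
  }
  key <- paste(df$sample_id, df$chrom, df$pos, df$alt)
  if (anyDuplicated(key)) {
    .parse_error(which(duplicated(key))[1] + 1L,
                 "duplicate (sample, chrom, pos, alt) call")
  }
  samples <- unique(df[c("sample_id", "patient_id", "tissue_class")])
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_id mapped to more than one patient or tissue class")
  }
  rownames(df) <- rownames(samples) <- NULL
  list(calls = df, samples = samples)
}

#' Write a mutation table
#'
#' @param calls Mutation call `data.frame` with the standard columns.
#' @param path Output path.
#' @export
write_mutation_table <- function(calls, path) {
  utils::write.table(calls[MUTATION_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read copy-number segments (SEG-like)
#'
#' Tab-separated with header `sample_id, chrom, start, end, cn_total`
#' (+ `cn_minor` for the allele-specific dialect). On-disk coordinates are
#' 1-based inclusive; internally segments are half-open zero-based. The
#' low-pass dialect carries no minor allele copy number (`cn_minor = NA`),
#' reflecting assays that cannot resolve copy-neutral LOH.
#'
#' @param path File path.
#' @param dialect `"allele_specific"` or `"lowpass"`.
#' @return `data.frame` with columns `sample_id, chrom, start, end, cn_total,
#'   cn_minor`, with a `dialect` attribute.
#' @export
read_segments <- function(path, dialect = c("allele_specific", "lowpass")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "cn_total")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  segs <- data.frame(sample_id = as.character(df$sample_id),
                     chrom = as.character(df$chrom),
                     start = as.numeric(df$start) - 1,
                     end = as.numeric(df$end),
                     cn_total = as.integer(df$cn_total),
                     stringsAsFactors = FALSE)
  if (dialect == "allele_specific" && "cn_minor" %in% names(df)) {
    segs$cn_minor <- as.integer(df$cn_minor)
  } else {
    segs$cn_minor <- NA_integer_
  }
  validate_segments(segs)
  attr(segs, "dialect") <- dialect
  segs
}

#' Validate segment invariants (internal)
#' @keywords internal
validate_segments <- function(segs) {
  if (any(segs$start >= segs$end)) stop("segment with start >= end")
  if (any(segs$cn_total < 0, na.rm = TRUE)) stop("negative total copy number")
  bad <- !is.na(segs$cn_minor) & segs$cn_minor > segs$cn_total / 2
  if (any(bad)) stop("cn_minor exceeds cn_total/2")
  for (key in unique(paste(segs$sample_id, segs$chrom))) {
    idx <- which(paste(segs$sample_id, segs$chrom) == key)
    s <- segs[idx, , drop = FALSE]
    o <- order(s$start)
    s <- s[o, , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      i <- which(s$start[-1] < s$end[-nrow(s)])[1]
      stop(sprintf(
        "overlapping segments for sample %s on %s: [%d,%d) and [%d,%d)",
        s$sample_id[1], s$chrom[1], s$start[i], s$end[i],
        s$start[i + 1], s$end[i + 1]))
    }
  }
  invisible(segs)
}

#' Write copy-number segments (1-based inclusive on disk)
#'
#' @param segs Segment `data.frame` in internal half-open zero-based form.
#' @param path Output path.
#' @export
write_segments <- function(segs, path) {
  out <- data.frame(sample_id = segs$sample_id, chrom = segs$chrom,
                    start = format(segs$start + 1, scientific = FALSE, trim = TRUE),
                    end = format(segs$end, scientific = FALSE, trim = TRUE),
                    cn_total = segs$cn_total, cn_minor = segs$cn_minor,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a genome layout table
#'
#' Tab-separated columns `chrom, length, centromere, is_autosome`.
#'
#' @param path File path.
#' @return A `genome_layout`.
#' @export
read_genome_layout <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  genome_layout(df$chrom, df$length, df$centromere, as.logical(df$is_autosome))
}

#' Write a genome layout table
#' @param layout A `genome_layout`.
#' @param path Output path.
#' @export
write_genome_layout <- function(layout, path) {
  out <- as.data.frame(layout)
  out$length <- format(out$length, scientific = FALSE, trim = TRUE)
  out$centromere <- format(out$centromere, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 96-channel signature matrix
#'
#' Tab-separated: first column the channel label (all 96, in the fixed
#' pyrimidine-centred order), remaining columns one signature each. Columns
#' must be non-negative and sum to 1 within 1e-6; accepted columns are then
#' renormalised so sums are exact.
#'
#' @param path File path.
#' @return Numeric 96 x K matrix with channel rownames.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) != 96) stop("signature matrix must have 96 data rows, found ",
                           nrow(df))
  if (!identical(df[[1]], sig_channels())) {
    stop("channel labels are not the 96 pyrimidine-centred channels in fixed order")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("negative signature entries")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6)) {
    stop("signature column(s) do not sum to 1: ",
         paste(colnames(m)[abs(cs - 1) > 1e-6], collapse = ", "))
  }
  sweep(m, 2, cs, "/")
}

#' Write a 96-channel signature matrix
#' @param signatures 96 x K matrix with channel rownames.
#' @param path Output path.
#' @export
write_signature_matrix <- function(signatures, path) {
  df <- data.frame(channel = rownames(signatures), signatures,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tree to newick
#'
#' Branch lengths are written; clade bootstrap supports, when present, are
#' written as internal-node labels. Reading the file back yields an
#' isomorphic tree.
#'
#' @param tree An `ape::phylo` or an `mp_tree` (its `$tree` is used, with
#'   bootstrap supports as node labels if attached).
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  phy <- as_phylo_tree(tree)
  if (is.null(phy$tip.label) || any(is.na(phy$tip.label)) ||
      any(phy$tip.label == "")) {
    stop("all leaves must be named")
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a newick tree
#' @param path File path.
#' @return An `ape::phylo`.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Coerce tree-like objects to ape::phylo (internal)
#' @keywords internal
as_phylo_tree <- function(tree) {
  if (inherits(tree, "mp_tree")) {
    phy <- tree$tree
    if (!is.null(tree$support)) {
      lab <- rep("", phy$Nnode)
      idx <- as.integer(names(tree$support)) - ape::Ntip(phy)
      keep <- idx >= 1 & idx <= phy$Nnode
      lab[idx[keep]] <- as.character(round(tree$support[keep]))
      phy$node.label <- lab
    }
    return(phy)
  }
  if (inherits(tree, "phylo")) return(tree)
  stop("not a tree object")
}
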