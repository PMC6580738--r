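#' Construct a genome layout
#'
#' A genome layout fixes the chromosome set used throughout the analysis:
#' lengths, centromere positions (which define the p/q arm split used for
#' arm-level copy-number calls), and an autosome flag. Sex chromosomes are
#' flagged `is_autosome = FALSE` and excluded from percent-genome-altered and
#' arm-level statistics by default.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer chromosome lengths in bp (> 0).
#' @param centromere Integer centromere positions in bp, strictly inside the
#'   chromosome.
#' @param is_autosome Logical flag per chromosome (default all `TRUE`).
#' @return A `data.frame` of class `genome_layout` with columns
#'   `chrom`, `length`, `centromere`, `is_autosome`.
#' @export
genome_layout <- function(chrom, length, centromere, is_autosome = TRUE) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  centromere <- as.numeric(centromere)
  is_autosome <- rep_len(as.logical(is_autosome), base::length(chrom))
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  if (any(centromere <= 0 | centromere >= length)) {
    stop("centromere must lie strictly inside the chromosome")
  }
  out <- data.frame(chrom = chrom, length = length, centromere = centromere,
                    is_autosome = is_autosome, stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Default synthetic genome: 22 autosomes at 10 percent of human scale
#'
#' Chromosome and centromere coordinates are the human (GRCh37) values scaled
#' down tenfold and rounded to 500-kbp multiples, so the genome stays
#' realistic in shape (many arms, heavy-tailed length distribution) while
#' 500-kbp binning yields a few hundred bins rather than ~6000. Total size is
#' about 289 Mb (~578 bins).
#'
#' @return A `genome_layout` with 22 autosomes.
#' @export
synthetic_genome <- function() {
  mb <- 1e6
  len <- c(25, 24.5, 20, 19, 18, 17, 16, 14.5, 14, 13.5, 13.5, 13.5,
           11.5, 10.5, 10.5, 9, 8, 8, 6, 6.5, 5, 5) * mb
  cen <- c(12.5, 9.5, 9, 5, 5, 6, 6, 4.5, 5, 4, 5.5, 3.5,
           2, 2, 2, 3.5, 2.5, 1.5, 2.5, 2.5, 1.5, 1.5) * mb
  genome_layout(paste0("chr", 1:22), len, cen, TRUE)
}

#' Chromosome arms of a genome layout
#'
#' Splits every chromosome at its centromere into p (before) and q (after)
#' arms, in half-open zero-based coordinates.
#'
#' @param layout A `genome_layout`.
#' @param autosomes_only Drop non-autosomes (default `TRUE`).
#' @return `data.frame` with columns `arm`, `chrom`, `start`, `end`, `length`.
#' @export
genome_arms <- function(layout, autosomes_only = TRUE) {
  stopifnot(inherits(layout, "genome_layout"))
  if (autosomes_only) layout <- layout[layout$is_autosome, , drop = FALSE]
  p <- data.frame(arm = paste0(sub("^chr", "", layout$chrom), "p"),
                  chrom = layout$chrom, start = 0, end = layout$centromere,
                  stringsAsFactors = FALSE)
  q <- data.frame(arm = paste0(sub("^chr", "", layout$chrom), "q"),
                  chrom = layout$chrom, start = layout$centromere,
                  end = layout$length, stringsAsFactors = FALSE)
  out <- rbind(p, q)
  out <- out[order(match(out$chrom, layout$chrom), out$start), , drop = FALSE]
  out$length <- out$end - out$start
  rownames(out) <- NULL
  out
}
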