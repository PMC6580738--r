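#' The 96 trinucleotide substitution channels
#'
#' Channel labels follow the pyrimidine-centred convention: the six
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G, each expanded over the
#' 16 flanking-base combinations (5' flank cycling slowest), giving labels of
#' the form `"A[C>A]A"`. This fixed order is used everywhere a 96-element
#' catalogue or signature column appears.
#'
#' @return Character vector of length 96.
#' @export
sig_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1)
    for (five in bases) {
      for (three in bases) {
        out <- c(out, paste0(five, "[", s, "]", three))
      }
    }
  }
  out
}

#' @keywords internal
.rc_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

#' Reverse complement of a DNA string (internal)
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(unname(.rc_base(strsplit(s, "", fixed = TRUE)[[1]]))), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Map a substitution with trinucleotide context to its 96-channel index
#'
#' Purine-centred calls (ref A or G) are reverse complemented onto the
#' pyrimidine strand first. Returns `NA` for indels (multi-base alleles),
#' unknown context, or malformed context (middle base not equal to ref).
#'
#' @param ref,alt Single-base allele strings.
#' @param context 3-mer with the mutated base central, or `NA`.
#' @return Integer channel index in 1..96, or `NA_integer_`.
#' @export
channel_index <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n); context <- rep_len(context, n)
  labels <- sig_channels()
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; ctx <- context[i]
    if (is.na(r) || is.na(a) || is.na(ctx)) next
    if (nchar(r) != 1L || nchar(a) != 1L || nchar(ctx) != 3L) next
    if (substr(ctx, 2, 2) != r) {
      stop("context middle base '", substr(ctx, 2, 2),
           "' does not match ref allele '", r, "'")
    }
    if (r %in% c("A", "G")) {
      ctx <- revcomp(ctx)
      r <- unname(.rc_base(r))
      a <- unname(.rc_base(a))
    }
    lab <- paste0(substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3))
    idx <- match(lab, labels)
    out[i] <- idx
  }
  out
}

#' Bundled synthetic reference signatures
#'
#' Three near-orthogonal 96-channel signatures intended for simulation and
#' testing. They are caricatures of well-known processes, not COSMIC
#' signatures:
#' \describe{
#'   \item{SigA}{C>T dominated, strongest at NpCpG-like flanks (ageing-style
#'     spontaneous deamination).}
#'   \item{SigB}{flat-ish mass spread over the T>A/T>C blocks (a diffuse,
#'     aetiology-free background).}
#'   \item{SigC}{C>A/C>G dominated (a damage-style process).}
#' }
#' Columns sum to 1 exactly (normalised at construction).
#'
#' @return A 96 x 3 numeric matrix with channel rownames and signature
#'   colnames, satisfying the signature-matrix invariants.
#' @export
example_signatures <- function() {
  ch <- sig_channels()
  n <- length(ch)
  sigA <- numeric(n); sigB <- numeric(n); sigC <- numeric(n)
  ct <- grepl("C>T", ch, fixed = TRUE)
  cpg <- ct & grepl("\\]G$", ch)
  sigA[ct] <- 1
  sigA[cpg] <- 8
  ta_tc <- grepl("T>A", ch, fixed = TRUE) | grepl("T>C", ch, fixed = TRUE)
  sigB[ta_tc] <- 1
  # small spill-over so supports are near- but not fully disjoint
  sigB[grepl("T>G", ch, fixed = TRUE)] <- 0.25
  ca_cg <- grepl("C>A", ch, fixed = TRUE) | grepl("C>G", ch, fixed = TRUE)
  sigC[ca_cg] <- 1
  sigC[grepl("A\\[C>A\\]", ch)] <- 4
  m <- cbind(SigA = sigA / sum(sigA), SigB = sigB / sum(sigB),
             SigC = sigC / sum(sigC))
  rownames(m) <- ch
  m
}
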