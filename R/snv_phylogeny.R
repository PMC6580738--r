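OUTGROUP <- "germline"

#' Construct a binary character matrix
#'
#' @param mat Integer 0/1 matrix, rows = samples (first row must be the
#'   all-absent `"germline"` outgroup), columns = mutations.
#' @param anno Optional `data.frame` with one row per column (`mutation_id`,
#'   `gene`, `effect`).
#' @return A `char_matrix` object.
#' @export
char_matrix <- function(mat, anno = NULL) {
  if (rownames(mat)[1] != OUTGROUP) stop("first row must be the germline outgroup")
  if (any(mat[1, ] != 0)) stop("outgroup row must be all-absent")
  if (!all(mat %in% c(0L, 1L))) stop("matrix values must be binary")
  if (ncol(mat) > 0 && any(colSums(mat) == 0)) stop("all-absent column present")
  if (is.null(anno)) {
    anno <- data.frame(mutation_id = colnames(mat),
                       gene = NA_character_, effect = NA_character_,
                       stringsAsFactors = FALSE)
  }
  structure(list(mat = mat, anno = anno), class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("Binary character matrix:", nrow(x$mat) - 1, "samples (+ germline outgroup),",
      ncol(x$mat), "mutations\n")
  invisible(x)
}

#' Build the mutation presence/absence matrix for one patient
#'
#' A mutation is scored present in a sample when a call exists for it in that
#' sample with VAF at or above `detection_threshold`. Columns absent from all
#' samples after thresholding are dropped (with a message). An all-absent
#' germline outgroup row is prepended for rooting.
#'
#' @param calls Mutation call `data.frame` (one patient).
#' @param samples Sample metadata `data.frame` (`sample_id`, `tissue_class`);
#'   at least two non-outgroup samples.
#' @param detection_threshold VAF presence cut-off (default 0.05).
#' @return A `char_matrix`.
#' @export
build_character_matrix <- function(calls, samples, detection_threshold = 0.05) {
  sample_ids <- unique(samples$sample_id)
  if (length(sample_ids) < 2) stop("need at least 2 samples")
  if (OUTGROUP %in% sample_ids) stop("'germline' is reserved for the outgroup")
  keep <- calls$vaf >= detection_threshold
  kept <- calls[keep, , drop = FALSE]
  ids <- mutation_id(kept)
  uids_all <- unique(mutation_id(calls))
  uids <- unique(ids)
  dropped <- setdiff(uids_all, uids)
  if (length(dropped) > 0) {
    message(length(dropped), " mutation(s) below threshold in every sample; dropped")
  }
  if (length(uids) == 0) stop("no variable characters after thresholding")
  mat <- matrix(0L, nrow = length(sample_ids) + 1L, ncol = length(uids),
                dimnames = list(c(OUTGROUP, sample_ids), uids))
  mat[cbind(match(kept$sample_id, sample_ids) + 1L, match(ids, uids))] <- 1L
  first <- kept[!duplicated(ids), , drop = FALSE]
  anno <- data.frame(mutation_id = uids,
                     gene = first$gene[match(uids, mutation_id(first))],
                     effect = first$effect[match(uids, mutation_id(first))],
                     stringsAsFactors = FALSE)
  char_matrix(mat, anno)
}

#' Parsimony fit statistics of a tree for a character matrix
#'
#' Counts, per character, the changes implied by a most-parsimonious (Fitch)
#' reconstruction on the given rooted topology; the minimum possible for a
#' variable binary character is one change, so the consistency index is
#' CI = sum(m_i)/sum(s_i) and the homoplasy index HI = 1 - CI.
#'
#' @param tree `ape::phylo` or `mp_tree`; leaves must match the matrix rows.
#' @param matrix A `char_matrix`.
#' @return A `parsimony_stats` list: `per_character` (`data.frame` of `s` and
#'   `m`), `score`, `ci`, `hi`.
#' @export
fitch_score <- function(tree, matrix) {
  phy <- as_phylo_tree(tree)
  mat <- matrix$mat
  if (!setequal(phy$tip.label, rownames(mat))) {
    stop("tree leaves do not match matrix samples")
  }
  rows <- mat[match(phy$tip.label, rownames(mat)), , drop = FALSE]
  finals <- fitch_finals(phy, rows)
  ch <- abs(finals[phy$edge[, 1], , drop = FALSE] -
            finals[phy$edge[, 2], , drop = FALSE])
  s <- colSums(ch)
  m <- as.integer(colSums(mat) > 0)
  out <- list(per_character = data.frame(mutation_id = colnames(mat),
                                         s = as.integer(s), m = m,
                                         stringsAsFactors = FALSE),
              score = sum(s), ci = sum(m) / sum(s), hi = 1 - sum(m) / sum(s))
  class(out) <- "parsimony_stats"
  out
}

#' @export
print.parsimony_stats <- function(x, ...) {
  cat(sprintf("Parsimony score %d over %d characters; CI = %.3f, HI = %.3f\n",
              x$score, nrow(x$per_character), x$ci, x$hi))
  invisible(x)
}

#' Maximum-parsimony tree search
#'
#' Finds a minimum-change tree for the binary presence/absence matrix, rooted
#' at the all-absent germline outgroup. With at most seven in-group samples
#' every topology is scored exhaustively; larger problems use random-order
#' stepwise addition followed by nearest-neighbour-interchange hill climbing
#' with `restarts` random restarts. Equally parsimonious trees are resolved
#' deterministically to the lexicographically smallest canonical newick.
#' Branch lengths are the changes assigned by a deterministic
#' most-parsimonious reconstruction (keep-parent-state Fitch backtrack).
#'
#' @param matrix A `char_matrix` with 3-20 in-group samples.
#' @param restarts Heuristic random restarts (default 20).
#' @param seed Seed for the heuristic search (default 1).
#' @param method `"auto"` (exhaustive up to seven samples, heuristic beyond),
#'   or force `"exhaustive"` / `"heuristic"`.
#' @return An `mp_tree`: `tree` (`ape::phylo` with integer branch lengths),
#'   `score`, `stats` (`parsimony_stats`), `method`, `n_ties`.
#' @export
search_mp_tree <- function(matrix, restarts = 20, seed = 1,
                           method = c("auto", "exhaustive", "heuristic")) {
  method <- match.arg(method)
  mat <- matrix$mat
  samples <- rownames(mat)[-1]
  k <- length(samples)
  if (k < 3) stop("need at least 3 samples")
  if (k > 20) stop("more than 20 samples not supported")
  labels <- c(samples, OUTGROUP)
  rows <- rbind(mat[-1, , drop = FALSE], mat[1, , drop = FALSE])
  cp <- compress_patterns(rows)
  sets <- cp$pat + 1L
  eng <- fitch_engine(sets)
  og <- k + 1L
  score_fun <- function(subtree) sum(eng(list(subtree, og))$ch * cp$weights)
  res <- mp_search_core(k, score_fun, labels, exhaustive_limit = 7,
                        restarts = restarts, seed = seed, method = method)
  full <- list(res$tree, og)
  phy <- nested_to_phylo(full, labels)
  tip_rows <- cp$pat[match(phy$tip.label, labels), , drop = FALSE]
  finals <- fitch_finals(phy, tip_rows)
  ch <- abs(finals[phy$edge[, 1], , drop = FALSE] -
            finals[phy$edge[, 2], , drop = FALSE])
  phy$edge.length <- as.numeric(ch %*% cp$weights)
  out <- list(tree = phy, score = res$score, method = res$method,
              n_ties = res$n_ties, support = NULL, annotations = NULL)
  class(out) <- "mp_tree"
  out$stats <- fitch_score(phy, matrix)
  out
}

#' @export
print.mp_tree <- function(x, ...) {
  hi <- if (is.null(x$stats)) "" else sprintf(", HI = %.3f", x$stats$hi)
  cat(sprintf("Maximum-parsimony tree (%s search): %d leaves, score %d%s\n",
              x$method, ape::Ntip(x$tree), as.integer(x$score), hi))
  if (!is.null(x$support)) cat("  bootstrap support attached\n")
  if (!is.null(x$annotations) && nrow(x$annotations) > 0) {
    cat("  driver annotations:", nrow(x$annotations), "\n")
  }
  invisible(x)
}

#' Bootstrap clade support
#'
#' Resamples characters (columns) with replacement `B` times, rebuilds the
#' tree for every replicate with the same search settings, and reports for
#' every internal clade of the original tree the percentage of replicates
#' containing it. Bands follow the reporting convention: blank for support
#' above 95, `"+"` for 65-95, `"++"` below 65.
#'
#' @param matrix A `char_matrix`.
#' @param B Number of replicates (>= 1).
#' @param seed Seed controlling resampling (and heuristic search).
#' @param tree Optional pre-built `mp_tree` for the original matrix.
#' @param restarts Search restarts passed through.
#' @return An `mp_tree` whose `support` element is a vector of percentages
#'   named by internal node id, with a `clades` data.frame attribute
#'   (`node`, `clade`, `support`, `band`).
#' @export
bootstrap_support <- function(matrix, B = 1000, seed = 1, tree = NULL,
                              restarts = 20) {
  stopifnot(B >= 1)
  if (is.null(tree)) tree <- search_mp_tree(matrix, restarts = restarts, seed = seed)
  orig_clades <- rooted_clades(tree$tree)
  counts <- setNames(numeric(length(orig_clades)), names(orig_clades))
  set.seed(seed)
  ncols <- ncol(matrix$mat)
  for (b in seq_len(B)) {
    idx <- sample.int(ncols, replace = TRUE)
    sub <- matrix$mat[, idx, drop = FALSE]
    keep <- colSums(sub) > 0
    sub <- sub[, keep, drop = FALSE]
    colnames(sub) <- paste0("c", seq_len(ncol(sub)))
    bm <- char_matrix(sub)
    bt <- search_mp_tree(bm, restarts = restarts, seed = seed + b)
    rep_clades <- rooted_clades(bt$tree)
    counts <- counts + as.numeric(vapply(orig_clades, function(cl) cl %in% rep_clades,
                                         logical(1)))
  }
  support <- 100 * counts / B
  tree$support <- support
  clades <- data.frame(node = as.integer(names(orig_clades)),
                       clade = unlist(orig_clades), support = unname(support),
                       band = support_band(unname(support)),
                       stringsAsFactors = FALSE)
  attr(tree$support, "clades") <- clades
  tree
}

#' Support band labels
#'
#' Blank above 95, `"+"` for 65-95, `"++"` below 65.
#' @param p Numeric support percentages.
#' @return Character vector of band labels.
#' @export
support_band <- function(p) {
  ifelse(p > 95, "", ifelse(p >= 65, "+", "++"))
}

#' Internal clades of a rooted tree as canonical leaf-set strings (internal)
#' @keywords internal
rooted_clades <- function(phy) {
  n_tip <- ape::Ntip(phy)
  po <- ape::reorder.phylo(phy, "postorder")$edge
  below <- vector("list", n_tip + phy$Nnode)
  for (t in seq_len(n_tip)) below[[t]] <- phy$tip.label[t]
  for (i in seq_len(nrow(po))) {
    below[[po[i, 1]]] <- c(below[[po[i, 1]]], below[[po[i, 2]]])
  }
  internal <- setdiff(unique(phy$edge[, 2]), seq_len(n_tip))
  out <- lapply(internal, function(v) paste(sort(below[[v]]), collapse = "|"))
  names(out) <- internal
  out
}

#' Annotate driver mutations onto tree branches
#'
#' Each driver-gene character is placed on the branch(es) where it is gained
#' under a gains-only reconstruction: somatic mutations are not reverted, so
#' a gain is assigned at the root edge of every maximal clade whose leaves
#' all carry the mutation. A single gain branch is the usual case; characters
#' requiring more than one independent gain on this tree (homoplasy,
#' convergent acquisition) are annotated on every gain branch and flagged.
#'
#' @param tree An `mp_tree`.
#' @param matrix The `char_matrix` the tree was built from.
#' @param driver_genes Non-empty character vector of gene symbols.
#' @return The `mp_tree` with an `annotations` data.frame (`edge`, `parent`,
#'   `child`, `mutation_id`, `gene`, `effect`, `homoplastic`).
#' @export
annotate_branches <- function(tree, matrix, driver_genes) {
  if (length(driver_genes) == 0) stop("driver gene list is empty")
  phy <- tree$tree
  mat <- matrix$mat
  rows <- mat[match(phy$tip.label, rownames(mat)), , drop = FALSE]
  n_tip <- ape::Ntip(phy)
  # per node: is every descendant leaf a carrier?
  po <- ape::reorder.phylo(phy, "postorder")$edge
  cols <- which(matrix$anno$gene %in% driver_genes)
  out <- list()
  for (j in cols) {
    all_carrier <- c(rows[, j] == 1L, rep(TRUE, phy$Nnode))
    for (i in seq_len(nrow(po))) {
      all_carrier[po[i, 1]] <- all_carrier[po[i, 1]] && all_carrier[po[i, 2]]
    }
    # gain edges: child clade all-carrier, parent clade not
    gains <- which(all_carrier[phy$edge[, 2]] & !all_carrier[phy$edge[, 1]])
    homo <- length(gains) > 1
    for (e in gains) {
      out[[length(out) + 1]] <- data.frame(
        edge = e, parent = phy$edge[e, 1], child = phy$edge[e, 2],
        mutation_id = matrix$anno$mutation_id[j], gene = matrix$anno$gene[j],
        effect = matrix$anno$effect[j], homoplastic = homo,
        stringsAsFactors = FALSE)
    }
  }
  tree$annotations <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(edge = integer(0), parent = integer(0), child = integer(0),
               mutation_id = character(0), gene = character(0),
               effect = character(0), homoplastic = logical(0))
  tree
}
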