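DIPLOID_REF <- "diploid"

#' Bin copy-number profiles into fixed-width integer-state characters
#'
#' Tiles the autosomes with `bin_size` bins (last bin of each chromosome may
#' be shorter) and assigns every (sample, bin) the length-weighted majority
#' total copy number of the overlapping segments. Ties go to the state closer
#' to 2, then to the lower state. Bins without segment coverage in any sample
#' are dropped from all samples. A synthetic all-2 diploid reference row is
#' included for rooting.
#'
#' @param profiles Segment `data.frame` covering one or more samples
#'   (`sample_id` column).
#' @param layout A `genome_layout`.
#' @param bin_size Bin width in bp (default 500 kbp).
#' @return A `binned_cn` object: `bins` (`data.frame` of `chrom`, `start`,
#'   `end`) and `mat` (samples x bins integer matrix, first row the diploid
#'   reference).
#' @export
bin_profiles <- function(profiles, layout, bin_size = 5e5) {
  stopifnot(bin_size > 0)
  auto <- layout[layout$is_autosome, , drop = FALSE]
  bins <- do.call(rbind, lapply(seq_len(nrow(auto)), function(i) {
    starts <- seq(0, auto$length[i] - 1, by = bin_size)
    data.frame(chrom = auto$chrom[i], start = starts,
               end = pmin(starts + bin_size, auto$length[i]),
               stringsAsFactors = FALSE)
  }))
  samples <- unique(profiles$sample_id)
  n_bins <- nrow(bins)
  offset <- c(0, cumsum(tapply(rep(1, n_bins), factor(bins$chrom, levels = auto$chrom),
                               sum)))
  names(offset) <- c(auto$chrom, "end")
  states <- matrix(NA_integer_, length(samples), n_bins,
                   dimnames = list(samples, NULL))
  max_cn <- max(profiles$cn_total, 2)
  for (si in seq_along(samples)) {
    segs <- autosome_segments(profiles[profiles$sample_id == samples[si], ,
                                       drop = FALSE], layout)
    ov <- matrix(0, n_bins, max_cn + 1L)
    for (j in seq_len(nrow(segs))) {
      ch <- segs$chrom[j]
      b0 <- floor(segs$start[j] / bin_size)
      b1 <- floor((segs$end[j] - 1) / bin_size)
      idx <- (offset[[ch]] + b0 + 1L):(offset[[ch]] + b1 + 1L)
      olap <- pmin(segs$end[j], bins$end[idx]) - pmax(segs$start[j], bins$start[idx])
      ov[idx, segs$cn_total[j] + 1L] <- ov[idx, segs$cn_total[j] + 1L] + olap
    }
    covered <- rowSums(ov) > 0
    st <- rep(NA_integer_, n_bins)
    cand_states <- 0:max_cn
    pref <- order(abs(cand_states - 2), cand_states)  # closer to 2, then lower
    ovp <- ov[, pref, drop = FALSE]
    best <- apply(ovp, 1, which.max)
    st[covered] <- cand_states[pref][best[covered]]
    states[si, ] <- st
  }
  keep <- colSums(is.na(states)) == 0
  bins <- bins[keep, , drop = FALSE]
  rownames(bins) <- NULL
  mat <- rbind(matrix(2L, 1, sum(keep), dimnames = list(DIPLOID_REF, NULL)),
               states[, keep, drop = FALSE])
  structure(list(bins = bins, mat = mat), class = "binned_cn")
}

#' @export
print.binned_cn <- function(x, ...) {
  cat("Binned copy-number matrix:", nrow(x$mat) - 1,
      "samples (+ diploid reference),", ncol(x$mat), "bins\n")
  invisible(x)
}

#' Copy-number parsimony tree
#'
#' Maximum parsimony over the binned integer copy-number states, rooted at
#' the synthetic diploid reference. With the default `"ordered"` (Wagner)
#' cost the change between states a and b costs |a - b|, scored by the
#' Sankoff algorithm; the `"unordered"` mode charges 1 for any change. Search
#' strategy and tie rule are identical to the SNA engine: exhaustive for at
#' most seven samples, stepwise addition plus NNI otherwise, ties resolved to
#' the lexicographically smallest canonical newick. Branch lengths are total
#' state change under a deterministic most-parsimonious assignment.
#'
#' @param binned A `binned_cn` with >= 3 samples.
#' @param cost `"ordered"` (default) or `"unordered"`.
#' @param restarts,seed Heuristic search settings.
#' @param method `"auto"` (exhaustive up to seven samples, heuristic beyond),
#'   or force `"exhaustive"` / `"heuristic"`.
#' @return An `mp_tree` (with `stats = NULL`; the homoplasy index is defined
#'   for the binary SNA engine).
#' @export
cna_tree <- function(binned, cost = c("ordered", "unordered"), restarts = 20,
                     seed = 1, method = c("auto", "exhaustive", "heuristic")) {
  cost <- match.arg(cost)
  method <- match.arg(method)
  mat <- binned$mat
  samples <- rownames(mat)[-1]
  k <- length(samples)
  if (k < 3) stop("need at least 3 samples")
  labels <- c(samples, DIPLOID_REF)
  rows <- rbind(mat[-1, , drop = FALSE], mat[1, , drop = FALSE])
  cp <- compress_patterns(rows)
  n_states <- max(mat) + 1L
  eng <- sankoff_engine(cp$pat, n_states, cost)
  ref <- k + 1L
  score_fun <- function(subtree) {
    C <- eng(list(subtree, ref))
    sum(apply(C, 2, min) * cp$weights)
  }
  res <- mp_search_core(k, score_fun, labels, exhaustive_limit = 7,
                        restarts = restarts, seed = seed, method = method)
  full <- list(res$tree, ref)
  phy <- nested_to_phylo(full, labels)
  tip_rows <- cp$pat[match(phy$tip.label, labels), , drop = FALSE]
  finals <- sankoff_finals(phy, tip_rows, n_states, cost)
  d <- abs(finals[phy$edge[, 1], , drop = FALSE] -
           finals[phy$edge[, 2], , drop = FALSE])
  if (cost == "unordered") d <- (d > 0) * 1
  phy$edge.length <- as.numeric(d %*% cp$weights)
  out <- list(tree = phy, score = res$score, method = res$method,
              n_ties = res$n_ties, support = NULL, annotations = NULL,
              stats = NULL, cost = cost)
  class(out) <- "mp_tree"
  out
}

#' Bootstrap support for a copy-number tree
#'
#' Bin columns are resampled with replacement and the tree rebuilt per
#' replicate; support is the percentage of replicates containing each clade
#' of the original tree. Banding follows [support_band()].
#'
#' @param binned A `binned_cn`.
#' @param B Number of replicates.
#' @param seed Seed.
#' @param tree Optional pre-built tree.
#' @param cost,restarts Passed to [cna_tree()].
#' @return The `mp_tree` with `support` attached (see [bootstrap_support()]).
#' @export
cna_bootstrap <- function(binned, B = 1000, seed = 1, tree = NULL,
                          cost = "ordered", restarts = 20) {
  stopifnot(B >= 1)
  if (is.null(tree)) tree <- cna_tree(binned, cost = cost, restarts = restarts,
                                      seed = seed)
  orig_clades <- rooted_clades(tree$tree)
  counts <- setNames(numeric(length(orig_clades)), names(orig_clades))
  set.seed(seed)
  ncols <- ncol(binned$mat)
  for (b in seq_len(B)) {
    idx <- sample.int(ncols, replace = TRUE)
    rep_binned <- structure(list(bins = binned$bins[idx, , drop = FALSE],
                                 mat = binned$mat[, idx, drop = FALSE]),
                            class = "binned_cn")
    bt <- cna_tree(rep_binned, cost = cost, restarts = restarts,
                   seed = seed + b)
    rep_clades <- rooted_clades(bt$tree)
    counts <- counts + as.numeric(vapply(orig_clades, function(cl) cl %in% rep_clades,
                                         logical(1)))
  }
  support <- 100 * counts / B
  tree$support <- support
  attr(tree$support, "clades") <- data.frame(
    node = as.integer(names(orig_clades)), clade = unlist(orig_clades),
    support = unname(support), band = support_band(unname(support)),
    stringsAsFactors = FALSE)
  tree
}

#' Punctuation profile of a copy-number tree
#'
#' Quantifies the burst-versus-gradual contrast: `trunk_changes` is the total
#' change on the path from the attachment of the LGD lineage down to the
#' most recent common ancestor of the HGD/carcinoma clade, and
#' `mean_branch_changes` is the mean branch length within that clade. Their
#' ratio (`punctuation_ratio = trunk / max(1, mean within-clade)`) is high
#' when copy-number change arrived as a punctuated burst at the LGD to HGD
#' transition and then stabilised, and near 1 under gradual ongoing
#' instability.
#'
#' @param tree An `mp_tree` from [cna_tree()].
#' @param grade_labels Named character vector mapping sample ids to tissue
#'   classes; must include LGD and at least one of HGD/carcinoma.
#' @return List with `trunk_changes`, `mean_branch_changes`,
#'   `punctuation_ratio`, `n_clade_samples`, `low_confidence`.
#' @export
punctuation_profile <- function(tree, grade_labels) {
  phy <- as_phylo_tree(tree)
  lgd <- intersect(names(grade_labels)[grade_labels == "LGD"], phy$tip.label)
  hc <- intersect(names(grade_labels)[grade_labels %in% c("HGD", "carcinoma")],
                  phy$tip.label)
  if (length(lgd) == 0) stop("no LGD sample among the leaves")
  if (length(hc) == 0) stop("no HGD or carcinoma sample among the leaves")
  n_tip <- ape::Ntip(phy)
  parent <- integer(n_tip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  edge_len <- setNames(phy$edge.length, phy$edge[, 2])
  node_b <- if (length(hc) == 1) match(hc, phy$tip.label) else
    ape::getMRCA(phy, hc)
  node_a <- ape::getMRCA(phy, c(lgd, hc))
  low_confidence <- length(hc) == 1
  # trunk: edges from node_b up to (excluding) node_a
  trunk <- 0
  v <- node_b
  while (v != node_a && parent[v] != 0) {
    trunk <- trunk + edge_len[[as.character(v)]]
    v <- parent[v]
  }
  if (node_b == node_a) trunk <- 0
  # within-clade branches: all edges strictly below node_b
  if (length(hc) == 1) {
    within <- edge_len[[as.character(node_b)]]
  } else {
    desc_edges <- which(phy$edge[, 1] == node_b)
    stackv <- phy$edge[desc_edges, 2]
    lens <- numeric(0)
    while (length(stackv) > 0) {
      v <- stackv[1]; stackv <- stackv[-1]
      lens <- c(lens, edge_len[[as.character(v)]])
      stackv <- c(stackv, phy$edge[phy$edge[, 1] == v, 2])
    }
    within <- mean(lens)
  }
  list(trunk_changes = trunk, mean_branch_changes = within,
       punctuation_ratio = trunk / max(1, within),
       n_clade_samples = length(hc), low_confidence = low_confidence)
}
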