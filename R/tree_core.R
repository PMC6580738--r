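# Internal tree machinery shared by the SNA (binary Fitch) and CNA (ordered
# Sankoff) parsimony engines. Trees under search are rooted binary trees over
# the in-group samples, represented as nested lists whose leaves are integer
# taxon indices; the all-ancestral outgroup (germline / diploid reference) is
# attached above the root by the scoring closures. Rooted-NNI moves on the
# in-group tree are exactly unrooted-NNI moves on the full tree with the
# outgroup pendant.

is_leaf <- function(node) !is.list(node)

#' @keywords internal
compress_patterns <- function(mat) {
  # columns -> unique patterns with multiplicities
  key <- apply(mat, 2, paste, collapse = ",")
  uk <- unique(key)
  idx <- match(key, uk)
  pat <- mat[, match(uk, key), drop = FALSE]
  list(pat = pat, weights = as.numeric(tabulate(idx, length(uk))), map = idx)
}

canon_newick <- function(node, labels) {
  if (is_leaf(node)) return(labels[node])
  kids <- sort(vapply(node, canon_newick, character(1), labels = labels))
  paste0("(", paste(kids, collapse = ","), ")")
}

# all rooted binary trees over leaves 1..k (stepwise insertion on every edge,
# including a new root edge)
enumerate_rooted_trees <- function(k) {
  if (k == 1) return(list(1L))
  trees <- list(list(1L, 2L))
  if (k == 2) return(trees)
  for (leaf in 3:k) {
    nxt <- vector("list", 0)
    for (tr in trees) nxt <- c(nxt, insert_leaf_all(tr, leaf))
    trees <- nxt
  }
  trees
}

# insert `leaf` on every edge of rooted tree `node` (including above the root)
insert_leaf_all <- function(node, leaf) {
  out <- list(list(node, leaf))  # above the root
  if (is_leaf(node)) return(out)
  for (i in seq_along(node)) {
    for (sub in insert_leaf_all(node[[i]], leaf)) {
      nn <- node
      nn[[i]] <- sub
      # drop the duplicate "above child root" = "on edge parent-child" — keep;
      # but insert_leaf_all(child) already returns edge(parent,child) as its
      # above-root case, so recursion alone covers each edge exactly once.
      out <- c(out, list(nn))
    }
  }
  out
}

subtree_at <- function(tree, path) {
  for (p in path) tree <- tree[[p]]
  tree
}

replace_at <- function(tree, path, value) {
  if (length(path) == 0) return(value)
  tree[[path[1]]] <- replace_at(tree[[path[1]]], path[-1], value)
  tree
}

# rooted-NNI neighbourhood of a rooted binary nested tree
nni_neighbors <- function(tree) {
  out <- list()
  walk <- function(node, path) {
    if (is_leaf(node)) return(invisible())
    for (i in 1:2) {
      child <- node[[i]]
      if (!is_leaf(child)) {
        sib <- node[[3 - i]]
        a <- child[[1]]; b <- child[[2]]
        out[[length(out) + 1]] <<- replace_at(tree, path, list(a, list(sib, b)))
        out[[length(out) + 1]] <<- replace_at(tree, path, list(b, list(sib, a)))
      }
      walk(child, c(path, i))
    }
  }
  walk(tree, integer(0))
  out
}

# ---- Fitch (binary, unordered) -------------------------------------------

# sets: taxa x P matrix coded 1 = {0}, 2 = {1}; combine children pairwise
fitch_engine <- function(sets) {
  rec <- function(node) {
    if (is_leaf(node)) return(list(set = sets[node, ], ch = 0))
    res <- rec(node[[1]])
    for (i in 2:length(node)) {
      r2 <- rec(node[[i]])
      inter <- bitwAnd(res$set, r2$set)
      un <- bitwOr(res$set, r2$set)
      miss <- inter == 0L
      res <- list(set = ifelse(miss, un, inter), ch = res$ch + r2$ch + miss)
    }
    res
  }
  rec
}

# ---- Sankoff (ordered / unordered multistate) ----------------------------

# leaf costs: states x P, 0 at observed state else Inf
sankoff_leaf_cost <- function(states_row, n_states) {
  m <- matrix(Inf, n_states, length(states_row))
  m[cbind(states_row + 1L, seq_along(states_row))] <- 0
  m
}

min_transform <- function(C, cost = c("ordered", "unordered")) {
  cost <- match.arg(cost)
  if (cost == "unordered") {
    best <- apply(C, 2, min)
    return(pmin(C, rep(best + 1, each = nrow(C))))
  }
  S <- nrow(C)
  if (S > 1) {
    for (s in 2:S) C[s, ] <- pmin(C[s, ], C[s - 1, ] + 1)
    for (s in (S - 1):1) C[s, ] <- pmin(C[s, ], C[s + 1, ] + 1)
  }
  C
}

sankoff_engine <- function(state_mat, n_states, cost = "ordered") {
  rec <- function(node) {
    if (is_leaf(node)) return(sankoff_leaf_cost(state_mat[node, ], n_states))
    acc <- NULL
    for (child in node) {
      tc <- min_transform(rec(child), cost)
      acc <- if (is.null(acc)) tc else acc + tc
    }
    acc
  }
  rec
}

# ---- generic search -------------------------------------------------------

#' @keywords internal
mp_search_core <- function(k, score_fun, labels, exhaustive_limit = 7,
                           restarts = 20, seed = 1,
                           method = c("auto", "exhaustive", "heuristic")) {
  method <- match.arg(method)
  stopifnot(k >= 3)
  if (method == "exhaustive" ||
      (method == "auto" && k <= exhaustive_limit)) {
    if (k > 8) stop("exhaustive enumeration limited to 8 samples")
    trees <- enumerate_rooted_trees(k)
    scores <- vapply(trees, score_fun, numeric(1))
    best <- min(scores)
    cand <- trees[abs(scores - best) < 1e-9]
    strs <- vapply(cand, canon_newick, character(1), labels = labels)
    tree <- cand[[order(strs)[1]]]
    return(list(tree = tree, score = best, n_ties = length(cand),
                method = "exhaustive"))
  }
  set.seed(seed)
  best_tree <- NULL
  best_score <- Inf
  best_str <- NULL
  for (r in seq_len(restarts)) {
    ord <- sample.int(k)
    tr <- list(ord[1], ord[2])
    for (i in 3:k) {
      cands <- insert_leaf_all(tr, ord[i])
      sc <- vapply(cands, score_fun, numeric(1))
      m <- min(sc)
      ties <- cands[abs(sc - m) < 1e-9]
      strs <- vapply(ties, canon_newick, character(1), labels = labels)
      tr <- ties[[order(strs)[1]]]
    }
    cur <- score_fun(tr)
    visited <- canon_newick(tr, labels)
    sideways <- 12L  # plateau moves allowed between improvements
    repeat {
      nb <- nni_neighbors(tr)
      if (length(nb) == 0) break
      sc <- vapply(nb, score_fun, numeric(1))
      m <- min(sc)
      if (m < cur - 1e-9) {
        ties <- nb[abs(sc - m) < 1e-9]
        strs <- vapply(ties, canon_newick, character(1), labels = labels)
        o <- order(strs)[1]
        tr <- ties[[o]]
        visited <- c(visited, strs[o])
        cur <- m
        sideways <- 12L
      } else if (abs(m - cur) < 1e-9 && sideways > 0L) {
        ties <- nb[abs(sc - m) < 1e-9]
        strs <- vapply(ties, canon_newick, character(1), labels = labels)
        new <- setdiff(sort(strs), visited)
        if (length(new) == 0) break
        tr <- ties[[match(new[1], strs)]]
        visited <- c(visited, new[1])
        sideways <- sideways - 1L
      } else break
    }
    str <- canon_newick(tr, labels)
    if (cur < best_score - 1e-9 ||
        (abs(cur - best_score) < 1e-9 && str < best_str)) {
      best_tree <- tr; best_score <- cur; best_str <- str
    }
  }
  list(tree = best_tree, score = best_score, n_ties = NA_integer_,
       method = "heuristic")
}

# ---- nested -> ape::phylo -------------------------------------------------

#' @keywords internal
nested_to_phylo <- function(full, labels) {
  n_tip <- sum(rapply(list(full), function(x) 1L, how = "unlist"))
  edges <- matrix(0L, 0, 2)
  tip_label <- character(0)
  tip_count <- 0L
  node_count <- n_tip  # internal ids start at n_tip + 1
  build <- function(node) {
    if (is_leaf(node)) {
      tip_count <<- tip_count + 1L
      tip_label[tip_count] <<- labels[node]
      return(tip_count)
    }
    node_count <<- node_count + 1L
    my_id <- node_count
    for (child in node) {
      # reserve edge slot, fill after child id known (preorder edge order)
      slot <- nrow(edges) + 1L
      edges <<- rbind(edges, c(my_id, 0L))
      cid <- build(child)
      edges[slot, 2] <<- cid
    }
    my_id
  }
  build(full)
  phy <- list(edge = edges, Nnode = node_count - n_tip, tip.label = tip_label)
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

#' @keywords internal
phylo_to_nested <- function(phy) {
  n_tip <- ape::Ntip(phy)
  root <- n_tip + 1L
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  rec <- function(id) {
    if (id <= n_tip) return(id)
    lapply(kids[[as.character(id)]], rec)
  }
  rec(root)
}

# ---- reconstruction (finals) on a phylo ----------------------------------

# Binary characters: Fitch downpass then keep-parent-state backtrack
# (root forced to the outgroup's all-absent state). Returns nodes x P
# 0/1 matrix of final states, rows indexed by phylo node id.
#' @keywords internal
fitch_finals <- function(phy, state_rows) {
  # state_rows: tips x P matrix of 0/1, rows in tip order
  n_tip <- ape::Ntip(phy)
  n_node <- n_tip + phy$Nnode
  P <- ncol(state_rows)
  sets <- matrix(0L, n_node, P)
  sets[seq_len(n_tip), ] <- state_rows + 1L  # code 1={0}, 2={1}
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    par <- po[i, 1]; child <- po[i, 2]
    if (all(sets[par, ] == 0L)) {
      sets[par, ] <- sets[child, ]
    } else {
      inter <- bitwAnd(sets[par, ], sets[child, ])
      un <- bitwOr(sets[par, ], sets[child, ])
      sets[par, ] <- ifelse(inter == 0L, un, inter)
    }
  }
  finals <- matrix(0L, n_node, P)
  root <- n_tip + 1L
  finals[root, ] <- ifelse(sets[root, ] == 2L, 1L, 0L)  # ambiguous -> ancestral 0
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  for (i in seq_len(nrow(pre))) {
    par <- pre[i, 1]; child <- pre[i, 2]
    pf <- finals[par, ]
    s <- sets[child, ]
    parent_ok <- bitwAnd(s, pf + 1L) > 0L
    finals[child, ] <- ifelse(parent_ok, pf, ifelse(s == 2L, 1L, 0L))
  }
  finals
}

# Ordered multistate: Sankoff downpass cost matrices then deterministic
# backtrack (root preferring states near the reference state 2, then lower).
#' @keywords internal
sankoff_finals <- function(phy, state_rows, n_states, cost = "ordered") {
  n_tip <- ape::Ntip(phy)
  n_node <- n_tip + phy$Nnode
  P <- ncol(state_rows)
  costs <- vector("list", n_node)
  for (t in seq_len(n_tip)) costs[[t]] <- sankoff_leaf_cost(state_rows[t, ], n_states)
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    par <- po[i, 1]; child <- po[i, 2]
    tc <- min_transform(costs[[child]], cost)
    costs[[par]] <- if (is.null(costs[[par]])) tc else costs[[par]] + tc
  }
  root <- n_tip + 1L
  pick <- function(total, ref_state) {
    # deterministic argmin: smallest |s - ref|, then smallest s
    states <- seq_len(nrow(total)) - 1L
    out <- integer(ncol(total))
    for (j in seq_len(ncol(total))) {
      m <- min(total[, j])
      cand <- states[total[, j] <= m + 1e-9]
      cand <- cand[order(abs(cand - ref_state[j]), cand)]
      out[j] <- cand[1]
    }
    out
  }
  finals <- matrix(0L, n_node, P)
  finals[root, ] <- pick(costs[[root]], rep(2L, P))
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  trans_cost <- function(s, t) if (cost == "ordered") abs(s - t) else (s != t) * 1
  for (i in seq_len(nrow(pre))) {
    par <- pre[i, 1]; child <- pre[i, 2]
    if (child <= n_tip) {
      finals[child, ] <- state_rows[child, ]
      next
    }
    C <- costs[[child]]
    states <- seq_len(n_states) - 1L
    pf <- finals[par, ]
    tot <- C + outer(states, pf, trans_cost)
    finals[child, ] <- pick(tot, pf)
  }
  finals
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the non-trivial unrooted splits of the two trees.
#' Leaf sets must match.
#'
#' @param tree_a,tree_b `ape::phylo` or `mp_tree` objects.
#' @return Non-negative integer.
#' @export
rf_distance <- function(tree_a, tree_b) {
  a <- as_phylo_tree(tree_a); b <- as_phylo_tree(tree_b)
  if (!setequal(a$tip.label, b$tip.label)) stop("trees have different leaf sets")
  sa <- tree_splits(a); sb <- tree_splits(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' Non-trivial unrooted splits of a phylo, canonicalised (internal)
#' @keywords internal
tree_splits <- function(phy) {
  n_tip <- ape::Ntip(phy)
  tips <- sort(phy$tip.label)
  root <- n_tip + 1L
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  below <- vector("list", n_tip + phy$Nnode)
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (t in seq_len(n_tip)) below[[t]] <- phy$tip.label[t]
  for (i in seq_len(nrow(po))) {
    par <- po[i, 1]; child <- po[i, 2]
    below[[par]] <- c(below[[par]], below[[child]])
  }
  splits <- character(0)
  internal <- setdiff(unique(phy$edge[, 2]), seq_len(n_tip))
  for (v in internal) {
    side <- sort(below[[v]])
    if (length(side) <= 1 || length(side) >= n_tip - 1) next  # trivial
    if (tips[1] %in% side) side <- setdiff(tips, side)
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}
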