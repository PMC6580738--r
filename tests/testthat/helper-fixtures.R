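# Shared fixture builders: everything is generated in code at test time.

# random binary character matrix with germline outgroup
random_char_matrix <- function(k, n_chars, p = 0.4) {
  m <- matrix(stats::rbinom(k * n_chars, 1, p), nrow = k)
  m <- rbind(0L, m)
  rownames(m) <- c("germline", paste0("S", seq_len(k)))
  colnames(m) <- paste0("c", seq_len(n_chars))
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2) return(NULL)
  char_matrix(m)
}

# random binned integer CN matrix with diploid reference
random_binned <- function(k, n_bins, max_state = 4) {
  mat <- matrix(sample(0:max_state, k * n_bins, replace = TRUE,
                       prob = c(0.05, 0.2, 0.4, 0.25, 0.1)[1:(max_state + 1)]),
                nrow = k)
  mat <- rbind(2L, mat)
  rownames(mat) <- c("diploid", paste0("S", seq_len(k)))
  structure(list(bins = data.frame(chrom = "chr1",
                                   start = (seq_len(n_bins) - 1) * 5e5,
                                   end = seq_len(n_bins) * 5e5),
                 mat = mat), class = "binned_cn")
}

# brute-force minimum parsimony score over every rooted in-group topology,
# independent of the search code path (direct per-tree Fitch via fitch_score)
brute_force_min_score <- function(cm) {
  k <- nrow(cm$mat) - 1
  samples <- rownames(cm$mat)[-1]
  trees <- crcevo:::enumerate_rooted_trees(k)
  labels <- c(samples, "germline")
  best <- Inf
  for (tr in trees) {
    phy <- crcevo:::nested_to_phylo(list(tr, k + 1L), labels)
    s <- fitch_score(phy, cm)$score
    if (s < best) best <- s
  }
  best
}

# quiet simulation defaults used across tests: deterministic counts off CNA
quiet_params <- function(...) {
  sim_params(noise = FALSE,
             cna_rates = c(arm_gain = 0, arm_loss = 0, cnloh = 0),
             drift_bins = 0, punctuated_burst_bins = 0, ...)
}

roles_of <- function(sp) setNames(sp$samples$tissue_class, sp$samples$sample_id)
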