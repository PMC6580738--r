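# Synthetic multiregion patient generator. The observational architecture it
# emulates: a mutational field in non-dysplastic mucosa shared with the
# cancer lineage, a long SNA trunk, progression normal mucosa -> LGD -> HGD
# -> multiregion carcinoma, and copy-number change that can arrive either
# gradually (focal drift + arm events on every branch) or as a punctuated
# burst on the LGD -> HGD transition. All distributional choices are
# stand-ins (the underlying study is observational); they are documented in
# the methods vignette.

#' Simulation parameters
#'
#' Defaults define the standard study conditions: one mucosa, one LGD, one
#' HGD and three carcinoma regions; Poisson SNA counts per clone-tree branch
#' whose means give a long trunk and a truncal/field overlap near 16 percent;
#' epoch-specific signature mixtures over the bundled three-signature set;
#' arm-level CNA events plus small focal drift on every branch and a
#' 200-bin punctuated burst on the LGD to HGD branch; VAF noise as binomial
#' read sampling at the given depth with a 5 percent detection threshold.
#'
#' @param n_carcinoma,n_mucosa,n_lgd,n_hgd Region counts (LGD/HGD at most 1).
#' @param snv_means Named means of Poisson SNA counts per branch type:
#'   `field`, `truncal`, `lgd_hgd`, `hgd_carc`, `shared` (internal carcinoma
#'   branches), `private` (every leaf branch).
#' @param sig_weights 3 x K matrix of signature mixture weights, rows
#'   `precancer`, `truncal`, `branch`, each summing to 1.
#' @param signatures 96 x K signature matrix.
#' @param cna_rates Poisson means per branch for `arm_gain`, `arm_loss`,
#'   `cnloh` events.
#' @param drift_bins Poisson mean of focally drifted bins per branch.
#' @param punctuated_burst_bins Bins changed by the burst on the LGD to HGD
#'   branch (0 disables).
#' @param wgd_prob Probability of whole-genome doubling on the truncal branch.
#' @param detection_threshold VAF at or above which a mutation is called.
#' @param depth Sequencing depth for binomial VAF noise.
#' @param purity Tumour purity of every region.
#' @param noise Logical; disable to make observed VAF exact.
#' @param poisson_counts Logical; `FALSE` makes branch SNA counts exactly
#'   their means (useful for by-construction checks).
#' @param bin_size Copy-number bin width in bp.
#' @param genome A `genome_layout`.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_carcinoma = 3, n_mucosa = 1, n_lgd = 1, n_hgd = 1,
                       snv_means = c(field = 12, truncal = 50, lgd_hgd = 8,
                                     hgd_carc = 7, shared = 15, private = 20),
                       sig_weights = rbind(precancer = c(0.70, 0.25, 0.05),
                                           truncal = c(0.60, 0.30, 0.10),
                                           branch = c(0.40, 0.40, 0.20)),
                       signatures = example_signatures(),
                       cna_rates = c(arm_gain = 0.5, arm_loss = 0.5,
                                     cnloh = 0.25),
                       drift_bins = 5, punctuated_burst_bins = 200,
                       wgd_prob = 0, detection_threshold = 0.05, depth = 100,
                       purity = 0.7, noise = TRUE, poisson_counts = TRUE,
                       bin_size = 5e5, genome = synthetic_genome()) {
  stopifnot(n_carcinoma >= 0, n_mucosa >= 0, n_lgd %in% 0:1, n_hgd %in% 0:1)
  need <- c("field", "truncal", "lgd_hgd", "hgd_carc", "shared", "private")
  if (!all(need %in% names(snv_means))) {
    stop("snv_means must name: ", paste(need, collapse = ", "))
  }
  if (any(snv_means < 0) || any(cna_rates < 0) || drift_bins < 0 ||
      punctuated_burst_bins < 0) stop("all counts/rates must be >= 0")
  if (any(abs(rowSums(sig_weights) - 1) > 1e-9) || any(sig_weights < 0)) {
    stop("signature mixture rows must be non-negative and sum to 1")
  }
  if (ncol(sig_weights) != ncol(signatures)) {
    stop("mixture weight columns must match the signature count")
  }
  if (detection_threshold <= 0 || detection_threshold >= 1) {
    stop("detection threshold must lie in (0,1)")
  }
  if (purity <= 0 || purity > 1) stop("purity must be in (0,1]")
  structure(list(n_carcinoma = n_carcinoma, n_mucosa = n_mucosa,
                 n_lgd = n_lgd, n_hgd = n_hgd, snv_means = snv_means,
                 sig_weights = sig_weights, signatures = signatures,
                 cna_rates = cna_rates, drift_bins = drift_bins,
                 punctuated_burst_bins = punctuated_burst_bins,
                 wgd_prob = wgd_prob,
                 detection_threshold = detection_threshold, depth = depth,
                 purity = purity, noise = noise,
                 poisson_counts = poisson_counts, bin_size = bin_size,
                 genome = genome), class = "sim_params")
}

# sample n channel indices from the mixture S w
#' @keywords internal
sample_channels <- function(n, signatures, weights) {
  p <- as.numeric(signatures %*% weights)
  p <- p / sum(p)
  sample.int(96, n, replace = TRUE, prob = p)
}

# decode a channel index into (ref, alt, context), randomly strand-flipped
#' @keywords internal
decode_channel <- function(idx) {
  lab <- sig_channels()[idx]
  five <- substr(lab, 1, 1)
  ref <- substr(lab, 3, 3)
  alt <- substr(lab, 5, 5)
  three <- substr(lab, 7, 7)
  ctx <- paste0(five, ref, three)
  flip <- stats::runif(length(idx)) < 0.5
  data.frame(ref = ifelse(flip, unname(.rc_base(ref)), ref),
             alt = ifelse(flip, unname(.rc_base(alt)), alt),
             context = ifelse(flip, revcomp(ctx), ctx),
             stringsAsFactors = FALSE)
}

#' Simulate one multiregion patient
#'
#' Builds the clone tree implied by the region counts, draws SNAs per branch
#' from the epoch's signature mixture, applies CNA events (arm gains/losses,
#' cnLOH, focal drift, optional punctuated burst, optional truncal WGD) along
#' each lineage, and emits observed mutation calls with the VAF model
#' `vaf = purity * mult / (purity * cn_total + 2 (1 - purity))` (mult = 1)
#' plus binomial sampling at the configured depth; a mutation is called in a
#' sample when the sampled VAF reaches the detection threshold. Deterministic
#' given `(params, seed)`.
#'
#' @param params A `sim_params`.
#' @param seed Integer seed.
#' @param patient_id Patient label.
#' @return A `synthetic_patient`: `samples`, `calls`, `segments` and a
#'   `truth` list (`tree` as `ape::phylo` incl. the germline leaf, per-branch
#'   tables, per-mutation truth labels, CNA event log, bin table).
#' @export
simulate_patient <- function(params, seed = 1, patient_id = "P1") {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_carcinoma < 1) stop("at least one carcinoma region is required")
  set.seed(seed)
  layout <- params$genome
  bin_size <- params$bin_size
  bins <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    starts <- seq(0, layout$length[i] - 1, by = bin_size)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = pmin(starts + bin_size, layout$length[i]),
               stringsAsFactors = FALSE)
  }))
  n_bins <- nrow(bins)
  arms <- genome_arms(layout, autosomes_only = FALSE)
  bin_arm <- arms$arm[vapply(seq_len(n_bins), function(i) {
    which(arms$chrom == bins$chrom[i] & arms$start <= bins$start[i] &
          arms$end >= bins$end[i])[1]
  }, integer(1))]

  # ---- samples and clone-tree scaffold -----------------------------------
  mk <- function(prefix, n) if (n > 0) paste0(patient_id, "_", prefix,
                                              seq_len(n)) else character(0)
  muc <- mk("MUC", params$n_mucosa)
  lgd <- mk("LGD", params$n_lgd)
  hgd <- mk("HGD", params$n_hgd)
  car <- mk("CA", params$n_carcinoma)
  samples <- data.frame(
    sample_id = c(muc, lgd, hgd, car), patient_id = patient_id,
    tissue_class = c(rep("normal_mucosa", length(muc)),
                     rep("LGD", length(lgd)), rep("HGD", length(hgd)),
                     rep("carcinoma", length(car))),
    purity = params$purity, stringsAsFactors = FALSE)

  # branches: child node name, parent node name, type, epoch, leaf sample
  branches <- list()
  add_branch <- function(child, parent, type, epoch, leaf = NA_character_) {
    branches[[length(branches) + 1]] <<- data.frame(
      branch = child, parent = parent, type = type, epoch = epoch,
      leaf = leaf, stringsAsFactors = FALSE)
  }
  add_branch("A", "root", "field", "precancer")
  for (s in muc) add_branch(s, "A", "private", "precancer", s)
  add_branch("T", "A", "truncal", "truncal")
  for (s in lgd) add_branch(s, "T", "private", "branch", s)
  pre_c <- "T"
  if (length(hgd) > 0) {
    add_branch("H", "T", "lgd_hgd", "truncal")
    for (s in hgd) add_branch(s, "H", "private", "branch", s)
    pre_c <- "H"
  }
  add_branch("C1", pre_c, if (length(hgd) > 0) "hgd_carc" else "lgd_hgd",
             "truncal")
  # pectinate carcinoma subtree: C1 -> (CA1, C2), C2 -> (CA2, C3), ...
  for (i in seq_along(car)) {
    node <- paste0("C", i)
    add_branch(car[i], node, "private", "branch", car[i])
    if (i < length(car) - 1) {
      add_branch(paste0("C", i + 1), node, "shared", "branch")
    } else if (i == length(car) - 1) {
      add_branch(car[i + 1], node, "private", "branch", car[i + 1])
      break
    }
  }
  branches <- do.call(rbind, branches)
  burst_branch <- if (length(hgd) > 0) "H" else "C1"

  # ---- SNAs per branch ----------------------------------------------------
  mean_of <- function(type) params$snv_means[[type]]
  n_snv <- vapply(seq_len(nrow(branches)), function(i) {
    m <- mean_of(branches$type[i])
    if (params$poisson_counts) stats::rpois(1, m) else as.integer(round(m))
  }, integer(1))
  effect_levels <- c("missense", "nonsense", "frameshift", "splice",
                     "synonymous", "other")
  effect_probs <- c(0.55, 0.08, 0.07, 0.05, 0.20, 0.05)
  mut_rows <- list()
  mid <- 0L
  for (i in seq_len(nrow(branches))) {
    n <- n_snv[i]
    if (n == 0) next
    w <- params$sig_weights[branches$epoch[i], ]
    ch <- sample_channels(n, params$signatures, w)
    dec <- decode_channel(ch)
    ci <- sample.int(nrow(layout), n, replace = TRUE, prob = layout$length)
    pos <- floor(stats::runif(n) * (layout$length[ci] - 2)) + 2
    eff <- sample(effect_levels, n, replace = TRUE, prob = effect_probs)
    is_indel <- eff == "frameshift"
    ref <- dec$ref; alt <- dec$alt; ctx <- dec$context
    ins <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt[is_indel] <- paste0(ref[is_indel], ins[is_indel])
    ctx[is_indel] <- NA_character_
    gene <- paste0("G", sprintf("%03d", sample.int(150, n, replace = TRUE)))
    ppos <- ifelse(eff %in% c("missense", "nonsense"),
                   sample.int(450, n, replace = TRUE), NA_integer_)
    mut_rows[[length(mut_rows) + 1]] <- data.frame(
      mutation_uid = paste0("M", sprintf("%04d", mid + seq_len(n))),
      branch = branches$branch[i], chrom = layout$chrom[ci], pos = pos,
      ref = ref, alt = alt, context = ctx, gene = gene, effect = eff,
      protein_pos = ppos, stringsAsFactors = FALSE)
    mid <- mid + n
  }
  muts <- if (length(mut_rows) > 0) do.call(rbind, mut_rows) else
    stop("simulation produced no mutations; increase snv_means")

  # ---- CNA events along branches -----------------------------------------
  parent_of <- setNames(branches$parent, branches$branch)
  cn_state <- list(root = list(total = rep(2L, n_bins), minor = rep(1L, n_bins)))
  events <- list()
  log_event <- function(branch, type, arm, n_changed, delta) {
    events[[length(events) + 1]] <<- data.frame(
      branch = branch, type = type, arm = arm, bins_changed = n_changed,
      delta = delta, stringsAsFactors = FALSE)
  }
  topo <- branches$branch  # parents always precede children by construction
  burst_changed <- 0L
  for (b in topo) {
    st <- cn_state[[parent_of[[b]]]]
    total <- st$total; minor <- st$minor
    if (b == "T" && stats::runif(1) < params$wgd_prob) {
      total <- 2L * total; minor <- 2L * minor
      log_event(b, "wgd", NA, n_bins, NA)
    }
    for (ev in c("arm_gain", "arm_loss", "cnloh")) {
      k <- stats::rpois(1, params$cna_rates[[ev]])
      for (j in seq_len(k)) {
        arm <- sample(unique(bin_arm), 1)
        idx <- which(bin_arm == arm)
        if (ev == "arm_gain") {
          total[idx] <- total[idx] + 1L
          log_event(b, ev, arm, length(idx), 1)
        } else if (ev == "arm_loss") {
          can <- idx[total[idx] > 0]
          minor[can] <- pmax(minor[can] - 1L, 0L)
          total[can] <- total[can] - 1L
          log_event(b, ev, arm, length(can), -1)
        } else {
          can <- idx[total[idx] == 2L & minor[idx] == 1L]
          minor[can] <- 0L
          log_event(b, ev, arm, length(can), 0)
        }
      }
    }
    nd <- stats::rpois(1, params$drift_bins)
    while (nd > 0) {
      len <- min(nd, sample.int(5, 1))
      arm <- sample(unique(bin_arm), 1)
      idx <- which(bin_arm == arm)
      if (length(idx) < len) { nd <- nd - 1; next }
      s0 <- sample.int(length(idx) - len + 1, 1)
      run <- idx[s0:(s0 + len - 1)]
      delta <- if (any(total[run] == 0L)) 1L else sample(c(-1L, 1L), 1)
      total[run] <- total[run] + delta
      if (delta < 0) minor[run] <- pmin(minor[run], total[run] %/% 2L)
      log_event(b, "drift", arm, len, delta)
      nd <- nd - len
    }
    if (b == burst_branch && params$punctuated_burst_bins > 0) {
      target <- params$punctuated_burst_bins
      changed <- rep(FALSE, n_bins)
      guard <- 0L
      while (sum(changed) < target && guard < 10000L) {
        guard <- guard + 1L
        remaining <- target - sum(changed)
        len <- min(remaining, sample(20:60, 1))
        arm <- sample(unique(bin_arm), 1)
        idx <- which(bin_arm == arm & !changed)
        if (length(idx) < 1) next
        len <- min(len, length(idx))
        s0 <- sample.int(length(idx) - len + 1, 1)
        run <- idx[s0:(s0 + len - 1)]
        delta <- if (any(total[run] == 0L)) 1L else
          sample(c(-1L, 1L), 1, prob = c(0.4, 0.6))
        total[run] <- total[run] + delta
        if (delta < 0) minor[run] <- pmin(minor[run], total[run] %/% 2L)
        changed[run] <- TRUE
        log_event(b, "burst", arm, len, delta)
      }
      burst_changed <- sum(changed)
    }
    cn_state[[b]] <- list(total = total, minor = minor)
  }
  events <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(branch = character(0), type = character(0), arm = character(0),
               bins_changed = integer(0), delta = numeric(0))

  # ---- leaf CN profiles as merged segments -------------------------------
  seg_rows <- list()
  leaf_branches <- branches$branch[!is.na(branches$leaf)]
  for (b in leaf_branches) {
    st <- cn_state[[b]]
    key <- paste(bins$chrom, st$total, st$minor)
    brk <- c(TRUE, key[-1] != key[-n_bins])
    grp <- cumsum(brk)
    seg_rows[[length(seg_rows) + 1]] <- data.frame(
      sample_id = b,
      chrom = tapply(bins$chrom, grp, `[`, 1),
      start = tapply(bins$start, grp, min),
      end = tapply(bins$end, grp, max),
      cn_total = as.integer(tapply(st$total, grp, `[`, 1)),
      cn_minor = as.integer(tapply(st$minor, grp, `[`, 1)),
      stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL
  attr(segments, "dialect") <- "allele_specific"

  # ---- observed mutation calls -------------------------------------------
  desc_leaves <- function(b) {
    kids <- branches$branch[branches$parent == b]
    leaf <- branches$leaf[branches$branch == b]
    out <- if (!is.na(leaf)) leaf else character(0)
    for (k in kids) out <- c(out, desc_leaves(k))
    out
  }
  carriers <- lapply(setNames(branches$branch, branches$branch), desc_leaves)
  bin_index <- function(chrom, pos) {
    which(bins$chrom == chrom & bins$start < pos & bins$end >= pos)[1]
  }
  mut_bin <- vapply(seq_len(nrow(muts)),
                    function(i) bin_index(muts$chrom[i], muts$pos[i]),
                    integer(1))
  call_rows <- list()
  for (s in samples$sample_id) {
    carried <- vapply(muts$branch, function(b) s %in% carriers[[b]], logical(1))
    idx <- which(carried)
    if (length(idx) == 0) next
    totals <- cn_state[[s]]$total[mut_bin[idx]]
    p <- params$purity
    vaf_true <- ifelse(totals == 0, 0, p * 1 / (p * totals + 2 * (1 - p)))
    vaf_obs <- if (params$noise) {
      stats::rbinom(length(idx), params$depth, vaf_true) / params$depth
    } else vaf_true
    keep <- vaf_obs >= params$detection_threshold
    if (!any(keep)) next
    ii <- idx[keep]
    call_rows[[length(call_rows) + 1]] <- data.frame(
      sample_id = s, patient_id = patient_id,
      tissue_class = samples$tissue_class[samples$sample_id == s],
      chrom = muts$chrom[ii], pos = muts$pos[ii], ref = muts$ref[ii],
      alt = muts$alt[ii], gene = muts$gene[ii], effect = muts$effect[ii],
      protein_pos = muts$protein_pos[ii], vaf = vaf_obs[keep],
      context = muts$context[ii], stringsAsFactors = FALSE)
  }
  calls <- if (length(call_rows) > 0) do.call(rbind, call_rows) else
    stop("no mutation detected in any sample; lower the detection threshold")
  rownames(calls) <- NULL

  # ---- truth labels and tree ---------------------------------------------
  carc <- samples$sample_id[samples$tissue_class == "carcinoma"]
  mucs <- samples$sample_id[samples$tissue_class == "normal_mucosa"]
  n_in_carc <- vapply(muts$branch,
                      function(b) length(intersect(carriers[[b]], carc)),
                      integer(1))
  in_muc <- vapply(muts$branch,
                   function(b) length(intersect(carriers[[b]], mucs)) > 0,
                   logical(1))
  pattern <- rep(NA_character_, nrow(muts))
  pattern[n_in_carc == length(carc)] <- "truncal"
  pattern[n_in_carc > 0 & n_in_carc < length(carc)] <-
    ifelse(n_in_carc[n_in_carc > 0 & n_in_carc < length(carc)] == 1,
           "private", "shared_subclonal")
  mut_truth <- data.frame(
    mutation_uid = muts$mutation_uid,
    mutation_id = paste(muts$chrom, muts$pos, muts$ref, muts$alt, sep = ":"),
    branch = muts$branch, epoch = branches$epoch[match(muts$branch, branches$branch)],
    cancer_pattern = pattern, in_mucosa = in_muc,
    mucosa_only = in_muc & n_in_carc == 0, stringsAsFactors = FALSE)

  truth_tree <- build_truth_phylo(branches, n_snv)

  structure(list(patient_id = patient_id, params = params, seed = seed,
                 samples = samples, calls = calls, segments = segments,
                 truth = list(tree = truth_tree, branches = cbind(branches, n_snv),
                              mutations = cbind(muts, mut_truth[
                                c("cancer_pattern", "in_mucosa", "mucosa_only",
                                  "epoch", "mutation_id")]),
                              cna_events = events, bins = bins,
                              burst_branch = burst_branch,
                              burst_bins_changed = burst_changed)),
            class = "synthetic_patient")
}

#' @keywords internal
build_truth_phylo <- function(branches, n_snv) {
  # nested list over sample leaves + germline, branch lengths = SNA counts
  kids_of <- split(branches$branch, branches$parent)
  rec <- function(node) {
    row <- which(branches$branch == node)
    leaf <- branches$leaf[row]
    kids <- kids_of[[node]]
    if (!is.na(leaf) && is.null(kids)) return(leaf)
    sub <- lapply(kids, rec)
    if (length(sub) == 1) sub[[1]] else sub
  }
  top <- kids_of[["root"]]
  nested <- lapply(top, rec)
  nested <- if (length(nested) == 1) nested[[1]] else nested
  full <- list(nested, "germline")
  labels_all <- c(stats::na.omit(branches$leaf), "germline")
  # nested uses labels directly; convert via an index mapping
  relabel <- function(node) {
    if (!is.list(node)) return(match(node, labels_all))
    lapply(node, relabel)
  }
  phy <- nested_to_phylo(relabel(full), labels_all)
  phy$edge.length <- rep(0, nrow(phy$edge))
  phy
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat("Synthetic patient", x$patient_id, "—", nrow(x$samples), "regions,",
      length(unique(x$truth$mutations$mutation_uid)), "true mutations,",
      nrow(x$truth$cna_events), "CNA events\n")
  invisible(x)
}

#' Simulate a cohort of multiregion patients
#'
#' Per-patient seeds are drawn from the master seed, logged in the result,
#' and reusable individually: re-simulating a patient from its logged seed
#' reproduces it exactly.
#'
#' @param params_list Non-empty list of `sim_params` (recycled if a single
#'   `sim_params` is given together with `n`).
#' @param seed Master seed.
#' @param n Number of patients when `params_list` is a single `sim_params`.
#' @param patient_ids Optional patient labels.
#' @return List of `synthetic_patient` objects, with a `seeds` attribute.
#' @export
simulate_cohort <- function(params_list, seed = 1, n = NULL,
                            patient_ids = NULL) {
  if (inherits(params_list, "sim_params")) {
    if (is.null(n)) stop("give n when supplying a single sim_params")
    params_list <- rep(list(params_list), n)
  }
  if (length(params_list) == 0) stop("empty parameter list")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(params_list))
  if (is.null(patient_ids)) {
    patient_ids <- paste0("P", sprintf("%02d", seq_along(params_list)))
  }
  out <- Map(function(p, s, id) simulate_patient(p, seed = s, patient_id = id),
             params_list, seeds, patient_ids)
  attr(out, "seeds") <- seeds
  out
}
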