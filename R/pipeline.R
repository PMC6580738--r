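#' Pipeline configuration
#'
#' Bundles the tunable parameters of the per-patient and cohort analyses.
#'
#' @param detection_threshold VAF presence cut-off for the character matrix.
#' @param footprint_mb Callable exome footprint (Mb) for SNAs/Mb.
#' @param msi_threshold SNAs/Mb flagging a hypermutated (MSI-like) sample.
#' @param signature_subset Signature names/indices to fit (default all).
#' @param bin_size Copy-number bin width (bp).
#' @param bootstrap_B Bootstrap replicates (0 disables bootstrap).
#' @param arm_threshold Arm-call fraction threshold.
#' @param restarts Heuristic tree-search restarts.
#' @param seed Seed for every stochastic step.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(detection_threshold = 0.05, footprint_mb = 34.7,
                            msi_threshold = 10, signature_subset = NULL,
                            bin_size = 5e5, bootstrap_B = 100,
                            arm_threshold = 0.5, restarts = 20, seed = 1) {
  structure(list(detection_threshold = detection_threshold,
                 footprint_mb = footprint_mb, msi_threshold = msi_threshold,
                 signature_subset = signature_subset, bin_size = bin_size,
                 bootstrap_B = bootstrap_B, arm_threshold = arm_threshold,
                 restarts = restarts, seed = seed),
            class = "pipeline_config")
}

#' Run the full per-patient analysis
#'
#' Orchestrates, for one patient: SNA character matrix and maximum-parsimony
#' tree (with bootstrap support), clonality classification and field overlap,
#' per-sample mutation burden, per-epoch signature fits, per-sample
#' copy-number burden and ploidy, binned copy-number parsimony tree, and the
#' punctuation profile. Missing inputs degrade gracefully: stages whose
#' inputs are absent are skipped and recorded in the manifest. When
#' `out_dir` is given, tables (TSV), trees (newick) and a JSON manifest are
#' written there.
#'
#' @param patient_id Patient to analyse.
#' @param calls Cohort or patient mutation call `data.frame`.
#' @param samples Sample metadata `data.frame` (`sample_id`, `patient_id`,
#'   `tissue_class`).
#' @param segments Optional segment `data.frame`.
#' @param layout A `genome_layout`.
#' @param signatures 96 x K signature matrix.
#' @param config A `pipeline_config`.
#' @param out_dir Optional output directory.
#' @return A report bundle (list) with elements `tree`, `clonality`,
#'   `field_overlap`, `burden`, `signature_fits`, `cn_burden`, `cna_tree`,
#'   `punctuation`, `manifest`.
#' @export
run_patient <- function(patient_id, calls, samples, segments = NULL,
                        layout = synthetic_genome(),
                        signatures = example_signatures(),
                        config = pipeline_config(), out_dir = NULL) {
  t0 <- Sys.time()
  notes <- character(0)
  note <- function(msg) notes <<- c(notes, msg)
  calls <- calls[calls$patient_id == patient_id, , drop = FALSE]
  samples <- samples[samples$patient_id == patient_id, , drop = FALSE]
  if (nrow(calls) == 0) stop("patient ", patient_id, " absent from inputs")
  roles <- setNames(samples$tissue_class, samples$sample_id)
  bundle <- list(patient_id = patient_id)

  cm <- tryCatch(build_character_matrix(calls, samples,
                                        config$detection_threshold),
                 error = function(e) { note(paste("matrix:", conditionMessage(e)))
                                       NULL })
  if (!is.null(cm)) {
    bundle$matrix <- cm
    tr <- tryCatch({
      tr <- search_mp_tree(cm, restarts = config$restarts, seed = config$seed)
      if (config$bootstrap_B > 0) {
        tr <- bootstrap_support(cm, B = config$bootstrap_B, seed = config$seed,
                                tree = tr, restarts = config$restarts)
      }
      tr
    }, error = function(e) { note(paste("sna_tree:", conditionMessage(e))); NULL })
    bundle$tree <- tr
    bundle$clonality <- tryCatch(classify_clonality(cm, roles),
                                 error = function(e) {
                                   note(paste("clonality:", conditionMessage(e)))
                                   NULL })
    if (!is.null(bundle$clonality)) {
      bundle$field_overlap <- suppressWarnings(
        field_overlap_fraction(bundle$clonality))
      bundle$signature_fits <- fit_by_epoch(calls, bundle$clonality,
                                            signatures,
                                            subset = config$signature_subset)
    }
  }
  bundle$burden <- do.call(rbind, lapply(samples$sample_id, function(s) {
    b <- mutation_burden(calls, s, config$footprint_mb, config$msi_threshold)
    data.frame(sample_id = s, tissue_class = roles[[s]],
               n_nonsyn = b$n_nonsyn, snas_per_mb = b$snas_per_mb,
               msi_flag = b$msi_flag, stringsAsFactors = FALSE)
  }))

  if (!is.null(segments)) {
    segs <- segments[segments$sample_id %in% samples$sample_id, , drop = FALSE]
    if (nrow(segs) > 0) {
      bundle$cn_burden <- do.call(rbind, lapply(unique(segs$sample_id),
        function(s) {
          prof <- segs[segs$sample_id == s, , drop = FALSE]
          bp <- pga(prof, layout)
          pl <- ploidy_summary(prof, layout)
          data.frame(sample_id = s, tissue_class = roles[[s]],
                     pga_full = bp$pga_full, pga_gl = bp$pga_gl,
                     psi = pl$psi, ploidy_class = pl$ploidy_class,
                     stringsAsFactors = FALSE)
        }))
      bundle$arm_calls <- lapply(setNames(nm = unique(segs$sample_id)),
        function(s) arm_calls(segs[segs$sample_id == s, , drop = FALSE],
                              layout, config$arm_threshold))
      binned <- bin_profiles(segs, layout, config$bin_size)
      bundle$binned <- binned
      if (nrow(binned$mat) - 1 >= 3) {
        ct <- tryCatch({
          ct <- cna_tree(binned, restarts = config$restarts, seed = config$seed)
          if (config$bootstrap_B > 0) {
            ct <- cna_bootstrap(binned, B = config$bootstrap_B,
                                seed = config$seed, tree = ct,
                                restarts = config$restarts)
          }
          ct
        }, error = function(e) { note(paste("cna_tree:", conditionMessage(e)))
                                 NULL })
        bundle$cna_tree <- ct
        if (!is.null(ct)) {
          bundle$punctuation <- tryCatch(punctuation_profile(ct, roles),
            error = function(e) { note(paste("punctuation:",
                                             conditionMessage(e))); NULL })
        }
      } else note("cna_tree: fewer than 3 samples with segments")
    } else note("cn: no segments for this patient")
  } else note("cn: segments not provided; CN stages skipped")

  bundle$manifest <- list(
    patient_id = patient_id,
    package_version = as.character(utils::packageVersion("crcevo")),
    r_version = R.version.string,
    parameters = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    n_calls = nrow(calls), n_samples = nrow(samples),
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = notes)

  if (!is.null(out_dir)) write_patient_bundle(bundle, out_dir)
  bundle
}

#' @keywords internal
write_patient_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pfx <- file.path(out_dir, bundle$patient_id)
  wtab <- function(x, name) if (!is.null(x)) {
    utils::write.table(x, paste0(pfx, "_", name, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$tree)) write_newick(bundle$tree, paste0(pfx, "_sna_tree.nwk"))
  if (!is.null(bundle$cna_tree)) {
    write_newick(bundle$cna_tree, paste0(pfx, "_cna_tree.nwk"))
  }
  wtab(bundle$clonality, "clonality")
  wtab(bundle$burden, "burden")
  wtab(bundle$cn_burden, "cn_burden")
  if (!is.null(bundle$signature_fits)) {
    sf <- do.call(rbind, lapply(names(bundle$signature_fits), function(ep) {
      f <- bundle$signature_fits[[ep]]
      data.frame(epoch = ep, signature = names(f$exposures),
                 exposure = unname(f$exposures),
                 relative = unname(f$relative), r2 = f$r2,
                 stringsAsFactors = FALSE)
    }))
    wtab(sf, "signatures")
  }
  jsonlite::write_json(bundle$manifest, paste0(pfx, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run the cohort-level analysis
#'
#' Aggregates per-patient bundles: per-gene mutation frequency tables with
#' Fisher + Benjamini-Hochberg comparison between two cohort labels,
#' arm-level frequency comparison, copy-number burden by lesion grade
#' (Kruskal-Wallis + pairwise Mann-Whitney), and median (range) summaries.
#' With a single cohort label the between-cohort comparisons are skipped.
#'
#' @param bundles Non-empty list of [run_patient()] bundles.
#' @param calls Cohort mutation call `data.frame` (for gene frequencies).
#' @param cohort_of Named character vector patient_id -> cohort label.
#' @return List with `gene_frequencies`, `gene_comparison`, `arm_comparison`,
#'   `burden_by_grade`, `summaries`.
#' @export
run_cohort <- function(bundles, calls, cohort_of) {
  if (length(bundles) == 0) stop("empty cohort")
  if (length(bundles) < 2) stop("need at least 2 patients")
  pids <- vapply(bundles, `[[`, character(1), "patient_id")
  labels <- cohort_of[pids]
  out <- list()
  freq_tabs <- lapply(split(pids, labels), function(ids) {
    gene_frequency_table(calls[calls$patient_id %in% ids, , drop = FALSE])
  })
  out$gene_frequencies <- freq_tabs
  if (length(unique(labels)) >= 2) {
    ll <- names(freq_tabs)[1:2]
    out$gene_comparison <- compare_gene_frequencies(freq_tabs[[ll[1]]],
                                                    freq_tabs[[ll[2]]])
    arm_lists <- lapply(ll, function(l) {
      unlist(lapply(bundles[labels == l], `[[`, "arm_calls"),
             recursive = FALSE)
    })
    if (all(lengths(arm_lists) > 0)) {
      out$arm_comparison <- compare_arm_frequencies(arm_lists[[1]],
                                                    arm_lists[[2]])
    }
  }
  cnb <- do.call(rbind, lapply(bundles, `[[`, "cn_burden"))
  if (!is.null(cnb) && nrow(cnb) > 0) {
    grades <- intersect(c("normal_mucosa", "LGD", "HGD", "carcinoma"),
                        unique(cnb$tissue_class))
    groups <- lapply(setNames(nm = grades),
                     function(g) cnb$pga_full[cnb$tissue_class == g])
    groups <- groups[lengths(groups) > 0]
    if (length(groups) >= 2) out$burden_by_grade <- burden_by_grade(groups)
  }
  burden <- do.call(rbind, lapply(bundles, `[[`, "burden"))
  fmt <- function(x) if (length(x) == 0 || all(is.na(x))) NA_character_ else
    sprintf("%.1f (range %.1f-%.1f)", stats::median(x, na.rm = TRUE),
            min(x, na.rm = TRUE), max(x, na.rm = TRUE))
  carc <- burden$tissue_class == "carcinoma"
  fo <- vapply(bundles, function(b)
    if (is.null(b$field_overlap)) NA_real_ else b$field_overlap, numeric(1))
  out$summaries <- list(
    snas_per_mb_carcinoma = fmt(burden$snas_per_mb[carc]),
    field_overlap_pct = fmt(100 * fo),
    pga_full_carcinoma = if (!is.null(cnb))
      fmt(100 * cnb$pga_full[cnb$tissue_class == "carcinoma"]) else NA)
  out
}
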