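#' Tally a 96-channel mutation catalogue
#'
#' Counts single-base substitutions into the fixed pyrimidine-centred channel
#' order; purine-centred calls are reverse complemented. Indels and calls
#' with unknown context are skipped and counted in the `n_skipped` attribute.
#' Calls appearing in several samples of one patient are counted once per
#' row supplied; deduplicate beforehand if a per-patient catalogue is wanted.
#'
#' @param calls Mutation call `data.frame`.
#' @param label Provenance label stored on the catalogue.
#' @return Integer vector of length 96 (named by channel) of class
#'   `mutation_catalogue`, with attributes `label` and `n_skipped`.
#' @export
tally_96 <- function(calls, label = "catalogue") {
  idx <- channel_index(calls$ref, calls$alt, calls$context)
  counts <- tabulate(idx, nbins = 96)
  out <- setNames(as.integer(counts), sig_channels())
  attr(out, "label") <- label
  attr(out, "n_skipped") <- sum(is.na(idx))
  class(out) <- "mutation_catalogue"
  out
}

#' Fit non-negative signature exposures to a catalogue
#'
#' Solves `min ||c - S e||^2` subject to `e >= 0` by active-set non-negative
#' least squares over the chosen signature subset. The goodness of fit is the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot`; by default the
#' total sum of squares is taken about the catalogue mean (`"centered"`), with
#' an `"uncentered"` alternative about zero.
#'
#' @param catalogue 96-vector of channel counts (a `mutation_catalogue` or
#'   plain numeric).
#' @param signatures 96 x K signature matrix.
#' @param subset Signature names or indices to fit (default all).
#' @param r2 R-squared convention, `"centered"` (default) or `"uncentered"`.
#' @return A `signature_fit` list: `exposures` (absolute, mutation units),
#'   `relative`, `r2`, `residuals`, `n_mutations`, `r2_convention`. An
#'   all-zero catalogue yields zero exposures and `r2 = NA` with
#'   `degenerate = TRUE`.
#' @export
fit_exposures <- function(catalogue, signatures, subset = NULL,
                          r2 = c("centered", "uncentered")) {
  r2 <- match.arg(r2)
  c_vec <- as.numeric(catalogue)
  if (length(c_vec) != nrow(signatures)) {
    stop("catalogue length does not match signature matrix rows")
  }
  if (is.null(subset)) subset <- seq_len(ncol(signatures))
  S <- signatures[, subset, drop = FALSE]
  if (ncol(S) == 0) stop("signature subset is empty")
  if (sum(c_vec) == 0) {
    out <- list(exposures = setNames(rep(0, ncol(S)), colnames(S)),
                relative = setNames(rep(NA_real_, ncol(S)), colnames(S)),
                r2 = NA_real_, residuals = c_vec, n_mutations = 0,
                r2_convention = r2, degenerate = TRUE)
    class(out) <- "signature_fit"
    return(out)
  }
  e <- pracma::lsqnonneg(S, c_vec)$x
  fitted <- as.numeric(S %*% e)
  resid <- c_vec - fitted
  ss_res <- sum(resid^2)
  ss_tot <- if (r2 == "centered") sum((c_vec - mean(c_vec))^2) else sum(c_vec^2)
  out <- list(exposures = setNames(e, colnames(S)),
              relative = setNames(if (sum(e) > 0) e / sum(e) else rep(NA_real_, length(e)),
                                  colnames(S)),
              r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
              residuals = resid, n_mutations = sum(c_vec),
              r2_convention = r2, degenerate = FALSE)
  class(out) <- "signature_fit"
  out
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Signature fit over", x$n_mutations, "mutations;",
      if (is.na(x$r2)) "R2 undefined" else sprintf("R2 = %.3f", x$r2), "\n")
  if (!x$degenerate) {
    rel <- round(100 * x$relative, 1)
    cat(paste0("  ", names(rel), ": ", rel, "%", collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Fit signature exposures separately per clonality epoch
#'
#' Partitions a patient's mutations into three temporal epochs — `field`
#' (present in the surrounding mucosa, the precancer compartment), `truncal`
#' (clonal in the carcinoma but absent from mucosa) and `branch`
#' (shared-subclonal and private) — and fits each catalogue independently.
#' Epochs with no context-bearing substitutions are skipped with a message.
#'
#' @param calls Mutation call `data.frame` for the patient (rows may repeat a
#'   mutation across samples; each mutation is counted once).
#' @param clonality_records Output of [classify_clonality()].
#' @param signatures 96 x K signature matrix.
#' @param subset Signature subset passed to [fit_exposures()].
#' @param r2 R-squared convention.
#' @return Named list of `signature_fit` objects (subset of `field`,
#'   `truncal`, `branch`).
#' @export
fit_by_epoch <- function(calls, clonality_records, signatures, subset = NULL,
                         r2 = "centered") {
  uniq <- calls[!duplicated(mutation_id(calls)), , drop = FALSE]
  rec <- clonality_records[match(mutation_id(uniq), clonality_records$mutation_id), ]
  epoch <- ifelse(rec$in_mucosa, "field",
                  ifelse(rec$cancer_pattern %in% "truncal", "truncal",
                         ifelse(rec$cancer_pattern %in% c("shared_subclonal", "private"),
                                "branch", NA_character_)))
  out <- list()
  for (ep in c("field", "truncal", "branch")) {
    sub <- uniq[!is.na(epoch) & epoch == ep, , drop = FALSE]
    cat96 <- tally_96(sub, label = ep)
    if (sum(cat96) == 0) {
      message("epoch '", ep, "' has no context-bearing substitutions; skipped")
      next
    }
    out[[ep]] <- fit_exposures(cat96, signatures, subset = subset, r2 = r2)
  }
  out
}
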