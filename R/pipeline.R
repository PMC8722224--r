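#' Run the full differential-occupancy pipeline
#'
#' Chains the per-GATC moderated-t statistics, max-gap peak building with
#' Simes-combined p-values and BH FDR, and minimum-FDR gene assignment.
#' When `tolerance` is `NULL` the genome's median GATC fragment distance is
#' used, matching the published procedure (350 bp on D. melanogaster
#' r6.21).
#'
#' @param counts Long count tibble (see [simulate_counts()] /
#'   [count_sam_samples()]).
#' @param fragments Fragment map from [gatc_fragment_map()].
#' @param genes Gene tibble.
#' @param treatment,reference Condition labels of the contrast.
#' @param tolerance Max-gap merge tolerance, bp, or `NULL` for the median
#'   GATC fragment distance.
#' @param p_threshold Per-GATC entry threshold (default `1e-5`).
#' @param fdr Gene-level FDR threshold (default 0.01).
#' @param merge_all Merge all fragments instead of only significant ones.
#' @param pseudocount Pseudocount on the CPM scale.
#' @param margin Upstream margin for gene assignment, bp.
#' @return A list of class `tada_result` with elements `fit` (`tada_fit`),
#'   `peaks`, `gene_calls`, `params`.
#' @export
tada_pipeline <- function(counts, fragments, genes,
                          treatment = "DN", reference = "Dam",
                          tolerance = NULL, p_threshold = 1e-5, fdr = 0.01,
                          merge_all = FALSE, pseudocount = 1, margin = 0) {
  if (is.null(tolerance)) tolerance <- median_fragment_distance(fragments)
  fit <- gatc_stats(counts, treatment = treatment, reference = reference,
                    pseudocount = pseudocount, p_threshold = p_threshold)
  peaks <- call_peaks(fit, tolerance = tolerance, p_threshold = p_threshold,
                      merge_all = merge_all)
  gene_calls <- assign_genes(peaks, genes, margin = margin, fdr = fdr)
  structure(list(
    fit = fit, peaks = peaks, gene_calls = gene_calls,
    params = list(treatment = treatment, reference = reference,
                  tolerance = tolerance, p_threshold = p_threshold,
                  fdr = fdr, merge_all = merge_all,
                  pseudocount = pseudocount, margin = margin)
  ), class = "tada_result")
}

#' @export
print.tada_result <- function(x, ...) {
  cat("<tada_result> ", x$params$treatment, " vs ", x$params$reference,
      "\n", sep = "")
  cat("  peaks: ", nrow(x$peaks), " (merge tolerance ",
      x$params$tolerance, " bp)\n", sep = "")
  cat("  genes with a peak: ", sum(!is.na(x$gene_calls$peak_id)),
      " / ", nrow(x$gene_calls), "\n", sep = "")
  cat("  significant genes at FDR < ", x$params$fdr, ": ",
      sum(x$gene_calls$significant), "\n", sep = "")
  invisible(x)
}

#' @rdname tada_pipeline
#' @param x A `tada_result`.
#' @param ... Unused.
#' @export
glance.tada_result <- function(x, ...) {
  tibble::tibble(
    n_fragments = nrow(x$fit$table),
    n_significant_gatc = sum(x$fit$table$significant),
    n_peaks = nrow(x$peaks),
    n_genes = nrow(x$gene_calls),
    n_significant_genes = sum(x$gene_calls$significant),
    tolerance = x$params$tolerance,
    fdr = x$params$fdr
  )
}

#' Compare gene-level calls against planted simulation truth
#'
#' Sensitivity is the fraction of planted differential genes called
#' significant; the empirical FDR is the fraction of significant calls that
#' are planted nulls.
#'
#' @param gene_calls Gene assignment tibble from [assign_genes()] or a
#'   `tada_result`.
#' @param truth A `tada_truth` from [simulate_occupancy()].
#' @return One-row tibble: `n_de`, `n_called`, `true_positive`,
#'   `false_positive`, `sensitivity`, `empirical_fdr`.
#' @export
recovery_stats <- function(gene_calls, truth) {
  if (inherits(gene_calls, "tada_result")) {
    gene_calls <- gene_calls$gene_calls
  }
  stopifnot(inherits(truth, "tada_truth"))
  tt <- dplyr::left_join(gene_calls, truth$genes, by = "gene_id")
  de <- tt$label != "null"
  called <- tt$significant
  tp <- sum(called & de)
  fp <- sum(called & !de)
  tibble::tibble(
    n_de = sum(de),
    n_called = sum(called),
    true_positive = tp,
    false_positive = fp,
    sensitivity = if (sum(de) == 0) NA_real_ else tp / sum(de),
    empirical_fdr = if (sum(called) == 0) 0 else fp / sum(called)
  )
}

#' Write pipeline outputs as TSV/BED text files
#'
#' Deterministic tab-separated exports: per-GATC statistics, peaks as
#' BED6+ (extra columns `n_gatc`, `mean_logfc`, `p_simes`, `q`) and the
#' gene table used for volcano plotting.
#'
#' @param result A `tada_result`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_tada_results <- function(result, dir) {
  stopifnot(inherits(result, "tada_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gatc = file.path(dir, "gatc_stats.tsv"),
    peaks = file.path(dir, "peaks.bed"),
    genes = file.path(dir, "gene_calls.tsv")
  )
  utils::write.table(
    result$fit$table[, c("fragment_id", "contig", "start", "end", "logFC",
                         "t", "p_value", "significant")],
    paths["gatc"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  pk <- result$peaks
  utils::write.table(
    data.frame(chrom = pk$contig, start = pk$start, end = pk$end,
               name = pk$peak_id, score = 0L, strand = ".",
               n_gatc = pk$n_gatc, mean_logfc = pk$mean_logfc,
               p_simes = pk$p_simes, q = pk$q),
    paths["peaks"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE
  )
  utils::write.table(
    result$gene_calls, paths["genes"], sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(paths)
}
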