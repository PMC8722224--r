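#' Simes combination of member p-values
#'
#' `p_region = min_i( m * p_(i) / i )` over the sorted member p-values,
#' clipped at 1. Valid under positive dependence of the members, which is
#' the expected regime for neighbouring GATC fragments.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, length >= 1.
#' @return The combined p-value.
#' @export
simes_combine <- function(p) {
  if (length(p) < 1L) stop("need at least one p-value", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  min(1, min(m * sort(p) / seq_len(m)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment (`stats::p.adjust(method = "BH")`):
#' `q_(i) = min_{j >= i} ( m * p_(j) / j )`, monotone non-decreasing in p.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) < 1L) stop("need at least one p-value", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Max-gap merging of GATC fragments
#'
#' Single-linkage clustering along each contig: consecutive fragments join
#' the same peak iff the gap between them (`next start - previous end`) is
#' at most `tolerance` bp. The default tolerance used throughout the
#' pipeline is the genome's median GATC fragment distance (350 bp on the
#' D. melanogaster r6.21 reference).
#'
#' @param stats Tibble of fragments carrying `contig`, `start`, `end`
#'   (typically a filtered [gatc_stats()] table).
#' @param tolerance Maximum gap, bp (>= 0).
#' @return The input rows (sorted by contig, start) with an added `peak_id`
#'   column.
#' @export
merge_gatcs <- function(stats, tolerance) {
  stopifnot(all(c("contig", "start", "end") %in% names(stats)),
            tolerance >= 0)
  if (nrow(stats) == 0L) {
    return(dplyr::mutate(stats, peak_id = character(0)))
  }
  out <- stats |>
    dplyr::arrange(.data$contig, .data$start) |>
    dplyr::group_by(.data$contig) |>
    dplyr::mutate(
      .gap = .data$start - dplyr::lag(cummax(.data$end)),
      .new = is.na(.data$.gap) | .data$.gap > tolerance
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(peak_id = sprintf("peak_%05d", cumsum(.data$.new))) |>
    dplyr::select(-".gap", -".new")
  out
}

#' Call peaks from per-GATC differential statistics
#'
#' The region-level step of the pipeline: fragments passing the per-GATC
#' p-value threshold (default `1e-5`; `merge_all = TRUE` merges every
#' fragment instead and relies on the combined test alone) are merged into
#' peaks at the max-gap tolerance, each peak receives the mean logFC of its
#' member GATCs, a Simes-combined p-value, and a Benjamini-Hochberg FDR
#' (q-value) across peaks.
#'
#' @param fit A `tada_fit` from [gatc_stats()], or its [tidy()] table.
#' @param tolerance Max-gap tolerance, bp; typically
#'   [median_fragment_distance()] of the genome.
#' @param p_threshold Per-GATC entry threshold (default `1e-5`).
#' @param merge_all Merge all fragments regardless of their p-value.
#' @return A tibble with one row per peak: `peak_id`, `contig`, `start`,
#'   `end`, `n_gatc`, `members` (list of fragment ids), `mean_logfc`,
#'   `mixed_sign`, `p_simes`, `q`, `direction`.
#' @export
call_peaks <- function(fit, tolerance, p_threshold = 1e-5,
                       merge_all = FALSE) {
  stats <- if (inherits(fit, "tada_fit")) fit$table else fit
  stopifnot(all(c("fragment_id", "contig", "start", "end", "logFC",
                  "p_value") %in% names(stats)))
  if (!merge_all) stats <- stats[stats$p_value < p_threshold, , drop = FALSE]
  if (nrow(stats) == 0L) {
    return(tibble::tibble(
      peak_id = character(0), contig = character(0), start = integer(0),
      end = integer(0), n_gatc = integer(0), members = list(),
      mean_logfc = numeric(0), mixed_sign = logical(0),
      p_simes = numeric(0), q = numeric(0), direction = numeric(0)
    ))
  }
  merged <- merge_gatcs(stats, tolerance)
  peaks <- merged |>
    dplyr::group_by(.data$peak_id) |>
    dplyr::summarise(
      contig = .data$contig[1],
      start = min(.data$start),
      end = max(.data$end),
      n_gatc = dplyr::n(),
      members = list(.data$fragment_id),
      mean_logfc = mean(.data$logFC),
      mixed_sign = length(unique(sign(.data$logFC[.data$logFC != 0]))) > 1L,
      p_simes = simes_combine(.data$p_value),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      q = bh_adjust(.data$p_simes),
      direction = sign(.data$mean_logfc)
    ) |>
    dplyr::arrange(.data$contig, .data$start)
  peaks
}

#' Assign each gene its minimum-FDR overlapping peak
#'
#' A peak overlaps a gene when its interval intersects the gene span
#' (TSS to gene end, optionally extended upstream by `margin` bp,
#' strand-aware). Per gene the overlapping peak with the smallest q-value is
#' chosen; ties break towards the larger absolute mean logFC, then the
#' leftmost peak. Genes without any overlapping peak keep `NA` and are not
#' significant. The gene-level significance call is `q < fdr` (default
#' 0.01).
#'
#' @param peaks Peak tibble from [call_peaks()].
#' @param genes Gene tibble.
#' @param margin Upstream margin, bp (default 0 = gene span only).
#' @param fdr Gene-level FDR threshold (default 0.01).
#' @return A tibble with one row per gene: `gene_id`, `gene_name`, `contig`,
#'   `peak_id`, `logFC`, `fdr`, `significant`.
#' @export
assign_genes <- function(peaks, genes, margin = 0, fdr = 0.01) {
  stopifnot(all(c("gene_id", "contig", "strand", "start", "end") %in%
                  names(genes)))
  gstart <- ifelse(genes$strand == "+", genes$start - margin, genes$start)
  gend <- ifelse(genes$strand == "+", genes$end, genes$end + margin)
  best <- rep(NA_integer_, nrow(genes))
  if (nrow(peaks) > 0L) {
    for (ctg in unique(genes$contig)) {
      gi <- which(genes$contig == ctg)
      pi <- which(peaks$contig == ctg)
      if (length(pi) == 0L) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(gstart[gi] + 1L, gend[gi]),
        IRanges::IRanges(peaks$start[pi] + 1L, peaks$end[pi])
      )
      if (length(hits) == 0L) next
      cand <- tibble::tibble(
        g = gi[S4Vectors::queryHits(hits)],
        p = pi[S4Vectors::subjectHits(hits)]
      ) |>
        dplyr::mutate(
          q = peaks$q[.data$p],
          alfc = abs(peaks$mean_logfc[.data$p]),
          pstart = peaks$start[.data$p]
        ) |>
        dplyr::arrange(.data$g, .data$q, dplyr::desc(.data$alfc),
                       .data$pstart) |>
        dplyr::distinct(.data$g, .keep_all = TRUE)
      best[cand$g] <- cand$p
    }
  }
  fdr_threshold <- fdr
  tibble::tibble(
    gene_id = genes$gene_id,
    gene_name = if ("gene_name" %in% names(genes)) {
      genes$gene_name
    } else {
      genes$gene_id
    },
    contig = genes$contig,
    peak_id = ifelse(is.na(best), NA_character_, peaks$peak_id[best]),
    logFC = ifelse(is.na(best), NA_real_, peaks$mean_logfc[best]),
    fdr = ifelse(is.na(best), NA_real_, peaks$q[best]),
    significant = !is.na(best) &
      dplyr::coalesce(peaks$q[best] < fdr_threshold, FALSE)
  )
}

#' Annotate peaks by genomic feature
#'
#' Priority classification of each peak interval against the gene models:
#' promoter (within `promoter_width` bp upstream of a TSS, strand-aware) >
#' 5' UTR > 3' UTR > exon > intron > downstream (within `downstream_width`
#' bp past the gene 3' end) > distal intergenic. UTR categories apply only
#' when the gene table carries `utr5` / `utr3` interval list-columns.
#'
#' @param peaks Peak tibble (needs `contig`, `start`, `end`).
#' @param genes Gene tibble with `exons` list-column.
#' @param promoter_width Promoter window upstream of the TSS, bp.
#' @param downstream_width Downstream window past the gene end, bp.
#' @return The peaks with an added `feature` factor column.
#' @export
annotate_peak_features <- function(peaks, genes, promoter_width = 1000,
                                   downstream_width = 1000) {
  levels <- c("promoter", "utr5", "utr3", "exon", "intron", "downstream",
              "distal_intergenic")
  if (nrow(peaks) == 0L) {
    return(dplyr::mutate(peaks, feature = factor(character(0), levels)))
  }
  feat <- feature_intervals(genes, promoter_width, downstream_width)
  assigned <- rep(NA_character_, nrow(peaks))
  for (cls in setdiff(levels, "distal_intergenic")) {
    ints <- feat[feat$class == cls, , drop = FALSE]
    if (nrow(ints) == 0L) next
    todo <- which(is.na(assigned))
    if (length(todo) == 0L) break
    for (ctg in unique(peaks$contig[todo])) {
      pi <- todo[peaks$contig[todo] == ctg]
      ci <- which(ints$contig == ctg)
      if (length(ci) == 0L) next
      ov <- IRanges::overlapsAny(
        IRanges::IRanges(peaks$start[pi] + 1L, peaks$end[pi]),
        IRanges::IRanges(ints$start[ci] + 1L, ints$end[ci])
      )
      assigned[pi[ov]] <- cls
    }
  }
  assigned[is.na(assigned)] <- "distal_intergenic"
  dplyr::mutate(peaks, feature = factor(assigned, levels))
}

feature_intervals <- function(genes, promoter_width, downstream_width) {
  pr_start <- ifelse(genes$strand == "+", genes$tss - promoter_width,
                     genes$tss + 1)
  pr_end <- ifelse(genes$strand == "+", genes$tss,
                   genes$tss + 1 + promoter_width)
  dn_start <- ifelse(genes$strand == "+", genes$end,
                     genes$start - downstream_width)
  dn_end <- ifelse(genes$strand == "+", genes$end + downstream_width,
                   genes$start)
  exons <- genes |>
    dplyr::select("contig", "exons") |>
    tidyr::unnest("exons") |>
    dplyr::mutate(class = "exon")
  introns <- purrr::pmap(genes[, c("contig", "start", "end", "exons")],
    function(contig, start, end, exons) {
      ex <- dplyr::arrange(exons, .data$start)
      if (nrow(ex) < 2L) return(NULL)
      tibble::tibble(contig = contig,
                     start = ex$end[-nrow(ex)], end = ex$start[-1]) |>
        dplyr::filter(.data$end > .data$start)
    }) |>
    dplyr::bind_rows()
  if (nrow(introns) > 0L) introns$class <- "intron"
  utr <- NULL
  for (u in c("utr5", "utr3")) {
    if (u %in% names(genes)) {
      uu <- genes |>
        dplyr::select("contig", dplyr::all_of(u)) |>
        tidyr::unnest(dplyr::all_of(u)) |>
        dplyr::mutate(class = u)
      utr <- dplyr::bind_rows(utr, uu)
    }
  }
  dplyr::bind_rows(
    tibble::tibble(contig = genes$contig, start = pmax(pr_start, 0),
                   end = pr_end, class = "promoter"),
    utr,
    exons,
    introns,
    tibble::tibble(contig = genes$contig, start = pmax(dn_start, 0),
                   end = dn_end, class = "downstream")
  )
}

#' Feature category proportions
#'
#' Summarises an annotated peak set into the pie-chart table of category
#' counts and proportions (proportions sum to 1).
#'
#' @param annotated Output of [annotate_peak_features()].
#' @return A tibble with columns `feature`, `n`, `proportion`.
#' @export
feature_proportions <- function(annotated) {
  stopifnot("feature" %in% names(annotated))
  annotated |>
    dplyr::count(.data$feature, name = "n", .drop = FALSE) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n))
}
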