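#' Signed distance from sites to the nearest TSS
#'
#' For every site the closest transcription start site (by absolute
#' distance) on the same contig is found; the sign is strand-aware relative
#' to that gene: negative = upstream of the TSS, positive = downstream into
#' the gene body. Sites on contigs without any TSS are dropped with a
#' message.
#'
#' @param sites Tibble with columns `contig`, `pos` (0-based positions) and
#'   optionally `class`.
#' @param genes Gene tibble with `tss` and `strand`.
#' @return The input rows with an added `distance` column.
#' @export
tss_distances <- function(sites, genes) {
  stopifnot(all(c("contig", "pos") %in% names(sites)),
            all(c("contig", "tss", "strand") %in% names(genes)))
  if (nrow(genes) == 0L) stop("no TSS available", call. = FALSE)
  out <- vector("list", 0L)
  dropped <- 0L
  for (ctg in unique(sites$contig)) {
    ss <- sites[sites$contig == ctg, , drop = FALSE]
    gg <- genes[genes$contig == ctg, , drop = FALSE]
    if (nrow(gg) == 0L) {
      dropped <- dropped + nrow(ss)
      next
    }
    ord <- order(gg$tss)
    tss <- gg$tss[ord]
    strand <- gg$strand[ord]
    i <- findInterval(ss$pos, tss)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(tss))
    d_lo <- abs(ss$pos - tss[lo])
    d_hi <- abs(ss$pos - tss[hi])
    nearest <- ifelse(d_lo <= d_hi, lo, hi)
    raw <- ss$pos - tss[nearest]
    signed <- ifelse(strand[nearest] == "+", raw, -raw)
    out[[length(out) + 1L]] <- dplyr::mutate(ss, distance = signed)
  }
  if (dropped > 0L) {
    message("dropping ", dropped, " site(s) on contigs without a TSS")
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) stop("no TSS available for any site", call. = FALSE)
  res
}

#' TSS distance meta-profile per site class
#'
#' Histogram of signed distance-to-nearest-TSS for each site class
#' (e.g. Dam-fusion methylated GATCs vs. all GATC motifs vs. random
#' positions), over a shared set of bin edges. The outermost bins are
#' open-ended so every site is counted.
#'
#' @param sites Tibble with columns `contig`, `pos`, `class`.
#' @param genes Gene tibble.
#' @param breaks Shared bin edges, bp (monotone increasing; `-Inf`/`Inf`
#'   added automatically when absent).
#' @return A tibble with columns `class`, `bin` (factor), `lower`, `upper`,
#'   `count`; per class the counts sum to the class site count.
#' @export
tss_distance_profile <- function(sites, genes,
                                 breaks = seq(-5000, 5000, by = 500)) {
  stopifnot("class" %in% names(sites))
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing", call. = FALSE)
  }
  if (is.finite(breaks[1])) breaks <- c(-Inf, breaks)
  if (is.finite(breaks[length(breaks)])) breaks <- c(breaks, Inf)
  dd <- tss_distances(sites, genes)
  dd$bin <- cut(dd$distance, breaks = breaks, right = FALSE)
  dd |>
    dplyr::count(.data$class, .data$bin, name = "count", .drop = FALSE) |>
    dplyr::mutate(
      lower = breaks[as.integer(.data$bin)],
      upper = breaks[as.integer(.data$bin) + 1L]
    ) |>
    dplyr::relocate("class", "bin", "lower", "upper", "count")
}

#' Fragments called methylated from Dam-fusion signal
#'
#' Operationalizes "methylated GATC sites" as fragments whose mean
#' normalized Dam-fusion count exceeds a quantile (default the median) of
#' the non-zero fragment means; each selected fragment is reported at its
#' midpoint.
#'
#' @param counts Long count tibble.
#' @param condition Condition label of the Dam-fusion samples.
#' @param quantile Quantile of the non-zero mean CPM distribution.
#' @return Tibble with columns `contig`, `pos` (fragment midpoints).
#' @export
methylated_gatc_sites <- function(counts, condition, quantile = 0.5) {
  cpm <- normalize_cpm(counts[counts$condition == condition, , drop = FALSE])
  means <- cpm |>
    dplyr::group_by(.data$fragment_id, .data$contig, .data$start,
                    .data$end) |>
    dplyr::summarise(mean_cpm = mean(.data$cpm), .groups = "drop")
  thr <- stats::quantile(means$mean_cpm[means$mean_cpm > 0], quantile,
                         names = FALSE)
  sel <- means[means$mean_cpm > thr, , drop = FALSE]
  tibble::tibble(contig = sel$contig,
                 pos = as.integer((sel$start + sel$end) %/% 2))
}

#' Gene-body occupancy profile by expression quantile
#'
#' Each gene body is rescaled to a fixed number of positional bins (plus
#' unscaled flanks), strand-aware so bin 1 is always the 5' end; genes are
#' grouped into expression quantiles and the mean track value per group and
#' bin is returned. Genes without an expression value are excluded with a
#' message.
#'
#' @param track Coverage track tibble (`contig`, `start`, `end`, `value`)
#'   whose bins tile each contig, e.g. from [log_ratio_track()].
#' @param genes Gene tibble.
#' @param expression Tibble with columns `gene_id`, `tpm`.
#' @param n_quantiles Number of expression groups (default 5).
#' @param n_bins Positional bins across the gene body (default 100).
#' @param flank_bp Flank size, bp, on each side (default 1000; 0 disables).
#' @param n_flank_bins Bins per flank (default 25).
#' @return A tibble with columns `quantile`, `bin`, `region` (`upstream`,
#'   `body`, `downstream`), `mean_value`.
#' @export
gene_body_profile <- function(track, genes, expression, n_quantiles = 5,
                              n_bins = 100, flank_bp = 1000,
                              n_flank_bins = 25) {
  stopifnot(all(c("gene_id", "tpm") %in% names(expression)))
  if (flank_bp == 0) n_flank_bins <- 0L
  gg <- dplyr::inner_join(genes, expression, by = "gene_id")
  missing <- setdiff(genes$gene_id, gg$gene_id)
  if (length(missing) > 0L) {
    message("excluding ", length(missing), " gene(s) without expression")
  }
  gg <- dplyr::mutate(gg, quantile = dplyr::ntile(.data$tpm, n_quantiles))
  empty <- setdiff(seq_len(n_quantiles), unique(gg$quantile))
  if (length(empty) > 0L) {
    stop("expression quantile ", empty[1], " is empty", call. = FALSE)
  }
  lookup <- split(track, track$contig)
  value_at <- function(ctg, pos) {
    tr <- lookup[[ctg]]
    v <- rep(NA_real_, length(pos))
    ok <- pos >= 0 & pos < max(tr$end)
    v[ok] <- tr$value[findInterval(pos[ok], tr$start)]
    v
  }
  total_bins <- n_bins + 2L * n_flank_bins
  prof <- purrr::pmap(gg[, c("contig", "strand", "start", "end",
                             "quantile")],
    function(contig, strand, start, end, quantile) {
      body <- start + (seq_len(n_bins) - 0.5) / n_bins * (end - start)
      if (n_flank_bins > 0L) {
        up <- start - flank_bp +
          (seq_len(n_flank_bins) - 0.5) / n_flank_bins * flank_bp
        dn <- end + (seq_len(n_flank_bins) - 0.5) / n_flank_bins * flank_bp
        pos <- c(up, body, dn)
      } else {
        pos <- body
      }
      if (strand == "-") pos <- rev(pos)
      tibble::tibble(quantile = quantile, bin = seq_len(total_bins),
                     value = value_at(contig, floor(pos)))
    }) |>
    dplyr::bind_rows()
  prof |>
    dplyr::group_by(.data$quantile, .data$bin) |>
    dplyr::summarise(mean_value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(region = dplyr::case_when(
      .data$bin <= n_flank_bins ~ "upstream",
      .data$bin > n_flank_bins + n_bins ~ "downstream",
      TRUE ~ "body"
    ))
}

#' Fisher exact enrichment of a labeled gene class
#'
#' Builds the 2x2 table (in-class & selected, in-class & not, out-of-class &
#' selected, out-of-class & not) over a gene universe and tests association
#' with Fisher's exact test (two-sided, point-probability rule: the p-value
#' sums all hypergeometric tables at the fixed margins whose probability
#' does not exceed the observed one). The odds ratio is the sample odds
#' ratio `(a d) / (b c)`, with a Haldane 0.5 correction applied to all cells
#' when any cell is zero.
#'
#' @param selected Character vector of selected gene ids (subset of
#'   `universe`).
#' @param universe Character vector: all gene ids under consideration.
#' @param class_members Character vector: the labeled class (e.g. published
#'   transcription factors), subset of `universe`.
#' @return One-row tibble: `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`.
#' @export
fisher_enrichment <- function(selected, universe, class_members) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  selected <- unique(selected)
  class_members <- unique(class_members)
  if (!all(selected %in% universe)) {
    stop("selected genes must be a subset of the universe", call. = FALSE)
  }
  if (!all(class_members %in% universe)) {
    stop("class members must be a subset of the universe", call. = FALSE)
  }
  a <- length(intersect(class_members, selected))
  b <- length(setdiff(class_members, selected))
  c <- length(setdiff(selected, class_members))
  d <- length(universe) - a - b - c
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    1
  } else {
    stats::fisher.test(tab)$p.value
  }
  or <- if (a == 0 || b == 0 || c == 0 || d == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  tibble::tibble(a = a, b = b, c = c, d = d, odds_ratio = or, p_value = p)
}

#' Overlap arithmetic over named gene lists
#'
#' Computes the exclusive intersection-region counts of two or more named
#' gene lists (the numbers of a Venn diagram) and the pairwise overlap
#' percentages, truncated to whole percent after rounding to one decimal
#' (`floor(round(100 * |A n B| / |A|, 1))`) — the convention that
#' reproduces the published overlap figures (339/1094 = 31%,
#' 510/1094 = 46%, 157/510 = 30%).
#'
#' @param lists Named list of character vectors. Empty lists are kept as
#'   empty sets with a warning.
#' @param strip_versions Strip trailing `.N` version suffixes off ids before
#'   comparing.
#' @return A list of class `tada_overlap` with elements `regions` (tibble
#'   `region`, `count`; regions are `&`-joined member names) and `pairwise`
#'   (tibble `from`, `to`, `n_from`, `n_overlap`, `percent`).
#' @export
set_overlap <- function(lists, strip_versions = FALSE) {
  stopifnot(is.list(lists), length(lists) >= 2L)
  if (is.null(names(lists)) || any(names(lists) == "")) {
    stop("lists must be named", call. = FALSE)
  }
  if (any(lengths(lists) == 0L)) {
    warning("empty gene list(s): ",
            paste(names(lists)[lengths(lists) == 0L], collapse = ", "),
            call. = FALSE)
  }
  norm <- function(x) {
    x <- unique(as.character(x))
    if (strip_versions) x <- sub("\\.\\d+$", "", x)
    x
  }
  lists <- lapply(lists, norm)
  nms <- names(lists)
  universe <- unique(unlist(lists))
  member <- vapply(lists, function(l) universe %in% l,
                   logical(length(universe)))
  if (!is.matrix(member)) {
    member <- matrix(member, nrow = length(universe), ncol = length(lists),
                     dimnames = list(NULL, nms))
  }
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(nms)))
  names(combos) <- nms
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  regions <- purrr::pmap(combos, function(...) {
    inc <- unlist(list(...))
    hit <- if (length(universe) == 0L) {
      logical(0)
    } else {
      apply(member, 1L, function(row) all(row == inc))
    }
    tibble::tibble(region = paste(nms[inc], collapse = "&"),
                   count = sum(hit))
  }) |>
    dplyr::bind_rows()
  pairs <- expand.grid(from = nms, to = nms, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  pairwise <- purrr::pmap(pairs, function(from, to) {
    n_from <- length(lists[[from]])
    n_overlap <- length(intersect(lists[[from]], lists[[to]]))
    tibble::tibble(
      from = from, to = to, n_from = n_from, n_overlap = n_overlap,
      percent = if (n_from == 0L) {
        NA_real_
      } else {
        floor(round(100 * n_overlap / n_from, 1))
      }
    )
  }) |>
    dplyr::bind_rows()
  structure(list(regions = regions, pairwise = pairwise),
            class = "tada_overlap")
}

#' @export
print.tada_overlap <- function(x, ...) {
  cat("<tada_overlap>\n")
  print(x$regions)
  print(x$pairwise)
  invisible(x)
}
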