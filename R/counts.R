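#' Read a SAM file into an alignment tibble
#'
#' Thin wrapper over Rsamtools/GenomicAlignments: the SAM text is converted
#' to a temporary BAM and every record (including unmapped, secondary and
#' supplementary ones, which downstream counting tallies as skipped) is
#' returned with 0-based half-open reference coordinates.
#'
#' @param path Path to a SAM file.
#' @return A tibble with columns `contig`, `strand` (`+`/`-`), `start`,
#'   `end` (0-based half-open; `NA` for unmapped records), `flag`,
#'   `primary_mapped`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file does not exist: ", path, call. = FALSE)
  bam <- Rsamtools::asBam(path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam))
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("flag", "rname", "pos", "strand", "cigar")
    )
  )[[1]]
  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L
  supplementary <- bitwAnd(flag, 2048L) != 0L
  refwidth <- rep(NA_integer_, length(flag))
  ok <- !is.na(res$cigar)
  refwidth[ok] <-
    GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[ok])
  start <- res$pos - 1L
  tibble::tibble(
    contig = as.character(res$rname),
    strand = as.character(res$strand),
    start = start,
    end = start + refwidth,
    flag = flag,
    primary_mapped = !unmapped & !secondary & !supplementary
  )
}

#' Count DamID reads mapped on edge to GATC fragments
#'
#' Implements edge counting: DamID reads begin at DpnI cut sites, so each
#' primary mapped read is assigned to the fragment whose boundary GATC lies
#' within `edge_tolerance` bp of the read's 5'-most aligned base. The rule is
#' strand-aware: forward reads use their leftmost base and are assigned to
#' the fragment *starting* at the matched boundary; reverse reads use their
#' rightmost base and are assigned to the fragment *ending* there. Reads
#' matching no boundary fall back to the fragment containing the 5' base
#' (tallied separately), or are rejected when `strict_edge = TRUE`.
#' Unmapped/secondary/supplementary records are skipped; reads on contigs
#' absent from the map go to a reject bucket.
#'
#' @param alignments A SAM path or an alignment tibble from [read_sam()].
#' @param fragments Fragment map from [gatc_fragment_map()].
#' @param edge_tolerance Maximum distance, bp, between the 5' base and a
#'   boundary GATC start (default 5).
#' @param strict_edge Reject reads without an edge match instead of falling
#'   back to the containing fragment.
#' @return A tibble with columns `fragment_id`, `count` covering every
#'   fragment in the map (zeros included), in map order. The attribute
#'   `tally` holds a named integer vector
#'   (`assigned_edge`, `assigned_fallback`, `rejected`, `skipped`,
#'   `unknown_contig`) whose sum equals the number of SAM records.
#' @export
count_reads_to_fragments <- function(alignments, fragments,
                                     edge_tolerance = 5L,
                                     strict_edge = FALSE) {
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_sam(alignments)
  }
  stopifnot(is.data.frame(alignments), is.data.frame(fragments),
            "site_start" %in% names(fragments))
  if (edge_tolerance < 0) {
    stop("edge_tolerance must be >= 0", call. = FALSE)
  }
  n_total <- nrow(alignments)
  skipped <- sum(!alignments$primary_mapped)
  reads <- alignments[alignments$primary_mapped, , drop = FALSE]
  known <- reads$contig %in% unique(fragments$contig)
  unknown_contig <- sum(!known)
  reads <- reads[known, , drop = FALSE]

  counts <- stats::setNames(integer(nrow(fragments)), fragments$fragment_id)
  assigned_edge <- 0L
  assigned_fallback <- 0L
  rejected <- 0L

  for (ctg in unique(reads$contig)) {
    rr <- reads[reads$contig == ctg, , drop = FALSE]
    fi <- which(fragments$contig == ctg)
    fr <- fragments[fi, , drop = FALSE]
    sites <- fr$start[fr$site_start]
    # fragment row (within fr) starting / ending at each site
    start_of <- match(sites, fr$start)
    end_of <- match(sites, fr$end)

    is_rev <- rr$strand == "-"
    b <- ifelse(is_rev, rr$end, rr$start)   # 5'-most base as boundary coord
    frag_row <- rep(NA_integer_, nrow(rr))
    edge_hit <- rep(FALSE, nrow(rr))
    if (length(sites) > 0L) {
      i <- findInterval(b, sites)
      lo <- pmax(i, 1L)
      hi <- pmin(i + 1L, length(sites))
      d_lo <- abs(b - sites[lo])
      d_hi <- abs(b - sites[hi])
      nearest <- ifelse(d_lo <= d_hi, lo, hi)
      dist <- pmin(d_lo, d_hi)
      hit <- dist <= edge_tolerance
      frag_row[hit & !is_rev] <- start_of[nearest[hit & !is_rev]]
      frag_row[hit & is_rev] <- end_of[nearest[hit & is_rev]]
      edge_hit <- hit & !is.na(frag_row)
      frag_row[!edge_hit] <- NA_integer_
    }
    need_fb <- which(!edge_hit)
    if (length(need_fb) > 0L && !strict_edge) {
      p5 <- ifelse(is_rev[need_fb], rr$end[need_fb] - 1L, rr$start[need_fb])
      j <- findInterval(p5, fr$start)
      ok <- j >= 1L & j <= nrow(fr) & p5 >= 0L & p5 < fr$end[pmax(j, 1L)]
      frag_row[need_fb[ok]] <- j[ok]
      assigned_fallback <- assigned_fallback + sum(ok)
      rejected <- rejected + sum(!ok)
    } else {
      rejected <- rejected + length(need_fb)
    }
    assigned_edge <- assigned_edge + sum(edge_hit)
    tab <- table(frag_row[!is.na(frag_row)])
    idx <- fi[as.integer(names(tab))]
    counts[idx] <- counts[idx] + as.integer(tab)
  }

  out <- tibble::tibble(fragment_id = fragments$fragment_id,
                        count = unname(counts))
  attr(out, "tally") <- c(
    assigned_edge = assigned_edge,
    assigned_fallback = assigned_fallback,
    rejected = rejected,
    skipped = as.integer(skipped),
    unknown_contig = as.integer(unknown_contig)
  )
  stopifnot(sum(attr(out, "tally")) == n_total)
  out
}

#' Count a set of per-sample SAM files into a long count table
#'
#' @param files Tibble with columns `sample`, `path` (e.g. from
#'   [write_sam()]); sample names may encode `condition_replicate`.
#' @param fragments Fragment map.
#' @param ... Passed to [count_reads_to_fragments()].
#' @return Long tibble `fragment_id`, `contig`, `start`, `end`, `sample`,
#'   `count`.
#' @export
count_sam_samples <- function(files, fragments, ...) {
  stopifnot(all(c("sample", "path") %in% names(files)))
  purrr::map2(files$sample, files$path, function(smp, pth) {
    cc <- count_reads_to_fragments(pth, fragments, ...)
    tibble::tibble(
      fragment_id = cc$fragment_id,
      contig = fragments$contig,
      start = fragments$start,
      end = fragments$end,
      sample = smp,
      count = cc$count
    )
  }) |>
    dplyr::bind_rows()
}

#' Counts-per-million normalization
#'
#' Scales each sample's counts so they sum to one million.
#'
#' @param counts Long count tibble with columns `sample`, `count`.
#' @return The input with an added `cpm` column.
#' @export
normalize_cpm <- function(counts) {
  stopifnot(all(c("sample", "count") %in% names(counts)))
  if (any(counts$count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  out <- counts |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(.lib = sum(.data$count)) |>
    dplyr::ungroup()
  if (any(out$.lib == 0)) {
    bad <- unique(out$sample[out$.lib == 0])
    stop("zero-depth sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out |>
    dplyr::mutate(cpm = .data$count / .data$.lib * 1e6) |>
    dplyr::select(-".lib")
}

#' Browser-style log2-ratio coverage track
#'
#' Reproduces the bamCompare-style recipe: each sample is scaled to 1x
#' genome coverage (scale factor = `effective_genome_size` / total aligned
#' bases), per-bin values are `log2((t + pc) / (r + pc))` on the normalized
#' coverages, and a centered running mean over `smooth` bins is applied
#' (window clamped at contig edges so values stay finite). Defaults follow
#' the Drosophila recipe: 1 bp bins, 5-bin smoothing, effective genome size
#' 142,573,017 bp.
#'
#' @param treatment,reference Alignment tibbles from [read_sam()] (primary
#'   mapped records are used), on the same genome.
#' @param genome Genome tibble (contig lengths).
#' @param effective_genome_size Effective genome size, bp.
#' @param bin Bin size, bp.
#' @param smooth Smoothing window, in bins (values < 2 disable smoothing).
#' @param pseudocount Pseudocount on the 1x-normalized coverage scale.
#' @return A tibble with columns `contig`, `start`, `end`, `value`; bins
#'   tile each contig.
#' @export
log_ratio_track <- function(treatment, reference, genome,
                            effective_genome_size = 142573017,
                            bin = 1L, smooth = 5L, pseudocount = 1) {
  stopifnot(bin >= 1, pseudocount > 0)
  tr <- treatment[treatment$primary_mapped, , drop = FALSE]
  rf <- reference[reference$primary_mapped, , drop = FALSE]
  if (!all(unique(c(tr$contig, rf$contig)) %in% genome$contig)) {
    stop("alignments reference contigs absent from the genome", call. = FALSE)
  }
  scale_t <- effective_genome_size / sum(tr$end - tr$start)
  scale_r <- effective_genome_size / sum(rf$end - rf$start)
  purrr::pmap(genome[, c("contig", "length")], function(contig, length) {
    cov_t <- base_coverage(tr, contig, length) * scale_t
    cov_r <- base_coverage(rf, contig, length) * scale_r
    val <- log2((cov_t + pseudocount) / (cov_r + pseudocount))
    starts <- seq.int(0L, length - 1L, by = bin)
    ends <- pmin(starts + bin, length)
    binned <- if (bin == 1L) {
      val
    } else {
      grp <- rep(seq_along(starts), times = ends - starts)
      as.numeric(tapply(val, grp, mean))
    }
    tibble::tibble(contig = contig, start = as.integer(starts),
                   end = as.integer(ends),
                   value = running_mean(binned, smooth))
  }) |>
    dplyr::bind_rows()
}

base_coverage <- function(reads, contig, length) {
  rr <- reads[reads$contig == contig, , drop = FALSE]
  if (nrow(rr) == 0L) return(numeric(length))
  cov <- IRanges::coverage(IRanges::IRanges(rr$start + 1L, rr$end),
                           width = length)
  as.numeric(cov)
}

# centered running mean, window clamped at the edges (always finite)
running_mean <- function(x, w) {
  if (is.na(w) || w < 2L) return(x)
  n <- length(x)
  half <- (as.integer(w) - 1L) %/% 2L
  half_up <- as.integer(w) - 1L - half
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half_up, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
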