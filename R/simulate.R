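#' Simulation configuration for synthetic TaDa experiments
#'
#' Defines the study conditions the generator emulates: a Dam-only reference
#' versus a Dam-fusion treatment, three biological replicates per condition,
#' negative-binomial fragment counts, and a configurable fraction of genes
#' with planted differential Pol II occupancy.
#'
#' @param contig_length Length of the simulated contig, bp.
#' @param n_genes Number of non-overlapping genes placed on the contig.
#' @param gene_length Gene span, bp.
#' @param gatc_spacing Mean distance between consecutive GATC motif starts,
#'   bp; spacings are geometric-like with this mean (must exceed the 4 bp
#'   motif length).
#' @param conditions Named character vector `c(reference = , treatment = )`;
#'   defaults to the Dam-only vs. dominant-negative contrast.
#' @param n_replicates Biological replicates per condition.
#' @param depth Expected total reads per sample.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); values below `1e-8` switch to Poisson noise.
#' @param frac_de Fraction of genes with planted differential occupancy.
#' @param log2fc Magnitude of the planted log2 fold-change.
#' @param background Dam-accessibility background occupancy added to every
#'   fragment (relative units; gene bodies add their expression level).
#' @param expression_sdlog Log-normal sd of per-gene expression levels.
#' @param promoter_margin Upstream margin, bp, when mapping fragments to
#'   genes (0 = gene span only).
#' @param read_length Read length used when emitting SAM records.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(contig_length = 7e5,
                       n_genes = 100,
                       gene_length = 2000,
                       gatc_spacing = 350,
                       conditions = c(reference = "Dam", treatment = "DN"),
                       n_replicates = 3,
                       depth = 1e6,
                       dispersion = 0.1,
                       frac_de = 0.2,
                       log2fc = 2,
                       background = 0.1,
                       expression_sdlog = 0.5,
                       promoter_margin = 0,
                       read_length = 75) {
  cfg <- list(
    contig_length = as.integer(contig_length), n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length), gatc_spacing = gatc_spacing,
    conditions = conditions, n_replicates = as.integer(n_replicates),
    depth = depth, dispersion = dispersion, frac_de = frac_de,
    log2fc = log2fc, background = background,
    expression_sdlog = expression_sdlog, promoter_margin = promoter_margin,
    read_length = as.integer(read_length)
  )
  if (cfg$contig_length < 1 || cfg$n_genes < 1 || cfg$gene_length < 1 ||
      cfg$n_replicates < 1 || cfg$read_length < 1) {
    stop("argument error: counts and lengths must be positive", call. = FALSE)
  }
  if (cfg$depth <= 0) stop("argument error: depth must be > 0", call. = FALSE)
  if (cfg$dispersion < 0) {
    stop("argument error: dispersion must be >= 0", call. = FALSE)
  }
  if (cfg$frac_de < 0 || cfg$frac_de > 1) {
    stop("argument error: frac_de must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$gatc_spacing <= 4) {
    stop("argument error: gatc_spacing must exceed the 4 bp motif length",
         call. = FALSE)
  }
  if (!all(c("reference", "treatment") %in% names(cfg$conditions))) {
    stop("argument error: conditions needs named reference and treatment",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a genome with realistic GATC spacing
#'
#' Random DNA with GATC motifs injected at right-skewed (gamma-Poisson)
#' inter-start spacings whose median sits at the configured spacing;
#' accidental motif occurrences created by the random filler are mutated
#' away, so the motif set equals the injected set. Deterministic under
#' `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A genome tibble (see [genome_table()]), single contig `chrSim`.
#' @export
simulate_genome <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(seed, {
    len <- config$contig_length
    # right-skewed gamma-Poisson spacings whose *median* sits at the
    # configured value (the median is the statistic the merge step uses);
    # shape 5 gives a realistic spread with median/mean ~ 0.93
    shape <- 5
    mu <- (config$gatc_spacing - 4) / 0.935
    n_draw <- max(16L, ceiling(2 * len / config$gatc_spacing))
    gaps <- 4L + stats::rnbinom(n_draw, size = shape, mu = mu)
    while (sum(gaps) < len) {
      gaps <- c(gaps, 4L + stats::rnbinom(n_draw, size = shape, mu = mu))
    }
    starts <- cumsum(gaps)
    starts <- starts[starts <= len - 4L]   # 1-based motif start positions
    base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    for (off in 0:3) {
      base[starts + off] <- c("G", "A", "T", "C")[off + 1L]
    }
    seq <- paste(base, collapse = "")
    occ <- gregexpr("GATC", seq, fixed = TRUE)[[1]]
    spurious <- setdiff(occ[occ > 0], starts)
    if (length(spurious) > 0L) {
      # mutate the A of each accidental motif; this cannot spawn new motifs
      base[spurious + 1L] <- "C"
      seq <- paste(base, collapse = "")
    }
    genome_table(c(chrSim = seq))
  })
}

#' Simulate non-overlapping gene models
#'
#' Places `n_genes` single-exon genes of fixed length in equal-width slots
#' along the contig (one gene per slot, uniform jitter inside the slot),
#' with random strands.
#'
#' @param genome Genome tibble from [simulate_genome()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A gene tibble in the [read_gene_models()] layout.
#' @export
simulate_genes <- function(genome, config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  len <- genome$length[1]
  slot <- len %/% config$n_genes
  if (slot <= config$gene_length) {
    stop("argument error: contig too short for n_genes genes of gene_length",
         call. = FALSE)
  }
  local_seed(seed, {
    jitter <- floor(stats::runif(config$n_genes,
                                 min = 0, max = slot - config$gene_length))
    start <- as.integer((seq_len(config$n_genes) - 1L) * slot + jitter)
    end <- start + config$gene_length
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    tibble::tibble(
      gene_id = sprintf("gene_%03d", seq_len(config$n_genes)),
      gene_name = sprintf("simg%03d", seq_len(config$n_genes)),
      contig = genome$contig[1],
      strand = strand,
      start = start,
      end = end,
      tss = ifelse(strand == "+", start, end - 1L),
      exons = purrr::map2(start, end, ~ tibble::tibble(start = .x, end = .y))
    )
  })
}

#' Plant Pol II occupancy truth on a fragment map
#'
#' Every fragment receives the background occupancy; fragments overlapping a
#' gene body (largest overlap wins when a fragment straddles two genes) add
#' that gene's expression level. A `frac_de` subset of genes is planted as
#' differential: treatment occupancy of their fragments is multiplied by
#' `2^(+-log2fc)` (up and down in equal numbers, up rounded up).
#'
#' @param genes Gene tibble.
#' @param fragments Fragment map from [gatc_fragment_map()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `tada_truth` with elements `genes` (tibble:
#'   `gene_id`, `label`, `planted_log2fc`, `expression`) and `fragments`
#'   (tibble: fragment coordinates, `gene_id` or `NA`, `occupancy_ref`,
#'   `occupancy_trt`).
#' @export
simulate_occupancy <- function(genes, fragments, config = sim_config(),
                               seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(genes) || nrow(genes) == 0L) {
    stop("argument error: no genes supplied", call. = FALSE)
  }
  local_seed(seed, {
    n <- nrow(genes)
    n_de <- round(config$frac_de * n)
    de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
    n_up <- ceiling(n_de / 2)
    label <- rep("null", n)
    label[de_idx[seq_len(n_up)]] <- "up"
    if (n_de > n_up) label[de_idx[(n_up + 1):n_de]] <- "down"
    gene_truth <- tibble::tibble(
      gene_id = genes$gene_id,
      label = label,
      planted_log2fc = ifelse(label == "up", config$log2fc,
                              ifelse(label == "down", -config$log2fc, 0)),
      expression = stats::rlnorm(n, meanlog = 0,
                                 sdlog = config$expression_sdlog)
    )
    # fragment -> gene by largest overlap with the (margin-extended) span
    margin <- config$promoter_margin
    gstart <- ifelse(genes$strand == "+", genes$start - margin, genes$start)
    gend <- ifelse(genes$strand == "+", genes$end, genes$end + margin)
    frag_gene <- rep(NA_character_, nrow(fragments))
    for (ctg in unique(fragments$contig)) {
      fi <- which(fragments$contig == ctg)
      gi <- which(genes$contig == ctg)
      if (length(gi) == 0L) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(fragments$start[fi] + 1L, fragments$end[fi]),
        IRanges::IRanges(gstart[gi] + 1L, gend[gi])
      )
      if (length(hits) == 0L) next
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::IRanges(fragments$start[fi] + 1L,
                         fragments$end[fi])[S4Vectors::queryHits(hits)],
        IRanges::IRanges(gstart[gi] + 1L,
                         gend[gi])[S4Vectors::subjectHits(hits)]
      ))
      best <- tibble::tibble(
        q = S4Vectors::queryHits(hits), s = S4Vectors::subjectHits(hits),
        ov = ov
      ) |>
        dplyr::group_by(.data$q) |>
        dplyr::slice_max(.data$ov, n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
      frag_gene[fi[best$q]] <- genes$gene_id[gi[best$s]]
    }
    expr <- gene_truth$expression[match(frag_gene, gene_truth$gene_id)]
    lfc <- gene_truth$planted_log2fc[match(frag_gene, gene_truth$gene_id)]
    occupancy_ref <- config$background + ifelse(is.na(expr), 0, expr)
    occupancy_trt <- occupancy_ref * 2^ifelse(is.na(lfc), 0, lfc)
    structure(list(
      genes = gene_truth,
      fragments = tibble::tibble(
        fragment_id = fragments$fragment_id,
        contig = fragments$contig,
        start = fragments$start,
        end = fragments$end,
        gene_id = frag_gene,
        occupancy_ref = occupancy_ref,
        occupancy_trt = occupancy_trt
      )
    ), class = "tada_truth")
  })
}

#' Simulate replicate DamID fragment counts
#'
#' Per sample, fragment counts are drawn from a negative binomial with mean
#' `depth * occupancy / sum(occupancy)` (occupancy of the sample's
#' condition) and the configured genome-wide dispersion; dispersion below
#' `1e-8` uses Poisson noise.
#'
#' @param truth A `tada_truth` from [simulate_occupancy()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A long tibble with columns `fragment_id`, `contig`, `start`,
#'   `end`, `sample`, `condition`, `replicate`, `count`.
#' @export
simulate_counts <- function(truth, config = sim_config(), seed = 1L) {
  stopifnot(inherits(truth, "tada_truth"), inherits(config, "sim_config"))
  if (config$depth <= 0) {
    stop("argument error: depth must be > 0", call. = FALSE)
  }
  fr <- truth$fragments
  conds <- config$conditions
  samples <- tidyr::expand_grid(
    condition = unname(conds[c("reference", "treatment")]),
    replicate = seq_len(config$n_replicates)
  ) |>
    dplyr::mutate(sample = paste0(.data$condition, "_", .data$replicate))
  local_seed(seed, {
    out <- purrr::pmap(samples, function(condition, replicate, sample) {
      occ <- if (condition == conds[["reference"]]) {
        fr$occupancy_ref
      } else {
        fr$occupancy_trt
      }
      mu <- config$depth * occ / sum(occ)
      count <- as.integer(if (config$dispersion < 1e-8) {
        stats::rpois(length(mu), lambda = mu)
      } else {
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
      })
      tibble::tibble(
        fragment_id = fr$fragment_id, contig = fr$contig,
        start = fr$start, end = fr$end,
        sample = sample, condition = condition,
        replicate = as.integer(replicate), count = count
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Emit simulated counts as per-sample SAM files
#'
#' Writes one unsorted minimal-header SAM file per sample whose reads sit
#' exactly on GATC fragment boundaries, for testing edge counting: internal
#' fragments alternate forward reads at the fragment start and reverse reads
#' ending at the fragment end; left-terminal fragments emit reverse reads at
#' their right boundary, right-terminal (and motif-free) fragments forward
#' reads at their start. Recounting these files with
#' [count_reads_to_fragments()] reproduces the count matrix exactly.
#'
#' @param counts Long count tibble from [simulate_counts()].
#' @param fragments Fragment map (for terminal flags).
#' @param genome Genome tibble (for header `@SQ` lines and read clipping).
#' @param dir Output directory.
#' @param read_length Read length, bp.
#' @return A tibble with columns `sample`, `path`.
#' @export
write_sam <- function(counts, fragments, genome, dir,
                      read_length = 75L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clen <- stats::setNames(as.integer(genome$length), genome$contig)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$contig,
                      as.integer(genome$length)))
  fr <- fragments[, c("fragment_id", "start", "end", "terminal")]
  samples <- unique(counts$sample)
  paths <- character(length(samples))
  for (i in seq_along(samples)) {
    smp <- samples[i]
    cc <- dplyr::inner_join(counts[counts$sample == smp, ], fr,
                            by = c("fragment_id", "start", "end"))
    cc <- cc[cc$count > 0, ]
    lines <- purrr::pmap(
      cc[, c("fragment_id", "contig", "start", "end", "terminal", "count")],
      function(fragment_id, contig, start, end, terminal, count) {
        L <- clen[[contig]]
        idx <- seq_len(count)
        if (terminal && start == 0L && end < L) {
          rev_read <- rep(TRUE, count)     # left-terminal: boundary at end
        } else if (terminal) {
          rev_read <- rep(FALSE, count)    # right-terminal / motif-free
        } else {
          rev_read <- idx %% 2L == 0L      # alternate strands
        }
        len_f <- min(read_length, L - start)
        len_r <- min(read_length, end)
        pos1 <- ifelse(rev_read, end - len_r + 1L, start + 1L)
        cig <- ifelse(rev_read, paste0(len_r, "M"), paste0(len_f, "M"))
        sprintf("%s_%d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                fragment_id, idx, ifelse(rev_read, 16L, 0L), contig,
                pos1, cig)
      }
    )
    paths[i] <- file.path(dir, paste0(smp, ".sam"))
    writeLines(c(header, unlist(lines)), paths[i])
  }
  tibble::tibble(sample = samples, path = paths)
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: genome, fragment map, gene models, planted truth and
#' replicate counts in one call, with sub-seeds derived from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (keep below 2^31 - 4).
#' @return A list of class `tada_sim` with elements `config`, `genome`,
#'   `fragments`, `genes`, `truth`, `counts`.
#' @export
simulate_tada <- function(config = sim_config(), seed = 1L) {
  genome <- simulate_genome(config, seed = seed)
  fragments <- gatc_fragment_map(genome)
  genes <- simulate_genes(genome, config, seed = seed + 1L)
  truth <- simulate_occupancy(genes, fragments, config, seed = seed + 2L)
  counts <- simulate_counts(truth, config, seed = seed + 3L)
  structure(list(config = config, genome = genome, fragments = fragments,
                 genes = genes, truth = truth, counts = counts),
            class = "tada_sim")
}
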