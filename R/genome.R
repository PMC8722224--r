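#' Read a genome FASTA file into a genome table
#'
#' Loads every record of a (possibly line-wrapped, possibly lowercase) FASTA
#' file and returns one row per contig. Sequences are uppercased; the IUPAC
#' ambiguity code `N` is allowed and never matches the GATC motif.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `contig` (character), `sequence` (uppercase
#'   DNA string) and `length` (integer, base pairs).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "gatcGATC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    stop("format error in ", path, " at line 1: empty FASTA file", call. = FALSE)
  }
  if (!startsWith(first, ">")) {
    stop("format error in ", path, " at line 1: expected '>' FASTA header",
         call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("format error in ", path, ": no FASTA records", call. = FALSE)
  }
  contig <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(contig)) {
    stop("duplicated contig names in ", path, ": ",
         paste(unique(contig[duplicated(contig)]), collapse = ", "),
         call. = FALSE)
  }
  genome <- tibble::tibble(
    contig   = contig,
    sequence = toupper(unname(as.character(seqs))),
    length   = unname(Biostrings::width(seqs))
  )
  validate_genome(genome)
}

#' Build a genome table from named sequences
#'
#' Convenience constructor used throughout the package and by the simulator:
#' takes a named character vector of DNA sequences and returns the same
#' genome tibble [read_fasta()] produces.
#'
#' @param sequences Named character vector of DNA sequences.
#' @return A genome tibble (`contig`, `sequence`, `length`).
#' @export
genome_table <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    names(sequences) <- paste0("contig_", seq_along(sequences))
  }
  validate_genome(tibble::tibble(
    contig   = names(sequences),
    sequence = toupper(unname(sequences)),
    length   = unname(nchar(sequences))
  ))
}

validate_genome <- function(genome) {
  stopifnot(is.data.frame(genome),
            all(c("contig", "sequence", "length") %in% names(genome)))
  if (anyDuplicated(genome$contig)) {
    stop("contig names must be unique", call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", genome$sequence)
  if (any(bad)) {
    stop("sequence for contig ", genome$contig[which(bad)[1]],
         " contains characters other than A/C/G/T/N", call. = FALSE)
  }
  if (!all(nchar(genome$sequence) == genome$length)) {
    stop("stored lengths disagree with sequence lengths", call. = FALSE)
  }
  tibble::as_tibble(genome)
}

#' Write a genome table to FASTA
#'
#' @param genome Genome tibble from [read_fasta()] or [genome_table()].
#' @param path Output FASTA path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  genome <- validate_genome(genome)
  seqs <- Biostrings::DNAStringSet(genome$sequence)
  names(seqs) <- genome$contig
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Locate GATC motif occurrences in a genome
#'
#' Scans every contig for the DpnI recognition motif GATC. The motif is its
#' own reverse complement, so the scan is strand-independent; `N` never
#' matches. Contigs shorter than the motif simply contribute zero sites.
#'
#' @param genome Genome tibble.
#' @return A tibble with columns `contig`, `start`, `end` — one row per motif
#'   occurrence, 0-based half-open coordinates (`end = start + 4`), sorted by
#'   contig then start.
#' @export
find_gatc_sites <- function(genome) {
  genome <- validate_genome(genome)
  if (nrow(genome) == 0L) stop("genome is empty", call. = FALSE)
  sites <- purrr::map2(genome$contig, genome$sequence, function(ctg, seq) {
    m <- Biostrings::matchPattern("GATC", Biostrings::DNAString(seq))
    tibble::tibble(contig = ctg, start = BiocGenerics::start(m) - 1L)
  })
  out <- dplyr::arrange(dplyr::bind_rows(sites), .data$contig, .data$start)
  dplyr::mutate(out, end = .data$start + 4L)
}

#' Build the GATC fragment map of a genome
#'
#' DamID resolution is the GATC fragment: the interval between consecutive
#' GATC motif start coordinates. Fragments tile each contig without gaps;
#' the sub-fragments before the first and after the last motif are retained
#' but flagged `terminal = TRUE` (they are not DpnI-digestible units and are
#' excluded from the median spacing statistic). A contig without any motif
#' yields a single whole-contig terminal fragment; a zero-width leading
#' fragment (motif at position 0) is dropped.
#'
#' @param genome Genome tibble.
#' @return A tibble with columns `fragment_id`, `contig`, `start`, `end`,
#'   `width`, `terminal` and `site_start` (does the fragment start at a GATC
#'   motif?), 0-based half-open, sorted by contig then start.
#' @export
gatc_fragment_map <- function(genome) {
  genome <- validate_genome(genome)
  sites <- find_gatc_sites(genome)
  frags <- purrr::map2(genome$contig, genome$length, function(ctg, len) {
    s <- sites$start[sites$contig == ctg]
    if (length(s) == 0L) {
      return(tibble::tibble(contig = ctg, start = 0L, end = as.integer(len),
                            terminal = TRUE, site_start = FALSE))
    }
    bounds <- c(0L, s, as.integer(len))
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
    terminal <- c(TRUE, rep(FALSE, length(s) - 1L), TRUE)
    site_start <- c(FALSE, rep(TRUE, length(s)))
    keep <- ends > starts  # drops the zero-width [0, 0) leading fragment
    tibble::tibble(contig = ctg, start = starts[keep], end = ends[keep],
                   terminal = terminal[keep], site_start = site_start[keep])
  })
  out <- dplyr::arrange(dplyr::bind_rows(frags), .data$contig, .data$start)
  dplyr::mutate(out,
    fragment_id = sprintf("frag_%06d", dplyr::row_number()),
    width = .data$end - .data$start,
    .before = 1L
  ) |>
    dplyr::relocate("fragment_id", "contig", "start", "end", "width",
                    "terminal", "site_start")
}

#' Median GATC fragment distance
#'
#' The distance between consecutive GATC motif start coordinates, pooled over
#' all contigs, summarised by the lower median (for an even number of
#' distances the smaller of the two central values is returned; no
#' averaging). Equivalently this is the lower median of non-terminal fragment
#' widths. This statistic is the default max-gap tolerance used when merging
#' significant fragments into peaks ([merge_gatcs()]); on the D. melanogaster
#' r6.21 reference it evaluates to 350 bp.
#'
#' @param fragments Fragment map from [gatc_fragment_map()].
#' @return Integer number of base pairs.
#' @export
median_fragment_distance <- function(fragments) {
  stopifnot(is.data.frame(fragments),
            all(c("width", "terminal") %in% names(fragments)))
  d <- fragments$width[!fragments$terminal]
  if (length(d) == 0L) {
    stop("undefined statistic: fewer than two GATC sites on every contig",
         call. = FALSE)
  }
  d <- sort(as.integer(d))
  d[ceiling(length(d) / 2)]
}

#' Write GATC sites or fragments as BED6
#'
#' 0-based half-open BED with the fragment id as name, score 0 and strand
#' `.` (the motif is strand-symmetric).
#'
#' @param fragments Fragment map tibble.
#' @param path Output BED path.
#' @param include_terminal Keep the terminal sub-fragments? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_gatc_bed <- function(fragments, path, include_terminal = FALSE) {
  stopifnot(is.data.frame(fragments))
  if (!include_terminal) fragments <- fragments[!fragments$terminal, ]
  bed <- data.frame(
    chrom = fragments$contig,
    start = fragments$start,
    end = fragments$end,
    name = fragments$fragment_id,
    score = 0L,
    strand = "."
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Parses gene and exon features, 1-based closed GTF coordinates converted to
#' the package's 0-based half-open convention. The transcription start site is
#' strand-aware: `start` for `+` genes, `end - 1` for `-` genes; when a gene
#' carries several transcripts the 5'-most transcript start is used.
#'
#' @param path Path to a GTF file.
#' @param genome Optional genome tibble; gene records on contigs absent from
#'   it trigger a warning.
#' @return A tibble with columns `gene_id`, `gene_name`, `contig`, `strand`,
#'   `start`, `end`, `tss` and a list-column `exons` of per-gene exon
#'   tibbles (`start`, `end`).
#' @export
read_gene_models <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("GTF file does not exist: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(meta)) {
    stop("record-level error: GTF carries no gene_id attribute", call. = FALSE)
  }
  df <- tibble::tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(meta$type),
    gene_id = as.character(meta$gene_id),
    gene_name = if ("gene_name" %in% names(meta)) {
      as.character(meta$gene_name)
    } else {
      as.character(meta$gene_id)
    }
  )
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop("record-level error at GTF record ", bad[1],
         ": missing or invalid strand", call. = FALSE)
  }
  exonish <- df[df$type %in% c("exon", "gene", "transcript", "mRNA"), ]
  genes <- exonish |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      gene_name = .data$gene_name[1],
      contig = .data$contig[1],
      strand = .data$strand[1],
      start = min(.data$start),
      end = max(.data$end),
      exons = list(exon_table(.data$start[.data$type == "exon"],
                              .data$end[.data$type == "exon"],
                              min(.data$start), max(.data$end))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L)
    ) |>
    dplyr::relocate("gene_id", "gene_name", "contig", "strand", "start",
                    "end", "tss", "exons") |>
    dplyr::arrange(.data$contig, .data$start)
  if (!is.null(genome)) {
    unknown <- setdiff(unique(genes$contig), genome$contig)
    if (length(unknown) > 0L) {
      warning("gene records on contigs absent from the genome: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  genes
}

exon_table <- function(starts, ends, gene_start, gene_end) {
  if (length(starts) == 0L) {
    # no explicit exon features: treat the whole span as one exon
    return(tibble::tibble(start = gene_start, end = gene_end))
  }
  dplyr::arrange(tibble::tibble(start = starts, end = ends), .data$start)
}

#' Write gene models as GTF
#'
#' Inverse of [read_gene_models()]: emits one `gene` feature and one `exon`
#' feature per exon, converting back to 1-based closed GTF coordinates.
#'
#' @param genes Gene tibble from [read_gene_models()] or [simulate_genes()].
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  stopifnot(is.data.frame(genes))
  rows <- purrr::pmap(genes, function(gene_id, gene_name, contig, strand,
                                      start, end, tss, exons, ...) {
    attr_str <- sprintf('gene_id "%s"; gene_name "%s";', gene_id, gene_name)
    gene_line <- sprintf("%s\ttadascope\tgene\t%d\t%d\t.\t%s\t.\t%s",
                         contig, start + 1L, end, strand, attr_str)
    exon_lines <- sprintf("%s\ttadascope\texon\t%d\t%d\t.\t%s\t.\t%s",
                          contig, exons$start + 1L, exons$end, strand,
                          attr_str)
    c(gene_line, exon_lines)
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Sample uniform random genomic positions
#'
#' Positions are drawn uniformly over the concatenated contig lengths, so
#' expected per-contig counts are proportional to contig length. Used as the
#' "random regions" background class in TSS meta-profiles.
#'
#' @param genome Genome tibble.
#' @param n Number of positions (>= 1).
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG state is used.
#' @return A tibble with columns `contig`, `pos` (0-based).
#' @export
sample_random_regions <- function(genome, n, seed = NULL) {
  genome <- validate_genome(genome)
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("argument error: n must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  draw <- function() {
    total <- sum(as.numeric(genome$length))
    offsets <- cumsum(c(0, as.numeric(genome$length)))
    u <- floor(stats::runif(n, min = 0, max = total))
    idx <- findInterval(u, offsets, rightmost.closed = FALSE)
    tibble::tibble(
      contig = genome$contig[idx],
      pos = as.integer(u - offsets[idx])
    )
  }
  local_seed(seed, draw())
}
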