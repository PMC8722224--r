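# Fixtures built in code; no files ship with the package.

# deterministic random DNA (no seed side effects on callers)
random_dna <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# independent brute-force motif scan: O(n) substring comparison
scan_gatc_naive <- function(seq) {
  n <- nchar(seq)
  if (n < 4) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - 3)) {
    if (substr(seq, i, i + 3) == "GATC") hits <- c(hits, i - 1L)
  }
  hits
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# a small genome/genes/fragments bundle used by several suites
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(contig_length = 1e5, n_genes = 20, depth = 5e4)
      cache <<- c(simulate_tada(cfg, seed = 3), list(cfg = cfg))
    }
    cache
  }
})

# stats-table stub for peak-calling tests
stats_row <- function(contig, start, end, logFC = 1, p = 1e-6,
                      id = NULL) {
  tibble::tibble(
    fragment_id = id %||% sprintf("f_%s_%d", contig, start),
    contig = contig, start = as.integer(start), end = as.integer(end),
    logFC = logFC, p_value = p
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
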