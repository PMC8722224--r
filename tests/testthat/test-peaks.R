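# O(n^2) transitive-closure clustering oracle
cluster_naive <- function(stats, tol) {
  stats <- stats[order(stats$contig, stats$start), ]
  n <- nrow(stats)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- stats$contig[i] == stats$contig[j] &&
        (stats$start[j] - stats$end[i] <= tol) &&
        (stats$start[i] - stats$end[j] <= tol)
    }
  }
  # transitive closure
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  grp <- integer(n)
  g <- 0L
  for (i in seq_len(n)) {
    if (grp[i] == 0L) {
      g <- g + 1L
      grp[adj[i, ]] <- g
    }
  }
  grp
}

simes_naive <- function(p) {
  m <- length(p)
  ps <- sort(p)
  min(1, min(m * ps / seq_len(m)))
}

bh_naive <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, 0)
  q <- numeric(m)
  q[o] <- qs
  q
}

test_that("max-gap merging matches hand examples", {
  st <- dplyr::bind_rows(
    stats_row("c1", 0, 100), stats_row("c1", 400, 500),
    stats_row("c1", 1000, 1100)
  )
  m <- merge_gatcs(st, 350)   # gaps 300 and 500
  expect_equal(length(unique(m$peak_id)), 2L)
  expect_equal(m$peak_id[1], m$peak_id[2])
  expect_false(m$peak_id[2] == m$peak_id[3])

  one <- call_peaks(stats_row("c1", 5, 10, p = 1e-7), tolerance = 350)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_gatc, 1L)
})

test_that("merging equals the transitive-closure oracle on random input", {
  withr::with_seed(17, {
    for (rep in 1:3) {
      starts <- sort(sample.int(20000, 200))
      widths <- sample(50:400, 200, replace = TRUE)
      st <- stats_row(sample(c("c1", "c2"), 200, replace = TRUE),
                      starts, starts + widths,
                      id = sprintf("f%03d", 1:200))
      tol <- sample(c(0, 100, 350), 1)
      got <- merge_gatcs(st, tol)
      oracle <- cluster_naive(st, tol)
      # same partition: peak ids and oracle groups must be bijective
      expect_equal(length(unique(got$peak_id)), length(unique(oracle)))
      expect_true(all(tapply(oracle, got$peak_id,
                             function(x) length(unique(x))) == 1))
    }
  })
})

test_that("Simes combination matches its definition", {
  expect_equal(simes_combine(0.2), 0.2)
  expect_equal(simes_combine(rep(0.07, 5)), 0.07)
  expect_equal(simes_combine(c(0.01, 0.04)), 0.02)
  expect_error(simes_combine(c(0.5, 1.2)), "0, 1")
  withr::with_seed(5, {
    for (i in 1:20) {
      p <- runif(sample(1:12, 1))
      got <- simes_combine(p)
      expect_equal(got, simes_naive(p))
      expect_gte(got, min(p))
      expect_lte(got, min(1, length(p) * min(p)))
    }
  })
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  withr::with_seed(6, {
    for (i in 1:20) {
      p <- runif(sample(1:15, 1))
      expect_equal(bh_adjust(p), bh_naive(p))
    }
    p <- runif(30)
    ord <- sample.int(30)
    expect_equal(bh_adjust(p)[ord], bh_adjust(p[ord]))
  })
})

test_that("genes take the minimum-FDR overlapping peak", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), gene_name = c("g1", "g2"),
    contig = "c1", strand = c("+", "-"),
    start = c(100L, 5000L), end = c(1000L, 6000L),
    tss = c(100L, 5999L),
    exons = list(tibble::tibble(start = 100L, end = 1000L),
                 tibble::tibble(start = 5000L, end = 6000L))
  )
  peaks <- tibble::tibble(
    peak_id = c("p1", "p2"), contig = "c1",
    start = c(150L, 800L), end = c(300L, 1200L),
    n_gatc = c(1L, 2L), members = list("a", c("b", "c")),
    mean_logfc = c(1, 2), mixed_sign = FALSE,
    p_simes = c(0.01, 1e-4), q = c(0.05, 0.001), direction = 1
  )
  got <- assign_genes(peaks, genes)
  expect_equal(got$peak_id, c("p2", NA))
  expect_equal(got$fdr, c(0.001, NA))
  expect_equal(got$significant, c(TRUE, FALSE))
})

test_that("gene assignment equals an exhaustive overlap scan", {
  withr::with_seed(23, {
    gstart <- sort(sample.int(50000, 50))
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:50), gene_name = gene_id,
      contig = "c1", strand = sample(c("+", "-"), 50, TRUE),
      start = gstart, end = gstart + sample(500:2000, 50, TRUE)
    )
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    pstart <- sort(sample.int(50000, 30))
    q <- runif(30, 0, 0.05)
    peaks <- tibble::tibble(
      peak_id = sprintf("p%02d", 1:30), contig = "c1",
      start = pstart, end = pstart + sample(100:800, 30, TRUE),
      n_gatc = 1L, members = as.list(peak_id),
      mean_logfc = rnorm(30), mixed_sign = FALSE,
      p_simes = q / 2, q = q, direction = 1
    )
    got <- assign_genes(peaks, genes, fdr = 0.01)
    for (i in seq_len(50)) {
      ov <- which(peaks$start < genes$end[i] & peaks$end > genes$start[i])
      if (length(ov) == 0L) {
        expect_true(is.na(got$peak_id[i]))
        expect_false(got$significant[i])
      } else {
        best <- ov[order(peaks$q[ov], -abs(peaks$mean_logfc[ov]),
                         peaks$start[ov])][1]
        expect_equal(got$peak_id[i], peaks$peak_id[best])
        expect_equal(got$significant[i], peaks$q[best] < 0.01)
      }
    }
    # significant-call count is monotone in the FDR threshold
    thresholds <- c(0.05, 0.01, 0.005, 0.001)
    n_sig <- vapply(thresholds, function(th) {
      sum(assign_genes(peaks, genes, fdr = th)$significant)
    }, 0L)
    expect_true(all(diff(n_sig) <= 0))
  })
})

test_that("peak feature annotation follows the priority rules", {
  genes <- tibble::tibble(
    gene_id = "g1", gene_name = "g1", contig = "c1", strand = "+",
    start = 2000L, end = 6000L, tss = 2000L,
    exons = list(tibble::tibble(start = c(2000L, 4000L),
                                end = c(2500L, 6000L)))
  )
  pk <- function(s, e) {
    tibble::tibble(peak_id = "p", contig = "c1",
                   start = as.integer(s), end = as.integer(e))
  }
  expect_equal(as.character(
    annotate_peak_features(pk(1700, 1900), genes)$feature), "promoter")
  expect_equal(as.character(
    annotate_peak_features(pk(3000, 3200), genes)$feature), "intron")
  expect_equal(as.character(
    annotate_peak_features(pk(6200, 6400), genes)$feature), "downstream")
  expect_equal(as.character(
    annotate_peak_features(pk(20000, 20100), genes)$feature),
    "distal_intergenic")
  # promoter outranks exon when a peak touches both
  expect_equal(as.character(
    annotate_peak_features(pk(1900, 2200), genes)$feature), "promoter")

  many <- dplyr::bind_rows(pk(1700, 1900), pk(3000, 3200),
                           pk(20000, 20100))
  many$peak_id <- c("a", "b", "c")
  props <- feature_proportions(annotate_peak_features(many, genes))
  expect_equal(sum(props$proportion), 1)
})

test_that("pipeline output is deterministic for identical inputs", {
  sim <- tiny_sim()
  r1 <- tada_pipeline(sim$counts, sim$fragments, sim$genes)
  r2 <- tada_pipeline(sim$counts, sim$fragments, sim$genes)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_tada_results(r1, d1)
  f2 <- write_tada_results(r2, d2)
  for (k in names(f1)) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  }
})
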