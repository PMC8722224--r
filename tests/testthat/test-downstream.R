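# exact two-sided Fisher p by full enumeration over fixed margins
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, r1, n - r1, c1)
  obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

test_that("TSS distances are signed by gene strand", {
  genes <- tibble::tibble(
    gene_id = c("gp", "gm"), contig = c("c1", "c2"),
    strand = c("+", "-"), start = c(1000L, 1000L), end = c(3000L, 3000L),
    tss = c(1000L, 2999L)
  )
  sites <- tibble::tibble(contig = c("c1", "c1", "c2", "c2"),
                          pos = c(1000L, 1300L, 2999L, 3299L))
  d <- tss_distances(sites, genes)
  expect_equal(d$distance, c(0L, 300L, 0L, -300L))
  expect_error(tss_distances(sites, genes[0, ]), "TSS")
})

test_that("planted TSS-proximal sites dominate the near-TSS bin", {
  sim <- tiny_sim()
  near <- withr::with_seed(41, tibble::tibble(
    contig = sim$genes$contig,
    pos = as.integer(sim$genes$tss +
                       sample(-200:200, nrow(sim$genes), TRUE)),
    class = "planted"
  ))
  rand <- sample_random_regions(sim$genome, 500, seed = 42)
  rand$class <- "random"
  prof <- tss_distance_profile(dplyr::bind_rows(near, rand), sim$genes,
                               breaks = seq(-5000, 5000, by = 500))
  frac_near <- function(cls) {
    pr <- prof[prof$class == cls, ]
    sum(pr$count[!is.na(pr$lower) & pr$lower >= -500 & pr$upper <= 500]) /
      sum(pr$count)
  }
  expect_gt(frac_near("planted"), frac_near("random"))
  # histogram mass equals the site count per class
  expect_equal(sum(prof$count[prof$class == "planted"]), nrow(near))
  expect_equal(sum(prof$count[prof$class == "random"]), 500L)
})

test_that("random-site TSS distances match the genome-wide distribution", {
  sim <- tiny_sim()
  rand <- sample_random_regions(sim$genome, 1e5, seed = 7)
  rand$class <- "random"
  d_rand <- tss_distances(rand, sim$genes)$distance
  all_pos <- tibble::tibble(contig = sim$genome$contig[1],
                            pos = 0:(sim$genome$length[1] - 1L))
  d_all <- tss_distances(all_pos, sim$genes)$distance
  ks <- suppressWarnings(stats::ks.test(d_rand, d_all))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("gene-body profiles are flat on constant tracks and strand-aware", {
  sim <- tiny_sim()
  genes <- sim$genes
  track_const <- tibble::tibble(contig = sim$genome$contig[1],
                                start = 0L,
                                end = sim$genome$length[1],
                                value = 3.5)
  expr <- tibble::tibble(gene_id = genes$gene_id,
                         tpm = seq_len(nrow(genes)))
  prof <- gene_body_profile(track_const, genes, expr, n_quantiles = 4)
  expect_true(all(prof$mean_value == 3.5))

  # signal planted only on the top-quantile genes
  top <- genes$gene_id[dplyr::ntile(expr$tpm, 4) == 4]
  tg <- genes[genes$gene_id %in% top, ]
  steps <- sort(unique(c(0L, tg$start, tg$end, sim$genome$length[1])))
  track_top <- tibble::tibble(
    contig = sim$genome$contig[1],
    start = steps[-length(steps)], end = steps[-1]
  )
  track_top$value <- vapply(seq_len(nrow(track_top)), function(i) {
    if (any(track_top$start[i] >= tg$start & track_top$end[i] <= tg$end)) {
      5
    } else {
      0
    }
  }, 0)
  prof2 <- gene_body_profile(track_top, genes, expr, n_quantiles = 4,
                             flank_bp = 0)
  body <- prof2[prof2$region == "body", ]
  top_prof <- body$mean_value[body$quantile == 4]
  bot_prof <- body$mean_value[body$quantile == 1]
  expect_true(all(top_prof > bot_prof))

  # a minus-strand gene's bins are the reverse of the same plus orientation
  g1 <- genes[1, ]
  g1$strand <- "+"
  g2 <- g1
  g2$strand <- "-"
  asym <- tibble::tibble(
    contig = sim$genome$contig[1],
    start = seq(g1$start, g1$end - 1L, by = 50L)
  )
  asym$end <- pmin(asym$start + 50L, g1$end)
  asym$value <- seq_len(nrow(asym))
  e1 <- tibble::tibble(gene_id = g1$gene_id, tpm = 1)
  p_plus <- gene_body_profile(asym, g1, e1, n_quantiles = 1, flank_bp = 0)
  p_minus <- gene_body_profile(asym, g2, e1, n_quantiles = 1, flank_bp = 0)
  expect_equal(p_minus$mean_value, rev(p_plus$mean_value))

  expect_error(
    gene_body_profile(track_const, genes[1:2, ], expr[1:2, ],
                      n_quantiles = 5),
    "quantile"
  )
})

test_that("Fisher enrichment matches exact enumeration and handles edges", {
  # balanced table: no association
  uni <- sprintf("g%02d", 1:20)
  got <- fisher_enrichment(uni[1:10], uni, uni[c(1:5, 11:15)])
  expect_equal(got$odds_ratio, 1)
  expect_equal(got$p_value, 1)

  # table (8,2,1,9) against the enumeration oracle
  uni2 <- sprintf("h%02d", 1:20)
  cls <- uni2[1:10]                 # a + b = 10
  sel <- uni2[c(1:8, 11)]           # a = 8, c = 1
  got2 <- fisher_enrichment(sel, uni2, cls)
  expect_equal(got2[, c("a", "b", "c", "d")],
               tibble::tibble(a = 8L, b = 2L, c = 1L, d = 9L),
               ignore_attr = TRUE)
  expect_equal(got2$p_value, fisher_enum(8, 2, 1, 9))

  # symmetric under simultaneous row and column swap
  swapped <- fisher_enrichment(setdiff(uni2, sel), uni2,
                               setdiff(uni2, cls))
  expect_equal(got2$p_value, swapped$p_value)

  # degenerate margins: selected = universe
  deg <- fisher_enrichment(uni2, uni2, cls)
  expect_equal(deg$p_value, 1)
  expect_error(fisher_enrichment("x", character(0), "x"), "universe")
})

test_that("set overlaps reproduce exclusive regions and percentages", {
  ov <- set_overlap(list(A = c("g1", "g2"), B = "g2"))
  expect_equal(ov$regions$count[ov$regions$region == "A&B"], 1L)
  pair <- ov$pairwise
  expect_equal(pair$percent[pair$from == "A" & pair$to == "B"], 50)

  withr::with_seed(13, {
    pool <- sprintf("id%04d", 1:400)
    lists <- list(A = sample(pool, 150), B = sample(pool, 120),
                  C = sample(pool, 90))
    ov3 <- set_overlap(lists)
    # brute-force set algebra oracle
    for (i in seq_len(nrow(ov3$regions))) {
      nm <- strsplit(ov3$regions$region[i], "&", fixed = TRUE)[[1]]
      inside <- Reduce(intersect, lists[nm])
      outside <- unlist(lists[setdiff(names(lists), nm)])
      expect_equal(ov3$regions$count[i],
                   length(setdiff(inside, outside)),
                   info = ov3$regions$region[i])
    }
    expect_equal(sum(ov3$regions$count),
                 length(unique(unlist(lists))))
  })
  expect_warning(set_overlap(list(A = character(0), B = "g1")), "empty")
})

test_that("methylated-site selection respects the coverage quantile", {
  sim <- tiny_sim()
  sites <- methylated_gatc_sites(sim$counts, condition = "DN",
                                 quantile = 0.5)
  expect_true(nrow(sites) > 0)
  expect_true(nrow(sites) < nrow(sim$fragments))
  expect_true(all(sites$pos >= 0 & sites$pos < sim$genome$length[1]))
})
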