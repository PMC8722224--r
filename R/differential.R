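#' Elementwise log2 transform with pseudocount
#'
#' @param x Numeric vector or matrix of non-negative values (typically CPM).
#' @param pseudocount Positive offset added before taking log2.
#' @return `log2(x + pseudocount)`, same shape as `x`.
#' @export
log_transform <- function(x, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  if (any(x < 0, na.rm = TRUE)) {
    stop("negative values cannot be log-transformed", call. = FALSE)
  }
  log2(x + pseudocount)
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Method-of-moments fit of the scaled inverse-chi-squared variance prior on
#' the log scale: with `z = log(s2)` and `e = z - digamma(d/2) + log(d/2)`,
#' the prior degrees of freedom solve
#' `trigamma(d0/2) = max(0, var(e) - mean(trigamma(d/2)))` and the prior
#' variance is `s0^2 = exp(mean(e) - digamma(d0/2) + log(d0/2))`. When the
#' observed spread of log variances does not exceed its sampling noise the
#' prior is degenerate (`d0 = Inf`, complete shrinkage to `s0^2`).
#'
#' @param s2 Per-fragment residual variances (>= 10 finite values with
#'   `df >= 1` required).
#' @param df Residual degrees of freedom (scalar or per-fragment vector).
#' @return A list of class `eb_hyperparams` with elements `d0` (prior df,
#'   possibly `Inf`) and `s0_sq` (prior variance).
#' @export
estimate_eb_hyperparams <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & df >= 1
  s2 <- s2[ok]
  df <- df[ok]
  if (all(s2 == 0)) {
    stop("degenerate data: all residual variances are zero", call. = FALSE)
  }
  pos <- s2 > 0
  s2 <- s2[pos]
  df <- df[pos]
  if (length(s2) < 10L) {
    stop("at least 10 fragments with positive variance and df >= 1 needed",
         call. = FALSE)
  }
  z <- log(s2)
  if (stats::var(z) < 1e-15) {
    # zero spread: a point-mass prior reproduces the common value exactly
    return(structure(list(d0 = Inf, s0_sq = exp(mean(z))),
                     class = "eb_hyperparams"))
  }
  e <- z - digamma(df / 2) + log(df / 2)
  rhs <- stats::var(e) - mean(trigamma(df / 2))
  if (!is.finite(rhs) || rhs <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "eb_hyperparams")
}

# Newton solve of trigamma(y) = x for y > 0
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated t-test on a log-expression matrix
#'
#' For each row, the log fold change is the treatment-group mean minus the
#' reference-group mean; the pooled residual variance (df `n1 + n2 - 2`) is
#' shrunk towards the prior: posterior variance
#' `(d0 * s0^2 + d * s2) / (d0 + d)`. The moderated t is the log fold change
#' over its posterior standard error and two-sided p-values use a
#' t-distribution with `d + d0` degrees of freedom (standard normal when
#' `d0 = Inf`). With `d0 = 0` the statistic reduces to the classical pooled
#' two-sample t-test.
#'
#' @param logmat Numeric matrix, fragments x samples, rownames = fragment
#'   ids.
#' @param treatment,reference Column names (or indices) of the two disjoint
#'   sample groups.
#' @param hyper Optional `eb_hyperparams`; estimated from the data when
#'   `NULL`.
#' @param p_threshold Significance threshold on the per-fragment p-value
#'   (default `1e-5`).
#' @return A tibble with columns `fragment_id`, `logFC`, `s2`, `df`, `t`,
#'   `p_value`, `posterior_var`, `significant`.
#' @export
moderated_t_test <- function(logmat, treatment, reference, hyper = NULL,
                             p_threshold = 1e-5) {
  stopifnot(is.matrix(logmat))
  if (is.character(treatment)) treatment <- match(treatment, colnames(logmat))
  if (is.character(reference)) reference <- match(reference, colnames(logmat))
  if (anyNA(treatment) || anyNA(reference)) {
    stop("unknown sample columns in treatment/reference", call. = FALSE)
  }
  if (length(intersect(treatment, reference)) > 0L) {
    stop("treatment and reference groups must be disjoint", call. = FALSE)
  }
  n1 <- length(treatment)
  n2 <- length(reference)
  if (n1 == 0L || n2 == 0L) {
    stop("both groups need at least one sample", call. = FALSE)
  }
  x1 <- logmat[, treatment, drop = FALSE]
  x2 <- logmat[, reference, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  lfc <- unname(m1 - m2)
  d <- n1 + n2 - 2L
  ss <- unname(rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2))
  s2 <- if (d > 0L) ss / d else rep(0, nrow(logmat))
  if (is.null(hyper)) {
    if (d < 1L) {
      stop("cannot estimate hyperparameters with zero residual df; ",
           "supply `hyper`", call. = FALSE)
    }
    hyper <- estimate_eb_hyperparams(s2, d)
  }
  stopifnot(inherits(hyper, "eb_hyperparams"))
  d0 <- hyper$d0
  s0 <- hyper$s0_sq
  post_var <- if (is.infinite(d0)) {
    rep(s0, length(s2))
  } else if (d0 + d == 0) {
    s2
  } else {
    (d0 * s0 + d * s2) / (d0 + d)
  }
  se <- sqrt(post_var * (1 / n1 + 1 / n2))
  t <- lfc / se
  t[lfc == 0 & se == 0] <- 0
  df_total <- d + d0
  p <- if (is.infinite(df_total)) {
    2 * stats::pnorm(-abs(t))
  } else {
    2 * stats::pt(-abs(t), df = df_total)
  }
  out <- tibble::tibble(
    fragment_id = rownames(logmat) %||% as.character(seq_len(nrow(logmat))),
    logFC = lfc,
    s2 = s2,
    df = as.numeric(d),
    t = t,
    p_value = p,
    posterior_var = post_var,
    significant = p < p_threshold
  )
  attr(out, "hyper") <- hyper
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-GATC differential occupancy statistics
#'
#' The full per-fragment differential step: CPM normalization, log2 with
#' pseudocount, empirical-Bayes hyperparameter estimation, and a moderated
#' t-test of the fusion condition against the Dam-only reference.
#' Fragments with zero counts in every sample are dropped (and counted in
#' `glance()`). The Jeb-style contrast can be marked `qualitative_only`,
#' mirroring its use as visual confirmation rather than a source of FDR
#' claims.
#'
#' @param counts Long count tibble (`fragment_id`, `contig`, `start`, `end`,
#'   `sample`, `condition`, `count`).
#' @param treatment,reference Condition labels of the contrast (defaults
#'   `"DN"` vs `"Dam"`).
#' @param pseudocount Pseudocount on the CPM scale before log2.
#' @param p_threshold Per-fragment significance threshold (default `1e-5`).
#' @param hyper Optional pre-computed `eb_hyperparams`.
#' @param qualitative_only Flag propagated to the result for contrasts used
#'   only as visual confirmation.
#' @return An object of class `tada_fit`: list with `table` (per-fragment
#'   statistics joined to fragment coordinates), `hyper`, `contrast`,
#'   `n_dropped`, `qualitative_only`. Use [tidy()] / [glance()] to extract.
#' @export
gatc_stats <- function(counts, treatment = "DN", reference = "Dam",
                       pseudocount = 1, p_threshold = 1e-5, hyper = NULL,
                       qualitative_only = FALSE) {
  stopifnot(all(c("fragment_id", "sample", "condition", "count") %in%
                  names(counts)))
  conds <- unique(counts$condition)
  if (!treatment %in% conds || !reference %in% conds) {
    stop("conditions ", treatment, "/", reference, " not found in counts",
         call. = FALSE)
  }
  used <- counts[counts$condition %in% c(treatment, reference), ]
  cpm <- normalize_cpm(used)
  wide <- cpm |>
    dplyr::select("fragment_id", "sample", "cpm") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "cpm")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$fragment_id
  sample_cond <- used |>
    dplyr::distinct(.data$sample, .data$condition)
  raw <- used |>
    dplyr::group_by(.data$fragment_id) |>
    dplyr::summarise(all_zero = all(.data$count == 0), .groups = "drop")
  drop_ids <- raw$fragment_id[raw$all_zero]
  if (length(drop_ids) > 0L) {
    message("dropping ", length(drop_ids), " all-zero fragment(s)")
    mat <- mat[!rownames(mat) %in% drop_ids, , drop = FALSE]
  }
  logmat <- log_transform(mat, pseudocount)
  tcols <- sample_cond$sample[sample_cond$condition == treatment]
  rcols <- sample_cond$sample[sample_cond$condition == reference]
  tab <- moderated_t_test(logmat, tcols, rcols, hyper = hyper,
                          p_threshold = p_threshold)
  hyper_used <- attr(tab, "hyper")
  coords <- counts |>
    dplyr::distinct(.data$fragment_id, .data$contig, .data$start, .data$end)
  tab <- dplyr::left_join(tab, coords, by = "fragment_id") |>
    dplyr::relocate("fragment_id", "contig", "start", "end")
  structure(list(
    table = tab,
    hyper = hyper_used,
    contrast = c(treatment = treatment, reference = reference),
    n_dropped = length(drop_ids),
    p_threshold = p_threshold,
    qualitative_only = qualitative_only
  ), class = "tada_fit")
}

#' @export
print.tada_fit <- function(x, ...) {
  cat("<tada_fit> ", x$contrast[["treatment"]], " vs ",
      x$contrast[["reference"]],
      if (x$qualitative_only) " (qualitative only)" else "", "\n", sep = "")
  cat("  fragments: ", nrow(x$table),
      " (", x$n_dropped, " all-zero dropped)\n", sep = "")
  cat("  significant at p < ", format(x$p_threshold), ": ",
      sum(x$table$significant), "\n", sep = "")
  cat("  prior: d0 = ", format(x$hyper$d0, digits = 4),
      ", s0^2 = ", format(x$hyper$s0_sq, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname gatc_stats
#' @param x A `tada_fit`.
#' @param ... Unused.
#' @export
tidy.tada_fit <- function(x, ...) {
  x$table
}

#' @rdname gatc_stats
#' @export
glance.tada_fit <- function(x, ...) {
  tibble::tibble(
    treatment = x$contrast[["treatment"]],
    reference = x$contrast[["reference"]],
    n_fragments = nrow(x$table),
    n_dropped = x$n_dropped,
    n_significant = sum(x$table$significant),
    d0 = x$hyper$d0,
    s0_sq = x$hyper$s0_sq,
    qualitative_only = x$qualitative_only
  )
}
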