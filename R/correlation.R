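#' Correlation strength of a group of expression profiles
#'
#' Measures how strongly a set of miRNAs is mutually (anti-)correlated:
#' the Frobenius norm of the upper triangle of their pairwise Pearson
#' correlation matrix, normalised by the number of pairs,
#' \deqn{c(X) = \sqrt{\sum_{i_1 < i_2} \rho_{i_1 i_2}^2 \; / \; (n^2 - n)/2}.}
#' `c = 0` for an entirely uncorrelated set and `c = 1` for a perfectly
#' (anti-)correlated one; anti-correlation counts through the square. The
#' statistic drives the per-gene elastic-net mixing parameter (see
#' [tune_alpha()]).
#'
#' @param X Numeric matrix with `n >= 2` miRNA expression rows over `s >= 3`
#'   samples.
#' @return A single number in `[0, 1]`.
#' @examples
#' x <- matrix(rnorm(30), 2, 15, byrow = TRUE)
#' x[2, ] <- -x[1, ]
#' correlation_strength(x) # 1: perfect anti-correlation
#' @export
correlation_strength <- function(X) {
  assert_matrix(X)
  n <- nrow(X)
  if (n < 2) {
    abort("correlation_strength() needs at least 2 rows.")
  }
  if (ncol(X) < 3) {
    abort("correlation_strength() needs at least 3 samples.")
  }
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- if (is.null(rownames(X))) which(sds == 0) else rownames(X)[sds == 0]
    abort(sprintf("Constant rows (zero variance): %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  R <- stats::cor(t(X))
  sqrt(sum(R[upper.tri(R)]^2) / ((n^2 - n) / 2))
}

#' Are co-targeting miRNA groups more correlated than random groups?
#'
#' For every gene in the prior with at least two expressed targeting miRNAs,
#' computes the correlation strength [correlation_strength()] of its
#' regulator group, then builds a resampling null by drawing random miRNA
#' sets from all expressed miRNAs and compares the two samples of c-values
#' with a one-sided (greater) Wilcoxon rank-sum test.
#'
#' @param mirna_expr Numeric matrix, miRNAs in rows, samples in columns.
#' @param prior Prior network tibble (`mirna`, `gene`).
#' @param n_resample Number of random sets drawn per observed group.
#' @param seed Optional integer seed for the resampling.
#' @param null `"matched"` draws, for each gene, sets of the gene's own group
#'   size (isolates the co-targeting effect); `"pooled"` draws set sizes at
#'   random from the observed size distribution.
#' @return An object of class `group_correlation_test`: a list with
#'   `observed` (tibble `gene`, `n_mirnas`, `c`), `null` (numeric c-values),
#'   `statistic` and `p.value`.
#' @export
group_correlation_test <- function(mirna_expr, prior, n_resample = 100,
                                   seed = NULL,
                                   null = c("matched", "pooled")) {
  assert_matrix(mirna_expr)
  null <- match.arg(null)
  prior <- as_edge_tibble(prior)
  usable <- rownames(mirna_expr)[apply(mirna_expr, 1, stats::sd) > 0]
  targets <- split(prior$mirna, prior$gene)
  groups <- lapply(targets, function(m) intersect(unique(m), usable))
  groups <- groups[lengths(groups) >= 2]
  if (!length(groups)) {
    abort("No gene has >= 2 expressed targeting miRNAs with non-zero variance.")
  }
  observed <- tibble(
    gene = names(groups),
    n_mirnas = lengths(groups),
    c = vapply(groups, function(m)
      correlation_strength(mirna_expr[m, , drop = FALSE]), numeric(1))
  )
  if (!is.null(seed)) set.seed(seed)
  sizes <- observed$n_mirnas
  null_c <- unlist(lapply(seq_len(n_resample), function(r) {
    draw_sizes <- if (null == "matched") sizes else
      sample(sizes, length(sizes), replace = TRUE)
    vapply(draw_sizes, function(k) {
      m <- sample(usable, k)
      correlation_strength(mirna_expr[m, , drop = FALSE])
    }, numeric(1))
  }))
  wt <- suppressWarnings(
    stats::wilcox.test(observed$c, null_c, alternative = "greater")
  )
  structure(
    list(observed = observed, null = null_c,
         statistic = unname(wt$statistic), p.value = wt$p.value,
         n_resample = n_resample, null_model = null),
    class = "group_correlation_test"
  )
}

#' @export
print.group_correlation_test <- function(x, ...) {
  cat("Group correlation-strength test\n")
  cat(sprintf("  %d co-targeting groups, median c = %.3f\n",
              nrow(x$observed), stats::median(x$observed$c)))
  cat(sprintf("  %d resampled groups (%s null), median c = %.3f\n",
              length(x$null), x$null_model, stats::median(x$null)))
  cat(sprintf("  one-sided Wilcoxon rank-sum p = %.3g\n", x$p.value))
  invisible(x)
}

#' @describeIn group_correlation_test Density overlay of observed vs.
#'   resampled correlation strengths.
#' @param object A `group_correlation_test`.
#' @param ... Ignored.
#' @method autoplot group_correlation_test
#' @export
autoplot.group_correlation_test <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(c = object$observed$c, set = "co-targeting groups"),
    tibble(c = object$null, set = "resampled groups")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$c, fill = .data$set)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "correlation strength c(X)", y = "density",
                  fill = NULL,
                  subtitle = sprintf("one-sided rank-sum p = %.2g",
                                     object$p.value)) +
    ggplot2::theme_minimal()
}
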