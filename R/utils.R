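# internal helpers shared across modules

# Deterministic 31-bit seed derived from a master seed and a string key.
# Arithmetic kept in doubles below 2^53 so the result is exact and stable
# across platforms; result always fits a 32-bit R integer.
derive_seed <- function(seed, key) {
  h <- 0
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((h + (as.numeric(seed) %% 2147483647) * 97) %% 2147483647)
}

# Left-tailed Wilcoxon rank-sum p-value for H1: values of x are shifted
# towards smaller values than y. Unreachable distances (Inf) are kept in the
# test as the largest tied rank: wilcox.test() would silently drop
# non-finite values, so they are mapped to one more than the largest finite
# value first, which leaves all ranks unchanged. Exact enumeration is used
# for small untied samples, otherwise the normal approximation with
# continuity correction.
wilcox_left <- function(x, y, exact_max = 25L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    return(NA_real_)
  }
  finite <- c(x, y)[is.finite(c(x, y))]
  cap <- if (length(finite)) max(finite) + 1 else 1
  x[is.infinite(x)] <- cap
  y[is.infinite(y)] <- cap
  exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "less", exact = exact,
                       correct = TRUE)$p.value
  )
}

# -log10 transform from a rank-sum p-value to a local enrichment score.
score_from_p <- function(p) -log10(p)

assert_matrix <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  invisible(x)
}

# Edge tibbles are exchanged between modules; normalize the accepted shapes.
as_edge_tibble <- function(x, require_coefficient = FALSE,
                           arg = deparse(substitute(x))) {
  if (inherits(x, "mirnet_fit")) {
    x <- x$edges
  }
  if (!is.data.frame(x) || !all(c("mirna", "gene") %in% names(x))) {
    abort(sprintf(
      "`%s` must be a mirnet_fit or a data frame with columns 'mirna' and 'gene'.",
      arg
    ))
  }
  if (require_coefficient && !"coefficient" %in% names(x)) {
    abort(sprintf("`%s` must carry a 'coefficient' column.", arg))
  }
  as_tibble(x)
}

edge_key <- function(edges) paste(edges$mirna, edges$gene, sep = "\r")
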