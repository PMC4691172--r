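#' Enrichment of inferred edges for validated interactions
#'
#' Tests whether the inferred interactions contain more experimentally
#' validated pairs than expected from the prior target network. The universe
#' is the prior's edge set; each prior edge is cross-classified by whether it
#' was inferred and whether it appears in the validated set, and the
#' resulting 2x2 table is tested with a one-sided (greater) Fisher's exact
#' test. Restricting the validated list (e.g. to a stringency tier) is the
#' caller's responsibility.
#'
#' @param inferred A [infer_network()] fit or edge tibble; edges must be a
#'   subset of `prior`.
#' @param validated Edge tibble of experimentally validated interactions
#'   (`mirna`, `gene`); edges outside the prior are ignored.
#' @param prior Prior network tibble (`mirna`, `gene`); must be non-empty.
#' @return A one-row tibble of class `enrichment_test`:
#'   `n_inferred_validated`, `n_inferred_other`, `n_rest_validated`,
#'   `n_rest_other`, `odds_ratio` (sample odds ratio `ad/bc`) and `p_value`.
#'   An empty inferred set yields `p_value = 1` by convention (with a
#'   message).
#' @export
enrichment_test <- function(inferred, validated, prior) {
  inferred <- as_edge_tibble(inferred)
  validated <- as_edge_tibble(validated)
  prior <- as_edge_tibble(prior) |> dplyr::distinct(.data$mirna, .data$gene)
  if (!nrow(prior)) {
    abort("The prior network is empty.")
  }
  pk <- edge_key(prior)
  ik <- unique(edge_key(inferred))
  extra <- setdiff(ik, pk)
  if (length(extra)) {
    abort(sprintf(
      "%d inferred edges are not part of the prior network; the universe must contain them.",
      length(extra)))
  }
  vk <- intersect(unique(edge_key(validated)), pk)
  inf <- pk %in% ik
  val <- pk %in% vk
  a <- sum(inf & val)
  b <- sum(inf & !val)
  c_ <- sum(!inf & val)
  d <- sum(!inf & !val)
  if (!length(ik)) {
    inform("enrichment_test(): empty inferred network; p = 1 by convention.")
    p <- 1
  } else {
    p <- stats::fisher.test(matrix(c(a, c_, b, d), nrow = 2),
                            alternative = "greater")$p.value
  }
  out <- tibble(
    n_inferred_validated = a, n_inferred_other = b,
    n_rest_validated = c_, n_rest_other = d,
    odds_ratio = (a * d) / (b * c_),
    p_value = p
  )
  class(out) <- c("enrichment_test", class(out))
  out
}
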