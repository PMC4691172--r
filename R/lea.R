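#' Transform regression coefficients into positive edge weights
#'
#' Scales each coefficient by the network-wide maximum absolute coefficient
#' and exponentiates, `w = exp(beta / max|beta|)`, giving weights in
#' `[exp(-1), 1)`. Strong repression (large `|beta|`) maps to small weights,
#' so strongly co-regulated genes end up close in path distance.
#'
#' @param net A [infer_network()] fit or an edge tibble with strictly
#'   negative `coefficient`s.
#' @return The edge tibble with an additional `weight` column.
#' @export
transform_edge_weights <- function(net) {
  edges <- as_edge_tibble(net, require_coefficient = TRUE)
  if (!nrow(edges)) {
    abort("transform_edge_weights(): the network has no edges.")
  }
  if (any(edges$coefficient >= 0)) {
    abort("All coefficients must be strictly negative.")
  }
  dplyr::mutate(edges,
                weight = exp(.data$coefficient / max(abs(.data$coefficient))))
}

#' Project a weighted bipartite network onto its genes
#'
#' Two genes become adjacent when at least one miRNA regulates both; the
#' connecting edge weight is the minimum, over the shared miRNAs, of the sum
#' of the two miRNA-gene weights. All-pairs shortest-path distances on this
#' projected graph (Dijkstra) define the distance matrix used by the local
#' enrichment scores; disconnected pairs are `Inf`.
#'
#' @param weights Edge tibble with columns `mirna`, `gene`, `weight`
#'   (positive), as produced by [transform_edge_weights()].
#' @return An object of class `gene_graph`: `genes`, the projected `edges`
#'   tibble (`from`, `to`, `weight`) and the symmetric distance matrix
#'   `dist`.
#' @export
project_gene_graph <- function(weights) {
  if (!is.data.frame(weights) ||
      !all(c("mirna", "gene", "weight") %in% names(weights))) {
    abort("`weights` needs columns 'mirna', 'gene' and 'weight'.")
  }
  if (any(weights$weight <= 0)) {
    abort("Edge weights must be positive.")
  }
  genes <- sort(unique(weights$gene))
  shared <- dplyr::inner_join(weights, weights, by = "mirna",
                              relationship = "many-to-many",
                              suffix = c("_a", "_b")) |>
    dplyr::filter(.data$gene_a < .data$gene_b)
  pairs <- if (nrow(shared)) {
    shared |>
      dplyr::group_by(from = .data$gene_a, to = .data$gene_b) |>
      dplyr::summarise(weight = min(.data$weight_a + .data$weight_b),
                       .groups = "drop")
  } else {
    tibble(from = character(), to = character(), weight = numeric())
  }
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE,
                                     vertices = genes)
  D <- igraph::distances(g, weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")
  D <- D[genes, genes, drop = FALSE]
  structure(list(genes = genes, edges = pairs, dist = D),
            class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("Projected gene graph: %d genes, %d edges, %d unreachable pairs\n",
              length(x$genes), nrow(x$edges),
              sum(is.infinite(x$dist)) / 2))
  invisible(x)
}

#' Local enrichment scores of genes for one gene set
#'
#' For each gene `j` of the network, compares the shortest-path distances
#' from `j` to the genes of the term against the distances from `j` to all
#' other genes with a left-tailed Wilcoxon rank-sum test: a small p-value
#' means the term's genes lie unusually close to `j`. Per convention the
#' term-side sample includes the zero self-distance when `j` itself belongs
#' to the term, and `j` is excluded from the background. The score is
#' `S = -log10(p)` (so `p = 7e-3` gives `S = 2.15`); unreachable genes enter
#' the test at the largest tied rank.
#'
#' @param graph A [project_gene_graph()] result.
#' @param term_genes Character vector of gene identifiers annotated to the
#'   term.
#' @return A tibble with one row per network gene: `gene`, `in_term`,
#'   `n_term` (term genes present in the network), `p`, `score`. Genes for
#'   which either sample is empty get `NA`.
#' @export
gene_scores <- function(graph, term_genes) {
  stopifnot(inherits(graph, "gene_graph"))
  genes <- graph$genes
  term <- intersect(genes, unique(term_genes))
  purrr::map_dfr(genes, function(j) {
    term_side <- graph$dist[j, term]
    background <- graph$dist[j, setdiff(genes, c(term, j))]
    p <- if (length(term_side) && length(background)) {
      wilcox_left(term_side, background)
    } else {
      NA_real_
    }
    tibble(gene = j, in_term = j %in% term, n_term = length(term),
           p = p, score = score_from_p(p))
  })
}

#' Aggregate gene scores into per-miRNA functional scores
#'
#' A miRNA inherits the local enrichment scores of its inferred targets. The
#' default aggregates by summation, so miRNAs regulating many high-scoring
#' genes rank highest; `method = "mean"` reports the plain average instead.
#'
#' @param net A [infer_network()] fit or edge tibble (`mirna`, `gene`).
#' @param scores A [gene_scores()] tibble (columns `gene`, `score`).
#' @param method `"sum"` (default) or `"mean"`.
#' @return A tibble `mirna`, `n_targets` (targets with a defined score),
#'   `score`. miRNAs without any scored target get `NA`.
#' @export
mir_scores <- function(net, scores, method = c("sum", "mean")) {
  method <- match.arg(method)
  edges <- as_edge_tibble(net)
  edges |>
    dplyr::left_join(dplyr::select(scores, "gene", "score"), by = "gene") |>
    dplyr::group_by(.data$mirna) |>
    dplyr::summarise(
      n_targets = sum(!is.na(.data$score)),
      score = if (sum(!is.na(.data$score)) == 0) NA_real_ else
        if (method == "sum") sum(.data$score, na.rm = TRUE) else
          mean(.data$score, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Term-level local enrichment
#'
#' Tests, for every gene set, whether the pairwise shortest-path distances
#' among its network genes are shifted towards smaller values than all
#' remaining gene-pair distances (left-tailed Wilcoxon rank-sum), i.e.
#' whether the term occupies a tight local neighbourhood of the network.
#' P-values are Bonferroni-corrected over the tested terms; a term is
#' enriched when the adjusted p-value is below `level`.
#'
#' @param graph A [project_gene_graph()] result.
#' @param genesets A [read_gmt()] tibble or named list of gene vectors.
#' @param level Significance threshold on the adjusted p-value.
#' @return A tibble `term`, `n_genes` (in the network), `p`, `p_adj`,
#'   `enriched`, with skipped terms (fewer than 2 network genes, or no
#'   background pair) in the `"skipped"` attribute.
#' @export
term_local_enrichment <- function(graph, genesets, level = 0.05) {
  stopifnot(inherits(graph, "gene_graph"))
  genesets <- as_geneset_tibble(genesets)
  genes <- graph$genes
  D <- graph$dist
  ut <- upper.tri(D)
  rows <- list()
  skipped <- list()
  for (k in seq_len(nrow(genesets))) {
    term <- genesets$term[k]
    members <- intersect(genes, unique(genesets$genes[[k]]))
    if (length(members) < 2) {
      skipped[[term]] <- "fewer than 2 genes in the network"
      next
    }
    in_term <- genes %in% members
    within_mask <- outer(in_term, in_term, `&`) & ut
    other_mask <- ut & !within_mask
    if (!any(other_mask)) {
      skipped[[term]] <- "no background pair (term covers the network)"
      next
    }
    p <- wilcox_left(D[within_mask], D[other_mask])
    rows[[term]] <- tibble(term = term, n_genes = length(members),
                           n_pairs = sum(within_mask), p = p)
  }
  if (!length(rows)) {
    abort("No term has at least 2 genes in the network.")
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(p_adj = pmin(1, .data$p * dplyr::n()),
                  enriched = .data$p_adj < level)
  attr(out, "skipped") <- if (length(skipped)) {
    tibble(term = names(skipped), reason = unlist(skipped, use.names = FALSE))
  } else {
    tibble(term = character(), reason = character())
  }
  out
}

#' Local enrichment analysis of an inferred miRNA-target network
#'
#' End-to-end LEA: transforms coefficients into positive edge weights,
#' projects the bipartite network onto its genes, computes all-pairs
#' shortest paths, tests every gene set for term-level local enrichment, and
#' scores genes and miRNAs against each tested term.
#'
#' @param net A [infer_network()] fit (or edge tibble with negative
#'   `coefficient`s).
#' @param genesets A [read_gmt()] tibble or named list of gene vectors.
#' @param score_method Aggregation for [mir_scores()], `"sum"` or `"mean"`.
#' @param level Significance threshold for term enrichment (Bonferroni
#'   adjusted).
#' @param only_enriched If `TRUE`, gene and miRNA scores are computed for
#'   enriched terms only (the usual report shape); otherwise for all tested
#'   terms.
#' @return An object of class `lea_result` with `terms` (tibble from
#'   [term_local_enrichment()]), `gene_scores` (`term`, `gene`, `p`,
#'   `score`), `mir_scores` (`term`, `mirna`, `n_targets`, `score`) and the
#'   projected `graph`.
#' @export
lea <- function(net, genesets, score_method = c("sum", "mean"), level = 0.05,
                only_enriched = FALSE) {
  score_method <- match.arg(score_method)
  genesets <- as_geneset_tibble(genesets)
  weights <- transform_edge_weights(net)
  graph <- project_gene_graph(weights)
  terms <- term_local_enrichment(graph, genesets, level = level)
  wanted <- if (only_enriched) terms$term[terms$enriched] else terms$term
  gs <- purrr::map_dfr(wanted, function(tm) {
    members <- genesets$genes[[match(tm, genesets$term)]]
    gene_scores(graph, members) |> dplyr::mutate(term = tm, .before = 1)
  })
  ms <- purrr::map_dfr(wanted, function(tm) {
    mir_scores(net, dplyr::filter(gs, .data$term == tm),
               method = score_method) |>
      dplyr::mutate(term = tm, .before = 1)
  })
  structure(
    list(terms = terms, gene_scores = gs, mir_scores = ms, graph = graph,
         score_method = score_method, level = level),
    class = "lea_result"
  )
}

#' @export
print.lea_result <- function(x, ...) {
  cat("Local enrichment analysis\n")
  cat(sprintf("  %d terms tested, %d locally enriched (Bonferroni p < %g)\n",
              nrow(x$terms), sum(x$terms$enriched), x$level))
  cat(sprintf("  scores for %d genes and %d miRNAs per term (%s aggregation)\n",
              length(x$graph$genes),
              dplyr::n_distinct(x$mir_scores$mirna), x$score_method))
  invisible(x)
}

#' @rdname lea
#' @param x A `lea_result`.
#' @param ... Ignored.
#' @method tidy lea_result
#' @export
tidy.lea_result <- function(x, ...) x$terms

#' @rdname lea
#' @method glance lea_result
#' @export
glance.lea_result <- function(x, ...) {
  tibble(n_terms = nrow(x$terms), n_enriched = sum(x$terms$enriched),
         n_genes = length(x$graph$genes),
         n_mirnas = dplyr::n_distinct(x$mir_scores$mirna))
}

#' @describeIn lea Heatmap of per-miRNA functional scores across (by
#'   default, enriched) terms.
#' @param object A `lea_result`.
#' @param enriched_only Restrict the heatmap to enriched terms.
#' @method autoplot lea_result
#' @export
autoplot.lea_result <- function(object, enriched_only = TRUE, ...) {
  df <- object$mir_scores
  if (enriched_only) {
    keep <- object$terms$term[object$terms$enriched]
    df <- dplyr::filter(df, .data$term %in% keep)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$mirna,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "miR score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
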