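#' Read a prior miRNA-target network from a two-column edge list
#'
#' The file holds at least two tab-separated columns: miRNA identifier, then
#' target gene identifier (the shape of TargetScan-style prediction exports
#' and of StarBase-style validated-interaction lists). Extra columns are
#' ignored, `#` lines are comments, and duplicate edges are collapsed. The
#' result must be bipartite: an identifier appearing both as a miRNA and as a
#' gene is an error.
#'
#' @param path Path to the edge-list file.
#' @param header If `TRUE`, skip the first non-comment line.
#' @return A tibble with character columns `mirna` and `gene`, one row per
#'   unique interaction.
#' @export
read_prior_network <- function(path, header = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("Network file not found: %s", path))
  }
  raw <- tryCatch(
    utils::read.delim(path, header = header, sep = "\t",
                      colClasses = "character", comment.char = "#",
                      check.names = FALSE, quote = ""),
    error = function(e) NULL
  )
  if (is.null(raw) || !nrow(raw)) {
    return(tibble(mirna = character(), gene = character()))
  }
  if (ncol(raw) < 2) {
    abort(sprintf("Edge list %s needs at least two tab-separated columns.", path))
  }
  edges <- tibble(mirna = raw[[1]], gene = raw[[2]]) |> dplyr::distinct()
  shared <- intersect(edges$mirna, edges$gene)
  if (length(shared)) {
    abort(sprintf(
      "Network in %s is not bipartite; these IDs occur on both sides: %s",
      path, paste(head(shared, 10), collapse = ", ")
    ))
  }
  edges
}

#' Write a miRNA-target edge list
#'
#' @param edges Data frame with columns `mirna` and `gene` (further columns
#'   are written as-is).
#' @param path Output file path.
#' @param header Write a header row? Match the `header` argument used when
#'   reading the file back.
#' @return `path`, invisibly.
#' @export
write_prior_network <- function(edges, path, header = FALSE) {
  edges <- as_edge_tibble(edges)
  readr::write_tsv(edges, path, col_names = header, progress = FALSE)
  invisible(path)
}

#' Read a precursor-to-mature miRNA mapping
#'
#' Two tab-separated columns: precursor identifier, mature identifier
#' (typically the -3p/-5p strands). A precursor may map to several matures.
#'
#' @param path Path to the mapping file.
#' @param header If `TRUE`, skip the first non-comment line.
#' @return A tibble with character columns `precursor` and `mature`.
#' @export
read_precursor_map <- function(path, header = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("Precursor map not found: %s", path))
  }
  raw <- tryCatch(
    utils::read.delim(path, header = header, sep = "\t",
                      colClasses = "character", comment.char = "#",
                      check.names = FALSE, quote = ""),
    error = function(e) NULL
  )
  if (is.null(raw) || !nrow(raw)) {
    return(tibble(precursor = character(), mature = character()))
  }
  if (ncol(raw) < 2) {
    abort(sprintf("Precursor map %s needs two tab-separated columns.", path))
  }
  tibble(precursor = raw[[1]], mature = raw[[2]]) |> dplyr::distinct()
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one term per line with at least three tab-separated fields
#' (term ID, description, then member genes). Genes are de-duplicated within
#' a term; duplicate term IDs are an error.
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `term`, `description`, `genes` (list column
#'   of character vectors) and `n_genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("GMT file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble(term = character(), description = character(),
                  genes = list(), n_genes = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    abort(sprintf("GMT line %d of %s has fewer than 3 tab-separated fields.",
                  short[1], path))
  }
  terms <- vapply(fields, `[[`, character(1), 1)
  dup <- unique(terms[duplicated(terms)])
  if (length(dup)) {
    abort(sprintf("Duplicated term IDs in %s: %s", path,
                  paste(dup, collapse = ", ")))
  }
  genes <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  tibble(
    term = terms,
    description = vapply(fields, `[[`, character(1), 2),
    genes = genes,
    n_genes = lengths(genes)
  )
}

# Accept a read_gmt() tibble or a plain named list of character vectors.
as_geneset_tibble <- function(genesets) {
  if (is.data.frame(genesets) && all(c("term", "genes") %in% names(genesets))) {
    return(as_tibble(genesets))
  }
  if (is.list(genesets) && !is.null(names(genesets))) {
    return(tibble(term = names(genesets),
                  description = names(genesets),
                  genes = unname(lapply(genesets, as.character)),
                  n_genes = lengths(genesets)))
  }
  abort("`genesets` must be a read_gmt() tibble or a named list of gene vectors.")
}

#' Re-key a mature-miRNA prior network by precursor
#'
#' Prediction resources key target sets by mature strand (-3p/-5p) while
#' expression may be quantified per precursor. This unifies the target sets
#' of all mature strands of each precursor: precursor `P` targets the union
#' of the targets of its strands.
#'
#' @param prior Tibble with columns `mirna` (mature IDs) and `gene`.
#' @param pmap Tibble with columns `precursor` and `mature`.
#' @return A precursor-keyed tibble with columns `mirna` (now precursor IDs)
#'   and `gene`. Matures in `pmap` without any prior edge are ignored with a
#'   warning.
#' @export
unify_precursor_targets <- function(prior, pmap) {
  prior <- as_edge_tibble(prior)
  missing <- setdiff(pmap$mature, prior$mirna)
  if (length(missing)) {
    warn(sprintf(
      "unify_precursor_targets(): %d mature IDs have no edge in the prior and are ignored: %s%s",
      length(missing), paste(head(missing, 5), collapse = ", "),
      if (length(missing) > 5) ", ..." else ""
    ))
  }
  pmap |>
    dplyr::inner_join(prior, by = c(mature = "mirna"),
                      relationship = "many-to-many") |>
    dplyr::distinct(mirna = .data$precursor, gene = .data$gene)
}

#' Intersect a precursor-keyed inferred network with mature predictions
#'
#' After inferring on precursor expression, keep an edge (precursor, gene)
#' only if at least one mature strand of the precursor is predicted to target
#' the gene in the mature-keyed prior. Coefficients are unchanged.
#'
#' @param inferred A [infer_network()] fit or an edge tibble keyed by
#'   precursor IDs.
#' @param mature_prior Mature-keyed prior tibble (`mirna`, `gene`).
#' @param pmap Tibble with columns `precursor` and `mature`.
#' @return Object of the same shape as `inferred` with non-supported edges
#'   removed. Precursors absent from `pmap` lose their edges with a warning.
#' @export
intersect_with_mature <- function(inferred, mature_prior, pmap) {
  edges <- as_edge_tibble(inferred)
  mature_prior <- as_edge_tibble(mature_prior)
  unmapped <- setdiff(edges$mirna, pmap$precursor)
  if (length(unmapped)) {
    warn(sprintf(
      "intersect_with_mature(): %d precursors absent from the map; their edges are dropped: %s%s",
      length(unmapped), paste(head(unmapped, 5), collapse = ", "),
      if (length(unmapped) > 5) ", ..." else ""
    ))
  }
  allowed <- pmap |>
    dplyr::inner_join(mature_prior, by = c(mature = "mirna"),
                      relationship = "many-to-many") |>
    dplyr::distinct(mirna = .data$precursor, gene = .data$gene)
  kept <- dplyr::semi_join(edges, allowed, by = c("mirna", "gene"))
  if (inherits(inferred, "mirnet_fit")) {
    inferred$edges <- kept
    return(inferred)
  }
  kept
}
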