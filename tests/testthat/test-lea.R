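make_graph_from_coefs <- function(edges) {
  project_gene_graph(transform_edge_weights(edges))
}

test_that("edge-weight transform scales by the strongest repression", {
  single <- tibble::tibble(mirna = "m1", gene = "g1", coefficient = -3)
  expect_equal(transform_edge_weights(single)$weight, exp(-1),
               tolerance = 1e-12)

  two <- tibble::tibble(mirna = c("m1", "m2"), gene = c("g1", "g2"),
                        coefficient = c(-2, -1))
  expect_equal(transform_edge_weights(two)$weight, c(exp(-1), exp(-0.5)),
               tolerance = 1e-12)

  # near-zero repression approaches weight 1 from below
  near <- tibble::tibble(mirna = c("m1", "m2"), gene = c("g1", "g2"),
                         coefficient = c(-1, -1e-9))
  w <- transform_edge_weights(near)$weight
  expect_lt(w[2], 1)
  expect_gt(w[2], 1 - 1e-8)

  empty <- tibble::tibble(mirna = character(), gene = character(),
                          coefficient = numeric())
  expect_error(transform_edge_weights(empty), "no edges")
  pos <- tibble::tibble(mirna = "m", gene = "g", coefficient = 0)
  expect_error(transform_edge_weights(pos), "strictly negative")
})

test_that("gene projection applies the chain-sum and min rules", {
  # A -(miR1)- B -(miR2)- C with all transformed weights 0.5
  w <- tibble::tibble(
    mirna = c("miR1", "miR1", "miR2", "miR2"),
    gene = c("A", "B", "B", "C"),
    weight = 0.5
  )
  pg <- project_gene_graph(w)
  expect_equal(pg$dist["A", "C"], 2.0, tolerance = 1e-12)
  expect_equal(pg$dist["A", "B"], 1.0, tolerance = 1e-12)

  # two shared miRNAs: the cheaper connection wins
  w2 <- tibble::tibble(
    mirna = c("m1", "m1", "m2", "m2"),
    gene = c("A", "B", "A", "B"),
    weight = c(0.6, 0.6, 0.4, 0.4)
  )
  pg2 <- project_gene_graph(w2)
  expect_equal(pg2$edges$weight, 0.8, tolerance = 1e-12)
})

test_that("projected shortest paths equal exhaustive path enumeration", {
  n_bad <- 0
  for (i in 1:200) {
    net <- random_bipartite_weights(n_genes = sample(3:8, 1),
                                    n_mirnas = sample(2:6, 1),
                                    p_edge = runif(1, 0.2, 0.6), seed = i)
    if (!nrow(net)) next
    pg <- make_graph_from_coefs(net)
    oracle <- brute_force_distances(pg$genes,
                                    as.data.frame(pg$edges))
    if (!isTRUE(all.equal(pg$dist, oracle, tolerance = 1e-9))) {
      n_bad <- n_bad + 1
    }
  }
  expect_identical(n_bad, 0)
})

test_that("the p-to-score transform reproduces the worked node scores", {
  expect_equal(round(mirnet:::score_from_p(7e-3), 2), 2.15)
  expect_equal(round(mirnet:::score_from_p(6.5e-1), 2), 0.19)
  expect_identical(mirnet:::score_from_p(1), 0)
})

test_that("gene scores use the self-distance convention and exact tails", {
  # build a network where the term forms a tight block around gene g01
  n <- 22
  genes <- sprintf("g%02d", 1:n)
  # one dedicated miRNA per gene links it to the hub g01, so distances from
  # g01 are controlled exactly; distinct coefficients keep all ranks untied
  term <- genes[1:11]
  edges <- dplyr::bind_rows(
    tibble::tibble(mirna = sprintf("mt%02d", 2:11), gene = genes[2:11],
                   coefficient = -(2 + 0.01 * (2:11))),
    tibble::tibble(mirna = sprintf("mt%02d", 2:11), gene = "g01",
                   coefficient = -(2 + 0.01 * (2:11))),
    tibble::tibble(mirna = sprintf("mb%02d", 12:n), gene = genes[12:n],
                   coefficient = -(0.01 + 0.001 * (12:n))),
    tibble::tibble(mirna = sprintf("mb%02d", 12:n), gene = "g01",
                   coefficient = -(0.01 + 0.001 * (12:n)))
  )
  pg <- make_graph_from_coefs(edges)
  sc <- gene_scores(pg, term)
  row <- sc[sc$gene == "g01", ]
  # g01 in term: term-side sample has 11 values (incl. self zero), bg 11
  expect_true(row$in_term)
  # every term distance is below every background distance -> exact minimal
  # left-tail rank-sum p = 1 / choose(22, 11)
  expect_equal(row$p, 1 / choose(22, 11), tolerance = 1e-12)
  expect_equal(row$score, -log10(1 / choose(22, 11)), tolerance = 1e-9)
  expect_true(all(sc$score[!is.na(sc$score)] >= 0))
})

test_that("gene scores are monotone when the term moves closer", {
  net <- random_bipartite_weights(8, 5, p_edge = 0.5, seed = 42)
  term <- c("g01", "g02", "g03")
  pg <- make_graph_from_coefs(net)
  base <- gene_scores(pg, term)
  # strengthen every edge touching a term gene -> term-side distances shrink
  closer <- net
  sel <- closer$gene %in% term
  closer$coefficient[sel] <- closer$coefficient[sel] * 5
  pg2 <- make_graph_from_coefs(closer)
  after <- gene_scores(pg2, term)
  for (g in setdiff(pg$genes, term)) {
    b <- base$score[base$gene == g]
    a <- after$score[after$gene == g]
    if (!is.na(b) && !is.na(a)) expect_gte(a + 1e-9, b)
  }
})

test_that("rescaling all coefficients leaves every LEA p-value unchanged", {
  net <- random_bipartite_weights(7, 5, p_edge = 0.5, seed = 9)
  sets <- list(T1 = c("g01", "g02", "g03"), T2 = c("g04", "g05"))
  r1 <- lea(net, sets)
  scaled <- net
  scaled$coefficient <- scaled$coefficient * 3.7
  r2 <- lea(scaled, sets)
  expect_equal(r1$terms$p, r2$terms$p, tolerance = 1e-9)
  expect_equal(r1$gene_scores$p, r2$gene_scores$p, tolerance = 1e-9)
})

test_that("miR scores aggregate target scores by sum (default) or mean", {
  net <- tibble::tibble(mirna = c("m1", "m2", "m2", "m2", "m3"),
                        gene = c("gA", "gA", "gB", "gC", "gD"))
  scores <- tibble::tibble(gene = c("gA", "gB", "gC", "gD"),
                           score = c(2.15, 2, 3, 0))
  one <- mir_scores(net[1, ], scores)
  expect_equal(one$score, 2.15)
  multi <- mir_scores(net, scores)
  expect_equal(multi$score[multi$mirna == "m2"], 2.15 + 2 + 3)
  expect_equal(mir_scores(net, scores, method = "mean")$score[2],
               (2.15 + 2 + 3) / 3)
  expect_equal(multi$score[multi$mirna == "m3"], 0)
  # no scored target -> NA
  na_scores <- tibble::tibble(gene = "gA", score = NA_real_)
  expect_true(is.na(mir_scores(net[1, ], na_scores)$score))
})

test_that("term-level enrichment flags tight cliques and skips degenerate terms", {
  # module genes pairwise connected by strong miRNAs; background sparse/weak
  module <- sprintf("g%02d", 1:5)
  others <- sprintf("g%02d", 6:14)
  pairs <- t(combn(module, 2))
  edges <- dplyr::bind_rows(
    tibble::tibble(mirna = sprintf("mm%02d", seq_len(nrow(pairs))),
                   gene = pairs[, 1], coefficient = -2),
    tibble::tibble(mirna = sprintf("mm%02d", seq_len(nrow(pairs))),
                   gene = pairs[, 2], coefficient = -2),
    tibble::tibble(mirna = sprintf("mo%02d", seq_along(others)),
                   gene = others, coefficient = -0.05),
    tibble::tibble(mirna = sprintf("mo%02d", seq_along(others)),
                   gene = c(others[-1], others[1]), coefficient = -0.05)
  )
  pg <- make_graph_from_coefs(edges)
  res <- term_local_enrichment(pg, list(module = module,
                                        everything = c(module, others)))
  expect_true(res$enriched[res$term == "module"])
  # the all-genes term has no background pair -> skipped
  expect_false("everything" %in% res$term)
  expect_identical(attr(res, "skipped")$term, "everything")
  expect_true(all(res$p_adj >= res$p))
})

test_that("planted tight modules are detected at a 2x weight contrast", {
  detected <- vapply(1:100, function(i) {
    set.seed(i)
    module <- sprintf("g%02d", 1:5)
    others <- sprintf("g%02d", 6:20)
    # random sparse background scaffold + strong module clique (2x coefs)
    scaffold <- random_bipartite_weights(20, 10, p_edge = 0.25, seed = i + 500)
    pairs <- t(combn(module, 2))
    module_edges <- dplyr::bind_rows(
      tibble::tibble(mirna = sprintf("mm%02d", seq_len(nrow(pairs))),
                     gene = pairs[, 1],
                     coefficient = -2 * runif(nrow(pairs), 0.5, 1)),
      tibble::tibble(mirna = sprintf("mm%02d", seq_len(nrow(pairs))),
                     gene = pairs[, 2],
                     coefficient = -2 * runif(nrow(pairs), 0.5, 1))
    )
    edges <- dplyr::bind_rows(scaffold[, c("mirna", "gene", "coefficient")],
                              module_edges)
    pg <- make_graph_from_coefs(edges)
    res <- term_local_enrichment(pg, list(module = module))
    isTRUE(res$enriched[1])
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})

test_that("lea() composes the full analysis and reports consistent shapes", {
  net <- random_bipartite_weights(10, 6, p_edge = 0.5, seed = 77)
  sets <- list(T1 = sprintf("g%02d", 1:4), T2 = sprintf("g%02d", 5:10))
  res <- lea(net, sets)
  expect_s3_class(res, "lea_result")
  expect_setequal(unique(res$gene_scores$term), res$terms$term)
  expect_true(all(res$gene_scores$score >= 0, na.rm = TRUE))
  expect_identical(nrow(glance(res)), 1L)
  expect_s3_class(autoplot(res, enriched_only = FALSE), "ggplot")
})
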