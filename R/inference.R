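#' Extract the predictor matrix for one target gene
#'
#' Collects the expressed miRNAs that the prior network proposes as
#' regulators of `gene` and returns them as a samples-by-regulators matrix
#' ready for regression, columns ordered by miRNA identifier.
#'
#' @param gene Gene identifier.
#' @param prior Prior network tibble (`mirna`, `gene`).
#' @param mirna_expr Numeric matrix, miRNAs in rows, samples in columns.
#' @return A list with `gene`, `mirnas` (sorted identifiers) and `X`
#'   (`s x n*` numeric matrix), or `NULL` with a message if the gene has no
#'   expressed targeting miRNA or is absent from the prior.
#' @export
select_predictors <- function(gene, prior, mirna_expr) {
  assert_matrix(mirna_expr)
  prior <- as_edge_tibble(prior)
  candidates <- unique(prior$mirna[prior$gene == gene])
  if (!length(candidates)) {
    inform(sprintf("select_predictors(): gene '%s' absent from the prior; skipped.", gene))
    return(NULL)
  }
  mirnas <- sort(intersect(candidates, rownames(mirna_expr)))
  if (!length(mirnas)) {
    inform(sprintf("select_predictors(): no expressed miRNA targets gene '%s'; skipped.", gene))
    return(NULL)
  }
  list(gene = gene, mirnas = mirnas,
       X = t(mirna_expr[mirnas, , drop = FALSE]))
}

#' Correlation-adaptive elastic-net mixing parameter
#'
#' Sets the per-gene mixing parameter from the correlation strength of the
#' gene's candidate regulators, `alpha = 10^(-c(X))`. Uncorrelated
#' regulators (`c = 0`) give `alpha = 1` (pure lasso); a perfectly correlated
#' group (`c = 1`) gives `alpha = 0.1`, which keeps the fit sparse while
#' letting the ridge component retain co-expressed miRNAs together. A single
#' predictor has no pairwise correlation; `c` is defined as 0 there.
#'
#' @param Xj Predictor matrix, samples in rows, miRNAs in columns.
#' @return Mixing parameter in `[0.1, 1]`.
#' @export
tune_alpha <- function(Xj) {
  assert_matrix(Xj)
  if (ncol(Xj) < 1) {
    abort("tune_alpha() needs at least one predictor column.")
  }
  cval <- if (ncol(Xj) == 1) 0 else correlation_strength(t(Xj))
  10^(-cval)
}

#' Negativity-constrained elastic-net fit for one gene
#'
#' Fits `y ~ intercept + X beta` under the elastic-net penalty
#' `lambda * ((1 - alpha)/2 ||beta||_2^2 + alpha ||beta||_1)` with every
#' coefficient constrained to be non-positive (miRNAs may only repress).
#' Predictors are standardised to zero mean and unit variance internally and
#' coefficients are reported on that standardised scale, so edge weights are
#' comparable across genes. The penalty weight `lambda` is chosen by k-fold
#' cross-validation on a 100-point log-spaced grid from the smallest
#' all-zero `lambda` down to `1e-4` of it; ties in CV error resolve to the
#' smallest (densest) `lambda`. Solved by glmnet coordinate descent with an
#' upper box limit of 0 on each coefficient; for the gaussian path glmnet
#' internally scales the response to unit variance, so the objective
#' minimised is `1/(2s)||y - b0 - X beta||^2 +
#' lambda (1-alpha)/(2 sd(y)) ||beta||^2 + lambda alpha ||beta||_1`
#' (population sd).
#'
#' @param y Numeric response vector (the gene's expression across samples).
#' @param X Predictor matrix, samples in rows, miRNAs in columns (named).
#' @param alpha Elastic-net mixing parameter; default tunes it from the
#'   predictor correlation structure via [tune_alpha()].
#' @param folds Number of cross-validation folds (>= 2, <= number of
#'   samples).
#' @param seed Optional integer seed controlling the fold assignment.
#' @param lambda_rule `"min"` picks the CV-error-minimising `lambda`
#'   (default, more sensitive); `"1se"` the sparsest model within one
#'   standard error of the minimum.
#' @param thresh Coordinate-descent convergence threshold.
#' @return An object of class `gene_model`: coefficients (named, all
#'   `<= 0`), `intercept`, `alpha`, `lambda`, the CV table (`lambda`, `cvm`,
#'   `cvsd`, `nzero`) and bookkeeping fields.
#' @export
fit_gene_model <- function(y, X, alpha = NULL, folds = 10, seed = NULL,
                           lambda_rule = c("min", "1se"), thresh = 1e-12) {
  assert_matrix(X)
  lambda_rule <- match.arg(lambda_rule)
  s <- length(y)
  if (nrow(X) != s) {
    abort("length(y) must equal nrow(X).")
  }
  if (folds < 2) {
    abort("`folds` must be at least 2.")
  }
  if (s < folds) {
    abort(sprintf("Too few samples (%d) for %d-fold cross-validation.", s, folds))
  }
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warn(sprintf("Dropping zero-variance predictors: %s",
                 paste(dropped, collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (!ncol(X)) {
    abort("All predictors have zero variance.")
  }
  if (is.null(alpha)) {
    alpha <- tune_alpha(X)
  }
  Xs <- scale(X)
  predictors <- colnames(X)
  # glmnet needs >= 2 columns; a zero column leaves the solution and the
  # lambda path untouched and its coefficient is exactly zero.
  padded <- ncol(Xs) == 1
  if (padded) {
    Xs <- cbind(Xs, .pad = 0)
  }
  if (!is.null(seed)) set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = s))
  cv <- suppressWarnings(glmnet::cv.glmnet(
    Xs, y, family = "gaussian", alpha = alpha,
    upper.limits = 0, lower.limits = -Inf,
    standardize = FALSE, intercept = TRUE,
    nlambda = 100, lambda.min.ratio = 1e-4, foldid = foldid,
    grouped = s / folds >= 3, thresh = thresh
  ))
  fit <- cv$glmnet.fit                    # full-data path, same lambdas as cv
  cvm <- cv$cvm
  idx <- if (lambda_rule == "min") {
    max(which(cvm == min(cvm)))           # ties: smallest lambda (densest)
  } else {
    imin <- which.min(cvm)
    min(which(cvm <= cvm[imin] + cv$cvsd[imin]))
  }
  lambda <- cv$lambda[idx]
  beta <- as.numeric(fit$beta[, idx])
  names(beta) <- colnames(Xs)
  if (padded) {
    beta <- beta[predictors]
  }
  structure(
    list(
      coefficients = beta,
      intercept = as.numeric(fit$a0[idx]),
      alpha = alpha,
      lambda = lambda,
      lambda_rule = lambda_rule,
      cv = tibble(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                  nzero = as.integer(cv$nzero)),
      folds = folds,
      seed = seed,
      dropped = dropped,
      n_samples = s
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "Negativity-constrained elastic-net gene model: %d predictors, %d selected\n",
    length(x$coefficients), sum(x$coefficients < 0)))
  cat(sprintf("  alpha = %.4f, lambda = %.4g (%s rule, %d-fold CV)\n",
              x$alpha, x$lambda, x$lambda_rule, x$folds))
  invisible(x)
}

#' @rdname fit_gene_model
#' @param x A `gene_model`.
#' @param ... Ignored.
#' @method tidy gene_model
#' @export
tidy.gene_model <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         selected = unname(x$coefficients) < 0)
}

#' @rdname fit_gene_model
#' @method glance gene_model
#' @export
glance.gene_model <- function(x, ...) {
  tibble(alpha = x$alpha, lambda = x$lambda,
         n_predictors = length(x$coefficients),
         n_selected = sum(x$coefficients < 0),
         folds = x$folds, n_samples = x$n_samples)
}

#' Infer a miRNA-target repression network
#'
#' Runs the negativity-constrained elastic-net fit gene by gene over the
#' prior target network and assembles all strictly negative coefficients
#' into a weighted bipartite network. Genes are processed independently with
#' per-gene fold seeds derived deterministically from `seed` and the gene
#' identifier, so results do not depend on processing order.
#'
#' @param mirna_expr Numeric matrix, miRNAs in rows, samples in columns.
#' @param mrna_expr Numeric matrix, genes in rows, samples in columns. Sample
#'   columns must match `mirna_expr` exactly and in the same order.
#' @param prior Prior network tibble (`mirna`, `gene`).
#' @param folds,lambda_rule,thresh Passed to [fit_gene_model()].
#' @param seed Integer master seed for the cross-validation folds.
#' @param alpha Optional fixed mixing parameter overriding the per-gene
#'   correlation-adaptive choice (e.g. `alpha = 1` for a plain
#'   negativity-constrained lasso).
#' @return An object of class `mirnet_fit`: `edges` (tibble `mirna`, `gene`,
#'   `coefficient`, all strictly negative), `models` (per-gene `alpha`,
#'   `lambda`, `intercept`, sizes) and `skipped` (gene, reason).
#' @export
infer_network <- function(mirna_expr, mrna_expr, prior, folds = 10, seed = 1,
                          alpha = NULL, lambda_rule = c("min", "1se"),
                          thresh = 1e-9) {
  assert_matrix(mirna_expr)
  assert_matrix(mrna_expr)
  lambda_rule <- match.arg(lambda_rule)
  prior <- as_edge_tibble(prior)
  if (!identical(colnames(mirna_expr), colnames(mrna_expr))) {
    only_mi <- setdiff(colnames(mirna_expr), colnames(mrna_expr))
    only_m <- setdiff(colnames(mrna_expr), colnames(mirna_expr))
    abort(sprintf(
      paste0("Sample IDs of the two matrices are not identical and aligned.\n",
             "  only in miRNA matrix: %s\n  only in mRNA matrix: %s%s"),
      paste(head(only_mi, 5), collapse = ", "),
      paste(head(only_m, 5), collapse = ", "),
      if (!length(only_mi) && !length(only_m)) "\n  (same IDs, different order)" else ""
    ))
  }
  targets <- split(prior$mirna, prior$gene)
  genes <- sort(intersect(names(targets), rownames(mrna_expr)))
  edges <- list()
  models <- list()
  skipped <- list()
  for (gene in genes) {
    mirnas <- sort(intersect(unique(targets[[gene]]), rownames(mirna_expr)))
    mirnas <- mirnas[apply(mirna_expr[mirnas, , drop = FALSE], 1, stats::sd) > 0]
    if (!length(mirnas)) {
      skipped[[gene]] <- "no expressed targeting miRNA"
      next
    }
    y <- mrna_expr[gene, ]
    if (stats::sd(y) == 0) {
      skipped[[gene]] <- "constant response"
      next
    }
    Xj <- t(mirna_expr[mirnas, , drop = FALSE])
    alpha_j <- alpha %||% tune_alpha(Xj)
    model <- fit_gene_model(y, Xj, alpha = alpha_j, folds = folds,
                            seed = derive_seed(seed, gene),
                            lambda_rule = lambda_rule, thresh = thresh)
    sel <- model$coefficients[model$coefficients < 0]
    if (length(sel)) {
      edges[[gene]] <- tibble(mirna = names(sel), gene = gene,
                              coefficient = unname(sel))
    }
    models[[gene]] <- tibble(
      gene = gene, alpha = model$alpha, lambda = model$lambda,
      intercept = model$intercept,
      n_predictors = length(model$coefficients),
      n_selected = length(sel)
    )
  }
  edges <- if (length(edges)) {
    dplyr::bind_rows(edges) |> dplyr::arrange(.data$gene, .data$mirna)
  } else {
    tibble(mirna = character(), gene = character(), coefficient = numeric())
  }
  structure(
    list(
      edges = edges,
      models = if (length(models)) dplyr::bind_rows(models) else
        tibble(gene = character(), alpha = numeric(), lambda = numeric(),
               intercept = numeric(), n_predictors = integer(),
               n_selected = integer()),
      skipped = if (length(skipped)) {
        tibble(gene = names(skipped),
               reason = unlist(skipped, use.names = FALSE))
      } else {
        tibble(gene = character(), reason = character())
      },
      folds = folds, seed = seed, alpha = alpha, lambda_rule = lambda_rule
    ),
    class = "mirnet_fit"
  )
}

#' @export
print.mirnet_fit <- function(x, ...) {
  cat("Inferred miRNA-target network\n")
  cat(sprintf("  %d repressive edges: %d miRNAs -> %d genes\n",
              nrow(x$edges), dplyr::n_distinct(x$edges$mirna),
              dplyr::n_distinct(x$edges$gene)))
  cat(sprintf("  %d gene models fitted, %d genes skipped (%s lambda, %d-fold CV, seed %s)\n",
              nrow(x$models), nrow(x$skipped), x$lambda_rule, x$folds,
              format(x$seed)))
  invisible(x)
}

#' @rdname infer_network
#' @param x A `mirnet_fit`.
#' @param ... Ignored.
#' @method tidy mirnet_fit
#' @export
tidy.mirnet_fit <- function(x, ...) x$edges

#' @rdname infer_network
#' @method glance mirnet_fit
#' @export
glance.mirnet_fit <- function(x, ...) {
  tibble(
    n_edges = nrow(x$edges),
    n_mirnas = dplyr::n_distinct(x$edges$mirna),
    n_genes = dplyr::n_distinct(x$edges$gene),
    n_models = nrow(x$models),
    n_skipped = nrow(x$skipped),
    mean_alpha = if (nrow(x$models)) mean(x$models$alpha) else NA_real_
  )
}

#' Write / read an inferred network
#'
#' The edge list goes to a three-column TSV (`mirna`, `gene`, `coefficient`,
#' full double precision) and the per-gene fit metadata to a JSON sidecar, so
#' a write-read round trip reproduces the network exactly.
#'
#' @param net A `mirnet_fit` (or edge tibble with a `coefficient` column).
#' @param path Output TSV path.
#' @param metadata_path JSON sidecar path; default `paste0(path, ".json")`.
#' @return `path`, invisibly (for `write_network`); a `mirnet_fit` (for
#'   `read_network`).
#' @export
write_network <- function(net, path, metadata_path = paste0(path, ".json")) {
  edges <- as_edge_tibble(net, require_coefficient = TRUE)
  out <- dplyr::mutate(edges,
                       coefficient = sprintf("%.17g", .data$coefficient))
  readr::write_tsv(out, path, progress = FALSE)
  meta <- list(models = if (inherits(net, "mirnet_fit")) net$models else NULL,
               folds = if (inherits(net, "mirnet_fit")) net$folds else NULL,
               seed = if (inherits(net, "mirnet_fit")) net$seed else NULL,
               lambda_rule = if (inherits(net, "mirnet_fit")) net$lambda_rule else NULL)
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, metadata_path = paste0(path, ".json")) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "character"),
                           comment.char = "#", check.names = FALSE,
                           quote = "")
  edges <- tibble(mirna = raw[[1]], gene = raw[[2]],
                  coefficient = as.numeric(raw[[3]]))
  meta <- if (file.exists(metadata_path)) {
    jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  } else {
    list()
  }
  structure(
    list(
      edges = edges,
      models = if (!is.null(meta$models)) as_tibble(meta$models) else
        tibble(gene = character(), alpha = numeric(), lambda = numeric(),
               intercept = numeric(), n_predictors = integer(),
               n_selected = integer()),
      skipped = tibble(gene = character(), reason = character()),
      folds = meta$folds, seed = meta$seed,
      alpha = NULL, lambda_rule = meta$lambda_rule %||% "min"
    ),
    class = "mirnet_fit"
  )
}
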