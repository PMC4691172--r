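#' Simulate co-expressed miRNA groups repressing a target gene
#'
#' Generates the benchmark's synthetic instance: miRNAs fall into groups,
#' each driven by a hidden factor `h ~ N(0,1)` shared by the group plus
#' independent within-group noise, `x_i = h_g(i) + tau * eta_i`, then
#' row-standardised to `xhat`. A subset of the miRNAs are true regulators and
#' the target expression is their negated sum plus noise,
#' `y = sigma * eps - sum(xhat_true)`. Small `tau` reproduces the blockwise
#' correlation structure typical of clustered miRNAs (within-group Pearson
#' correlation is about `1 / (1 + tau^2)`).
#'
#' @param s Number of samples.
#' @param sigma Noise weight on the target (>= 0).
#' @param n_mirna Number of miRNAs.
#' @param n_groups Number of co-expression groups (hidden factors).
#' @param n_true Number of true regulators (used by `true_set = "random"`).
#' @param tau Within-group noise weight (> 0).
#' @param true_set `"random"` (default) draws `n_true` regulators uniformly
#'   without replacement across all miRNAs; `"group"` plants one entire
#'   co-expression group as the regulator set (ignoring `n_true`).
#' @param standardize If `TRUE` (default) the target is built from the
#'   row-standardised profiles; the raw profiles are used otherwise.
#' @param seed Optional integer seed; the instance is fully deterministic
#'   given the seed.
#' @return An object of class `synthetic_instance`: `mirna` (standardised
#'   `n_mirna x s` matrix), `mirna_raw`, `response` (length-`s` vector),
#'   `groups` (tibble `mirna`, `group`), `true_regulators` (character) and
#'   the generating parameters.
#' @export
simulate_instance <- function(s = 30, sigma = 1, n_mirna = 20, n_groups = 4,
                              n_true = 5, tau = 0.3,
                              true_set = c("random", "group"),
                              standardize = TRUE, seed = NULL) {
  true_set <- match.arg(true_set)
  if (n_true > n_mirna || n_groups > n_mirna || n_true < 1 || n_groups < 1) {
    abort("Need 1 <= n_true <= n_mirna and 1 <= n_groups <= n_mirna.")
  }
  if (tau <= 0 || sigma < 0 || s < 2) {
    abort("Need tau > 0, sigma >= 0 and s >= 2.")
  }
  if (!is.null(seed)) set.seed(seed)
  group <- rep(seq_len(n_groups), length.out = n_mirna)
  h <- matrix(stats::rnorm(n_groups * s), n_groups, s)
  X <- h[group, , drop = FALSE] +
    tau * matrix(stats::rnorm(n_mirna * s), n_mirna, s)
  dimnames(X) <- list(sprintf("miR-%02d", seq_len(n_mirna)),
                      sprintf("sample%02d", seq_len(s)))
  xhat <- t(scale(t(X)))
  true_idx <- if (true_set == "group") {
    which(group == sample(n_groups, 1))
  } else {
    sort(sample(n_mirna, n_true))
  }
  basis <- if (standardize) xhat else X
  y <- as.numeric(sigma * stats::rnorm(s) -
                    colSums(basis[true_idx, , drop = FALSE]))
  structure(
    list(
      mirna = xhat, mirna_raw = X, response = y,
      groups = tibble(mirna = rownames(X), group = group),
      true_regulators = rownames(X)[true_idx],
      s = s, sigma = sigma, tau = tau, n_mirna = n_mirna,
      n_groups = n_groups, true_set = true_set,
      standardized = standardize, seed = seed
    ),
    class = "synthetic_instance"
  )
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat(sprintf(
    "Synthetic instance: %d miRNAs in %d groups, %d samples, sigma = %g, tau = %g\n",
    x$n_mirna, x$n_groups, x$s, x$sigma, x$tau))
  cat(sprintf("  true regulators (%s): %s\n", x$true_set,
              paste(x$true_regulators, collapse = ", ")))
  invisible(x)
}

#' Expression matrices and prior for an instance
#'
#' Packages a synthetic instance into the inputs [infer_network()] expects:
#' the miRNA matrix, a one-gene mRNA matrix holding the simulated target,
#' and a prior proposing every miRNA as a candidate regulator of it.
#'
#' @param instance A [simulate_instance()] result.
#' @param gene_id Identifier for the simulated target gene.
#' @return A list with `mirna_expr`, `mrna_expr` and `prior`.
#' @export
instance_data <- function(instance, gene_id = "target") {
  stopifnot(inherits(instance, "synthetic_instance"))
  mrna <- matrix(instance$response, nrow = 1,
                 dimnames = list(gene_id, colnames(instance$mirna)))
  list(
    mirna_expr = instance$mirna,
    mrna_expr = mrna,
    prior = tibble(mirna = rownames(instance$mirna), gene = gene_id)
  )
}

#' Precision, recall and F1 of a recovered regulator set
#'
#' Standard confusion-matrix arithmetic against the planted truth:
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`, with the convention
#' that an undefined ratio is 0.
#'
#' @param selected Character vector of selected miRNA identifiers.
#' @param truth Character vector of true regulators.
#' @return A one-row tibble `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
f1_measure <- function(selected, truth) {
  selected <- unique(selected)
  truth <- unique(truth)
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  fn <- length(setdiff(truth, selected))
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(tp = tp, fp = fp, fn = fn,
         precision = precision, recall = recall, f1 = f1)
}

#' Correlation-analysis baseline regulator selection
#'
#' Selects the miRNAs whose Pearson correlation with the target is negative
#' and whose one-sided Bonferroni-adjusted p-value (corrected over the
#' instance's miRNA count) falls below `level`.
#'
#' @param instance A [simulate_instance()] result.
#' @param level Family-wise significance level.
#' @return Character vector of selected miRNA identifiers (sorted).
#' @export
correlation_baseline <- function(instance, level = 0.05) {
  stopifnot(inherits(instance, "synthetic_instance"))
  X <- instance$mirna
  y <- instance$response
  p <- apply(X, 1, function(x)
    stats::cor.test(x, y, alternative = "less")$p.value)
  rho <- apply(X, 1, function(x) stats::cor(x, y))
  sort(rownames(X)[rho < 0 & pmin(p * nrow(X), 1) < level])
}

#' Select regulators of a synthetic instance with one method
#'
#' Dispatch for the benchmark's three arms. `"mirlastic"` runs the full
#' [infer_network()] machinery (correlation-adaptive alpha); `"lasso"` is the
#' identical fit with `alpha` fixed to 1; `"correlation"` is
#' [correlation_baseline()].
#'
#' @param instance A [simulate_instance()] result.
#' @param method One of `"mirlastic"`, `"lasso"`, `"correlation"`.
#' @param folds,seed,lambda_rule Passed to [infer_network()].
#' @param level Significance level for the correlation baseline.
#' @return Character vector of selected miRNA identifiers (sorted).
#' @export
select_regulators <- function(instance,
                              method = c("mirlastic", "lasso", "correlation"),
                              folds = 10, seed = 1, lambda_rule = "min",
                              level = 0.05) {
  method <- match.arg(method)
  if (method == "correlation") {
    return(correlation_baseline(instance, level = level))
  }
  dat <- instance_data(instance)
  fit <- infer_network(dat$mirna_expr, dat$mrna_expr, dat$prior,
                       folds = folds, seed = seed,
                       alpha = if (method == "lasso") 1 else NULL,
                       lambda_rule = lambda_rule)
  sort(fit$edges$mirna)
}

#' Benchmark the inference against lasso and correlation baselines
#'
#' Repeatedly simulates instances over a grid of sample sizes and noise
#' levels, runs the three selection methods on every instance, and records
#' precision, recall and F1 per run. Per-run seeds are derived
#' deterministically from the master seed, so the grid is reproducible and
#' the three methods see identical instances.
#'
#' @param sample_sizes Integer vector of sample counts.
#' @param noise_levels Numeric vector of noise weights `sigma`.
#' @param runs Runs per grid cell.
#' @param seed Master integer seed.
#' @param methods Subset of `c("mirlastic", "lasso", "correlation")`.
#' @param folds CV folds for the regression arms.
#' @param ... Further arguments to [simulate_instance()] (e.g. `tau`,
#'   `n_true`, `true_set`).
#' @return A tibble of class `mirnet_benchmark`: one row per
#'   `(method, s, sigma, run)` with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @export
run_benchmark <- function(sample_sizes = c(10, 30, 50),
                          noise_levels = c(0.5, 1, 2, 4),
                          runs = 100, seed = 1,
                          methods = c("mirlastic", "lasso", "correlation"),
                          folds = 10, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  grid <- tidyr::expand_grid(s = sample_sizes, sigma = noise_levels,
                             run = seq_len(runs))
  out <- purrr::pmap_dfr(grid, function(s, sigma, run) {
    tag <- paste(s, sigma, run, sep = "|")
    instance <- simulate_instance(s = s, sigma = sigma,
                                  seed = derive_seed(seed, paste0("inst|", tag)),
                                  ...)
    fit_seed <- derive_seed(seed, paste0("fit|", tag))
    purrr::map_dfr(methods, function(m) {
      sel <- select_regulators(instance, method = m, folds = folds,
                               seed = fit_seed)
      dplyr::bind_cols(
        tibble(method = m, s = s, sigma = sigma, run = run),
        f1_measure(sel, instance$true_regulators)
      )
    })
  })
  class(out) <- c("mirnet_benchmark", class(out))
  attr(out, "seed") <- seed
  out
}

#' @rdname run_benchmark
#' @param x A `mirnet_benchmark`.
#' @param ... Ignored.
#' @method glance mirnet_benchmark
#' @export
glance.mirnet_benchmark <- function(x, ...) {
  dplyr::group_by(as_tibble(x), .data$method, .data$s, .data$sigma) |>
    dplyr::summarise(runs = dplyr::n(),
                     precision = mean(.data$precision),
                     recall = mean(.data$recall),
                     f1 = mean(.data$f1), .groups = "drop")
}

#' @describeIn run_benchmark Mean F1 against noise level, one line per
#'   method, faceted by sample size.
#' @param object A `mirnet_benchmark`.
#' @method autoplot mirnet_benchmark
#' @export
autoplot.mirnet_benchmark <- function(object, ...) {
  df <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma, y = .data$f1,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~s, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(sigma ~ "(noise weight)"), y = "mean F1",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
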