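# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately naive (enumeration, brute force) and never
# calls the code paths it is used to check.

# --- file fixtures -----------------------------------------------------------

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# --- exact-correlation matrix construction -----------------------------------

# Build an n x s matrix whose *sample* Pearson correlation matrix is exactly R:
# orthonormalize i.i.d. rows (QR on centered columns), then mix with chol(R).
matrix_with_correlation <- function(R, s, seed = 1) {
  n <- nrow(R)
  stopifnot(s > n + 1)
  set.seed(seed)
  Z <- matrix(rnorm(s * n), s, n)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z))            # orthonormal, zero-mean columns (span _|_ 1)
  ev <- eigen(R, symmetric = TRUE)   # eigen sqrt handles singular R
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n) %*% t(ev$vectors)
  X <- Q %*% L
  t(scale(X))                 # rows: unit variance, exact correlations R
}

# --- shortest-path brute force ----------------------------------------------

# Exhaustive enumeration of all simple paths on the projected gene graph.
# edges: data.frame(from, to, weight); returns all-pairs distance matrix.
brute_force_distances <- function(genes, edges) {
  D <- matrix(Inf, length(genes), length(genes),
              dimnames = list(genes, genes))
  diag(D) <- 0
  adj <- lapply(setNames(genes, genes), function(g) {
    rbind(
      data.frame(to = edges$to[edges$from == g],
                 w = edges$weight[edges$from == g]),
      data.frame(to = edges$from[edges$to == g],
                 w = edges$weight[edges$to == g])
    )
  })
  visit <- function(node, target, seen, acc) {
    if (node == target) return(acc)
    best <- Inf
    nb <- adj[[node]]
    for (i in seq_len(nrow(nb))) {
      nxt <- nb$to[i]
      if (nxt %in% seen) next
      v <- visit(nxt, target, c(seen, nxt), acc + nb$w[i])
      if (v < best) best <- v
    }
    best
  }
  for (a in seq_along(genes)) {
    for (b in seq_along(genes)) {
      if (a < b) {
        d <- visit(genes[a], genes[b], genes[a], 0)
        D[a, b] <- D[b, a] <- d
      }
    }
  }
  D
}

# Random weighted bipartite network fixture for projection tests.
random_bipartite_weights <- function(n_genes, n_mirnas, p_edge = 0.4,
                                     seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  mirnas <- sprintf("m%02d", seq_len(n_mirnas))
  grid <- expand.grid(mirna = mirnas, gene = genes,
                      stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) < p_edge, , drop = FALSE]
  grid$coefficient <- -runif(nrow(grid), 0.2, 2)
  tibble::as_tibble(grid)
}

# --- constrained elastic net: enumeration oracle -----------------------------

# Exact minimizer of the objective fit_gene_model() documents:
#   1/(2s)||yc - X b||^2 + lambda (1-alpha)/(2 sd_pop(y)) ||b||^2
#     + lambda alpha ||b||_1   subject to b <= 0,
# by enumerating active sets (exact for the smooth-on-the-box objective).
constrained_enet_oracle <- function(y, Xs, lambda, alpha) {
  s <- length(y)
  yc <- y - mean(y)
  sy <- sqrt(mean(yc^2))
  n <- ncol(Xs)
  objf <- function(beta) {
    sum((yc - Xs %*% beta)^2) / (2 * s) +
      lambda * (1 - alpha) / (2 * sy) * sum(beta^2) +
      lambda * alpha * sum(abs(beta))
  }
  best <- rep(0, n)
  bestval <- objf(best)
  for (mask in seq_len(2^n - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    Xf <- Xs[, free, drop = FALSE]
    A <- crossprod(Xf) / s + lambda * (1 - alpha) / sy * diag(length(free))
    bf <- tryCatch(solve(A, crossprod(Xf, yc) / s + lambda * alpha),
                   error = function(e) NULL)
    if (is.null(bf) || any(bf > 1e-12)) next
    beta <- rep(0, n)
    beta[free] <- pmin(bf, 0)
    v <- objf(beta)
    if (v < bestval) {
      bestval <- v
      best <- beta
    }
  }
  list(beta = best, objective = bestval, objf = objf)
}

# --- confusion-matrix oracle --------------------------------------------------

confusion_f1_oracle <- function(selected, truth, universe) {
  pred <- universe %in% selected
  act <- universe %in% truth
  tp <- sum(pred & act)
  fp <- sum(pred & !act)
  fn <- sum(!pred & act)
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  rc <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
}

# --- access to internal seed derivation --------------------------------------

derive_seed_for_test <- function(seed, key) mirnet:::derive_seed(seed, key)
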