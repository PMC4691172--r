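#' Read an expression matrix from a tab-separated file
#'
#' The expected layout is the common features-by-samples export: a header row
#' of sample identifiers, a first column of feature identifiers, and a
#' numeric body. Lines starting with `#` are treated as comments. Feature and
#' sample identifiers must be unique; identifiers are opaque, case-sensitive
#' strings and are not normalised.
#'
#' @param path Path to a tab-separated text file.
#' @param log2 If `TRUE`, apply `log2(x + 1)` to all values after reading.
#'   The pseudocount of 1 keeps zero counts at zero. The transform applied is
#'   recorded in the `"log2"` attribute of the result.
#' @return A numeric matrix (features in rows, samples in columns) with
#'   feature identifiers as row names and sample identifiers as column names.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\ts1\ts2", "g1\t1\t3", "g2\t7\t15"), tf)
#' read_expression(tf, log2 = TRUE)
#' @export
read_expression <- function(path, log2 = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("Expression file not found: %s", path))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "#",
                           check.names = FALSE, quote = "")
  if (ncol(raw) < 2) {
    abort(sprintf("Expression file %s needs a feature-ID column plus at least one sample column.", path))
  }
  features <- raw[[1]]
  dup <- unique(features[duplicated(features)])
  if (length(dup)) {
    abort(sprintf("Duplicated feature IDs in %s: %s", path,
                  paste(dup, collapse = ", ")))
  }
  samples <- colnames(raw)[-1]
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s)) {
    abort(sprintf("Duplicated sample IDs in %s: %s", path,
                  paste(dup_s, collapse = ", ")))
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(values) & !(is.na(body) | body %in% c("NA", "NaN")),
               arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "Non-numeric value '%s' at row %d (feature '%s'), column %d (sample '%s') of %s",
      body[bad[1, 1], bad[1, 2]], bad[1, 1], features[bad[1, 1]],
      bad[1, 2], samples[bad[1, 2]], path
    ))
  }
  dimnames(values) <- list(features, samples)
  if (log2) {
    values <- log2(values + 1)
  }
  attr(values, "log2") <- log2
  values
}

#' Write an expression matrix to a tab-separated file
#'
#' Values are written with full double precision so that a
#' [read_expression()] round trip reproduces the matrix exactly.
#'
#' @param mat Numeric matrix, features in rows, samples in columns.
#' @param path Output file path.
#' @param id_column Name used for the feature-ID header field.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, id_column = "feature_id") {
  assert_matrix(mat)
  chr <- apply(mat, 2, function(x) sprintf("%.17g", x))  # exact round trip
  df <- tibble(!!id_column := rownames(mat)) |>
    dplyr::bind_cols(as_tibble(matrix(chr, nrow(mat),
                                      dimnames = dimnames(mat))))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Filter low-information expression features
#'
#' Keeps features detected in strictly more than `min_nonzero_frac` of the
#' samples (the conventional "non-zero in more than 80% of patients" rule)
#' and, optionally, with non-zero standard deviation across samples. Feature
#' order is preserved and the operation is idempotent.
#'
#' @param mat Numeric matrix, features in rows, samples in columns.
#' @param min_nonzero_frac Fraction in `[0, 1]`; a feature is kept only if
#'   its number of non-zero values exceeds `min_nonzero_frac * ncol(mat)`
#'   strictly.
#' @param require_sd If `TRUE`, additionally drop features whose standard
#'   deviation across samples is zero.
#' @return The filtered matrix. An empty result raises a warning, not an
#'   error.
#' @export
filter_expression <- function(mat, min_nonzero_frac = 0.8, require_sd = TRUE) {
  assert_matrix(mat)
  if (min_nonzero_frac < 0 || min_nonzero_frac > 1) {
    abort("`min_nonzero_frac` must be in [0, 1].")
  }
  keep <- rowSums(mat != 0) > min_nonzero_frac * ncol(mat)
  if (require_sd) {
    keep <- keep & apply(mat, 1, stats::sd) > 0
  }
  out <- mat[keep, , drop = FALSE]
  if (!nrow(out)) {
    warn("filter_expression(): no feature passed the filter.")
  }
  attr(out, "log2") <- attr(mat, "log2")
  out
}
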