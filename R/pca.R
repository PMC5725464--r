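#' PCA-based gene selection on the first principal component
#'
#' Treats genes as observations and methods as variables: the
#' complete-case submatrix (genes observed by every method) is column
#' centered (and unit-scaled when `scale = TRUE`), its first right
#' singular vector gives the principal axis, and each gene's PC1 score is
#' its projection on that axis.  The sign is fixed so the method with the
#' largest absolute loading loads positively, making outputs reproducible
#' across linear-algebra backends.  Genes whose scores fall strictly
#' outside the boxplot fences at multiplier `k` are selected.
#'
#' @param matrix a `profile_matrix`.
#' @param k fence multiplier passed to [iqr_select()] (default 1.5, the
#'   whisker convention).
#' @param scale unit-scale the columns before the decomposition
#'   (default FALSE: log2FC columns are unit-comparable, so covariance
#'   PCA is used).
#' @return a `pca_selection` list: `pc1_scores` (named numeric),
#'   `loadings`, `explained_frac`, `sign_anchor`, `selection` (a
#'   `selection_result`), `n_complete`.
#' @export
pc1_select <- function(matrix, k = 1.5, scale = FALSE) {
  X <- unclass(matrix)
  complete <- stats::complete.cases(X)
  X <- X[complete, , drop = FALSE]
  if (nrow(X) < 4L) {
    abort_data("need at least 4 complete-case genes, got ", nrow(X))
  }
  sds <- apply(X, 2L, stats::sd)
  if (sum(sds > 0) < 2L) {
    abort_numeric("need at least 2 methods with nonzero variance")
  }
  Xc <- sweep(X, 2L, colMeans(X))
  if (scale) {
    if (any(sds == 0)) {
      abort_numeric("cannot unit-scale zero-variance method(s): ",
                    paste(colnames(X)[sds == 0], collapse = ", "))
    }
    Xc <- sweep(Xc, 2L, sds, "/")
  }
  if (sum(Xc^2) == 0) abort_numeric("matrix has zero total variance")
  sv <- svd(Xc)
  loadings <- stats::setNames(sv$v[, 1L], colnames(X))
  anchor <- names(loadings)[which.max(abs(loadings))]
  flip <- if (loadings[anchor] < 0) -1 else 1
  loadings <- flip * loadings
  scores <- stats::setNames(flip * sv$u[, 1L] * sv$d[1L], rownames(X))
  explained <- sv$d[1L]^2 / sum(sv$d^2)
  structure(list(pc1_scores = scores,
                 loadings = loadings,
                 explained_frac = explained,
                 sign_anchor = anchor,
                 selection = iqr_select(scores, k = k,
                                        statistic_name = "pc1_score"),
                 n_complete = nrow(X)),
            class = "pca_selection")
}

#' @export
print.pca_selection <- function(x, ...) {
  cat(sprintf(
    "pc1 selection: %d complete genes, PC1 explains %.1f%% (anchor %s), %d selected\n",
    x$n_complete, 100 * x$explained_frac, x$sign_anchor,
    length(x$selection$selected)))
  invisible(x)
}
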