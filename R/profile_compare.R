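# Profile-comparison analytics: row scaling, SVD-based missing-value
# imputation, PCA over profiles, and correlation-distance average-linkage
# clustering — the preprocessing and display conventions of ClustVis-style
# heatmap/PCA tools.

#' Row-wise scaling of a profile matrix
#'
#' Rows are taxa, columns profiles (sample x primer set or combined).
#' `"center"` subtracts the row mean; `"unit_variance"` additionally
#' divides by the row standard deviation so each row has mean 0 and
#' variance 1. Constant rows cannot be unit-scaled and are dropped with a
#' warning. Unit-variance scaling is idempotent.
#'
#' @param m Numeric matrix.
#' @param scaling One of `"unit_variance"`, `"center"`, `"none"`.
#' @return The scaled matrix.
#' @export
preprocess_matrix <- function(m, scaling = c("unit_variance", "center", "none")) {
  scaling <- match.arg(scaling)
  stopifnot(is.matrix(m), is.numeric(m))
  if (scaling == "none") return(m)
  if (scaling == "unit_variance") {
    sds <- apply(m, 1L, stats::sd)
    const <- !is.na(sds) & sds == 0
    if (any(const)) {
      warning(sum(const), " constant row(s) dropped before unit-variance scaling",
              call. = FALSE)
      m <- m[!const, , drop = FALSE]
    }
  }
  centered <- m - rowMeans(m)
  if (scaling == "center") return(centered)
  centered / apply(m, 1L, stats::sd)
}

#' Iterative SVD imputation of missing matrix cells
#'
#' Missing cells are initialised at the row mean and refined by repeatedly
#' replacing them with the corresponding cells of the rank-`k` truncated
#' SVD reconstruction until successive imputations differ by less than
#' `tol` (max-norm) or `max_iter` is reached. Observed cells are never
#' altered.
#'
#' @param m Numeric matrix with `NA` for missing cells; every row and
#'   column must retain at least one observed value.
#' @param k Reconstruction rank (default 2, the plotted components).
#' @param tol Convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 100).
#' @return The completed matrix.
#' @export
svd_impute <- function(m, k = 2, tol = 1e-6, max_iter = 100) {
  stopifnot(is.matrix(m), is.numeric(m))
  miss <- is.na(m)
  if (!any(miss)) return(m)
  if (any(rowSums(!miss) == 0L)) stop("fully missing row", call. = FALSE)
  if (any(colSums(!miss) == 0L)) stop("fully missing column", call. = FALSE)
  k <- min(k, dim(m) - 1L, min(dim(m)))
  filled <- m
  row_means <- rowMeans(m, na.rm = TRUE)
  filled[miss] <- row_means[row(m)[miss]]
  for (i in seq_len(max_iter)) {
    s <- svd(filled, nu = k, nv = k)
    approx <- s$u %*% (diag(s$d[seq_len(k)], k, k)) %*% t(s$v)
    delta <- max(abs(filled[miss] - approx[miss]))
    filled[miss] <- approx[miss]
    if (delta < tol) break
  }
  filled
}

#' Principal component analysis of profile columns
#'
#' Columns (profiles) are the observations, rows (taxa) the variables;
#' apply [preprocess_matrix()] first for unit-variance row scaling. Columns
#' of the matrix are centred per variable by `prcomp`.
#'
#' @param m Complete numeric matrix (rows taxa, columns profiles).
#' @return List with `scores` (profiles x components), `loadings`
#'   (taxa x components) and `explained` (percentage of variance per
#'   component, decreasing, summing to 100).
#' @export
pca_profiles <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m), !anyNA(m))
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >= 2 rows and columns",
                                         call. = FALSE)
  fit <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  var_pct <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, loadings = fit$rotation, explained = var_pct,
       center = fit$center)
}

#' Correlation-distance average-linkage clustering
#'
#' Items (matrix rows, or columns with `margin = "cols"`) are clustered
#' with distance `d(x, y) = 1 - Pearson(x, y)` (range 0..2) under average
#' linkage (UPGMA). Constant items have undefined correlation and raise an
#' error.
#'
#' @param m Numeric matrix.
#' @param margin Cluster `"rows"` or `"cols"`.
#' @return An [stats::hclust] object.
#' @export
hcluster_profiles <- function(m, margin = c("rows", "cols")) {
  margin <- match.arg(margin)
  stopifnot(is.matrix(m), is.numeric(m), !anyNA(m))
  x <- if (margin == "rows") t(m) else m
  if (ncol(x) < 2L) stop("need >= 2 items to cluster", call. = FALSE)
  if (any(apply(x, 2L, stats::sd) == 0)) {
    stop("constant item(s): correlation distance undefined", call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(x))
  stats::hclust(d, method = "average")
}

#' Serialize a dendrogram to Newick
#'
#' @param hc An [stats::hclust] object.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
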