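#' Bray-Curtis dissimilarity matrix
#'
#' d(a,b) = sum|a_i - b_i| / sum(a_i + b_i), bounded in \[0,1\]. Computed on
#' raw counts or on per-sample relative abundances; the choice is recorded on
#' the result.
#'
#' @param table a `count_table` (or numeric sample x taxa matrix) with >= 2
#'   samples.
#' @param normalize `"raw"` (default) or `"relative"`: whether to divide each
#'   sample by its total before computing distances.
#' @return symmetric `dist_matrix` with zero diagonal; attribute `metric` =
#'   `"bray-curtis"`, attribute `normalized` records the choice.
#' @export
bray_curtis <- function(table, normalize = c("raw", "relative")) {
  normalize <- match.arg(normalize)
  x <- unclass(as.matrix(table)) * 1.0
  if (nrow(x) < 2) stopf("bray_curtis needs >= 2 samples")
  tot <- rowSums(x)
  if (any(tot == 0)) {
    z <- rownames(x)[which(tot == 0)]
    stopf("all-zero sample(s) %s: Bray-Curtis undefined",
          paste(z, collapse = ", "))
  }
  if (normalize == "relative") x <- x / tot
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ])
  }
  dist_matrix(d, metric = "bray-curtis", normalized = normalize)
}

#' Distance matrix container
#'
#' Validates symmetry (to 1e-12), zero diagonal, and non-negativity.
#' @param d square numeric matrix with dimnames.
#' @param metric,normalized provenance tags.
#' @return matrix of class `dist_matrix`.
#' @export
dist_matrix <- function(d, metric = "unknown", normalized = NA) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stopf("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-12) stopf("distance matrix not symmetric")
  if (any(diag(d) != 0)) stopf("distance matrix diagonal must be 0")
  if (any(d < 0)) stopf("negative distances")
  structure(d, metric = metric, normalized = normalized,
            class = c("dist_matrix", "matrix", "array"))
}

#' UPGMA (average-linkage) clustering
#'
#' Agglomerates samples by unweighted average linkage on a distance matrix.
#' On ultrametric input the cophenetic distances of the result reproduce the
#' input exactly; exported branch lengths are half merge heights.
#'
#' @param d a `dist_matrix` (n >= 2).
#' @return list with `hclust` (the merge tree), `phylo` (ape tree) and
#'   `newick` (Newick string), class `upgma_tree`.
#' @export
upgma <- function(d) {
  if (nrow(d) < 2) stopf("upgma needs >= 2 samples")
  hc <- stats::hclust(stats::as.dist(unclass(d)), method = "average")
  ph <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = ph,
                 newick = ape::write.tree(ph)),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree:", x$newick, "\n")
  invisible(x)
}

#' Principal coordinates analysis
#'
#' Eigen-decomposition of the Gower-centered matrix -0.5 D^2. Negative
#' eigenvalues (non-Euclidean distances) are reported as-is, never silently
#' corrected; coordinate axes are returned only for positive eigenvalues.
#'
#' @param d a `dist_matrix` with n >= 3 samples.
#' @return list with `scores` (samples x positive axes, scaled by
#'   sqrt(eigenvalue)), `eigenvalues` (all, decreasing), `negative` (logical,
#'   any negative eigenvalues present).
#' @export
pcoa <- function(d) {
  n <- nrow(d)
  if (n < 3) stopf("pcoa needs >= 3 samples")
  G <- gower_center(unclass(d))
  e <- eigen(G, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(ev) * 1e-10 & ev > 0)
  sc <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), length(pos))
  rownames(sc) <- rownames(d)
  colnames(sc) <- paste0("PCo", seq_along(pos))
  list(scores = sc, eigenvalues = ev, negative = any(ev < -max(ev) * 1e-8))
}

# Gower double-centering of -0.5 * D^2
gower_center <- function(d) {
  A <- -0.5 * d^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}
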