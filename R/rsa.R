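#' Grid-flattened feature vectors
#'
#' Embeds each movement's per-channel dB map onto the array grid and
#' flattens it row-major; the unmapped (excluded) reference is dropped, so
#' the default geometry yields 1023-dimensional vectors.
#'
#' @param db_maps channels x movements matrix (or a named list of
#'   per-channel vectors).
#' @param geometry array geometry.
#' @param fill value for unoccupied grid cells.
#' @return movements x (n_rows * n_cols) matrix.
#' @export
feature_vectors <- function(db_maps, geometry, fill = 0) {
  if (is.list(db_maps)) db_maps <- do.call(cbind, db_maps)
  if (is.vector(db_maps)) db_maps <- matrix(db_maps, ncol = 1)
  if (nrow(db_maps) != n_contacts(geometry))
    stopf("maps have %d channels; geometry has %d contacts",
          nrow(db_maps), n_contacts(geometry))
  out <- t(apply(db_maps, 2, function(v)
    as.vector(t(grid_embed(v, geometry, fill)))))
  if (ncol(db_maps) == 1) out <- matrix(out, nrow = 1)
  rownames(out) <- colnames(db_maps)
  out
}

#' Euclidean representational dissimilarity matrix
#'
#' `d(i, j) = ||x_i - x_j||_2` between movement feature vectors; symmetric
#' with a zero diagonal.
#'
#' @param vectors items x dimensions matrix.
#' @return object of class `msom_rdm`: `distances` (full symmetric matrix),
#'   `labels`.
#' @export
rdm_euclidean <- function(vectors) {
  d <- as.matrix(dist(vectors, method = "euclidean"))
  structure(list(distances = d,
                 labels = rownames(vectors) %||%
                   paste0("item", seq_len(nrow(vectors)))),
            class = "msom_rdm")
}

kruskal_stress <- function(d_orig, d_proj) {
  lo <- lower.tri(d_orig)
  sqrt(sum((d_orig[lo] - d_proj[lo])^2) / sum(d_orig[lo]^2))
}

#' Metric multidimensional scaling with Kruskal stress
#'
#' Stress-minimizing (metric) MDS via SMACOF majorization, initialized from
#' classical scaling plus random restarts; the best (lowest-stress) solution
#' is kept. Stress is Kruskal's normalized stress
#' `sqrt(sum (d_orig - d_proj)^2 / sum d_orig^2)`.
#'
#' @param rdm an [rdm_euclidean()] object (or a symmetric matrix).
#' @param dims embedding dimensionality (2 or 3).
#' @param n_restarts random restarts in addition to the classical-scaling
#'   start.
#' @param max_iter,tol SMACOF iteration cap and stress-change convergence
#'   tolerance.
#' @param seed RNG seed (scoped).
#' @return object of class `msom_mds`: `coords` (items x dims), `stress`.
#' @export
mds_embed <- function(rdm, dims = 2, n_restarts = 8, max_iter = 500,
                      tol = 1e-9, seed = NULL) {
  d <- if (inherits(rdm, "msom_rdm")) rdm$distances else as.matrix(rdm)
  n <- nrow(d)
  if (!dims %in% c(2, 3)) stopf("dims must be 2 or 3")
  if (n < dims + 1) stopf("need at least dims + 1 items")
  smacof <- function(X) {
    for (it in seq_len(max_iter)) {
      dp <- as.matrix(dist(X))
      s_old <- kruskal_stress(d, dp)
      ratio <- ifelse(dp > 0, d / dp, 0)
      B <- -ratio
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- B %*% X / n
      dp <- as.matrix(dist(X))
      s_new <- kruskal_stress(d, dp)
      if (abs(s_old - s_new) < tol) break
    }
    list(X = X, stress = s_new)
  }
  with_seed(seed, {
    init <- suppressWarnings(cmdscale(d, k = dims))
    if (ncol(init) < dims)
      init <- cbind(init, matrix(0, n, dims - ncol(init)))
    best <- smacof(init)
    scale0 <- max(d)
    for (r in seq_len(n_restarts)) {
      cand <- smacof(matrix(rnorm(n * dims, sd = scale0), n, dims))
      if (cand$stress < best$stress) best <- cand
    }
    structure(list(coords = best$X, stress = best$stress, dims = dims),
              class = "msom_mds")
  })
}

#' Ward-linkage dendrogram of movement representations
#'
#' Agglomerative hierarchical clustering with Ward's criterion on the
#' Euclidean dissimilarities (Ward on the feature vectors and Ward.D2 on
#' their pairwise Euclidean distances coincide). Ties follow `hclust`'s
#' deterministic input-order rule.
#'
#' @param x items x dimensions feature matrix, or an `msom_rdm`.
#' @return an `hclust` tree whose labels are the movement labels.
#' @export
ward_tree <- function(x) {
  if (inherits(x, "msom_rdm")) {
    if (nrow(x$distances) < 2) stopf("need at least two items")
    dd <- stats::as.dist(x$distances)
    attr(dd, "Labels") <- x$labels
  } else {
    if (nrow(x) < 2) stopf("need at least two items")
    dd <- dist(x)
  }
  hclust(dd, method = "ward.D2")
}

#' Export a dendrogram as a Newick string
#'
#' @param tree an `hclust` object.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when writing to a file.
#' @export
tree_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Principal components of population activity
#'
#' Eigendecomposition of the channels x channels covariance of a channels x
#' time activity matrix: orthonormal spatial components, their projected
#' timecourses, and explained-variance fractions (summing to 1).
#'
#' @param hg channels x time matrix (e.g. trial-averaged high-gamma dB).
#' @param k number of components to keep (default all).
#' @return list: `components` (channels x k), `timecourses` (k x time),
#'   `explained_variance` (length k fractions of total variance).
#' @export
population_pca <- function(hg, k = NULL) {
  if (ncol(hg) < 2) stopf("need at least two timepoints")
  centered <- hg - rowMeans(hg)
  if (all(abs(centered) < 1e-15)) stopf("constant data; covariance is zero")
  cv <- tcrossprod(centered) / (ncol(hg) - 1)
  e <- eigen(cv, symmetric = TRUE)
  k <- k %||% nrow(hg)
  vals <- pmax(e$values, 0)
  list(components = e$vectors[, seq_len(k), drop = FALSE],
       timecourses = t(e$vectors[, seq_len(k), drop = FALSE]) %*% centered,
       explained_variance = (vals / sum(vals))[seq_len(k)])
}
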