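#' Principal component analysis of pigment ratios
#'
#' Column-centers (and by default scales to unit variance) the station x
#' ratio matrix and decomposes it by singular value decomposition,
#' X = U S V'. Loadings are the right singular vectors (variable x mode),
#' scores are U S (station x mode), and the variance explained by mode k
#' is s_k^2 / sum(s^2). Ratio variables span orders of magnitude, hence
#' the standardization default. The sign of each mode is fixed so that its
#' largest-magnitude loading is positive, making output reproducible.
#'
#' @param R numeric stations x variables matrix (e.g. from
#'   [ratios_to_tchla()], possibly augmented with ancillary variables).
#' @param standardize scale columns to unit variance (default TRUE).
#' @return Object of class `pca_result`: `loadings`, `scores`,
#'   `explained_variance`, `singular_values`, `center`, `scale`.
#' @export
pca_ratios <- function(R, standardize = TRUE) {
  R <- as.matrix(R)
  if (nrow(R) < 2 || ncol(R) < 2)
    stop("need at least 2 stations and 2 variables", call. = FALSE)
  if (anyNA(R)) stop("missing values not allowed (below-LOD cells are 0)",
                     call. = FALSE)
  ctr <- colMeans(R)
  X <- sweep(R, 2, ctr)
  scl <- rep(1, ncol(R))
  if (standardize) {
    scl <- apply(R, 2, stats::sd)
    if (any(scl == 0))
      stop("constant column(s) cannot be standardized: ",
           paste(colnames(R)[scl == 0], collapse = ", "), call. = FALSE)
    X <- sweep(X, 2, scl, `/`)
  }
  sv <- svd(X)
  flip <- apply(sv$v, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  V <- sweep(sv$v, 2, flip, `*`)
  U <- sweep(sv$u, 2, flip, `*`)
  scores <- U %*% diag(sv$d, length(sv$d))
  modes <- paste0("PC", seq_along(sv$d))
  dimnames(V) <- list(colnames(R), modes)
  dimnames(scores) <- list(rownames(R), modes)
  structure(list(loadings = V, scores = scores,
                 explained_variance = sv$d^2 / sum(sv$d^2),
                 singular_values = sv$d, center = ctr, scale = scl,
                 standardize = standardize),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " stations, ", nrow(x$loadings),
      " variables\n  explained variance: ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance[
        seq_len(min(4, length(x$explained_variance)))]), collapse = " "),
      " ...\n", sep = "")
  invisible(x)
}

#' Hierarchical clustering of pigments
#'
#' Clusters pigment ratio variables with Ward linkage on Pearson
#' correlation distance d = 1 - r (signed, so anticorrelated pigments are
#' far apart) and cuts the tree at a fixed linkage distance. Pigments with
#' zero variance across stations carry no correlation information and are
#' excluded with a warning.
#'
#' @param R stations x pigments ratio matrix.
#' @param cutoff tree cut height (default 0.5).
#' @return Object of class `hca_result`: the `hclust` tree, `cluster_of`
#'   (named pigment -> cluster id), `cutoff`, `distance` matrix and the
#'   excluded pigments.
#' @export
hca_pigments <- function(R, cutoff = 0.5) {
  R <- as.matrix(R)
  v <- apply(R, 2, stats::var)
  excluded <- colnames(R)[v == 0]
  if (length(excluded))
    warning("zero-variance pigment(s) excluded: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  R <- R[, v > 0, drop = FALSE]
  if (ncol(R) < 3)
    stop("need at least 3 pigments with nonzero variance", call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(R))
  tree <- stats::hclust(d, method = "ward.D2")
  cl <- stats::cutree(tree, h = cutoff)
  structure(list(tree = tree, cluster_of = cl, cutoff = cutoff,
                 distance = as.matrix(d), excluded = excluded),
            class = "hca_result")
}

#' @export
print.hca_result <- function(x, ...) {
  cat("<hca_result> ", length(x$cluster_of), " pigments, ",
      max(x$cluster_of), " clusters at cutoff ", x$cutoff, "\n", sep = "")
  print(split(names(x$cluster_of), x$cluster_of))
  invisible(x)
}

#' Assign stations to pigment clusters
#'
#' Each station is assigned to the pigment cluster whose template profile
#' best matches (maximal Pearson correlation) the station's ratio vector.
#' A cluster's template has, at its member pigments, the across-station
#' mean ratio of that pigment, and 0 elsewhere. Ties (including stations
#' with constant ratio vectors, for which correlation is undefined) go
#' deterministically to the lowest cluster id, with a warning.
#'
#' @param R stations x pigments ratio matrix (same pigments as used for
#'   the clustering).
#' @param hca an [hca_pigments()] result.
#' @return Named integer vector station -> cluster id.
#' @export
assign_stations_to_clusters <- function(R, hca) {
  R <- as.matrix(R)[, names(hca$cluster_of), drop = FALSE]
  k <- max(hca$cluster_of)
  templates <- sapply(seq_len(k), function(ci) {
    t <- rep(0, ncol(R))
    member <- hca$cluster_of == ci
    t[member] <- colMeans(R[, member, drop = FALSE])
    t
  })
  out <- integer(nrow(R))
  tied <- character(0)
  for (i in seq_len(nrow(R))) {
    x <- R[i, ]
    if (stats::sd(x) == 0) {
      out[i] <- 1L
      tied <- c(tied, rownames(R)[i])
      next
    }
    cors <- suppressWarnings(apply(templates, 2, function(t)
      if (stats::sd(t) == 0) NA_real_ else stats::cor(x, t)))
    best <- max(cors, na.rm = TRUE)
    hits <- which(abs(cors - best) < 1e-12)
    if (length(hits) > 1) tied <- c(tied, rownames(R)[i])
    out[i] <- min(hits)
  }
  if (length(tied))
    warning("tie-broken station assignment(s) (lowest cluster id): ",
            paste(tied, collapse = ", "), call. = FALSE)
  stats::setNames(out, rownames(R))
}

#' Export a dendrogram as Newick-like nested text
#'
#' @param hca an [hca_pigments()] result.
#' @return A single character string (Newick format, heights as branch
#'   lengths).
#' @export
hca_newick <- function(hca) {
  tree <- hca$tree
  n <- length(tree$labels)
  node_txt <- function(i, parent_h) {
    if (i < 0) {
      lab <- tree$labels[-i]
      sprintf("%s:%g", lab, parent_h)
    } else {
      h <- tree$height[i]
      sprintf("(%s,%s):%g",
              node_txt(tree$merge[i, 1], h), node_txt(tree$merge[i, 2], h),
              parent_h - h)
    }
  }
  root <- n - 1
  h <- tree$height[root]
  sprintf("(%s,%s);",
          node_txt(tree$merge[root, 1], h), node_txt(tree$merge[root, 2], h))
}
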