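#' Weighted pigment correlation network
#'
#' Builds the pigment similarity matrix s_ij = |pearson(x_i, x_j)| from a
#' stations x pigments ratio matrix and soft-thresholds it into an
#' adjacency a_ij = s_ij^beta. Raising beta suppresses weak correlations
#' relative to strong ones, sharpening community structure before
#' detection; note the absolute value, in contrast to the signed distance
#' used by [hca_pigments()] — the network treats strong anticorrelation as
#' association, the dendrogram separates it.
#'
#' @param R stations x pigments ratio matrix (>= 3 stations); pigments
#'   with zero variance are excluded with a warning.
#' @param beta soft-threshold exponent (> 0, default 6).
#' @return Object of class `pigment_network`: `similarity`, `adjacency`
#'   (both with unit diagonal), `beta`, `excluded`.
#' @export
build_network <- function(R, beta = 6) {
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  R <- as.matrix(R)
  if (nrow(R) < 3) stop("need at least 3 stations", call. = FALSE)
  v <- apply(R, 2, stats::var)
  excluded <- colnames(R)[v == 0]
  if (length(excluded))
    warning("zero-variance pigment(s) excluded: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  R <- R[, v > 0, drop = FALSE]
  s <- abs(stats::cor(R))
  a <- s^beta
  structure(list(similarity = s, adjacency = a, beta = beta,
                 excluded = excluded),
            class = "pigment_network")
}

#' Louvain community detection on a pigment network
#'
#' Runs the Louvain modularity-maximization heuristic on the weighted
#' graph defined by the adjacency (self-loops removed) and reports the
#' weighted modularity Q of the returned partition. Q > 0.3 is flagged as
#' strong community structure. The Louvain heuristic involves random
#' vertex orderings; the seed makes the run reproducible.
#'
#' @param network a [build_network()] result, or a symmetric non-negative
#'   adjacency matrix.
#' @param seed RNG seed (default 1).
#' @return Object of class `network_communities`: `communities` (named
#'   pigment -> community id), `modularity`, `strong_structure`,
#'   `n_communities`.
#' @export
detect_communities <- function(network, seed = 1L) {
  a <- if (inherits(network, "pigment_network")) network$adjacency
       else as.matrix(network)
  if (nrow(a) == 0) stop("empty graph", call. = FALSE)
  if (any(a < 0)) stop("adjacency must be non-negative", call. = FALSE)
  if (max(abs(a - t(a))) > 1e-12) stop("adjacency must be symmetric",
                                       call. = FALSE)
  diag(a) <- 0
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  membership <- igraph::membership(cl)
  Q <- igraph::modularity(g, membership, weights = igraph::E(g)$weight)
  structure(list(communities = stats::setNames(as.integer(membership),
                                               rownames(a)),
                 modularity = Q, strong_structure = Q > 0.3,
                 n_communities = length(unique(membership))),
            class = "network_communities")
}

#' Weighted modularity of a given partition
#'
#' Closed-form weighted modularity
#' Q = sum_ij (a_ij - k_i k_j / 2m) delta(c_i, c_j) / 2m with the diagonal
#' excluded; used for reporting and for comparing partitions.
#'
#' @param adjacency symmetric non-negative matrix.
#' @param membership integer community labels.
#' @return Numeric Q.
#' @export
partition_modularity <- function(adjacency, membership) {
  a <- as.matrix(adjacency)
  diag(a) <- 0
  m2 <- sum(a)
  if (m2 == 0) return(0)
  k <- rowSums(a)
  same <- outer(membership, membership, `==`)
  sum((a - outer(k, k) / m2) * same) / m2
}

#' @export
print.network_communities <- function(x, ...) {
  cat("<network_communities> ", x$n_communities, " communities, Q = ",
      signif(x$modularity, 3),
      if (x$strong_structure) " (strong structure)" else "", "\n", sep = "")
  invisible(x)
}

#' Label stations by dominant pigment community
#'
#' Each station is labeled by the pigment community carrying the largest
#' share of its summed pigment concentration. When a CHEMTAX result is
#' supplied, community ids are renamed to the phytoplankton group whose
#' refined ratios put the most mass on the community's pigments; a
#' community with no ratio mass in the fitted matrix cannot be resolved
#' taxonomically and is labeled `"mixed/pico-nano"`.
#'
#' @param m a [pigment_matrix()].
#' @param communities a [detect_communities()] result (or a named
#'   pigment -> community id vector).
#' @param chemtax optional [fit_chemtax()] result used to rename
#'   communities.
#' @return data.frame `station_id`, `community`, `label` (plus `lat`/`lon`
#'   when present in the metadata).
#' @export
dominant_group_map <- function(m, communities, chemtax = NULL) {
  stopifnot(inherits(m, "pigment_matrix"))
  comm <- if (inherits(communities, "network_communities"))
    communities$communities else communities
  pigs <- intersect(names(comm), colnames(m$values))
  ids <- sort(unique(comm))
  share <- do.call(cbind, lapply(ids, function(ci) {
    member <- intersect(pigs, names(comm)[comm == ci])
    if (!length(member)) return(rep(0, nrow(m$values)))
    rowSums(m$values[, member, drop = FALSE])
  }))
  dom <- ids[apply(share, 1, which.max)]
  label <- as.character(dom)
  if (!is.null(chemtax)) {
    Fv <- chemtax$F_final$values
    name_of <- sapply(ids, function(ci) {
      member <- intersect(names(comm)[comm == ci], colnames(Fv))
      if (!length(member)) return("mixed/pico-nano")
      mass <- rowSums(Fv[, member, drop = FALSE])
      if (max(mass) == 0) return("mixed/pico-nano")
      rownames(Fv)[which.max(mass)]
    })
    label <- name_of[match(dom, ids)]
  }
  out <- data.frame(station_id = m$stations$station_id,
                    community = dom, label = label, row.names = NULL)
  for (v in c("lat", "lon"))
    if (!is.null(m$stations[[v]])) out[[v]] <- m$stations[[v]]
  out
}

#' Export a network as a weighted edge list
#'
#' @param network a [build_network()] result.
#' @param path CSV path (columns from, to, similarity, adjacency).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  s <- network$similarity
  idx <- which(upper.tri(s), arr.ind = TRUE)
  df <- data.frame(from = rownames(s)[idx[, 1]],
                   to = colnames(s)[idx[, 2]],
                   similarity = s[idx],
                   adjacency = network$adjacency[idx])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
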