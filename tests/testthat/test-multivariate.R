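test_that("PCA handles rank-1 data and reconstructs the input", {
  set.seed(42)
  u <- rnorm(30); v <- c(1, -2, 0.5, 3)
  X <- outer(u, v)
  colnames(X) <- paste0("v", 1:4)
  p <- pca_ratios(X, standardize = FALSE)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-12)

  syn <- generate_pigment_data(generator_config(seed = 12))
  R <- ratios_to_tchla(syn$matrix)
  R <- R[, apply(R, 2, sd) > 0]
  p2 <- pca_ratios(R)
  Xc <- scale(R, center = p2$center, scale = p2$scale)
  attr(Xc, "scaled:center") <- attr(Xc, "scaled:scale") <- NULL
  expect_equal(p2$scores %*% t(p2$loadings), unclass(Xc),
               tolerance = 1e-10, ignore_attr = TRUE)
  # scores are centered and total variance is conserved
  expect_true(all(abs(colMeans(p2$scores)) < 1e-10))
  expect_equal(sum(p2$scores^2), sum(Xc^2), tolerance = 1e-10)
  # loadings are orthonormal
  expect_equal(crossprod(p2$loadings), diag(ncol(p2$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # deterministic sign convention: dominant loading of each mode positive
  for (k in seq_len(ncol(p2$loadings))) {
    lk <- p2$loadings[, k]
    expect_gt(lk[which.max(abs(lk))], 0)
  }
})

test_that("PCA rejects constant columns under standardization", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_error(pca_ratios(X), "constant column.*b")
  expect_silent(pca_ratios(X, standardize = FALSE))
})

test_that("two latent drivers with a 70/30 variance split are recovered", {
  set.seed(7)
  n <- 500
  z1 <- rnorm(n, sd = sqrt(0.7)); z2 <- rnorm(n, sd = sqrt(0.3))
  v1 <- c(1, 1, 0, 0) / sqrt(2); v2 <- c(0, 0, 1, -1) / sqrt(2)
  X <- outer(z1, v1) + outer(z2, v2) + matrix(rnorm(n * 4, sd = 0.02), n)
  colnames(X) <- paste0("v", 1:4)
  p <- pca_ratios(X, standardize = FALSE)
  expect_equal(p$explained_variance[1], 0.7, tolerance = 0.08)
  expect_equal(p$explained_variance[2], 0.3, tolerance = 0.08)
})

test_that("clustering merges identical columns first and cuts correctly", {
  set.seed(1)
  base <- rnorm(20)
  R <- cbind(A = base, B = base, C = -base + rnorm(20, sd = 0.01))
  h <- hca_pigments(R)
  # identical columns have distance 0 and merge at height ~0
  expect_lt(h$tree$height[1], 1e-6)
  expect_equal(sort(h$tree$merge[1, ]), c(-2, -1))
  # hand-computed distances: d(A,B) = 0, d(A,C) = d(B,C) = 2 - eps;
  # brute-force agglomeration puts the anticorrelated C on its own
  expect_equal(max(h$cluster_of), 2)
  expect_equal(unname(h$cluster_of["A"]), unname(h$cluster_of["B"]))
  expect_false(h$cluster_of[["A"]] == h$cluster_of[["C"]])
  # merge heights are monotone
  expect_true(all(diff(h$tree$height) >= -1e-12))
})

test_that("zero-variance pigments are excluded with a warning", {
  set.seed(2)
  R <- cbind(A = rnorm(10), B = rnorm(10), C = rnorm(10), D = rep(1, 10))
  expect_warning(h <- hca_pigments(R), "zero-variance.*D")
  expect_false("D" %in% names(h$cluster_of))
})

test_that("the generator's three pigment blocks split at cutoff 0.5", {
  hits <- sapply(1:50, function(s) {
    syn <- generate_pigment_data(generator_config(seed = s))
    h <- hca_pigments(planted_ratios(syn))
    max(h$cluster_of) == 3 &&
      isTRUE(ari(h$cluster_of[names(planted_blocks)], planted_blocks) == 1)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("stations map onto the matching pigment cluster", {
  syn <- generate_pigment_data(generator_config(seed = 2))
  R <- planted_ratios(syn)
  h <- hca_pigments(R)
  # a station whose only nonzero ratios are one cluster's pigments
  members <- names(h$cluster_of)[h$cluster_of == h$cluster_of[["Allo"]]]
  x <- rep(0, ncol(R)); names(x) <- colnames(R)
  x[members] <- colMeans(R)[members]
  got <- assign_stations_to_clusters(rbind(st = x), h)
  expect_equal(unname(got), unname(h$cluster_of[["Allo"]]))
  # a uniform ratio vector is a tie: lowest cluster id, with a warning
  u <- rep(0.1, ncol(R)); names(u) <- colnames(R)
  expect_warning(tie <- assign_stations_to_clusters(rbind(st = u), h),
                 "tie-broken")
  expect_equal(unname(tie), 1L)
})

test_that("single-block synthetic stations are assigned to their block", {
  correct <- 0L; total <- 0L
  blocks <- split(names(planted_blocks), planted_blocks)
  for (s in 1:50) {
    syn <- generate_pigment_data(generator_config(seed = s))
    R <- planted_ratios(syn)
    h <- hca_pigments(R)
    if (max(h$cluster_of) != 3) next
    set.seed(s + 500)
    for (b in blocks) {
      cl <- unique(h$cluster_of[b])
      if (length(cl) != 1) next
      x <- rep(0, ncol(R)); names(x) <- colnames(R)
      x[b] <- colMeans(R)[b] * runif(length(b), 0.5, 1.5)
      correct <- correct + (assign_stations_to_clusters(rbind(st = x), h) == cl)
      total <- total + 1L
    }
  }
  expect_gte(correct / total, 0.95)
})

test_that("clustering is invariant to station order and column scaling", {
  syn <- generate_pigment_data(generator_config(seed = 10))
  R <- planted_ratios(syn)
  h1 <- hca_pigments(R)
  set.seed(99)
  h2 <- hca_pigments(R[sample(nrow(R)), ])
  expect_equal(h2$cluster_of, h1$cluster_of)
  R3 <- R
  R3[, "Zea"] <- R3[, "Zea"] * 1000
  h3 <- hca_pigments(R3)
  expect_equal(h3$cluster_of, h1$cluster_of)
})

test_that("the dendrogram export is valid Newick text", {
  syn <- generate_pigment_data(generator_config(seed = 3))
  h <- hca_pigments(planted_ratios(syn))
  nwk <- hca_newick(h)
  expect_match(nwk, "^\\(.*\\);$")
  for (p in names(h$cluster_of)) expect_match(nwk, p, fixed = TRUE)
})
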