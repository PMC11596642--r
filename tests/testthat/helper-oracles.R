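# Independent oracles and shared fixtures for the test suite. These are
# deliberately written from scratch (no quadprog / igraph) so that the
# package implementation is checked against a second route.

# Lawson-Hanson active-set non-negative least squares.
lh_nnls <- function(A, b, tol = 1e-12) {
  n <- ncol(A)
  x <- rep(0, n)
  passive <- rep(FALSE, n)
  for (outer in seq_len(10 * n)) {
    w <- drop(crossprod(A, b - A %*% x))
    w[passive] <- -Inf
    if (all(w <= tol)) break
    passive[which.max(w)] <- TRUE
    repeat {
      s <- rep(0, n)
      s[passive] <- qr.solve(A[, passive, drop = FALSE], b)
      if (all(s[passive] > tol)) { x <- s; break }
      drop_set <- passive & s <= tol
      alpha <- min(x[drop_set] / (x[drop_set] - s[drop_set]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
  }
  x
}

# All set partitions of 1..n (Bell(8) = 4140, fine for n <= 8).
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1]] <- q
    }
    p[[length(p) + 1]] <- n
    out[[length(out) + 1]] <- p
  }
  out
}

# Exhaustive-search maximum weighted modularity over all partitions.
brute_modularity <- function(a) {
  n <- nrow(a)
  stopifnot(n <= 8)
  best <- -Inf
  for (p in set_partitions(n)) {
    memb <- integer(n)
    for (k in seq_along(p)) memb[p[[k]]] <- k
    q <- partition_modularity(a, memb)
    if (q > best) best <- q
  }
  best
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sr <- sum(choose(rowSums(tab), 2))
  sc <- sum(choose(colSums(tab), 2))
  s <- sum(choose(tab, 2))
  e <- sr * sc / choose(n, 2)
  (s - e) / ((sr + sc) / 2 - e)
}

# The generator's built-in covarying pigment blocks (size classes) with
# single-dominant-class support under the default configuration.
planted_blocks <- c(Chlide_a = 1, TChl_c = 1, Peri = 1, Diad = 1,
                    Diato = 1, Fuco = 2, Viola = 2, Allo = 2,
                    Neo = 3, Lut = 3, Zea = 3, Echin = 3, TChl_b = 3)

planted_ratios <- function(syn) {
  ratios_to_tchla(syn$matrix)[, names(planted_blocks)]
}

# A tiny hand-built station table for I/O and validation tests.
tiny_table_csv <- function(path) {
  writeLines(c(
    "station_id,campaign,lat,lon,depth_m,temp_C,spm,MVchl_a,DVchl_a,Chlide_a,Fuco,Zea,Peri,Allo,TChl_b,TChl_c,Caro_b",
    "m1s1,1,45.5,8.31,120,16.2,0.01,2.0,0,0.1,0.5,0.2,<LOD,0.15,0.08,0.2,0.18",
    "m1s2,1,45.51,8.32,200,16.8,0.012,1.5,0,0.05,0.4,,0.08,0.1,0.06,0.15,0.12",
    "m3s1,3,45.52,8.33,300,23.1,0.009,3.0,0,0.2,0.9,0.3,0.12,0.2,0.1,0.3,0.25"),
    path)
  path
}
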