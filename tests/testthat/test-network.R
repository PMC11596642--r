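test_that("soft thresholding follows the power rule", {
  set.seed(5)
  base <- rnorm(30)
  R <- cbind(A = base, B = 2.5 * base, C = rnorm(30), D = rnorm(30))
  net1 <- build_network(R, beta = 1)
  expect_equal(net1$adjacency, net1$similarity)
  net6 <- build_network(R, beta = 6)
  # proportional columns: similarity 1 at any beta
  expect_equal(unname(net6$similarity["A", "B"]), 1, tolerance = 1e-12)
  expect_equal(unname(net6$adjacency["A", "B"]), 1, tolerance = 1e-12)
  expect_equal(net6$adjacency, net1$similarity^6)
  # s = 0.5 maps to 0.5^6 = 0.015625
  expect_equal(0.5^6, 0.015625)
  # raising beta weakly decreases every off-diagonal entry
  net9 <- build_network(R, beta = 9)
  off <- upper.tri(net6$adjacency)
  expect_true(all(net9$adjacency[off] <= net6$adjacency[off] + 1e-15))
  expect_error(build_network(R, beta = 0), "beta")
})

test_that("Louvain matches the exhaustive modularity optimum on small graphs", {
  two_cliques <- function(k, w_in = 1, w_out = 0) {
    n <- 2 * k
    a <- matrix(w_out, n, n)
    a[1:k, 1:k] <- w_in
    a[(k + 1):n, (k + 1):n] <- w_in
    diag(a) <- 0
    rownames(a) <- colnames(a) <- paste0("p", 1:n)
    a
  }
  graphs <- list(
    disconnected = two_cliques(4),
    bridged = two_cliques(4, w_out = 0.05),
    threeblock = {
      a <- matrix(0.02, 8, 8)
      a[1:3, 1:3] <- 1; a[4:6, 4:6] <- 1; a[7:8, 7:8] <- 1
      diag(a) <- 0
      rownames(a) <- colnames(a) <- paste0("p", 1:8)
      a
    },
    uniform = {
      a <- matrix(1, 6, 6); diag(a) <- 0
      rownames(a) <- colnames(a) <- paste0("p", 1:6)
      a
    })
  for (nm in names(graphs)) {
    a <- graphs[[nm]]
    cm <- detect_communities(a, seed = 1)
    expect_equal(cm$modularity, brute_modularity(a), tolerance = 1e-9,
                 label = paste("graph", nm))
    expect_equal(cm$modularity,
                 partition_modularity(a, cm$communities),
                 tolerance = 1e-9)
  }
  # two disconnected equal cliques: Q = 1/2 by the closed-form sum
  cm <- detect_communities(graphs$disconnected, seed = 1)
  expect_equal(cm$n_communities, 2)
  expect_equal(cm$modularity, 0.5, tolerance = 1e-12)
  # uniform complete graph has no structure: one community, Q = 0
  cm_u <- detect_communities(graphs$uniform, seed = 1)
  expect_equal(cm_u$n_communities, 1)
  expect_equal(cm_u$modularity, 0, tolerance = 1e-12)
  expect_false(cm_u$strong_structure)
})

test_that("community detection validates its input and is seeded", {
  expect_error(detect_communities(matrix(numeric(0), 0, 0)), "empty")
  a <- matrix(c(0, -1, -1, 0), 2)
  expect_error(detect_communities(a), "non-negative")
  syn <- generate_pigment_data(generator_config(seed = 4))
  net <- build_network(planted_ratios(syn))
  c1 <- detect_communities(net, seed = 7)
  c2 <- detect_communities(net, seed = 7)
  expect_identical(c1$communities, c2$communities)
  expect_identical(c1$modularity, c2$modularity)
})

test_that("returned partitions never lose to the trivial one", {
  for (s in 1:10) {
    syn <- generate_pigment_data(generator_config(seed = s))
    net <- build_network(planted_ratios(syn))
    cm <- detect_communities(net, seed = s)
    a <- net$adjacency
    expect_gte(cm$modularity,
               partition_modularity(a, rep(1, nrow(a))) - 1e-12)
  }
})

test_that("the generator's planted blocks are recovered by Louvain", {
  hits <- sapply(1:50, function(s) {
    syn <- generate_pigment_data(generator_config(seed = s))
    cm <- detect_communities(build_network(planted_ratios(syn)), seed = s)
    isTRUE(ari(cm$communities[names(planted_blocks)], planted_blocks) == 1)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("stations are labeled by their dominant pigment community", {
  syn <- generate_pigment_data(generator_config(seed = 2))
  R <- planted_ratios(syn)
  cm <- detect_communities(build_network(R), seed = 2)
  # station with only Fuco nonzero -> Fuco's community
  vals <- matrix(0, 1, ncol(R), dimnames = list("st", colnames(R)))
  vals[, "Fuco"] <- 1
  m1 <- pigment_matrix(cbind(vals, MVchl_a = 2),
                       data.frame(station_id = "st"),
                       panel = pigment_panel(c(colnames(R), "MVchl_a")))
  map <- dominant_group_map(m1, cm)
  expect_equal(map$community, unname(cm$communities[["Fuco"]]))
  # with CHEMTAX attached, an alloxanthin-only community reads Cryptophytes
  fit <- fit_chemtax(syn$matrix, lake_f1(),
                     chemtax_config(max_iter = 50))
  fake_comm <- c(Allo = 1L, Fuco = 2L, Zea = 3L)
  vals2 <- matrix(0, 1, 3, dimnames = list("st", names(fake_comm)))
  vals2[, "Allo"] <- 1
  m2 <- pigment_matrix(cbind(vals2, MVchl_a = 2),
                       data.frame(station_id = "st"),
                       panel = pigment_panel(c(names(fake_comm), "MVchl_a")))
  map2 <- dominant_group_map(m2, fake_comm, fit)
  expect_equal(map2$label, "Cryptophytes")
})

test_that("strongly dominant planted classes drive the station labels", {
  classes <- list(micro = c("Diatoms", "Dinophyceae"),
                  nano = c("Chrysophytes", "Cryptophytes"),
                  pico = c("Cyanophytes", "Chlorophyceae"))
  base <- c(Diatoms = 0.70, Chlorophyceae = 0.30, Cyanophytes = 0.46,
            Chrysophytes = 0.62, Dinophyceae = 0.203, Cryptophytes = 0.65)
  agree <- unlist(lapply(1:10, function(s) {
    syn0 <- generate_pigment_data(generator_config(seed = s))
    cm <- detect_communities(build_network(planted_ratios(syn0)), seed = s)
    fit <- fit_chemtax(syn0$matrix, lake_f1(), chemtax_config(max_iter = 50))
    sapply(names(classes), function(cl) {
      gm <- base
      gm[classes[[cl]]] <- gm[classes[[cl]]] * 10
      syn <- generate_pigment_data(generator_config(seed = s + 99,
                                                    group_mean = gm))
      mean(dominant_group_map(syn$matrix, cm, fit)$label %in% classes[[cl]])
    })
  }))
  expect_gte(mean(agree), 0.9)
})

test_that("edge lists round-trip the network weights", {
  syn <- generate_pigment_data(generator_config(seed = 5))
  net <- build_network(planted_ratios(syn))
  path <- tempfile(fileext = ".csv")
  write_edge_list(net, path)
  df <- read.csv(path)
  expect_equal(nrow(df), choose(nrow(net$similarity), 2))
  i <- which(df$from == "TChl_c" & df$to == "Peri" |
             df$from == "Peri" & df$to == "TChl_c")
  expect_equal(df$similarity[i], net$similarity["TChl_c", "Peri"],
               tolerance = 1e-9)
  expect_equal(df$adjacency[i], df$similarity[i]^6, tolerance = 1e-9)
})
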