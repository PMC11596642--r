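#' Group x pigment ratio matrix
#'
#' The CHEMTAX ratio matrix: for each phytoplankton group, the expected
#' pigment:TChl a weight ratios. The TChl a column is identically 1 (each
#' group's biomass is expressed as TChl a). Zero entries are structural:
#' the group does not produce the pigment and the entry stays 0 through
#' refinement.
#'
#' @param values numeric matrix, groups x pigments, with row names (group
#'   names) and column names (pigment ids, including `TChl_a`).
#' @param structural_zero logical matrix marking entries fixed at 0;
#'   default `values == 0`.
#' @return Object of class `ratio_matrix`.
#' @export
ratio_matrix <- function(values, structural_zero = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("ratio matrix needs group row names and pigment column names",
         call. = FALSE)
  colnames(values) <- resolve_pigment(colnames(values))
  if (!"TChl_a" %in% colnames(values))
    stop("ratio matrix must contain a TChl_a column", call. = FALSE)
  if (any(abs(values[, "TChl_a"] - 1) > 1e-12))
    stop("TChl_a column must be identically 1", call. = FALSE)
  if (any(values < 0)) stop("ratios must be >= 0", call. = FALSE)
  if (is.null(structural_zero)) structural_zero <- values == 0
  structural_zero <- as.matrix(structural_zero)
  stopifnot(identical(dim(structural_zero), dim(values)))
  if (any(values[structural_zero] != 0))
    stop("structural zeros must have value 0", call. = FALSE)
  structure(list(values = values, structural_zero = structural_zero),
            class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat("<ratio_matrix> ", nrow(x$values), " groups x ", ncol(x$values),
      " pigments\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Read / write a ratio matrix as CSV
#'
#' Layout: header row of pigment ids, first column `group`.
#' @param path CSV path.
#' @return A [ratio_matrix()].
#' @export
read_ratio_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  grp <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- grp
  ratio_matrix(vals)
}

#' @rdname read_ratio_matrix
#' @param f a `ratio_matrix`.
#' @export
write_ratio_matrix <- function(f, path) {
  df <- data.frame(group = rownames(f$values),
                   as.data.frame(f$values, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Refined ratio matrix for the Lake Maggiore survey
#'
#' The published refined (F1) CHEMTAX matrix for the six groups resolved
#' in the Lake Maggiore 2023 survey, with chlorophyll c1 stored under the
#' canonical `TChl_c` id. Useful as a realistic starting point for lake
#' datasets and as `F_true` for the synthetic generator.
#'
#' @return A [ratio_matrix()], 6 groups x 11 pigments (incl. TChl_a).
#' @export
lake_f1 <- function() {
  pig <- c("TChl_c", "Peri", "Fuco", "Neo", "Viola", "Allo", "Lut",
           "Zea", "Echin", "TChl_b", "TChl_a")
  vals <- rbind(
    Diatoms       = c(0.021, 0,     0.039, 0,     0,     0,     0,     0.005, 0,     0,     1),
    Chlorophyceae = c(0,     0,     0,     0.030, 0.025, 0,     0.099, 0.001, 0,     0.172, 1),
    Cyanophytes   = c(0,     0,     0,     0,     0,     0,     0,     0.284, 0.055, 0,     1),
    Chrysophytes  = c(0,     0,     0.207, 0,     0.094, 0,     0,     0.001, 0,     0,     1),
    Dinophyceae   = c(0,     0.334, 0,     0,     0,     0,     0,     0,     0,     0,     1),
    Cryptophytes  = c(0,     0,     0,     0,     0,     0.143, 0,     0,     0,     0,     1))
  colnames(vals) <- pig
  ratio_matrix(vals)
}

#' Example initial ratio matrix
#'
#' An initial (F0) matrix built by multiplicatively jittering the nonzero
#' entries of [lake_f1()], emulating the situation where only approximate
#' literature ratios are available. Structural zeros are preserved.
#'
#' @param perturb_pct percent jitter half-width (default 20).
#' @param seed RNG seed.
#' @return A [ratio_matrix()].
#' @export
example_f0 <- function(perturb_pct = 20, seed = 1L) {
  jitter_ratio_matrix(lake_f1(), perturb_pct, seed)
}

jitter_ratio_matrix <- function(f, perturb_pct, seed) {
  set.seed(seed)
  v <- f$values
  idx <- which(!f$structural_zero & colnames(v)[col(v)] != "TChl_a")
  v[idx] <- v[idx] * stats::runif(length(idx), 1 - perturb_pct / 100,
                                  1 + perturb_pct / 100)
  ratio_matrix(v, f$structural_zero)
}

#' Default CHEMTAX pigment set
#'
#' The twelve pigments conventionally used to resolve the six lake groups:
#' TChl a, TChl b, TChl c (c1+c2), fucoxanthin, zeaxanthin, peridinin,
#' alloxanthin, diadinoxanthin, echinenone, beta-carotene, chlorophyllide
#' a and chlorophyll c3. Any override is validated against the canonical
#' vocabulary; note that a shipped ratio matrix may legitimately use a
#' different (e.g. 11-pigment) set — the solver is pigment-set-agnostic.
#'
#' @param override optional character vector of pigment ids replacing the
#'   default set.
#' @return Character vector of canonical pigment ids.
#' @export
chemtax_pigment_set <- function(override = NULL) {
  if (is.null(override))
    return(c("TChl_a", "TChl_b", "TChl_c", "Fuco", "Zea", "Peri", "Allo",
             "Diad", "Echin", "Caro_b", "Chlide_a", "Chlc3"))
  resolve_pigment(override)
}

#' CHEMTAX solver configuration
#'
#' @param ratio_limit_pct element-wise ratio limit as a percentage of the
#'   initial matrix: refined entries are confined to
#'   `[max(0, F0 (1 - L/100)), F0 (1 + L/100)]`. The conventional default
#'   of 500 therefore allows each nonzero ratio to move in `[0, 6 F0]`.
#' @param max_iter maximum alternating iterations.
#' @param tol convergence tolerance on the relative change of the weighted
#'   RMSE between iterations.
#' @param n_multistart number of starts for [multistart_chemtax()].
#' @param perturb_pct multiplicative jitter (percent) applied to F0 for
#'   the additional starts.
#' @param seed RNG seed used by the multistart jitter.
#' @param pigment_weighting `"inverse_mean"` (residuals weighted by the
#'   reciprocal of each pigment's mean concentration, so abundant pigments
#'   do not dominate the fit) or `"none"`.
#' @return List of class `chemtax_config`.
#' @export
chemtax_config <- function(ratio_limit_pct = 500, max_iter = 500,
                           tol = 1e-6, n_multistart = 1, perturb_pct = 10,
                           seed = 1L,
                           pigment_weighting = c("inverse_mean", "none")) {
  pigment_weighting <- match.arg(pigment_weighting)
  if (ratio_limit_pct <= 0) stop("ratio_limit_pct must be > 0", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (n_multistart < 1) stop("n_multistart must be >= 1", call. = FALSE)
  structure(list(ratio_limit_pct = ratio_limit_pct, max_iter = max_iter,
                 tol = tol, n_multistart = n_multistart,
                 perturb_pct = perturb_pct, seed = as.integer(seed),
                 pigment_weighting = pigment_weighting),
            class = "chemtax_config")
}

# Build the stations x pigments data matrix S (including derived TChl_a)
# restricted to the pigments of F0.
chemtax_data_matrix <- function(S, F0) {
  pig <- colnames(F0$values)
  if (inherits(S, "pigment_matrix")) {
    tchla <- derive_sums_quiet(S)$TChl_a
    other <- setdiff(pig, "TChl_a")
    missing <- setdiff(other, colnames(S$values))
    if (length(missing))
      stop("pigment(s) required by the ratio matrix absent from data: ",
           paste(missing, collapse = ", "), call. = FALSE)
    X <- cbind(S$values[, other, drop = FALSE], TChl_a = tchla)[, pig]
    rownames(X) <- S$stations$station_id
  } else {
    X <- as.matrix(S)
    colnames(X) <- resolve_pigment(colnames(X))
    missing <- setdiff(pig, colnames(X))
    if (length(missing))
      stop("pigment(s) required by the ratio matrix absent from data: ",
           paste(missing, collapse = ", "), call. = FALSE)
    X <- X[, pig, drop = FALSE]
  }
  if (any(X[, "TChl_a"] <= 0))
    stop("stations with TChl a <= 0 cannot be fit", call. = FALSE)
  X
}

#' Fit a CHEMTAX model
#'
#' Estimates per-station biomass of each phytoplankton group (expressed as
#' TChl a) and a refined ratio matrix, given pigment concentrations and an
#' initial ratio matrix, by minimizing the weighted Frobenius discrepancy
#' `|| W o (S - C F) ||` under the constraints `C >= 0`, structural zeros
#' of F fixed, the TChl a column of F fixed at 1, and every other entry of
#' F confined to its ratio-limit box around F0.
#'
#' The optimizer is an alternating scheme of exact convex subproblems:
#' a non-negative least-squares step for each station's group vector given
#' F, and a box-constrained least-squares step for each pigment column of
#' F given C. Each step cannot increase the objective, so the reported
#' RMSE trace is non-increasing.
#'
#' @param S a [pigment_matrix()] (TChl a is derived from its components)
#'   or a numeric stations x pigments matrix that already contains a
#'   `TChl_a` column.
#' @param F0 a [ratio_matrix()] (initial ratios).
#' @param cfg a [chemtax_config()].
#' @return Object of class `chemtax_result`: `C` (stations x groups, mg
#'   TChl a/m^3), `F_final` (a `ratio_matrix`), `rmse`, `rmse_trace`,
#'   `n_iter`, `converged`, plus the weights used.
#' @export
fit_chemtax <- function(S, F0, cfg = chemtax_config()) {
  stopifnot(inherits(F0, "ratio_matrix"))
  X <- chemtax_data_matrix(S, F0)
  Fv <- F0$values
  pig <- colnames(Fv)
  acc <- setdiff(pig, "TChl_a")
  zero_row <- rowSums(Fv[, acc, drop = FALSE]) == 0
  if (any(zero_row))
    stop("group(s) with all-zero accessory ratios: ",
         paste(rownames(Fv)[zero_row], collapse = ", "), call. = FALSE)
  L <- cfg$ratio_limit_pct / 100
  lo <- pmax(Fv * (1 - L), 0)   # pmax(matrix, scalar) keeps dims this way
  hi <- Fv * (1 + L)
  lo[F0$structural_zero] <- 0
  hi[F0$structural_zero] <- 0
  lo[, "TChl_a"] <- hi[, "TChl_a"] <- 1
  w <- switch(cfg$pigment_weighting,
              inverse_mean = {
                cm <- colMeans(X)
                if (any(cm <= 0)) cm[cm <= 0] <- min(cm[cm > 0])
                1 / cm
              },
              none = rep(1, ncol(X)))
  names(w) <- pig
  n <- nrow(X); G <- nrow(Fv)
  rmse_of <- function(C, Fm) {
    R <- (X - C %*% Fm) * rep(w, each = n)
    sqrt(mean(R^2))
  }
  c_step <- function(Fm) {
    A <- t(Fm) * w                       # pigments x groups, row-weighted
    C <- matrix(0, n, G, dimnames = list(rownames(X), rownames(Fv)))
    for (i in seq_len(n)) C[i, ] <- nnls_ls(A, X[i, ] * w)
    C
  }
  Fm <- Fv
  C <- c_step(Fm)
  trace <- rmse_of(C, Fm)
  # numerical noise floor: an RMSE this far below the data scale means the
  # model is exact and further iterations only churn round-off
  floor_rmse <- 1e-9 * sqrt(mean((X * rep(w, each = n))^2))
  converged <- trace[1] <= floor_rmse
  iter <- 0L
  while (!converged && iter < cfg$max_iter) {
    iter <- iter + 1L
    for (j in acc) {
      Fm[, j] <- bounded_ls(C, X[, j], lo[, j], hi[, j])
    }
    # TChl a column is pinned at 1, so the row renormalization that keeps
    # biomass on the TChl a scale is the identity here.
    C <- c_step(Fm)
    r <- rmse_of(C, Fm)
    trace <- c(trace, r)
    prev <- trace[length(trace) - 1]
    if (r <= floor_rmse ||
        abs(prev - r) / max(prev, .Machine$double.eps) < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(C = C,
                 F_final = ratio_matrix(Fm, F0$structural_zero),
                 rmse = trace[length(trace)], rmse_trace = trace,
                 n_iter = iter, converged = converged, weights = w,
                 config = cfg),
            class = "chemtax_result")
}

#' @export
print.chemtax_result <- function(x, ...) {
  cat("<chemtax_result> ", nrow(x$C), " stations x ", ncol(x$C),
      " groups; rmse ", signif(x$rmse, 4), " after ", x$n_iter,
      " iterations (converged: ", x$converged, ")\n", sep = "")
  invisible(x)
}

#' Multistart CHEMTAX
#'
#' Runs [fit_chemtax()] from `F0` and `n_multistart - 1` multiplicatively
#' jittered copies of it and returns the lowest-RMSE solution; a cheap
#' guard against local minima of the alternating scheme. All runs' RMSE
#' values are returned in `$multistart_rmse`.
#'
#' @inheritParams fit_chemtax
#' @return A `chemtax_result` (the best run).
#' @export
multistart_chemtax <- function(S, F0, cfg = chemtax_config()) {
  best <- fit_chemtax(S, F0, cfg)
  rmses <- best$rmse
  if (cfg$n_multistart > 1) {
    for (k in seq_len(cfg$n_multistart - 1)) {
      Fk <- jitter_ratio_matrix(F0, cfg$perturb_pct, cfg$seed + k)
      fit <- fit_chemtax(S, Fk, cfg)
      rmses <- c(rmses, fit$rmse)
      if (fit$rmse < best$rmse) best <- fit
    }
  }
  best$multistart_rmse <- rmses
  best
}
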