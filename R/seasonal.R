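#' One-way seasonal ANOVA with Tukey HSD
#'
#' Standard one-way analysis of variance of a measured variable across
#' seasons, followed by Tukey honest-significant-difference pairwise
#' comparisons. Unbalanced designs (the usual case for lake campaigns) are
#' handled by the Tukey-Kramer adjustment built into [stats::TukeyHSD()].
#' No correction across variables is applied: each variable is tested on
#' its own, as in conventional seasonal pigment tables.
#'
#' @param values numeric vector, one value per station.
#' @param season factor/character of seasons, same length.
#' @param alpha significance level for flagging Tukey pairs (default 0.05).
#' @return Object of class `seasonal_test`: `F_stat`, `p_value`, and a
#'   `tukey` data.frame (`pair`, `diff`, `p_adj`, `significant`).
#' @export
seasonal_anova <- function(values, season, alpha = 0.05) {
  season <- droplevels(factor(season))
  ok <- is.finite(values)
  values <- values[ok]; season <- droplevels(season[ok])
  tab <- table(season)
  if (length(tab) < 2)
    stop("need at least 2 seasons with data", call. = FALSE)
  if (any(tab < 2))
    stop("season(s) with fewer than 2 observations: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  fit <- stats::aov(values ~ season)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$season
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  structure(list(F_stat = an[["F value"]][1],
                 p_value = an[["Pr(>F)"]][1],
                 df = c(an[["Df"]][1], an[["Df"]][2]),
                 tukey = tukey, alpha = alpha),
            class = "seasonal_test")
}

#' @export
print.seasonal_test <- function(x, ...) {
  cat(sprintf("<seasonal_test> F(%d,%d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F_stat, x$p_value))
  sig <- x$tukey[x$tukey$significant, ]
  if (nrow(sig))
    cat("  Tukey significant:",
        paste(sprintf("%s (p=%.4g)", sig$pair, sig$p_adj), collapse = ", "),
        "\n")
  else cat("  Tukey significant: none\n")
  invisible(x)
}

#' Seasonal ANOVA table across pigments and ancillary variables
#'
#' Applies [seasonal_anova()] to each pigment column (and to metadata
#' variables such as SPM when present), producing one row per variable
#' with the F statistic, p value and the significant Tukey season pairs.
#'
#' @param m a [pigment_matrix()] with a `season` metadata column.
#' @param variables which columns to test; default: all pigment columns
#'   with nonzero variance plus `spm` when available.
#' @param alpha significance level.
#' @return data.frame: `variable`, `F_value`, `p_value`,
#'   `tukey_significant` (comma-separated "pair (p=...)" strings).
#' @export
seasonal_table <- function(m, variables = NULL, alpha = 0.05) {
  stopifnot(inherits(m, "pigment_matrix"))
  if (is.null(m$stations$season))
    stop("matrix has no season metadata", call. = FALSE)
  cols <- list()
  if (is.null(variables)) {
    keep <- apply(m$values, 2, stats::var) > 0
    for (p in colnames(m$values)[keep]) cols[[p]] <- m$values[, p]
    if (!is.null(m$stations$spm)) cols[["SPM"]] <- m$stations$spm
  } else {
    for (v in variables) {
      cols[[v]] <- if (v %in% colnames(m$values)) m$values[, v]
                   else m$stations[[v]]
      if (is.null(cols[[v]])) stop("unknown variable: ", v, call. = FALSE)
    }
  }
  rows <- lapply(names(cols), function(v) {
    st <- seasonal_anova(cols[[v]], m$stations$season, alpha)
    sig <- st$tukey[st$tukey$significant, ]
    data.frame(variable = v, F_value = st$F_stat, p_value = st$p_value,
               tukey_significant = if (nrow(sig))
                 paste(sprintf("%s (p=%.4g)", sig$pair, sig$p_adj),
                       collapse = ", ") else "none")
  })
  do.call(rbind, rows)
}
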