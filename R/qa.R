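#' Log-log regression of accessory pigments on total chlorophyll a
#'
#' Internal-consistency check for HPLC pigment datasets: total accessory
#' pigments (TAcc) co-vary with total chlorophyll a across a well-measured
#' dataset, so ordinary least squares of log10(TAcc) on log10(TChl a)
#' should give a slope near 1 and a high r-squared.
#'
#' @param sums data.frame from [derive_sums()] (needs `TChl_a`, `TAcc`).
#' @return List with `slope`, `intercept`, `r2` (squared Pearson
#'   correlation of the log-transformed variables).
#' @export
aiken_regression <- function(sums) {
  check_positive_sums(sums)
  if (nrow(sums) < 3)
    stop("need at least 3 stations for the consistency regression",
         call. = FALSE)
  x <- log10(sums$TChl_a)
  y <- log10(sums$TAcc)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = unname(stats::cor(x, y)^2))
}

check_positive_sums <- function(sums) {
  bad <- sums$TChl_a <= 0 | sums$TAcc <= 0
  if (any(bad))
    stop("non-positive TChl a or TAcc for station(s): ",
         paste(sums$station_id[bad], collapse = ", "), call. = FALSE)
}

#' Dataset quality verdict (Aiken criteria)
#'
#' Applies the standard three-part internal-consistency rule:
#' (i) log-log regression of TAcc on TChl a has r^2 above `r2_min` and a
#' slope inside `slope_band`; (ii) per station, |TChl a - TAcc| is below
#' `reldiff_max` x TPig (TPig = TChl a + TAcc); (iii) at least
#' `station_frac` of the stations satisfy (ii). All thresholds default to
#' the values conventionally used for bio-optical dataset qualification
#' but are configurable for other datasets.
#'
#' @param sums data.frame from [derive_sums()].
#' @param r2_min minimum r-squared (default 0.9).
#' @param slope_band numeric length-2 acceptable slope range (default
#'   `c(0.7, 1.4)`).
#' @param reldiff_max maximum |TChl a - TAcc| / TPig (default 0.3).
#' @param station_frac minimum fraction of stations passing the
#'   relative-difference rule (default 0.85).
#' @return Object of class `qa_report`: the regression terms, per-station
#'   relative differences and pass flags, `pass_fraction`, and
#'   `dataset_pass`.
#' @export
aiken_verdict <- function(sums, r2_min = 0.9, slope_band = c(0.7, 1.4),
                          reldiff_max = 0.3, station_frac = 0.85) {
  reg <- aiken_regression(sums)
  reldiff <- abs(sums$TChl_a - sums$TAcc) / (sums$TChl_a + sums$TAcc)
  names(reldiff) <- sums$station_id
  station_pass <- reldiff < reldiff_max
  pass_fraction <- mean(station_pass)
  dataset_pass <- (reg$r2 > r2_min) &&
    reg$slope >= slope_band[1] && reg$slope <= slope_band[2] &&
    pass_fraction >= station_frac
  structure(list(slope = reg$slope, intercept = reg$intercept, r2 = reg$r2,
                 per_station_reldiff = reldiff,
                 station_pass = station_pass,
                 pass_fraction = pass_fraction,
                 dataset_pass = dataset_pass,
                 thresholds = list(r2_min = r2_min, slope_band = slope_band,
                                   reldiff_max = reldiff_max,
                                   station_frac = station_frac)),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report>\n")
  cat(sprintf("  log10(TAcc) ~ log10(TChl a): slope %.3f, r2 %.3f\n",
              x$slope, x$r2))
  cat(sprintf("  stations passing |TChl a - TAcc| < %.2f TPig: %.0f%%\n",
              x$thresholds$reldiff_max, 100 * x$pass_fraction))
  cat("  dataset pass:", x$dataset_pass, "\n")
  invisible(x)
}

#' Serialize a QA report to JSON
#' @param report a `qa_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qa_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
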