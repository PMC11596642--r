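#' Station x pigment concentration matrix
#'
#' The central data container: per-station pigment concentrations with a
#' below-detection mask and station metadata. Below-LOD cells are stored as
#' exact zeros with `below_lod = TRUE`; nothing is imputed, matching common
#' HPLC reporting practice.
#'
#' @param values numeric matrix, stations x pigments, non-negative
#'   concentrations (mg/m^3 for lake samples; ng per injection for culture
#'   profiles). Column names must resolve to panel pigments.
#' @param stations data.frame of station metadata with at least
#'   `station_id`; recognised columns: `campaign` (integer 1-5), `season`
#'   (spring/summer/fall), `lat`, `lon`, `depth_m`, `temp_C`, `spm`.
#' @param panel a [pigment_panel()]; defaults to [default_panel()].
#' @param below_lod logical matrix, same shape as `values`; if `NULL`,
#'   derived as `values < LOD`.
#' @param units concentration units recorded as file-level metadata.
#' @return Object of class `pigment_matrix`.
#' @export
pigment_matrix <- function(values, stations, panel = default_panel(),
                           below_lod = NULL, units = "mg/m3") {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("`values` must have pigment column names", call. = FALSE)
  colnames(values) <- resolve_pigment(colnames(values))
  extra <- setdiff(colnames(values), panel$pigments)
  if (length(extra))
    stop("pigments not in panel: ", paste(extra, collapse = ", "),
         call. = FALSE)
  stations <- as.data.frame(stations)
  if (is.null(stations$station_id))
    stop("`stations` must contain a station_id column", call. = FALSE)
  stations$station_id <- as.character(stations$station_id)
  dup <- stations$station_id[duplicated(stations$station_id)]
  if (length(dup))
    stop("duplicated station_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (nrow(stations) != nrow(values))
    stop("stations and values disagree on the number of stations",
         call. = FALSE)
  if (!is.null(stations$season)) {
    stations$season <- validate_season(stations$season)
  } else if (!is.null(stations$campaign)) {
    stations$season <- campaign_season(stations$campaign)
  }
  if (!is.null(stations$depth_m) && any(stations$depth_m <= 0, na.rm = TRUE))
    stop("depth_m must be > 0", call. = FALSE)
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative concentration at station '",
         stations$station_id[neg[1, 1]], "', pigment '",
         colnames(values)[neg[1, 2]], "'", call. = FALSE)
  lod <- panel$lod[colnames(values)]
  if (is.null(below_lod)) {
    below_lod <- sweep(values, 2, lod, `<`)
  } else {
    below_lod <- as.matrix(below_lod)
    stopifnot(identical(dim(below_lod), dim(values)))
  }
  values[below_lod] <- 0
  rownames(values) <- rownames(below_lod) <- stations$station_id
  colnames(below_lod) <- colnames(values)
  structure(list(values = values, below_lod = below_lod,
                 stations = stations, panel = panel, units = units),
            class = "pigment_matrix")
}

validate_season <- function(x) {
  x <- tolower(as.character(x))
  x[x %in% c("autumn", "early autumn")] <- "fall"
  bad <- setdiff(unique(x), c("spring", "summer", "fall"))
  if (length(bad))
    stop("unknown season value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  factor(x, levels = c("spring", "summer", "fall"))
}

#' Campaign to season mapping
#'
#' The five monthly survey campaigns map onto three seasons:
#' campaigns 1-2 spring, 3-4 summer, 5 fall.
#'
#' @param campaign integer vector in 1..5.
#' @return Factor with levels spring/summer/fall.
#' @export
campaign_season <- function(campaign) {
  campaign <- as.integer(campaign)
  if (any(is.na(campaign)) || any(campaign < 1L | campaign > 5L))
    stop("campaign must be an integer in 1..5", call. = FALSE)
  factor(c("spring", "spring", "summer", "summer", "fall")[campaign],
         levels = c("spring", "summer", "fall"))
}

#' @export
print.pigment_matrix <- function(x, ...) {
  cat("<pigment_matrix> ", nrow(x$values), " stations x ",
      ncol(x$values), " pigments [", x$units, "]\n", sep = "")
  cat("  below-LOD cells: ", sum(x$below_lod), "\n", sep = "")
  invisible(x)
}

#' Number of stations / pigments
#' @param m a `pigment_matrix`.
#' @return Integer.
#' @export
n_stations <- function(m) nrow(m$values)

metadata_cols <- c("station_id", "campaign", "season", "lat", "lon",
                   "depth_m", "temp_C", "spm")

#' Read a station x pigment table
#'
#' Reads a CSV/TSV with one station per row: metadata columns first
#' (`station_id`, optionally `campaign`, `season`, `lat`, `lon`, `depth_m`,
#' `temp_C`, `spm`), then pigment columns. Below-detection cells may be
#' written as the sentinel `"<LOD"` or left blank; they are stored as 0
#' with the mask set. Values below the panel LOD are likewise masked.
#' Unknown columns are reported with a warning and kept in `$extra`,
#' never silently dropped.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.tsv` means tab, otherwise comma).
#' @param panel a [pigment_panel()].
#' @param units unit metadata recorded on the result.
#' @return A [pigment_matrix()] (with an `$extra` data.frame when unknown
#'   columns were present).
#' @export
read_pigment_table <- function(path, panel = default_panel(),
                               units = "mg/m3") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (!"station_id" %in% names(raw))
    stop("input table must have a station_id column", call. = FALSE)
  resolved <- resolve_pigment(names(raw), error = FALSE)
  is_meta <- names(raw) %in% metadata_cols
  is_pig <- !is.na(resolved) & !is_meta
  unknown <- names(raw)[is.na(resolved) & !is_meta]
  if (length(unknown))
    warning("unknown columns kept in $extra: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  pig_names <- resolved[is_pig]
  if (!"MVchl_a" %in% pig_names)
    stop("required TChl a component MVchl_a missing from table",
         call. = FALSE)
  sentinel <- matrix(FALSE, nrow(raw), sum(is_pig))
  vals <- matrix(0, nrow(raw), sum(is_pig),
                 dimnames = list(NULL, pig_names))
  for (j in seq_along(which(is_pig))) {
    col <- trimws(raw[[which(is_pig)[j]]])
    is_lod <- col %in% c("<LOD", "<lod", "") | is.na(col)
    num <- suppressWarnings(as.numeric(col))
    if (any(!is_lod & is.na(num)))
      stop("non-numeric concentration for pigment '", pig_names[j],
           "', station '", raw$station_id[which(!is_lod & is.na(num))[1]],
           "'", call. = FALSE)
    num[is_lod] <- 0
    if (any(num < 0))
      stop("negative concentration at station '",
           raw$station_id[which(num < 0)[1]], "', pigment '",
           pig_names[j], "'", call. = FALSE)
    vals[, j] <- num
    sentinel[, j] <- is_lod
  }
  meta <- raw[intersect(metadata_cols, names(raw))]
  for (v in intersect(c("campaign"), names(meta)))
    meta[[v]] <- as.integer(meta[[v]])
  for (v in intersect(c("lat", "lon", "depth_m", "temp_C", "spm"),
                      names(meta)))
    meta[[v]] <- as.numeric(meta[[v]])
  lod_mask <- sentinel | sweep(vals, 2, panel$lod[pig_names], `<`)
  m <- pigment_matrix(vals, meta, panel = panel, below_lod = lod_mask,
                      units = units)
  if (length(unknown)) m$extra <- raw[unknown]
  m
}

#' Write a station x pigment table
#'
#' Inverse of [read_pigment_table()]: masked cells are written as the
#' `"<LOD"` sentinel so the round trip preserves both values and mask.
#'
#' @param m a `pigment_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pigment_table <- function(m, path) {
  vals <- format(m$values, digits = 12, trim = TRUE, scientific = FALSE)
  vals[m$below_lod] <- "<LOD"
  out <- cbind(m$stations[intersect(metadata_cols, names(m$stations))],
               as.data.frame(vals, stringsAsFactors = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
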