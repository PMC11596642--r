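#' Canonical pigment identifiers
#'
#' The fixed vocabulary of HPLC phytoplankton pigments handled by the
#' package, as short canonical ids. `TChl_c` denotes chlorophyll c1+c2
#' (chlorophyll c3 has its own id, `Chlc3`); the three chlorophyll-a
#' components (`MVchl_a`, `DVchl_a`, `Chlide_a`) are stored separately and
#' summed to total chlorophyll a (TChl a) by [derive_sums()].
#'
#' @return Character vector of canonical pigment ids.
#' @export
canonical_pigments <- function() {
  c("Fuco", "Peri", "Zea", "Echin", "Allo", "Diad", "Diato",
    "TChl_b", "TChl_c", "Chlc3", "Chlide_a", "MVchl_a", "DVchl_a",
    "Caro_a", "Caro_b", "Hex", "But", "Neo", "Viola", "Pras", "Lut",
    "Myxo", "Gyro", "Anthe", "Pheo", "Phy")
}

#' Alias table for pigment column names
#'
#' HPLC exports vary in their pigment naming; this maps common variants to
#' canonical ids. Matching is case-insensitive after stripping non
#' alphanumeric characters.
#'
#' @return Named character vector, `alias -> canonical id`.
#' @export
pigment_aliases <- function() {
  c(
    "fucoxanthin"        = "Fuco",
    "peridinin"          = "Peri",
    "perid"              = "Peri",
    "zeaxanthin"         = "Zea",
    "echinenone"         = "Echin",
    "alloxanthin"        = "Allo",
    "diadinoxanthin"     = "Diad",
    "diadino"            = "Diad",
    "diatoxanthin"       = "Diato",
    "diat"               = "Diato",
    "tchlb"              = "TChl_b",
    "chlb"               = "TChl_b",
    "tchlc"              = "TChl_c",
    "chlc1c2"            = "TChl_c",
    "chlc1"              = "TChl_c",
    "chlc3"              = "Chlc3",
    "chlidea"            = "Chlide_a",
    "chlorophyllidea"    = "Chlide_a",
    "mvchla"             = "MVchl_a",
    "chla"               = "MVchl_a",
    "dvchla"             = "DVchl_a",
    "acaro"              = "Caro_a",
    "alphacarotene"      = "Caro_a",
    "abcarotene"         = "Caro_a",
    "bcaro"              = "Caro_b",
    "betacarotene"       = "Caro_b",
    "bbcarotene"         = "Caro_b",
    "bbcaro"             = "Caro_b",
    "hexanoyloxyfucoxanthin" = "Hex",
    "19hex"              = "Hex",
    "butanoyloxyfucoxanthin" = "But",
    "19but"              = "But",
    "neoxanthin"         = "Neo",
    "neo"                = "Neo",
    "violaxanthin"       = "Viola",
    "viol"               = "Viola",
    "prasinoxanthin"     = "Pras",
    "lutein"             = "Lut",
    "myxoxanthophyll"    = "Myxo",
    "gyroxanthin"        = "Gyro",
    "antheraxanthin"     = "Anthe",
    "pheophorbidea"      = "Pheo",
    "pheophytina"        = "Phy",
    "phytina"            = "Phy"
  )
}

squash_name <- function(x) tolower(gsub("[^A-Za-z0-9]", "", x))

#' Resolve pigment names to canonical ids
#'
#' @param x character vector of pigment names (canonical ids or aliases).
#' @param error unknown names raise an error (default) or return `NA`.
#' @return Character vector of canonical ids.
#' @export
resolve_pigment <- function(x, error = TRUE) {
  canon <- canonical_pigments()
  ali <- pigment_aliases()
  out <- character(length(x))
  squashed_canon <- squash_name(canon)
  for (i in seq_along(x)) {
    if (x[i] %in% canon || identical(x[i], "TChl_a")) {
      out[i] <- x[i]
      next
    }
    s <- squash_name(x[i])
    if (s == "tchla") { out[i] <- "TChl_a"; next }
    hit <- match(s, squashed_canon)
    if (!is.na(hit)) { out[i] <- canon[hit]; next }
    hit <- match(s, names(ali))
    if (!is.na(hit)) { out[i] <- unname(ali[hit]); next }
    if (error) stop("unknown pigment name: '", x[i], "'", call. = FALSE)
    out[i] <- NA_character_
  }
  out
}

#' Construct a pigment panel
#'
#' A panel is the ordered set of pigments a dataset is quantified for,
#' together with per-pigment limits of detection (LOD, mg/m^3; 0 means the
#' pigment is always quantified when present).
#'
#' @param pigments character vector of canonical ids (or aliases).
#' @param lod named numeric vector of detection limits; pigments not named
#'   get `default_lod`.
#' @param default_lod detection limit applied where `lod` is silent.
#' @return Object of class `pigment_panel` with elements `pigments`, `lod`.
#' @export
pigment_panel <- function(pigments = canonical_pigments(), lod = NULL,
                          default_lod = 0) {
  pigments <- resolve_pigment(pigments)
  if (anyDuplicated(pigments))
    stop("duplicated pigment ids in panel: ",
         paste(unique(pigments[duplicated(pigments)]), collapse = ", "),
         call. = FALSE)
  full <- rep(default_lod, length(pigments))
  names(full) <- pigments
  if (!is.null(lod)) {
    nm <- resolve_pigment(names(lod))
    bad <- setdiff(nm, pigments)
    if (length(bad))
      stop("LOD given for pigments not in panel: ",
           paste(bad, collapse = ", "), call. = FALSE)
    full[nm] <- as.numeric(lod)
  }
  if (any(full < 0)) stop("LOD values must be >= 0", call. = FALSE)
  structure(list(pigments = pigments, lod = full), class = "pigment_panel")
}

#' Default panel for lake survey data
#'
#' All canonical pigments with detection limits calibrated so that the
#' synthetic generator censors pigments at roughly the rates observed in
#' the Lake Maggiore survey table (sporadic peridinin, diatoxanthin and
#' echinenone non-detections; hexanoyl- and butanoyloxyfucoxanthin mostly
#' below detection).
#'
#' @return A [pigment_panel()].
#' @export
default_panel <- function() {
  pigment_panel(
    lod = c(Peri = 0.015, Diato = 0.020, Echin = 0.009,
            Hex = 0.003, But = 0.003, Pras = 0.003, DVchl_a = 0.005,
            Myxo = 0.003, Gyro = 0.003, Anthe = 0.003),
    default_lod = 0.001
  )
}

#' @export
print.pigment_panel <- function(x, ...) {
  cat("<pigment_panel> ", length(x$pigments), " pigments\n", sep = "")
  cat("  ", paste(x$pigments, collapse = " "), "\n", sep = "")
  invisible(x)
}
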