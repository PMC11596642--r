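#' Derived pigment sums
#'
#' Computes the standard aggregate pigment pools per station:
#' \describe{
#'   \item{TChl_a}{MVchl a + DVchl a + Chlide a (total chlorophyll a)}
#'   \item{TChl_b}{total chlorophyll b}
#'   \item{TChl_c}{chlorophyll c1+c2 + chlorophyll c3}
#'   \item{Caro}{alpha- + beta-carotene}
#'   \item{PPC}{photoprotective carotenoids: Allo + Diad + Diato + Zea + Caro}
#'   \item{PSC}{photosynthetic carotenoids: But + Fuco + Hex + Peri}
#'   \item{TAcc}{total accessory pigments: PPC + PSC + TChl_b + TChl_c}
#'   \item{TPig}{TChl_a + TAcc}
#' }
#' Component pigments absent from the matrix contribute 0, with a warning
#' (some lakes lack e.g. butanoyloxyfucoxanthin entirely).
#'
#' @param m a [pigment_matrix()].
#' @return data.frame with one row per station: `station_id`, `TChl_a`,
#'   `TChl_b`, `TChl_c`, `Caro`, `PPC`, `PSC`, `TAcc`, `TPig`.
#' @export
derive_sums <- function(m) {
  stopifnot(inherits(m, "pigment_matrix"))
  have <- colnames(m$values)
  col0 <- function(id) {
    if (id %in% have) m$values[, id] else rep(0, nrow(m$values))
  }
  need <- c("MVchl_a", "DVchl_a", "Chlide_a", "TChl_b", "TChl_c", "Chlc3",
            "Caro_a", "Caro_b", "Allo", "Diad", "Diato", "Zea",
            "But", "Fuco", "Hex", "Peri")
  missing <- setdiff(need, have)
  if (length(missing))
    warning("pigments absent from matrix treated as 0: ",
            paste(missing, collapse = ", "), call. = FALSE)
  TChl_a <- col0("MVchl_a") + col0("DVchl_a") + col0("Chlide_a")
  TChl_b <- col0("TChl_b")
  TChl_c <- col0("TChl_c") + col0("Chlc3")
  Caro <- col0("Caro_a") + col0("Caro_b")
  PPC <- col0("Allo") + col0("Diad") + col0("Diato") + col0("Zea") + Caro
  PSC <- col0("But") + col0("Fuco") + col0("Hex") + col0("Peri")
  TAcc <- PPC + PSC + TChl_b + TChl_c
  data.frame(station_id = m$stations$station_id,
             TChl_a = TChl_a, TChl_b = TChl_b, TChl_c = TChl_c,
             Caro = Caro, PPC = PPC, PSC = PSC, TAcc = TAcc,
             TPig = TChl_a + TAcc, row.names = NULL)
}

#' Pigment ratios to total chlorophyll a
#'
#' Normalizes each pigment column by the station's total chlorophyll a,
#' the input for clustering, ordination and network construction.
#' Below-LOD entries stay 0.
#'
#' @param m a [pigment_matrix()].
#' @param pigments pigment ids to include; default all columns of `m`
#'   except the chlorophyll-a components themselves.
#' @return Numeric matrix, stations x pigments, dimensionless.
#' @export
ratios_to_tchla <- function(m, pigments = NULL) {
  stopifnot(inherits(m, "pigment_matrix"))
  tchla <- derive_sums_quiet(m)$TChl_a
  if (any(tchla <= 0))
    stop("TChl a is zero for station(s): ",
         paste(m$stations$station_id[tchla <= 0], collapse = ", "),
         call. = FALSE)
  if (is.null(pigments))
    pigments <- setdiff(colnames(m$values),
                        c("MVchl_a", "DVchl_a"))
  pigments <- resolve_pigment(pigments)
  bad <- setdiff(pigments, colnames(m$values))
  if (length(bad))
    stop("pigments not present in matrix: ", paste(bad, collapse = ", "),
         call. = FALSE)
  r <- m$values[, pigments, drop = FALSE] / tchla
  rownames(r) <- m$stations$station_id
  r
}

derive_sums_quiet <- function(m) suppressWarnings(derive_sums(m))

#' Ratio of one pigment to another
#'
#' Station-wise concentration ratio, e.g. zeaxanthin to beta-carotene in a
#' cyanobacterial culture profile. `denominator = "TChl_a"` uses the
#' derived total chlorophyll a.
#'
#' @param m a [pigment_matrix()].
#' @param numerator,denominator pigment ids (or `"TChl_a"`).
#' @return Named numeric vector (one value per station).
#' @export
pigment_ratio <- function(m, numerator, denominator = "TChl_a") {
  stopifnot(inherits(m, "pigment_matrix"))
  getcol <- function(id) {
    id <- resolve_pigment(id)
    if (identical(id, "TChl_a")) return(derive_sums_quiet(m)$TChl_a)
    if (!id %in% colnames(m$values))
      stop("pigment not present: ", id, call. = FALSE)
    m$values[, id]
  }
  num <- getcol(numerator)
  den <- getcol(denominator)
  if (any(den <= 0))
    stop("zero denominator for station(s): ",
         paste(m$stations$station_id[den <= 0], collapse = ", "),
         call. = FALSE)
  stats::setNames(num / den, m$stations$station_id)
}
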