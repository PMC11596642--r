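#' Phytoplankton size-fraction proportion factors
#'
#' Diagnostic-pigment proxies of the community size structure: the
#' microplankton factor (mPF) from fucoxanthin + peridinin, the
#' nanoplankton factor (nPF) from 19'-hexanoyloxyfucoxanthin +
#' 19'-butanoyloxyfucoxanthin + alloxanthin, and the picoplankton factor
#' (pPF) from zeaxanthin + total chlorophyll b. Each factor is the
#' class sum divided by the total diagnostic pigment pool, so the three
#' factors add to 1 wherever the pool is nonzero.
#'
#' The default weights are all 1 (plain concentration sums). The
#' classical weighted diagnostic-pigment coefficients are available as
#' `weights = "dp_weighted"` (fucoxanthin 1.41, peridinin 1.41,
#' hexanoyloxyfucoxanthin 1.27, butanoyloxyfucoxanthin 0.35, alloxanthin
#' 0.60, zeaxanthin 0.86, TChl b 1.01).
#'
#' @param m a [pigment_matrix()]; diagnostic pigments absent from the
#'   matrix contribute 0.
#' @param weights named numeric map pigment -> coefficient, or the preset
#'   name `"dp_weighted"`.
#' @return data.frame per station: `mPF`, `nPF`, `pPF`, `dp_total`
#'   (mg/m^3) and `undefined` (TRUE where the pool is 0 and the fractions
#'   are therefore NA).
#' @export
proportion_factors <- function(m, weights = NULL) {
  stopifnot(inherits(m, "pigment_matrix"))
  dp <- c("Fuco", "Peri", "Hex", "But", "Allo", "Zea", "TChl_b")
  if (identical(weights, "dp_weighted")) {
    weights <- c(Fuco = 1.41, Peri = 1.41, Hex = 1.27, But = 0.35,
                 Allo = 0.60, Zea = 0.86, TChl_b = 1.01)
  }
  w <- stats::setNames(rep(1, length(dp)), dp)
  if (!is.null(weights)) {
    nm <- resolve_pigment(names(weights))
    bad <- setdiff(nm, dp)
    if (length(bad))
      stop("weights given for non-diagnostic pigments: ",
           paste(bad, collapse = ", "), call. = FALSE)
    w[nm] <- as.numeric(weights)
  }
  col0 <- function(id) {
    if (id %in% colnames(m$values)) m$values[, id] else rep(0, nrow(m$values))
  }
  micro <- w["Fuco"] * col0("Fuco") + w["Peri"] * col0("Peri")
  nano <- w["Hex"] * col0("Hex") + w["But"] * col0("But") +
    w["Allo"] * col0("Allo")
  pico <- w["Zea"] * col0("Zea") + w["TChl_b"] * col0("TChl_b")
  total <- micro + nano + pico
  undefined <- total == 0
  if (any(undefined))
    warning("diagnostic pigment pool is 0 for station(s): ",
            paste(m$stations$station_id[undefined], collapse = ", "),
            call. = FALSE)
  safe <- ifelse(undefined, NA_real_, total)
  data.frame(station_id = m$stations$station_id,
             mPF = micro / safe, nPF = nano / safe, pPF = pico / safe,
             dp_total = total, undefined = undefined, row.names = NULL)
}

#' Ternary coordinates for size-fraction plotting
#'
#' Converts (mPF, nPF, pPF) triples into 2-D ternary plot coordinates
#' (equilateral triangle with the micro vertex on top).
#'
#' @param pf data.frame from [proportion_factors()].
#' @return data.frame `station_id`, `x`, `y`.
#' @export
ternary_coordinates <- function(pf) {
  data.frame(station_id = pf$station_id,
             x = pf$pPF + pf$mPF / 2,
             y = pf$mPF * sqrt(3) / 2)
}
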