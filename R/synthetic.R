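#' Lognormal parameters from arithmetic mean and CV
#'
#' Moment matching: returns the log-scale parameters (mu, sigma) of the
#' lognormal distribution whose arithmetic mean and coefficient of
#' variation equal the given values: sigma^2 = log(1 + cv^2),
#' mu = log(mean) - sigma^2 / 2.
#'
#' @param mean arithmetic mean (> 0).
#' @param cv coefficient of variation as a fraction (> 0), e.g. 0.547 for
#'   54.7%.
#' @return List with `mu` and `sigma`.
#' @export
lognormal_from_mean_cv <- function(mean, cv) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (!is.finite(cv) || cv <= 0) stop("cv must be > 0", call. = FALSE)
  sigma2 <- log(1 + cv^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

rlnorm_cv <- function(n, mean = 1, cv = 1) {
  p <- lognormal_from_mean_cv(mean, cv)
  stats::rlnorm(n, p$mu, p$sigma)
}

#' Generator configuration
#'
#' Describes the synthetic lake survey the generator draws: 27 stations
#' over 5 campaigns (2 spring, 2 summer, 1 fall), per-group lognormal
#' biomasses whose sum reproduces the survey's total chlorophyll a
#' marginal (mean 2.933 mg/m^3, CV ~55%), pigments derived from the
#' biomasses through a known ratio matrix `F_true`, accessory pigments
#' outside `F_true` drawn as bloom-coupled lognormals with survey-table
#' marginals, multiplicative measurement noise, and LOD censoring.
#'
#' The variance budget is decomposed into (i) seasonal multipliers
#' (spring > summer > fall, normalized to station-weighted mean 1), (ii)
#' a station "bloom" factor shared by all groups, (iii) a size-class
#' driver shared by the groups of each cell-size fraction (micro:
#' diatoms + dinoflagellates; nano: chrysophytes + cryptophytes; pico:
#' cyanobacteria + chlorophytes) which is what gives pigment ratios their
#' three covarying blocks, and (iv) per-group residual variation. See the
#' methods vignette for the derivation of the default CVs.
#'
#' @param n_stations total stations (default 27; campaign sizes are
#'   scaled when a different total is requested).
#' @param F_true ratio matrix used as ground truth (default [lake_f1()]).
#' @param group_mean named per-group mean biomass as TChl a (mg/m^3);
#'   must cover the groups of `F_true`.
#' @param season_multipliers named (spring, summer, fall) multipliers,
#'   internally normalized to station-weighted mean 1.
#' @param cv_station,cv_size,cv_group CVs of the bloom factor, size-class
#'   driver and per-group residual.
#' @param noise_cv multiplicative lognormal measurement noise per cell
#'   (default 0.10; 0 disables).
#' @param censor apply LOD censoring (default TRUE).
#' @param panel pigment panel supplying the LODs.
#' @param chlide_frac_range chlorophyllide a (diatom senescence marker)
#'   fraction of diatom biomass, drawn uniformly per station.
#' @param extra_pigments data.frame (`pigment`, `mean`, `cv`) of
#'   accessory pigments not produced by `F_true` groups.
#' @param seed integer RNG seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_stations = 27L,
                             F_true = lake_f1(),
                             group_mean = c(Diatoms = 0.70,
                                            Chlorophyceae = 0.30,
                                            Cyanophytes = 0.46,
                                            Chrysophytes = 0.62,
                                            Dinophyceae = 0.203,
                                            Cryptophytes = 0.65),
                             season_multipliers = c(spring = 1.6,
                                                    summer = 0.92,
                                                    fall = 0.48),
                             cv_station = 0.08, cv_size = 0.55,
                             cv_group = 0.06, noise_cv = 0.10,
                             censor = TRUE, panel = default_panel(),
                             chlide_frac_range = c(0.03, 0.06),
                             extra_pigments = default_extra_pigments(),
                             seed = 1L) {
  stopifnot(inherits(F_true, "ratio_matrix"))
  groups <- rownames(F_true$values)
  missing <- setdiff(groups, names(group_mean))
  if (length(missing))
    stop("group_mean missing group(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(group_mean <= 0)) stop("group means must be > 0", call. = FALSE)
  if (any(season_multipliers <= 0))
    stop("season multipliers must be > 0", call. = FALSE)
  if (any(c(cv_station, cv_size, cv_group) <= 0))
    stop("CVs must be > 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(list(n_stations = as.integer(n_stations), F_true = F_true,
                 group_mean = group_mean[groups],
                 season_multipliers = season_multipliers,
                 cv_station = cv_station, cv_size = cv_size,
                 cv_group = cv_group, noise_cv = noise_cv,
                 censor = censor, panel = panel,
                 chlide_frac_range = chlide_frac_range,
                 extra_pigments = extra_pigments,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Default marginals for pigments outside the ratio matrix
#'
#' Accessory pigments the fitted ratio matrix omits, with
#' lake-survey-scale means (mg/m^3) and CVs. Most are drawn as
#' bloom-coupled lognormals (`driver = "bloom"`); diadinoxanthin and
#' diatoxanthin are the diatom xanthophyll-cycle pigments, so they track
#' diatom biomass (`driver = "diatom"`) — their CV column is then the
#' residual variation on top of the biomass signal and the realized
#' marginal CV is somewhat larger than for a free lognormal.
#'
#' @return data.frame with columns `pigment`, `mean`, `cv`, `driver`.
#' @export
default_extra_pigments <- function() {
  data.frame(
    pigment = c("Caro_b", "Caro_a", "Diato", "Diad", "Chlc3", "Hex",
                "But", "Pras", "Pheo", "Phy"),
    mean = c(0.166, 0.029, 0.0405, 0.040, 0.180, 0.0015,
             0.0010, 0.004, 0.010, 0.010),
    cv = c(0.56, 0.56, 0.15, 0.15, 0.55, 0.80, 0.80, 0.60, 0.60, 0.60),
    driver = c("bloom", "bloom", "diatom", "diatom", "bloom", "bloom",
               "bloom", "bloom", "bloom", "bloom"),
    stringsAsFactors = FALSE)
}

default_campaign_sizes <- function(n_stations) {
  base <- c(m1 = 6L, m2 = 5L, m3 = 5L, m4 = 6L, m5 = 5L)
  if (n_stations == 27L) return(base)
  sz <- pmax(1L, as.integer(round(base / 27 * n_stations)))
  while (sum(sz) > n_stations) sz[which.max(sz)] <- sz[which.max(sz)] - 1L
  while (sum(sz) < n_stations) sz[which.min(sz)] <- sz[which.min(sz)] + 1L
  sz
}

size_class_of <- function(groups) {
  map <- c(Diatoms = "micro", Dinophyceae = "micro",
           Chrysophytes = "nano", Cryptophytes = "nano",
           Cyanophytes = "pico", Chlorophyceae = "pico")
  cl <- map[groups]
  cl[is.na(cl)] <- "nano"  # unknown custom groups default to nano
  cl
}

#' Generate a synthetic pigment dataset with hidden ground truth
#'
#' Draws per-station group biomasses `C_true`, forms the noiseless
#' pigment table `S = C_true F_true`, fills in the remaining panel
#' pigments, applies multiplicative measurement noise and LOD censoring,
#' and attaches plausible station metadata (subalpine-lake coordinate
#' box, depths 60-383 m, surface temperatures 15.5-25.6 degC by season,
#' lognormal suspended particulate matter). The return value carries the
#' ground truth needed for parameter-recovery tests.
#'
#' @param cfg a [generator_config()].
#' @return List of class `synthetic_pigment_data`:
#'   `matrix` (a [pigment_matrix()]), and `truth` with `C_true`
#'   (stations x groups), `F_true`, `S_clean` (noiseless station x
#'   pigment table for the `F_true` pigments), `censored` (cell index
#'   data.frame), `seed`.
#' @export
generate_pigment_data <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  sizes <- default_campaign_sizes(cfg$n_stations)
  campaign <- rep(seq_along(sizes), sizes)
  station_id <- unlist(lapply(seq_along(sizes), function(ci)
    paste0("m", ci, "s", seq_len(sizes[ci]))))
  season <- campaign_season(campaign)
  n <- length(station_id)
  groups <- rownames(cfg$F_true$values)
  G <- length(groups)

  mult <- cfg$season_multipliers[as.character(season)]
  mult <- mult / mean(mult)               # station-weighted mean 1
  B0 <- rlnorm_cv(n, 1, cfg$cv_station)
  cls <- size_class_of(groups)
  Bsize <- sapply(unique(cls), function(cl) rlnorm_cv(n, 1, cfg$cv_size))
  eps <- matrix(rlnorm_cv(n * G, 1, cfg$cv_group), n, G)
  C_true <- sweep(eps, 2, cfg$group_mean, `*`) *
    (mult * B0) * Bsize[, cls[groups], drop = FALSE]
  dimnames(C_true) <- list(station_id, groups)

  S_clean <- C_true %*% cfg$F_true$values
  tchla <- S_clean[, "TChl_a"]

  pigs <- cfg$panel$pigments
  vals <- matrix(0, n, length(pigs), dimnames = list(station_id, pigs))
  fpig <- setdiff(colnames(cfg$F_true$values), "TChl_a")
  vals[, intersect(fpig, pigs)] <- S_clean[, intersect(fpig, pigs)]
  # chlorophyllide a marks diatom senescence, so it scales with diatom
  # biomass (falling back to total biomass for custom group sets); MVchl a
  # takes up the remainder so the chlorophyll a components sum to TChl a
  phi <- stats::runif(n, cfg$chlide_frac_range[1], cfg$chlide_frac_range[2])
  chlide_base <- if ("Diatoms" %in% groups) C_true[, "Diatoms"] else tchla
  vals[, "Chlide_a"] <- phi * chlide_base
  vals[, "MVchl_a"] <- tchla - vals[, "Chlide_a"]

  # pigments outside F_true: either bloom-coupled lognormals (residual CV
  # backed out so the marginal CV approximates the configured value) or
  # diatom-biomass-driven (xanthophyll-cycle pigments), where the cv
  # column is residual variation on top of the biomass signal
  vb <- stats::var(mult) / mean(mult)^2
  shared <- (1 + cfg$cv_station^2) * (1 + vb)
  driver <- if (!is.null(cfg$extra_pigments$driver))
    cfg$extra_pigments$driver else rep("bloom", nrow(cfg$extra_pigments))
  for (k in seq_len(nrow(cfg$extra_pigments))) {
    p <- cfg$extra_pigments$pigment[k]
    if (!p %in% pigs || p %in% fpig) next
    tgt <- cfg$extra_pigments$cv[k]
    if (identical(driver[k], "diatom") && "Diatoms" %in% groups) {
      vals[, p] <- cfg$extra_pigments$mean[k] *
        (C_true[, "Diatoms"] / cfg$group_mean["Diatoms"]) *
        rlnorm_cv(n, 1, max(tgt, 0.05))
    } else {
      resid_cv <- sqrt(max(0.05^2, (1 + tgt^2) / shared - 1))
      vals[, p] <- cfg$extra_pigments$mean[k] * mult * B0 *
        rlnorm_cv(n, 1, resid_cv)
    }
  }

  if (cfg$noise_cv > 0) {
    noise <- matrix(rlnorm_cv(n * length(pigs), 1, cfg$noise_cv),
                    n, length(pigs))
    vals <- vals * noise
  }

  stations <- data.frame(
    station_id = station_id, campaign = campaign, season = season,
    lat = stats::runif(n, 45.482, 45.559),
    lon = stats::runif(n, 8.305, 8.347),
    depth_m = stats::runif(n, 60, 383),
    temp_C = ifelse(season == "spring", stats::runif(n, 15.5, 20.5),
                    ifelse(season == "summer", stats::runif(n, 22, 25.6),
                           stats::runif(n, 18, 21))),
    spm = rlnorm_cv(n, 0.0119, 0.389))

  lod <- cfg$panel$lod[pigs]
  mask <- if (cfg$censor) sweep(vals, 2, lod, `<`)
          else matrix(FALSE, n, length(pigs), dimnames = dimnames(vals))
  m <- pigment_matrix(vals, stations, panel = cfg$panel,
                      below_lod = mask, units = "mg/m3")
  cens <- which(mask, arr.ind = TRUE)
  censored <- data.frame(station_id = station_id[cens[, 1]],
                         pigment = pigs[cens[, 2]], row.names = NULL)
  structure(list(matrix = m,
                 truth = list(C_true = C_true, F_true = cfg$F_true,
                              S_clean = S_clean, censored = censored,
                              seed = cfg$seed),
                 config = cfg),
            class = "synthetic_pigment_data")
}

#' @export
print.synthetic_pigment_data <- function(x, ...) {
  cat("<synthetic_pigment_data> seed ", x$truth$seed, "\n", sep = "")
  print(x$matrix)
  invisible(x)
}

#' Pure-culture pigment profiles
#'
#' The two cyanobacterial reference culture profiles (per-injection
#' amounts, ng/inj): *Microcystis aeruginosa* and *Anabaena* sp. PCC 7120,
#' with their myxoxanthophyll, zeaxanthin, gyroxanthin, echinenone,
#' beta-carotene and chlorophyll a amounts as printed in the survey's
#' culture table. Useful for checking ratio arithmetic against the
#' published percentages (e.g. zeaxanthin at 12.9% of TChl a in
#' *Microcystis*).
#'
#' @return A [pigment_matrix()] with `units = "ng/inj"` and two rows.
#' @export
culture_fixtures <- function() {
  vals <- rbind(
    Microcystis_aeruginosa = c(Myxo = 6.3, Zea = 27.1, Gyro = 2.1,
                               Echin = 5.2, Caro_b = 16.9,
                               MVchl_a = 209.2),
    Anabaena_PCC7120 = c(Myxo = 2.4, Zea = 2.1, Gyro = 3.1,
                         Echin = 22.4, Caro_b = 29, MVchl_a = 190.8))
  pigment_matrix(vals,
                 data.frame(station_id = rownames(vals)),
                 panel = pigment_panel(colnames(vals), default_lod = 0),
                 units = "ng/inj")
}
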