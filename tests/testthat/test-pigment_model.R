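test_that("reading a station table handles sentinels, masks and dimensions", {
  path <- tiny_table_csv(tempfile(fileext = ".csv"))
  m <- read_pigment_table(path)
  expect_s3_class(m, "pigment_matrix")
  expect_equal(n_stations(m), 3)
  # "<LOD" sentinel and blank cell both become 0 with the mask set
  expect_equal(unname(m$values["m1s1", "Peri"]), 0)
  expect_true(m$below_lod["m1s1", "Peri"])
  expect_true(m$below_lod["m1s2", "Zea"])
  expect_equal(unname(m$values["m1s2", "Zea"]), 0)
  # season derived from the campaign map
  expect_equal(as.character(m$stations$season), c("spring", "spring", "summer"))
})

test_that("table validation rejects duplicates, negatives and missing chl a", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("station_id,MVchl_a,Fuco", "s1,1.0,0.2", "s1,2.0,0.3"), path)
  expect_error(read_pigment_table(path), "duplicated station_id.*s1")
  writeLines(c("station_id,MVchl_a,Fuco", "s1,1.0,-0.2"), path)
  expect_error(read_pigment_table(path), "negative concentration.*s1.*Fuco")
  writeLines(c("station_id,Fuco", "s1,0.2"), path)
  expect_error(read_pigment_table(path), "MVchl_a")
  writeLines(c("station_id,MVchl_a,mystery", "s1,1.0,9"), path)
  expect_warning(m <- read_pigment_table(path), "unknown columns.*mystery")
  expect_equal(m$extra$mystery, "9")
})

test_that("write -> read round trip preserves values and mask", {
  syn <- generate_pigment_data(generator_config(seed = 3))
  path <- tempfile(fileext = ".csv")
  write_pigment_table(syn$matrix, path)
  m2 <- read_pigment_table(path)
  expect_equal(m2$values, syn$matrix$values, tolerance = 1e-9)
  expect_identical(m2$below_lod, syn$matrix$below_lod)
  expect_identical(m2$stations$station_id, syn$matrix$stations$station_id)
})

test_that("derived sums follow the pool definitions", {
  vals <- rbind(s1 = c(MVchl_a = 2.0, DVchl_a = 0, Chlide_a = 0.1,
                       Fuco = 0.5, Zea = 0.2, Allo = 0.1, TChl_b = 0.05,
                       TChl_c = 0.2, Caro_b = 0.15))
  m <- pigment_matrix(vals, data.frame(station_id = "s1"),
                      panel = pigment_panel(colnames(vals)))
  sums <- suppressWarnings(derive_sums(m))
  expect_equal(sums$TChl_a, 2.1)
  expect_equal(sums$Caro, 0.15)
  expect_equal(sums$PPC, 0.1 + 0.2 + 0.15)   # Allo + Zea + Caro
  expect_equal(sums$PSC, 0.5)
  expect_equal(sums$TAcc, sums$PPC + sums$PSC + 0.05 + 0.2)
  expect_equal(sums$TPig, sums$TChl_a + sums$TAcc)

  # all accessories zero: TAcc = 0, TPig = TChl a
  vals0 <- rbind(s1 = c(MVchl_a = 2.0))
  m0 <- pigment_matrix(vals0, data.frame(station_id = "s1"),
                       panel = pigment_panel("MVchl_a"))
  s0 <- suppressWarnings(derive_sums(m0))
  expect_equal(s0$TAcc, 0)
  expect_equal(s0$TPig, 2.0)
})

test_that("derive_sums is linear and matches an independent recompute", {
  syn <- generate_pigment_data(generator_config(seed = 5))
  m <- syn$matrix
  sums <- suppressWarnings(derive_sums(m))
  # independent bookkeeping: direct column sums from the raw matrix
  v <- m$values
  tacc <- rowSums(v[, c("Allo", "Diad", "Diato", "Zea", "Caro_a", "Caro_b",
                        "But", "Fuco", "Hex", "Peri", "TChl_b", "TChl_c",
                        "Chlc3")])
  expect_equal(unname(sums$TAcc), unname(tacc), tolerance = 1e-12)
  # scaling all concentrations by k scales every sum by k
  m2 <- m
  m2$values <- m$values * 3.7
  s2 <- suppressWarnings(derive_sums(m2))
  for (col in c("TChl_a", "TAcc", "PPC", "PSC", "TPig"))
    expect_equal(s2[[col]], 3.7 * sums[[col]], tolerance = 1e-12)
})

test_that("culture profiles reproduce the published ratio percentages", {
  cult <- culture_fixtures()
  expect_equal(n_stations(cult), 2)
  expect_equal(cult$units, "ng/inj")
  r_tchla <- function(p) 100 * pigment_ratio(cult, p)
  r_caro <- function(p) 100 * pigment_ratio(cult, p, "Caro_b")
  mic <- "Microcystis_aeruginosa"; ana <- "Anabaena_PCC7120"
  # printed percentages, to within 0.1 percentage point
  expect_equal(unname(r_tchla("Zea")[mic]), 12.9, tolerance = 0.1 / 12.9)
  expect_equal(unname(r_caro("Zea")[mic]), 160.4, tolerance = 0.1 / 160.4)
  expect_equal(unname(r_caro("Myxo")[mic]), 37.3, tolerance = 0.1 / 37.3)
  expect_equal(unname(r_tchla("Echin")[mic]), 2.5, tolerance = 0.1 / 2.5)
  expect_equal(unname(r_tchla("Echin")[ana]), 11.7, tolerance = 0.1 / 11.7)
  expect_equal(unname(r_caro("Echin")[ana]), 77.2, tolerance = 0.1 / 77.2)
  expect_equal(unname(r_tchla("Caro_b")[ana]), 15.2, tolerance = 0.1 / 15.2)
})

test_that("ratios to TChl a behave at the edges", {
  vals <- rbind(s1 = c(MVchl_a = 2.0, Fuco = 2.0, Zea = 0.5))
  m <- pigment_matrix(vals, data.frame(station_id = "s1"),
                      panel = pigment_panel(colnames(vals)))
  r <- ratios_to_tchla(m, c("Fuco", "Zea"))
  expect_equal(unname(r["s1", "Fuco"]), 1)       # pigment equal to TChl a
  expect_equal(unname(r["s1", "Zea"]), 0.25)
  vals0 <- rbind(s1 = c(MVchl_a = 0, Fuco = 1))
  m0 <- pigment_matrix(vals0, data.frame(station_id = "s1"),
                       panel = pigment_panel(colnames(vals0)))
  expect_error(ratios_to_tchla(m0), "TChl a is zero.*s1")
})

test_that("pigment name resolution accepts aliases and rejects unknowns", {
  expect_equal(resolve_pigment(c("fucoxanthin", "b,b-carotene", "chl c1")),
               c("Fuco", "Caro_b", "TChl_c"))
  expect_error(resolve_pigment("notapigment"), "unknown pigment")
})
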