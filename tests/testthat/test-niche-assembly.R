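test_that("repeated measurements are averaged per species and trait", {
  rec <- data.frame(
    species = c("X", "X", "Y", "Y", "Y"),
    trait = c("T_min", "T_min", "T_min", "T_max", "T_max"),
    value = c(-8, -10, -3, 44, 46),
    hardening = c("hardened", "hardened", "unknown", "unknown", "unknown"),
    group = "angiosperm")
  tab <- average_repeated_measurements(rec)
  expect_equal(tab$T_min[tab$species == "X"], -9)
  expect_equal(tab$T_max[tab$species == "Y"], 45)
  expect_true(is.na(tab$T_max[tab$species == "X"]))
  expect_identical(tab$hardening, c("hardened", "unknown"))

  # single measurement passes through
  one <- average_repeated_measurements(
    data.frame(species = "Z", trait = "T_max", value = 50))
  expect_equal(one$T_max, 50)

  # grouping oracle: row count equals distinct species
  set.seed(12)
  big <- data.frame(species = sample(sprintf("sp%03d", 1:300), 1000,
                                     replace = TRUE),
                    trait = sample(c("T_min", "T_max"), 1000, TRUE))
  big$value <- rnorm(1000, ifelse(big$trait == "T_min", -10, 45))
  out <- average_repeated_measurements(big)
  expect_equal(nrow(out), length(unique(big$species)))

  expect_error(average_repeated_measurements(
    data.frame(species = "a", trait = "T_min", value = "cold")),
    "non-numeric")
  expect_warning(average_repeated_measurements(
    data.frame(species = "a", trait = c("T_min", "T_min"),
               value = c(-5, -7),
               hardening = c("hardened", "non_hardened"))),
    "conflicting hardening")
})

test_that("niche summaries follow the stated percentile definition", {
  one <- summarize_niche(data.frame(species = "s", longitude = 0,
                                    latitude = 0, bio5 = 30, bio6 = 2))
  expect_equal(one$mean_MTWM, 30)
  expect_equal(one$lower_MTCM, 2)
  expect_equal(one$n_occurrences, 1L)

  occ <- data.frame(species = "s", longitude = 0, latitude = 0,
                    bio5 = 20 + 0:10, bio6 = 0:10)
  s <- summarize_niche(occ)
  expect_equal(s$lower_MTCM, 1.0)   # linear-interpolation 10th percentile
  expect_equal(s$upper_MTWM, 29.0)

  # literal tail-mean alternative
  s2 <- summarize_niche(occ, tail_mode = "tail_mean")
  expect_equal(s2$lower_MTCM, mean(0:1))
  expect_equal(s2$upper_MTWM, mean(29:30))

  # arithmetic oracle + permutation invariance on many points
  set.seed(5)
  big <- data.frame(species = "s", longitude = runif(500, -10, 10),
                    latitude = runif(500, -10, 10),
                    bio6 = rnorm(500, 2, 4))
  big$bio5 <- big$bio6 + 15
  sb <- summarize_niche(big)
  expect_equal(sb$mean_MTCM, mean(big$bio6), tolerance = 1e-9)
  expect_equal(summarize_niche(big[sample(500), ]), sb)
  expect_lte(sb$lower_MTCM, sb$mean_MTCM)
  expect_gte(sb$upper_MTWM, sb$mean_MTWM)

  expect_error(summarize_niche(data.frame(species = "s", longitude = 200,
                                          latitude = 0, bio5 = 1,
                                          bio6 = 0)), "longitude")
})

test_that("grid extraction is nearest-cell with documented edge rules", {
  g <- make_climate_grid(0, 0, 1, ncols = 10, nrows = 5,
                         fun = function(lo, la) 2 * lo + 10 * la)
  # cell centers return the analytic surface
  set.seed(2)
  ci <- sample(10, 30, TRUE); ri <- sample(5, 30, TRUE)
  lon <- ci - 0.5; lat <- ri - 0.5
  expect_equal(extract_grid_values(g, lon, lat), 2 * lon + 10 * lat)
  # anywhere inside a cell returns that cell's center value
  expect_equal(extract_grid_values(g, 3.2, 1.9),
               2 * 3.5 + 10 * 1.5)
  # edge tie goes to the larger-index (east/north) cell
  expect_equal(extract_grid_values(g, 3, 1.5), 2 * 3.5 + 10 * 1.5)
  # out of extent is missing, not an error
  expect_true(is.na(extract_grid_values(g, -1, 2)))
  expect_true(is.na(extract_grid_values(g, 10, 2)))  # exact east boundary
})

test_that("ESRI ASCII grids round-trip", {
  g <- make_climate_grid(-3, 7, 0.25, ncols = 8, nrows = 6,
                         fun = function(lo, la) lo - la)
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_grid(g, path)
  g2 <- read_esri_grid(path)
  expect_equal(g2$values, g$values, tolerance = 1e-8)
  expect_equal(g2$cellsize, 0.25)
  expect_equal(g2$xll, -3)
})

test_that("analysis-table assembly joins, selects variants, stratifies", {
  traits <- data.frame(species = c("A", "B"), T_min = c(-5, -8),
                       T_max = c(40, 42),
                       hardening = c("hardened", "unknown"),
                       group = "angiosperm")
  niches <- data.frame(species = c("B", "C"), n_occurrences = 5,
                       mean_MTWM = c(30, 31), mean_MTCM = c(0, 1),
                       upper_MTWM = c(33, 34), lower_MTCM = c(-4, -3))
  tab <- suppressMessages(assemble_analysis_table(traits, niches))
  expect_identical(tab$species, "B")
  expect_equal(tab$MTCM, 0)
  tabt <- suppressMessages(assemble_analysis_table(traits, niches, "tail"))
  expect_equal(tabt$MTCM, -4)
  expect_equal(tabt$MTWM, 33)
  expect_error(assemble_analysis_table(traits, niches, "local"), "local")

  # join oracle with partly disjoint species
  set.seed(8)
  spT <- sprintf("s%03d", 1:300)
  spN <- sprintf("s%03d", 31:330)
  tr2 <- data.frame(species = spT, T_min = rnorm(300), T_max = rnorm(300),
                    hardening = sample(c("hardened", "non_hardened",
                                         "unknown"), 300, TRUE),
                    group = "fern")
  ni2 <- data.frame(species = spN, n_occurrences = 1,
                    mean_MTWM = rnorm(300), mean_MTCM = rnorm(300),
                    upper_MTWM = rnorm(300), lower_MTCM = rnorm(300))
  out <- suppressMessages(assemble_analysis_table(tr2, ni2))
  expect_equal(nrow(out), length(intersect(spT, spN)))
  # hardening-type counts partition the total
  expect_equal(sum(table(out$hardening)), nrow(out))
})
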