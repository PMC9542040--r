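test_that("valid rows pass through and bad units are rejected with a log", {
  rows <- rbind(db_row(), db_row(species = "Gadus morhua", pcrit = 8),
                db_row(species = "Salmo salar", pcrit = 6))
  traits <- rbind(traits_row(), traits_row("Gadus morhua", 0.9, 4e4),
                  traits_row("Salmo salar", 3.0, 2e4))
  db <- read_fixture_db(rows, traits)
  expect_equal(nrow(db$records), 3)
  expect_equal(nrow(db$rejections), 0)

  rows2 <- rows
  rows2$pcrit_unit[2] <- "furlongs"
  db2 <- read_fixture_db(rows2, traits)
  expect_equal(nrow(db2$records), 2)
  expect_equal(nrow(db2$rejections), 1)
  expect_match(db2$rejections$reason, "furlongs")
  expect_equal(db2$rejections$row, 2)
})

test_that("rows with missing mandatory fields are rejected, not dropped silently", {
  rows <- rbind(db_row(), db_row(species = NA), db_row(temp_meas = NA),
                db_row(pcrit = -1), db_row(temp_meas = 60))
  db <- read_fixture_db(rows, traits_row())
  expect_equal(nrow(db$records) + nrow(db$rejections), nrow(rows))
  expect_equal(nrow(db$records), 1)
})

test_that("species without trait entries are retained but flagged", {
  rows <- rbind(db_row(), db_row(species = "Unknownfish spx"))
  db <- read_fixture_db(rows, traits_row())
  expect_equal(nrow(db$records), 2)
  expect_identical(db$records$traits_missing, c(FALSE, TRUE))
  expect_message(clean <- standardize(db), "dropped")
  expect_equal(nrow(clean), 1)
})

test_that("duplicate trait entries are averaged", {
  rows <- db_row()
  traits <- rbind(traits_row(genome_size_pg = 1.5),
                  traits_row(genome_size_pg = 2.5))
  expect_message(db <- read_fixture_db(rows, traits), NA)
  expect_equal(nrow(db$traits), 1)
  expect_equal(db$traits$genome_size_pg, 2)
})

test_that("salinity resolution maps the seawater token to 35 PSU", {
  r <- resolve_salinity(c("seawater", "0", "12.5", "Seawater"))
  expect_equal(r$salinity, c(35, 0, 12.5, 35))
  expect_identical(r$salinity_imputed, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(resolve_salinity("-3"), "negative")
  expect_error(resolve_salinity("brackish-ish"), "unparseable")
})

test_that("standardization converts units and derives covariates", {
  rows <- rbind(
    db_row(pcrit = 50, pcrit_unit = "percent_airsat", temp_meas = 15,
           temp_acclim = 15, salinity = "0", body_mass_g = 50),
    db_row(species = "Gadus morhua", pcrit = 5, pcrit_unit = "kPa",
           temp_meas = 25, temp_acclim = 20, salinity = "seawater",
           body_mass_g = 100, metabolic_rate = 2, mr_unit = "mg_O2_per_h")
  )
  traits <- rbind(traits_row(max_body_mass_g = 1000),
                  traits_row("Gadus morhua", 0.9, 4e4))
  db <- read_fixture_db(rows, traits)
  clean <- standardize(db)
  expect_s3_class(clean, "pcrit_clean")
  expect_equal(clean$pcrit_kpa[1], 10.43, tolerance = 0.001)
  expect_equal(clean$rel_acclim, c(0, -5))
  expect_equal(clean$salinity, c(0, 35))
  expect_identical(clean$salinity_imputed, c(FALSE, TRUE))
  expect_equal(clean$pct_max_mass[1], 5)
  expect_equal(clean$log10_pct[1], log10(5), tolerance = 1e-10)
  expect_equal(clean$log10_pct[1], 0.699, tolerance = 0.001)
  # 2 mg O2/h = 2000/31.998 umol/h
  expect_equal(clean$mr_umol_h[2], 2000 / 31.998)
  expect_true(is.na(clean$mr_umol_h[1]))
})

test_that("standardizing an already-kPa record is the identity on pcrit", {
  db <- read_fixture_db(db_row(pcrit = 7.3, pcrit_unit = "kPa"),
                        traits_row())
  clean <- standardize(db)
  expect_identical(clean$pcrit_kpa, 7.3)
  # and rel_acclim is 0 when acclimation equals measurement temperature
  expect_identical(clean$rel_acclim, 0)
})

test_that("mass-specific metabolic units scale with body mass", {
  rows <- rbind(
    db_row(metabolic_rate = 100, mr_unit = "mg_O2_per_kg_per_h",
           body_mass_g = 500),
    db_row(metabolic_rate = 0.5, mr_unit = "umol_O2_per_g_per_h",
           body_mass_g = 20)
  )
  db <- read_fixture_db(rows, traits_row(max_body_mass_g = 1000))
  clean <- standardize(db)
  expect_equal(clean$mr_umol_h[1], 100 * 0.5 * 1000 / 31.998)
  expect_equal(clean$mr_umol_h[2], 10)
})

test_that("records heavier than the species maximum warn but survive", {
  rows <- db_row(body_mass_g = 3)
  expect_warning(db <- read_fixture_db(rows, traits_row(max_body_mass_g = 2)),
                 "maximum")
  clean <- suppressWarnings(standardize(db))
  expect_gt(clean$pct_max_mass, 100)
})

test_that("column maps adapt foreign headers and unreadable files error", {
  rows <- db_row()
  names(rows)[names(rows) == "species"] <- "sciname"
  d <- tempfile("colmap")
  dir.create(d)
  p1 <- write_db_fixture(rows, d)
  p2 <- write_traits_fixture(traits_row(), d)
  db <- read_database(p1, p2, col_map = c(species = "sciname"))
  expect_equal(db$records$species, "Danio rerio")
  expect_error(read_database(file.path(d, "nope.csv"), p2), "cannot read")
})

test_that("clean output and validation report can be written and reread", {
  db <- read_fixture_db(db_row(), traits_row())
  clean <- standardize(db)
  d <- tempfile("out")
  dir.create(d)
  csv <- file.path(d, "clean.csv")
  rep <- file.path(d, "report.json")
  info <- write_clean(clean, db, csv, rep)
  expect_equal(info$n_records, 1)
  back <- utils::read.csv(csv)
  expect_equal(back$pcrit_kpa, clean$pcrit_kpa)
  expect_true(file.exists(rep))
})
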