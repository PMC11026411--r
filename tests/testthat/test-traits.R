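test_that("trait tables round-trip through CSV with NA for unparseable numbers", {
  raw <- make_raw_traits()
  raw$weaning_weight_g <- as.character(raw$weaning_weight_g)
  raw$weaning_weight_g[2] <- "not-a-number"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, path, row.names = FALSE)
  rec <- read_traits(path)
  expect_equal(nrow(rec), 5L)
  expect_equal(rec$weaning_mass[1], 700)
  expect_equal(rec$litter_size[1], 4.5)     # fractional litter sizes kept
  expect_true(is.na(rec$weaning_mass[2]))   # unparseable -> NA, never zero
  expect_equal(rec$species[3], "Macropus rufus")
})

test_that("TSV input is sniffed from the header", {
  raw <- make_raw_traits()
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(raw, path, sep = "\t", row.names = FALSE)
  rec <- read_traits(path)
  expect_equal(rec$adult_mass, raw$adult_body_mass_g)
})

test_that("schema and validation errors are specific", {
  raw <- make_raw_traits()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw[, setdiff(names(raw), "litter_or_clutch_size_n")], path,
            row.names = FALSE)
  expect_error(read_traits(path), "litter_or_clutch_size_n",
               class = "allomi_schema_error")

  dup <- rbind(raw, raw[2, ])
  expect_error(traits_from_data_frame(dup), "Rattus rattus",
               class = "allomi_validation_error")

  writeLines("", path)
  expect_warning(rec <- read_traits(path), "empty")
  expect_equal(nrow(rec), 0L)
})

test_that("non-positive masses and litter sizes below one are invalidated", {
  raw <- make_raw_traits()
  raw$adult_body_mass_g[1] <- -5
  raw$litter_or_clutch_size_n[2] <- 0.4
  expect_warning(rec <- traits_from_data_frame(raw), "set to NA")
  expect_true(is.na(rec$adult_mass[1]))
  expect_true(is.na(rec$litter_size[2]))
})

test_that("consistency filters follow the strict more-than-15% rules", {
  base <- data.frame(
    species = c("keepB", "dropB", "dropA_high", "dropA_low", "keepA", "nosex"),
    adult_body_mass_g = c(1000, 1000, 1000, 1000, 1000, 1000),
    female_body_mass_g = c(NA, NA, 400, 1300, 900, NA),
    male_body_mass_g = c(NA, NA, 500, 1500, 1100, NA),
    weaning_weight_g = c(1150, 1200, 100, 100, 100, 100),
    litter_or_clutch_size_n = rep(2, 6),
    check.names = FALSE, stringsAsFactors = FALSE)
  rec <- traits_from_data_frame(base)
  out <- clean_traits(rec)
  # rule B: 1200 > 1.15 * 1000 excluded; 1150 retained (strict inequality)
  expect_true("keepB" %in% out$records$species)
  expect_false("dropB" %in% out$records$species)
  # rule A: default 1000 > 1.15 * max(400, 500) = 575 -> excluded
  expect_false("dropA_high" %in% out$records$species)
  # rule A: default 1000 < 0.85 * min(1300, 1500) = 1105 -> excluded
  expect_false("dropA_low" %in% out$records$species)
  # within [0.85 * 900, 1.15 * 1100] -> retained
  expect_true("keepA" %in% out$records$species)
  expect_true("nosex" %in% out$records$species)  # rule A skipped without sex masses
  expect_equal(out$report$n_input, out$report$n_retained + nrow(out$report$exclusions))
  expect_true(all(table(out$report$exclusions$species) == 1))  # one rule per exclusion
})

test_that("filtering is idempotent and order-invariant", {
  rec <- traits_from_data_frame(make_raw_traits())
  rec$weaning_mass[2] <- 400   # force a rule-B exclusion (400 > 1.15 * 300)
  once <- clean_traits(rec)
  twice <- clean_traits(once$records)
  expect_equal(once$records, twice$records)
  expect_equal(nrow(twice$report$exclusions), 0L)
  perm <- clean_traits(rec[c(4, 2, 5, 1, 3), ])
  expect_setequal(perm$records$species, once$records$species)
})

test_that("corrections are applied before filtering and logged", {
  rec <- traits_from_data_frame(make_raw_traits())
  rec$weaning_mass[1] <- 7e5     # absurd entry that rule B would drop
  corr <- data.frame(species = "Vulpes vulpes", field = "weaning_mass",
                     value = 700, stringsAsFactors = FALSE)
  out <- clean_traits(rec, corrections = corr)
  expect_true("Vulpes vulpes" %in% out$records$species)
  expect_equal(out$report$corrections_applied$old, 7e5)
  expect_error(clean_traits(rec, data.frame(species = "nope", field = "weaning_mass",
                                            value = 1)),
               class = "allomi_validation_error")
})

test_that("analysis variables are the log10 derived quantities", {
  rec <- traits_from_data_frame(make_raw_traits())
  tab <- analysis_table(rec)
  i <- match("Vulpes vulpes", tab$species)
  expect_equal(tab$y[i], log10(700 * 4.5))
  expect_equal(tab$x[i], log10(5000))
  expect_equal(tab$z[i], log10(52 + 56))
  # the fruit-bat style check: 120 d gestation + 42 d lactation
  one <- traits_from_data_frame(data.frame(
    species = "Cynopterus sphinx", adult_body_mass_g = 50,
    weaning_weight_g = 20, litter_or_clutch_size_n = 1,
    gestation_d = 120, weaning_d = 42, check.names = FALSE))
  expect_equal(analysis_table(one)$z, log10(162), tolerance = 1e-12)
  # litter size 1 -> y is just log10 weaning mass
  expect_equal(analysis_table(one)$y, log10(20))
})

test_that("mass proxy selection and missing-data dropping work per analysis", {
  rec <- traits_from_data_frame(make_raw_traits())
  tab_f <- suppressMessages(analysis_table(rec, mass_proxy = "female"))
  expect_true(all(tab_f$species %in% c("Vulpes vulpes", "Macropus rufus",
                                       "Loxodonta africana")))
  expect_equal(attr(tab_f, "mass_proxy"), "female")
  rec$female_mass <- NA_real_
  expect_error(analysis_table(rec, mass_proxy = "female"),
               class = "allomi_validation_error")
  rec2 <- traits_from_data_frame(make_raw_traits())
  rec2$gestation[2] <- NA
  expect_message(tab <- analysis_table(rec2), "dropped")
  expect_false("Rattus rattus" %in% tab$species)
  tab_nd <- analysis_table(rec2, duration_required = FALSE)
  expect_true("Rattus rattus" %in% tab_nd$species)
})

test_that("rule B restated on the derived scale holds for every retained species", {
  rec <- traits_from_data_frame(make_raw_traits())
  rec$weaning_mass[3] <- 4.5e4           # near the boundary
  out <- clean_traits(rec)
  tab <- analysis_table(out$records, duration_required = FALSE)
  litter <- 10^tab$y
  ls <- out$records$litter_size[match(tab$species, out$records$species)]
  expect_true(all(litter / ls <= 1.15 * 10^tab$x + 1e-9))
})
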