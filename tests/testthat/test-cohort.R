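no_events <- function() {
  list(icd = data.frame(patient_id = character(), code = character(),
                        date = character()),
       sf = data.frame(patient_id = character(), value = character(),
                       date = character()))
}

test_that("indication source follows the window and value-set rules", {
  cfg <- cohort_config()
  e <- no_events()

  icd <- data.frame(patient_id = "P1", code = "W34.00XA", date = "2015-06-01")
  r <- classify_indication(icd, e$sf, cfg)
  expect_equal(r$source, "icd")

  sf <- data.frame(patient_id = "P2", value = "recent", date = "2022-03-01")
  expect_equal(classify_indication(e$icd, sf, cfg)$source, "smartform")

  # a qualifying value before the SmartForm go-live does not count
  sf_pre <- data.frame(patient_id = "P3", value = "recent", date = "2021-12-01")
  expect_equal(classify_indication(e$icd, sf_pre, cfg)$source, "none")

  # both criteria -> both
  both <- classify_indication(icd |> transform(patient_id = "P4"),
                              sf |> transform(patient_id = "P4"), cfg)
  expect_equal(both$source, "both")

  # non-firearm code, out-of-window code, non-qualifying value -> none
  r2 <- classify_indication(
    data.frame(patient_id = c("P5", "P6"), code = c("J45.909", "X95.0"),
               date = c("2015-01-01", "2011-06-01")),
    data.frame(patient_id = "P7", value = "none", date = "2022-06-01"), cfg)
  expect_equal(sort(unique(r2$source)), "none")
})

test_that("code matching is by prefix, case- and dot-insensitive", {
  cfg <- cohort_config()
  e <- no_events()
  codes <- c("w34.00xa", "X9500XA", "Y35.013A", "Y351XXA")
  r <- classify_indication(
    data.frame(patient_id = paste0("P", 1:4), code = codes,
               date = "2020-01-01"), e$sf, cfg)
  # Y35.1 is not in the firearm set (only Y35.0 legal-intervention discharge)
  expect_equal(r$source, c("icd", "icd", "icd", "none"))

  # SmartForm values compared case-insensitively after trimming
  r2 <- classify_indication(e$icd,
    data.frame(patient_id = "P1", value = "  Recent ", date = "2022-05-01"),
    cfg)
  expect_equal(r2$source, "smartform")
})

test_that("malformed dates and empty patient ids are rejected", {
  e <- no_events()
  expect_error(classify_indication(
    data.frame(patient_id = "P1", code = "W34", date = "06/01/2015"), e$sf),
    "malformed")
  expect_error(classify_indication(
    data.frame(patient_id = " ", code = "W34", date = "2015-06-01"), e$sf),
    "patient_id")
})

test_that("cohort partitions patients and reports a unit-sum mixture", {
  icd <- data.frame(patient_id = c("A", "C"), code = c("W34.00XA", "J45.9"),
                    date = "2015-06-01")
  sf <- data.frame(patient_id = c("B", "C"), value = c("historical", "none"),
                   date = "2022-06-01")
  bc <- build_cohort(icd, sf)
  expect_equal(bc$n_input, 3)
  expect_equal(bc$n_included, 2)
  expect_setequal(bc$cohort$source, c("icd", "smartform"))
  expect_equal(sum(bc$mixture$prop), 1)
  expect_equal(sort(bc$mixture$prop, decreasing = TRUE), c(0.5, 0.5, 0))

  # every patient maps to exactly one source
  all_sources <- classify_indication(icd, sf)
  expect_equal(nrow(all_sources), length(unique(all_sources$patient_id)))

  # empty qualifying value set leaves only icd-derived members
  bc2 <- build_cohort(icd, sf, cohort_config(qualifying_smartform_values = character()))
  expect_equal(bc2$cohort$source, "icd")
})

test_that("shrinking a window never grows the cohort", {
  pop <- generate_population(generator_config(n_patients = 200, seed = 11))
  full <- build_cohort(pop$icd_events, pop$smartform_events)
  shrunk <- build_cohort(pop$icd_events, pop$smartform_events,
                         cohort_config(icd_window = c("2018-01-01", "2022-12-31"),
                                       smartform_window = c("2022-06-01", "2022-12-31")))
  expect_lte(shrunk$n_included, full$n_included)
  expect_true(all(shrunk$cohort$patient_id %in% full$cohort$patient_id))
})
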