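test_that("enrichment derives BMI and tolerates missing height/weight", {
  r <- rx_patient(clinical = list(height = 1.79, weight = 80))
  e <- enrich(r)
  expect_equal(e$clinical$bmi, 80 / 1.79^2, tolerance = 1e-10)
  expect_equal(round(e$clinical$bmi, 2), 24.97)

  r2 <- enrich(rx_patient(clinical = list(weight = 80)))
  expect_null(r2$clinical$bmi)
})

test_that("relative-posology change flags compare the proposal to the current treatment", {
  hist <- list(tx(metformin_drug(mg(500)), status = "current"))
  flag_for <- function(proposed) {
    e <- enrich(rx_patient(history = hist, proposed = proposed))
    e$proposed$changes
  }
  expect_identical(flag_for(tx(metformin_drug(mg(1000)))), "dose_increase")
  expect_identical(flag_for(tx(metformin_drug(mg(250)))), "dose_decrease")
  expect_identical(flag_for(tx(sulfonamide_drug())), "inn_change")
  expect_identical(flag_for(tx(metformin_drug(mg(500)))), character())
  # no current treatment: nothing to compare against
  expect_identical(
    enrich(rx_patient(proposed = tx(metformin_drug())))$proposed$changes,
    character())
})

test_that("enrich is idempotent", {
  r <- rx_patient(clinical = list(height = 1.7, weight = 90),
                  history = list(tx(metformin_drug(mg(500)), status = "current")),
                  proposed = tx(metformin_drug(mg(1000))))
  once <- enrich(r)
  expect_identical(enrich(once), once)
})

test_that("dual failures are re-labelled to follow the poor-tolerance pathway", {
  dual <- tx(metformin_drug(tolerance = "poorly_tolerated"), status = "past",
             efficacy = "ineffective", start = "2024-01-01", end = "2025-01-01")
  ineff_only <- tx(metformin_drug(tolerance = "well_tolerated"), status = "past",
                   efficacy = "ineffective", start = "2024-01-01",
                   end = "2025-01-01")
  eff_poor <- tx(metformin_drug(tolerance = "poorly_tolerated"), status = "past",
                 efficacy = "effective", start = "2024-01-01", end = "2025-01-01")
  r <- normalize_outcomes(rx_patient(history = list(dual, ineff_only, eff_poor)))
  expect_identical(r$history[[1]]$efficacy, "unknown")
  expect_match(r$history[[1]]$notes, "dual failure")
  expect_identical(r$history[[2]]$efficacy, "ineffective")  # untouched
  expect_identical(r$history[[3]]$efficacy, "effective")    # untouched
  # tolerance values are never altered, and the pass is idempotent
  expect_identical(r$history[[1]]$components[[1]]$tolerance, "poorly_tolerated")
  expect_identical(normalize_outcomes(r), r)
})

test_that("indication assignment partitions by dose and duplicates multi-indication drugs", {
  kb <- rx_kb(
    name = "cardio",
    drug_classes = list(aspirin = "B01AC06", beta_blocker = "C07AB"),
    treatments = list(asp = list(components = list(
      rx_drug("B01AC06", "aspirin", mg(100))))),
    recommendations = list(list(
      id = "r", type = "should_not_prescribe", conditions = NULL,
      pattern = rx_pattern(components = list(rx_class_ref("aspirin"), rx_any())),
      criticism_label = "x")),
    indications = list(
      list(class = "aspirin", indication = "antiplatelet",
           dose_max = 325, unit = "mg"),
      list(class = "aspirin", indication = "analgesic",
           dose_min = 326, unit = "mg"),
      list(class = "beta_blocker", indication = "hypertension"),
      list(class = "beta_blocker", indication = "atrial_fibrillation")))

  low <- rx_patient(proposed = tx(rx_drug("B01AC06", "aspirin", mg(100))))
  high <- rx_patient(proposed = tx(rx_drug("B01AC06", "aspirin", mg(500))))
  expect_identical(names(assign_indications(low, kb)), "antiplatelet")
  expect_identical(names(assign_indications(high, kb)), "analgesic")

  bb <- rx_patient(proposed = tx(rx_drug("C07AB03", "atenolol", mg(50))))
  groups <- assign_indications(bb, kb)
  expect_setequal(names(groups), c("hypertension", "atrial_fibrillation"))

  # empty prescription -> empty map; unmapped drug flagged and excluded
  expect_length(assign_indications(rx_patient(), kb), 0)
  odd <- rx_patient(proposed = tx(rx_drug("N05BA01", "diazepam", mg(5))))
  expect_warning(g <- assign_indications(odd, kb), "unmapped")
  expect_length(g, 0)
  expect_identical(attr(g, "unmapped"), "diazepam")
})

test_that("indication groups conserve the mapped proposed drugs", {
  kb <- rx_kb(
    name = "cardio",
    drug_classes = list(aspirin = "B01AC06", beta_blocker = "C07AB"),
    treatments = list(asp = list(components = list(
      rx_drug("B01AC06", "aspirin", mg(100))))),
    recommendations = list(list(
      id = "r", type = "should_not_prescribe", conditions = NULL,
      pattern = rx_pattern(components = list(rx_class_ref("aspirin"), rx_any())),
      criticism_label = "x")),
    indications = list(
      list(class = "aspirin", indication = "antiplatelet"),
      list(class = "beta_blocker", indication = "hypertension"),
      list(class = "beta_blocker", indication = "atrial_fibrillation")))
  r <- rx_patient(proposed = tx(rx_drug("B01AC06", "aspirin", mg(100)),
                                rx_drug("C07AB03", "atenolol", mg(50))))
  groups <- assign_indications(r, kb)
  inns <- unique(unlist(lapply(groups, function(g)
    vapply(rxcritic:::drug_components(g$proposed), function(d) d$inn,
           character(1)))))
  expect_setequal(inns, c("aspirin", "atenolol"))
  n_distinct_across <- length(unlist(lapply(groups, function(g)
    vapply(rxcritic:::drug_components(g$proposed), function(d) d$inn,
           character(1)))))
  expect_gte(n_distinct_across, 2)
})

test_that("patient records read from YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "id: p1",
    "clinical: {height: 1.79, weight: 80}",
    "biological: {hba1c: 6.0}",
    "critique_date: 2026-01-01",
    "history:",
    "  - components:",
    "      - non_drug: diet",
    "      - drug: {atc: A10BA02, inn: metformin, dose: {value: 500, unit: mg, per: day}}",
    "    status: past",
    "    efficacy: ineffective",
    "    start: 2024-02-01",
    "    end: 2025-02-01",
    "proposed:",
    "  components:",
    "    - non_drug: diet",
    "    - drug: {atc: A10BF01, inn: acarbose, dose: {value: 100, unit: mg, per: day}}"),
    f)
  r <- read_patient(f)
  expect_s3_class(r, "rx_patient")
  expect_identical(r$id, "p1")
  expect_length(r$history, 1)
  expect_identical(r$history[[1]]$efficacy, "ineffective")
  expect_identical(r$proposed$status, "proposed")
  expect_identical(r$critique_date, as.Date("2026-01-01"))
})
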