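# shared builders for concrete treatments and patients

mg <- function(value) list(value = value, unit = "mg", per = "day")

tx <- function(..., status = "proposed", efficacy = "unknown",
               start = NULL, end = NULL) {
  rx_treatment(list(...), status = status, efficacy = efficacy,
               start = start, end = end)
}

metformin_drug <- function(dose = mg(500), tolerance = "unknown")
  rx_drug("A10BA02", "metformin", dose = dose, tolerance = tolerance)

agi_drug <- function(dose = mg(100), tolerance = "unknown")
  rx_drug("A10BF01", "acarbose", dose = dose, tolerance = tolerance)

sulfonamide_drug <- function(dose = mg(60), tolerance = "unknown")
  rx_drug("A10BB09", "gliclazide", dose = dose, tolerance = tolerance)

diet <- function() rx_non_drug_component("diet")

blank_ctx <- function(kb, critique_date = "2026-01-01")
  match_context(rx_patient(critique_date = critique_date), kb)
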