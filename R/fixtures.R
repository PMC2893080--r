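#' Bundled example knowledge bases
#'
#' Three small knowledge bases ship with the package:
#' * `"diabetes"` — the type 2 diabetes monotherapy recommendation
#'   (metformin first-line, alpha-glucosidase inhibitor second-line, under
#'   an HbA1c condition), with its three criticism labels;
#' * `"statins"` — a dyslipidaemia guideline fragment: no lipid-lowering
#'   drug above 80 years in primary prevention, simvastatin / pravastatin /
#'   atorvastatin first-line, rosuvastatin only after tolerance or efficacy
#'   problems with other statins;
#' * `"generics"` — a generic-recommendation exercise base with a
#'   multi-code glinide class, a beta-blocker class (for the
#'   same-class-association rule) and a bupropion exception to the
#'   dose-lowering rule (narrow therapeutic range).
#'
#' @param name One of `"diabetes"`, `"statins"`, `"generics"`.
#' @return A validated `rx_kb`.
#' @export
example_kb <- function(name = c("diabetes", "statins", "generics")) {
  name <- match.arg(name)
  read_kb(system.file("extdata", paste0(name, ".yaml"),
                      package = "rxcritic", mustWork = TRUE))
}

#' Worked-example patients for the diabetes knowledge base
#'
#' Two patient records bracketing the monotherapy recommendation: a patient
#' at the stage of first-line treatment (no failed treatment in the
#' history) and one at the stage of second-line treatment (a past
#' ineffective diet + metformin treatment), both with HbA1c 6.0%.
#'
#' @return Named list of `rx_patient` objects (`stage1`, `stage2`).
#' @export
diabetes_patients <- function() {
  metformin_tx <- function(status, efficacy, start, end)
    rx_treatment(
      list(rx_non_drug_component("diet"),
           rx_drug("A10BA02", "metformin",
                   dose = list(value = 500, unit = "mg", per = "day"))),
      status = status, efficacy = efficacy, start = start, end = end)
  list(
    stage1 = rx_patient(biological = list(hba1c = 6.0),
                        critique_date = "2026-01-01", id = "stage1"),
    stage2 = rx_patient(biological = list(hba1c = 6.0),
                        history = list(metformin_tx("past", "ineffective",
                                                    "2024-02-01",
                                                    "2025-02-01")),
                        critique_date = "2026-01-01", id = "stage2"))
}

#' Candidate proposals for the diabetes worked example
#'
#' The three prescriptions a physician can propose under the monotherapy
#' recommendation: diet + metformin (first line), diet + an
#' alpha-glucosidase inhibitor (second line), and diet + any other oral
#' antidiabetic (here a sulfonamide), standing for "any other treatment".
#'
#' @param kb The diabetes `rx_kb` (for the treatment templates).
#' @return Named list of proposed `rx_treatment`s.
#' @export
diabetes_proposals <- function(kb = example_kb("diabetes")) {
  list(
    metformin = template_treatment(kb$treatments[["diet_metformin"]]),
    agi = template_treatment(kb$treatments[["diet_agi"]]),
    other = rx_treatment(
      list(rx_non_drug_component("diet"),
           rx_drug("A10BB09", "gliclazide",
                   dose = list(value = 60, unit = "mg", per = "day"))),
      status = "proposed"))
}

#' Critique matrix: every (stage, proposal) situation of a recommendation
#'
#' Runs the engine over the cross product of patient stages and candidate
#' proposals and tabulates the verdicts — the package's worked example
#' reproduces the six situations of the diabetes monotherapy
#' recommendation (two stages, three proposals, three criticized cells).
#'
#' @param kb An `rx_kb`.
#' @param patients Named list of `rx_patient` records (the stages).
#' @param proposals Named list of proposed `rx_treatment`s.
#' @param ruleset Rule set to use; by default the recommendation rules
#'   alone (`compile_kb(kb, generics = FALSE)`), since re-prescription
#'   policing is the task of the generic rules.
#' @return A tibble with columns `stage`, `proposal`, `conforms`, `text`.
#' @export
critique_matrix <- function(kb, patients = diabetes_patients(),
                            proposals = diabetes_proposals(kb),
                            ruleset = compile_kb(kb, generics = FALSE)) {
  rows <- list()
  for (pn in names(patients)) {
    for (tn in names(proposals)) {
      r <- patients[[pn]]
      r$proposed <- proposals[[tn]]
      res <- critique(r, kb, ruleset)
      rows[[length(rows) + 1]] <- tibble::tibble(
        stage = pn, proposal = tn, conforms = res$conforms,
        text = res$composed_text)
    }
  }
  do.call(rbind, rows)
}

#' Build the full fixture set
#'
#' Loads the bundled knowledge bases, builds the worked-example patients
#' and a seeded set of random patient scenarios, and recomputes the
#' engine-derived expectations (critique matrix, verification labels). The
#' derived expectations shipped in `inst/extdata/expected.json` are
#' regenerated — never hand-maintained — and the test suite fails if the
#' committed file drifts from what this function computes.
#'
#' @param seed Seed for the random patient scenarios.
#' @return A list with elements `kbs`, `patients`, `proposals`,
#'   `random_patients`, `expected`.
#' @export
build_fixtures <- function(seed = 20101) {
  kbs <- list(diabetes = example_kb("diabetes"),
              statins = example_kb("statins"),
              generics = example_kb("generics"))
  set.seed(seed)
  random_patients <- lapply(seq_len(5), function(i)
    synth_patient(kbs$diabetes))
  list(kbs = kbs,
       patients = diabetes_patients(),
       proposals = diabetes_proposals(kbs$diabetes),
       random_patients = random_patients,
       expected = fixture_expectations(kbs))
}

#' Engine-derived fixture expectations
#'
#' @param kbs Named list of the bundled knowledge bases.
#' @return A list serializable to JSON: the diabetes critique matrix and
#'   the statin verification labels.
#' @export
fixture_expectations <- function(kbs = list(diabetes = example_kb("diabetes"),
                                            statins = example_kb("statins"))) {
  mat <- critique_matrix(kbs$diabetes)
  ds <- build_dataset(kbs$statins)
  list(
    diabetes_matrix = lapply(seq_len(nrow(mat)), function(i) as.list(mat[i, ])),
    statin_labels = lapply(seq_len(nrow(ds)), function(i) as.list(ds[i, ])))
}

#' Refresh the committed fixture expectations
#'
#' Recomputes every engine-derived expectation and writes it to
#' `expected.json` in `dir`. Run after any engine or fixture change; the
#' test suite compares the committed file against a fresh computation.
#'
#' @param dir Directory holding `expected.json` (defaults to the source
#'   `inst/extdata`).
#' @return The path written, invisibly.
#' @export
refresh_fixture_expectations <- function(dir = "inst/extdata") {
  path <- file.path(dir, "expected.json")
  jsonlite::write_json(fixture_expectations(), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

# ---- synthetic generators ---------------------------------------------------

#' Synthesize a small random knowledge base
#'
#' Generates a minimal but fully valid knowledge base for property testing:
#' `n_classes` drug classes with non-overlapping ATC prefixes, one
#' `should_prescribe` recommendation whose `n_lines` lines each hold one
#' class-level pattern, one recommendable single-drug treatment per line,
#' and distinct auto-generated criticism labels. Classes beyond `n_lines`
#' exist only as non-recommended proposals. Uses the session RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @param n_classes Number of drug classes (>= `n_lines`).
#' @param n_lines Number of treatment lines N of the recommendation.
#' @param generics Applicability value for generics #5, #6 and #8
#'   (`"not_applicable"` keeps the rule set to the recommendation alone).
#' @return A validated `rx_kb`.
#' @export
synth_kb <- function(n_classes = 4, n_lines = 2,
                     generics = "not_applicable") {
  stopifnot(n_classes >= n_lines, n_classes <= 26)
  codes <- paste0(LETTERS[seq_len(n_classes)],
                  sprintf("%02d", seq_len(n_classes)), "A")
  classes <- stats::setNames(as.list(codes),
                             paste0("class", seq_len(n_classes)))
  treatments <- stats::setNames(lapply(seq_len(n_lines), function(i)
    list(components = list(rx_drug(paste0(codes[i], "01"),
                                   paste0("drug", i))))),
    paste0("treat", seq_len(n_lines)))
  rec <- list(
    id = "ladder", type = "should_prescribe", conditions = NULL,
    lines = lapply(seq_len(n_lines), function(i)
      list(rx_pattern(components = list(rx_class_ref(paste0("class", i)))))),
    explanation_labels = c("", paste0("Line ", seq(2, n_lines + 1),
                                      " is not yet indicated.")),
    advice_labels = paste0("The guideline recommends a line ",
                           seq_len(n_lines), " treatment."),
    reference_label = "")
  rx_kb(name = paste0("synthetic-", n_classes, "c-", n_lines, "l"),
        drug_classes = classes, treatments = treatments,
        recommendations = list(rec),
        generics = list(applicability = list(`5` = generics, `6` = generics,
                                             `7` = "full", `8` = generics)))
}

#' Synthesize a random therapeutic history for a knowledge base
#'
#' Draws, for each drug class, an optional past single-drug treatment with
#' random efficacy and tolerance outcomes, with sequential non-overlapping
#' date ranges ending before the critique date. Uses the session RNG.
#'
#' @param kb An `rx_kb` (typically from [synth_kb()]).
#' @param p_include Probability that a class contributes a past treatment.
#' @param critique_date Anchor date; treatments end before it.
#' @return A list of `rx_treatment`s (possibly empty).
#' @export
synth_history <- function(kb, p_include = 0.5,
                          critique_date = as.Date("2026-01-01")) {
  history <- list()
  t0 <- critique_date - 900
  for (cn in names(kb$drug_classes)) {
    if (stats::runif(1) > p_include) next
    eff <- sample(c("ineffective", "effective", "unknown"), 1)
    tol <- sample(c("well_tolerated", "poorly_tolerated", "unknown"), 1,
                  prob = c(0.5, 0.25, 0.25))
    history[[length(history) + 1]] <- rx_treatment(
      list(rx_drug(class_member_atc(kb, cn), cn, tolerance = tol)),
      status = "past", efficacy = eff,
      start = t0, end = t0 + 60)
    t0 <- t0 + 90
  }
  history
}

#' Synthesize a random patient with a random proposal
#'
#' A random history ([synth_history()]) plus a proposed single-drug
#' treatment drawn uniformly from the knowledge base's drug classes (so
#' the proposal may or may not be a recommended treatment). Uses the
#' session RNG.
#'
#' @inheritParams synth_history
#' @return An `rx_patient` with a proposal.
#' @export
synth_patient <- function(kb, p_include = 0.5,
                          critique_date = as.Date("2026-01-01")) {
  cn <- sample(names(kb$drug_classes), 1)
  rx_patient(
    history = synth_history(kb, p_include, critique_date),
    proposed = rx_treatment(
      list(rx_drug(class_member_atc(kb, cn), cn)),
      status = "proposed"),
    critique_date = critique_date)
}

# a concrete member ATC code of a class: extend short prefixes to a full
# seven-character code, use long ones as-is (a code is a prefix of itself)
class_member_atc <- function(kb, class_name) {
  code <- kb$drug_classes[[class_name]][1]
  if (nchar(code) <= 5) paste0(code, "01") else code
}
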