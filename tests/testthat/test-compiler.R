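test_that("rule counts follow the closed forms for every recommendation type", {
  # should_prescribe: N(N+1)/2 rules over pairs (X, Y), 1<=X<=N, X+1<=Y<=N+1
  for (n in 1:5) {
    kb <- synth_kb(n_classes = max(n, 2) + 1, n_lines = n)
    rules <- compile_recommendation(kb$recommendations[[1]])
    expect_length(rules, n * (n + 1) / 2)
    xy <- t(vapply(rules, function(r) c(r$X, r$Y), integer(2)))
    expect_true(all(xy[, 1] >= 1 & xy[, 1] <= n))
    expect_true(all(xy[, 2] > xy[, 1] & xy[, 2] <= n + 1))
    expect_identical(nrow(unique(xy)), nrow(xy))
  }
  # should_not_prescribe: always exactly one rule
  snp <- list(id = "s", type = "should_not_prescribe", conditions = NULL,
              pattern = rx_pattern(components = list(rx_class_ref("class1"))),
              criticism_label = "no")
  expect_length(compile_recommendation(snp), 1)
  # increasing power with N levels: N-1 rules; N < 2 is a compile error
  ip <- function(n) list(
    id = "p", type = "increasing_power", conditions = NULL,
    levels = lapply(seq_len(n), function(i)
      list(rx_pattern(components = list(rx_class_ref(paste0("class", i)))))),
    criticism_label = "weaker than a failed treatment")
  expect_length(compile_recommendation(ip(3)), 2)
  expect_length(compile_recommendation(ip(2)), 1)
  expect_error(compile_recommendation(ip(1)), ">= 2")
})

test_that("the diabetes recommendation compiles to its three labelled rules", {
  kb <- example_kb("diabetes")
  rs <- compile_kb(kb, generics = FALSE)
  expect_length(rs$rules, 3)
  td <- tidy(rs)
  expect_identical(td$criticism[td$X == 1 & td$Y == 2],
                   paste("AGI should be prescribed only as second-line treatment.",
                         "Guideline recommends metformin as first-line treatment."))
  # label composition: rules sharing X share the advice fragment, rules
  # sharing Y share the explanation fragment
  rec <- kb$recommendations[[1]]
  for (i in seq_len(nrow(td)))
    expect_identical(td$criticism[i],
                     paste(rec$explanation_labels[td$Y[i]],
                           rec$advice_labels[td$X[i]]))
})

test_that("stage conditions partition histories over the recommendation's lines", {
  kb <- synth_kb(4, 3)
  rec <- kb$recommendations[[1]]

  eval_stage <- function(history, X) {
    r <- normalize_outcomes(rx_patient(history = history,
                                       critique_date = "2026-01-01"))
    eval_condition(stage_condition(rec, X), match_context(r, kb))
  }
  line_tx <- function(i, efficacy = "ineffective", tolerance = "unknown")
    tx(rx_drug(paste0(kb$drug_classes[[paste0("class", i)]][1], "01"),
               paste0("drug", i), tolerance = tolerance),
       status = "past", efficacy = efficacy,
       start = "2024-01-01", end = "2024-06-01")

  # no failed treatment: stage 1 only
  expect_true(eval_stage(list(), 1))
  expect_false(eval_stage(list(), 2))
  expect_false(eval_stage(list(), 3))
  # failed line 1 only: stage 2 uniquely
  expect_false(eval_stage(list(line_tx(1)), 1))
  expect_true(eval_stage(list(line_tx(1)), 2))
  expect_false(eval_stage(list(line_tx(1)), 3))
  # poor tolerance counts as failure just like inefficacy
  h_tol <- list(line_tx(1, efficacy = "unknown", tolerance = "poorly_tolerated"))
  expect_true(eval_stage(h_tol, 2))
  # failed line 2: stage 3 (no failure at >= 2 is violated for stage 2)
  expect_true(eval_stage(list(line_tx(2)), 3))
  expect_false(eval_stage(list(line_tx(2)), 2))

  # property: exactly one stage holds for random histories
  set.seed(44)
  for (i in 1:60) {
    h <- synth_history(kb)
    truths <- vapply(1:3, function(X) eval_stage(h, X), logical(1))
    expect_identical(sum(truths), 1L, info = paste("case", i))
  }
})

test_that("the two-line stage predicate reproduces the worked example", {
  kb <- example_kb("diabetes")
  rec <- kb$recommendations[[1]]
  pats <- diabetes_patients()
  st <- function(p, X)
    eval_condition(stage_condition(rec, X),
                   match_context(normalize_outcomes(p), kb))
  expect_true(st(pats$stage1, 1)); expect_false(st(pats$stage1, 2))
  expect_false(st(pats$stage2, 1)); expect_true(st(pats$stage2, 2))
})

test_that("an increasing-power rule criticizes a weaker level than one that failed", {
  kb <- rx_kb(
    name = "lipids",
    drug_classes = list(fibrate = "C10AB", statin = "C10AA"),
    treatments = list(f = list(components = list(rx_drug("C10AB05", "fenofibrate"))),
                      s = list(components = list(rx_drug("C10AA01", "simvastatin")))),
    recommendations = list(list(
      id = "power", type = "increasing_power", conditions = NULL,
      levels = list(list(rx_pattern(components = list(rx_class_ref("fibrate"), rx_any()))),
                    list(rx_pattern(components = list(rx_class_ref("statin"), rx_any())))),
      criticism_label = "A statin was already ineffective; a fibrate is weaker.")))
  rs <- compile_kb(kb, generics = FALSE)
  expect_length(rs$rules, 1)
  failed_statin <- tx(rx_drug("C10AA01", "simvastatin"), status = "past",
                      efficacy = "ineffective",
                      start = "2024-01-01", end = "2025-01-01")
  r <- rx_patient(history = list(failed_statin),
                  proposed = tx(rx_drug("C10AB05", "fenofibrate")),
                  critique_date = "2026-01-01")
  res <- critique(r, kb, rs)
  expect_false(res$conforms)
  expect_identical(res$composed_text,
                   "A statin was already ineffective; a fibrate is weaker.")
  # the converse order (statin after failed fibrate) conforms
  failed_fibrate <- tx(rx_drug("C10AB05", "fenofibrate"), status = "past",
                       efficacy = "ineffective",
                       start = "2024-01-01", end = "2025-01-01")
  r2 <- rx_patient(history = list(failed_fibrate),
                   proposed = tx(rx_drug("C10AA01", "simvastatin")),
                   critique_date = "2026-01-01")
  expect_true(critique(r2, kb, rs)$conforms)
})

test_that("generic rules follow the per-item mapping with scope and exceptions", {
  kb <- example_kb("generics")
  gr <- compile_generics(kb)
  src <- vapply(gr, function(r) r$source, character(1))
  expect_identical(sum(src == "generic1"), 1L)
  expect_identical(sum(src %in% c("generic2", "generic3", "generic4")), 3L)
  expect_identical(sum(src == "generic5"), length(kb$treatments))
  expect_identical(sum(src == "generic6"), length(kb$drug_classes))
  expect_identical(sum(src == "generic8"), length(kb$drug_classes))
  expect_length(gr, 1 + 3 + length(kb$treatments) + 2 * length(kb$drug_classes))
  # generic #7 never produces a rule: it acts through outcome normalization
  expect_false(any(vapply(gr, function(r) identical(r$generic_id, 7L),
                          logical(1))))

  # disabling ids drops their rules
  kb2 <- kb
  kb2$generics$applicability[["6"]] <- "not_applicable"
  gr2 <- compile_generics(kb2)
  expect_length(gr2, length(gr) - length(kb$drug_classes))

  # partial applicability restricts per-item generation to the scope
  kb3 <- kb
  kb3$generics$applicability[["8"]] <- "partial"
  kb3$generics$scope <- list(`8` = list("beta_blocker"))
  gr3 <- compile_generics(kb3)
  expect_identical(sum(vapply(gr3, function(r) r$source, character(1)) ==
                         "generic8"), 1L)
})

test_that("the bupropion exception removes it from the dose-increase rule's reach", {
  kb <- example_kb("generics")
  rs <- compile_kb(kb)
  poorly_tolerated_current <- function(drug)
    rx_patient(history = list(tx(drug, status = "current",
                                 start = "2025-06-01")),
               critique_date = "2026-01-01")
  fired_g4 <- function(record) {
    res <- critique(record, kb, rs)
    any(tidy(res)$source == "generic4")
  }
  # increasing the dose of poorly tolerated bupropion: exception applies,
  # because its narrow therapeutic range rules out dose adjustment advice
  r_bup <- poorly_tolerated_current(
    rx_drug("N06AX12", "bupropion", mg(150), tolerance = "poorly_tolerated"))
  r_bup$proposed <- tx(rx_drug("N06AX12", "bupropion", mg(300)))
  expect_false(fired_g4(r_bup))
  # the same situation with a beta-blocker is criticized
  r_bb <- poorly_tolerated_current(
    rx_drug("C07AB03", "atenolol", mg(50), tolerance = "poorly_tolerated"))
  r_bb$proposed <- tx(rx_drug("C07AB03", "atenolol", mg(100)))
  expect_true(fired_g4(r_bb))
})

test_that("compilation is pure and its audit dump deterministic", {
  kb <- example_kb("statins")
  d1 <- ruleset_dump(compile_kb(kb))
  d2 <- ruleset_dump(compile_kb(read_kb(system.file(
    "extdata", "statins.yaml", package = "rxcritic"))))
  expect_identical(d1, d2)
  # generics off: the three statin_choice rules plus the single prohibition
  expect_length(compile_kb(kb, generics = FALSE)$rules, 4)
})
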