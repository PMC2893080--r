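kb4 <- synth_kb(4, 2)

test_that("clinical predicates use fail-closed three-valued semantics", {
  r <- rx_patient(clinical = list(age = 80, diabetic = TRUE))
  ctx <- match_context(r, kb4)
  expect_false(eval_predicate(list(attribute = "age", op = "<", value = 75), ctx))
  expect_true(eval_predicate(list(attribute = "age", op = ">=", value = 75), ctx))
  expect_true(eval_predicate(list(attribute = "diabetic", op = "=", value = TRUE), ctx))
  expect_true(eval_predicate(list(attribute = "age", op = "in",
                                  value = c(75, 80)), ctx))
  # missing value: false, with an accumulated missing-data note
  expect_false(eval_predicate(list(attribute = "hba1c", op = "<=", value = 6.5), ctx))
  expect_identical(ctx_notes(ctx), "missing data: hba1c")
  expect_error(eval_predicate(list(attribute = "diabetic", op = "<", value = 1), ctx),
               "diabetic")
})

test_that("treatment patterns require exact cover unless a wildcard absorbs extras", {
  kb <- example_kb("diabetes")
  ctx <- blank_ctx(kb)
  pat_mono <- rx_pattern(
    components = list(rx_non_drug("diet"), rx_class_ref("oral_antidiabetic")),
    status = "proposed")
  expect_true(match_treatment(tx(diet(), metformin_drug()), pat_mono, ctx))
  # an extra drug breaks exact cover
  bi <- tx(diet(), metformin_drug(), sulfonamide_drug())
  expect_false(match_treatment(bi, pat_mono, ctx))
  # the Any wildcard absorbs the leftover component
  pat_any <- rx_pattern(
    components = list(rx_class_ref("metformin"), rx_any()))
  expect_true(match_treatment(bi, pat_any, ctx))
  expect_true(match_treatment(tx(metformin_drug()), pat_any, ctx))
  # cardinality counts drug components only: diet + 2 drugs is a bitherapy
  pat_card <- rx_pattern(components = list(rx_any()), cardinality = 1)
  expect_false(match_treatment(bi, pat_card, ctx))
  expect_true(match_treatment(tx(diet(), metformin_drug()), pat_card, ctx))
})

test_that("dose, form and tolerance constraints are enforced per component", {
  kb <- example_kb("diabetes")
  ctx <- blank_ctx(kb)
  p <- function(...) rx_pattern(components = list(rx_class_ref("metformin", ...)))
  t500 <- tx(metformin_drug(mg(500)))
  expect_true(match_treatment(t500, p(dose = list(op = "<=", value = 500, unit = "mg")), ctx))
  expect_false(match_treatment(t500, p(dose = list(op = ">", value = 500, unit = "mg")), ctx))
  # unit mismatch is a non-match, never a silent conversion
  expect_false(match_treatment(t500, p(dose = list(op = "<=", value = 1, unit = "g")), ctx))
  expect_false(match_treatment(t500, p(tolerance = "well_tolerated"), ctx))
  expect_true(match_treatment(
    tx(metformin_drug(tolerance = "well_tolerated")),
    p(tolerance = "well_tolerated"), ctx))
})

test_that("matching equals the brute-force assignment enumerator on random cases", {
  set.seed(41)
  classes <- names(kb4$drug_classes)
  codes <- unlist(kb4$drug_classes)
  rand_component <- function() {
    k <- sample(3, 1)
    if (k == 1) return(rx_non_drug(sample(c("diet", "exercise"), 1)))
    if (k == 2) return(rx_any(min = sample(0:1, 1)))
    rx_class_ref(sample(classes, 1),
                 dose = if (runif(1) < 0.4)
                   list(op = sample(c("=", "<", ">="), 1),
                        value = sample(c(100, 500), 1), unit = "mg"),
                 tolerance = if (runif(1) < 0.3)
                   sample(c("well_tolerated", "poorly_tolerated"), 1))
  }
  rand_treatment <- function() {
    n <- sample(0:4, 1)
    comps <- lapply(seq_len(n), function(i) {
      if (runif(1) < 0.25) return(rx_non_drug_component(sample(c("diet", "exercise"), 1)))
      rx_drug(paste0(sample(codes, 1), "01"), paste0("inn", i),
              dose = if (runif(1) < 0.7) mg(sample(c(100, 500, 1000), 1)),
              tolerance = sample(c("well_tolerated", "poorly_tolerated",
                                   "unknown"), 1))
    })
    status <- sample(c("past", "current", "proposed"), 1)
    rx_treatment(comps, status = status,
                 efficacy = sample(c("ineffective", "effective", "unknown"), 1),
                 start = "2024-01-01",
                 end = if (status == "past") "2025-01-01")
  }
  ctx <- blank_ctx(kb4)
  n_match <- 0
  for (i in 1:300) {
    pat <- rx_pattern(
      components = lapply(seq_len(sample(1:4, 1)), function(j) rand_component()),
      status = if (runif(1) < 0.3) sample(c("past", "proposed"), 1),
      failed = if (runif(1) < 0.2) TRUE,
      cardinality = if (runif(1) < 0.2) sample(0:2, 1))
    t <- rand_treatment()
    got <- match_treatment(t, pat, ctx)
    want <- oracle_match(t, pat, kb4)
    expect_identical(got, want, info = paste("case", i))
    n_match <- n_match + got
  }
  expect_gt(n_match, 10)  # the random cases exercise both outcomes
})

test_that("adding an unconstrained wildcard never destroys a match", {
  set.seed(42)
  kb <- example_kb("diabetes")
  ctx <- blank_ctx(kb)
  classes <- names(kb$drug_classes)
  for (i in 1:100) {
    comps <- lapply(seq_len(sample(1:3, 1)), function(j)
      rx_class_ref(sample(classes, 1)))
    pat <- rx_pattern(components = comps)
    n <- sample(1:3, 1)
    t <- rx_treatment(lapply(seq_len(n), function(j)
      rx_drug(sample(unlist(kb$drug_classes), 1), "x")),
      status = "proposed")
    if (match_treatment(t, pat, ctx)) {
      wider <- rx_pattern(components = c(comps, list(rx_any())))
      expect_true(match_treatment(t, wider, ctx))
    }
  }
})

test_that("history queries quantify existentially with status and window filters", {
  kb <- example_kb("diabetes")
  past_fail <- tx(diet(), metformin_drug(), status = "past",
                  efficacy = "ineffective",
                  start = "2024-02-01", end = "2025-02-01")
  r <- rx_patient(history = list(past_fail), critique_date = "2026-01-01")
  ctx <- match_context(r, kb)
  pat <- rx_pattern(components = list(rx_non_drug("diet"), rx_class_ref("metformin")),
                    status = "past", efficacy = "ineffective")
  expect_true(history_exists(pat, ctx))
  expect_false(history_exists(rx_pattern(
    components = list(rx_non_drug("diet"), rx_class_ref("metformin")),
    status = "current"), ctx))
  # empty history: any past-status pattern is false
  ctx0 <- blank_ctx(kb)
  expect_false(history_exists(pat, ctx0))

  # three-year recency window measured from the treatment's end date
  win <- rx_pattern(components = list(rx_non_drug("diet"), rx_class_ref("metformin")),
                    status = "past", window_years = 3)
  expect_true(history_exists(win, match_context(r, kb)))
  old <- tx(diet(), metformin_drug(), status = "past", efficacy = "ineffective",
            start = "2021-01-01", end = "2022-01-01")  # 4 years before
  r_old <- rx_patient(history = list(old), critique_date = "2026-01-01")
  expect_false(history_exists(win, match_context(r_old, kb)))
})

test_that("condition evaluation matches an independent formula evaluator", {
  expect_true(eval_condition(rx_not(rx_clinical("age", "<", 0)),
                             match_context(rx_patient(clinical = list(age = 50)),
                                           kb4)))
  set.seed(43)
  attrs <- paste0("a", 1:4)
  rand_expr <- function(depth) {
    if (depth == 0 || runif(1) < 0.4)
      return(rx_clinical(sample(attrs, 1), "=", 1))
    op <- sample(c("and", "or", "not"), 1)
    if (op == "not") return(rx_not(rand_expr(depth - 1)))
    f <- if (op == "and") rx_and else rx_or
    f(rand_expr(depth - 1), rand_expr(depth - 1))
  }
  count_leaves <- function(e) {
    if (e$op == "clinical") return(1L)
    sum(vapply(e$children, count_leaves, integer(1)))
  }
  leaf_attrs <- function(e) {
    if (e$op == "clinical") return(e$pred$attribute)
    unlist(lapply(e$children, leaf_attrs))
  }
  for (i in 1:100) {
    e <- rand_expr(3)
    vals <- stats::setNames(as.list(sample(0:1, 4, replace = TRUE)), attrs)
    ctx <- match_context(rx_patient(clinical = vals), kb4)
    leaves <- vapply(leaf_attrs(e), function(a) vals[[a]] == 1, logical(1))
    expect_identical(eval_condition(e, ctx),
                     oracle_eval_formula(e, leaves), info = paste("case", i))
    # De Morgan duality on the same expression
    if (e$op == "and" || e$op == "or") {
      dual <- if (e$op == "and")
        do.call(rx_or, lapply(e$children, rx_not))
      else do.call(rx_and, lapply(e$children, rx_not))
      expect_identical(eval_condition(rx_not(e), ctx),
                       eval_condition(dual, ctx))
    }
  }
})
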