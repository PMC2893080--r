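#' @title Compiling recommendations into "if conditions then criticism" rules
#' @description The compiler turns the declarative knowledge base into an
#'   executable rule set. A `should_not_prescribe` recommendation yields one
#'   rule; a `treatments of increasing power` recommendation with N levels
#'   yields N-1 rules; a `should_prescribe` recommendation with N lines
#'   yields N(N+1)/2 rules, one per pair (X, Y) with 1 <= X <= N and
#'   X+1 <= Y <= N+1, where X is the patient's stage and Y the line of the
#'   proposed treatment (line N+1 standing for "any other treatment").
#'   Generic recommendations add guideline-independent rules.
#' @name rule_compiler
NULL

new_rule <- function(id, source, source_type, condition, criticism,
                     X = NA_integer_, Y = NA_integer_, relaxable = FALSE,
                     generic_id = NA_integer_) {
  stopifnot(nzchar(criticism))
  list(id = id, source = source, source_type = source_type,
       generic_id = generic_id, X = X, Y = Y,
       gap = if (!is.na(X) && !is.na(Y)) Y - X else NA_integer_,
       relaxable = relaxable, condition = condition, criticism = criticism)
}

join_labels <- function(...) {
  parts <- c(...)
  paste(parts[nzchar(parts)], collapse = " ")
}

or_over <- function(conds) {
  conds <- conds[!vapply(conds, is.null, logical(1))]
  stopifnot(length(conds) >= 1)
  do.call(rx_or, conds)
}

line_exists_failed <- function(rec, lines_idx) {
  or_over(unlist(lapply(lines_idx, function(L)
    lapply(rec$lines[[L]], function(p)
      rx_therapeutic(pattern_variant(p, status = c("past", "current"),
                                     failed = TRUE)))),
    recursive = FALSE))
}

proposed_matches_line <- function(rec, Y) {
  n <- length(rec$lines)
  if (Y <= n) {
    or_over(lapply(rec$lines[[Y]], function(p)
      rx_therapeutic(pattern_variant(p, status = "proposed"))))
  } else {
    # line N+1: "any other treatment" = the proposal matches no declared line
    do.call(rx_and, unlist(lapply(seq_len(n), function(L)
      lapply(rec$lines[[L]], function(p)
        rx_not(rx_therapeutic(pattern_variant(p, status = "proposed"))))),
      recursive = FALSE))
  }
}

#' Stage-of-treatment condition
#'
#' Builds the condition under which the patient is at the stage of line `X`
#' of a `should_prescribe` recommendation, from the failure history
#' ("failed" = ineffective or poorly tolerated, after
#' [normalize_outcomes()]):
#' * `X = 1`: no failed treatment of any line in the history;
#' * `2 <= X <= N-1`: no failed treatment of line `>= X`, and a failed
#'   treatment of line `X - 1`;
#' * `X = N`: a failed treatment of line `N - 1` or `N`.
#'
#' For `N = 1` the two clauses degenerate and overlap; a single-line
#' recommendation has only one stage, so the patient is always at it and
#' the condition is vacuously true (`NULL`). A failed treatment of the
#' implicit line `N + 1` never advances the stage: the clauses quantify
#' over the recommendation's own lines only.
#'
#' @param rec A `should_prescribe` recommendation (element of
#'   `kb$recommendations`).
#' @param X Line index, `1 <= X <= N`.
#' @return An `rx_cond`.
#' @export
stage_condition <- function(rec, X) {
  stopifnot(identical(rec$type, "should_prescribe"))
  n <- length(rec$lines)
  if (X < 1 || X > n) stop("stage index out of range: ", X)
  if (n == 1) return(NULL)
  if (X == 1)
    return(rx_not(line_exists_failed(rec, seq_len(n))))
  if (X < n)
    return(rx_and(rx_not(line_exists_failed(rec, X:n)),
                  line_exists_failed(rec, X - 1)))
  line_exists_failed(rec, c(n - 1, n))
}

compile_should_prescribe <- function(rec) {
  n <- length(rec$lines)
  rules <- list()
  for (X in seq_len(n)) {
    for (Y in seq(X + 1, n + 1)) {
      cond <- rx_and(
        rec$conditions,
        stage_condition(rec, X),
        proposed_matches_line(rec, Y),
        # the proposal may match several lines (they can overlap); only the
        # lowest matching line counts, so exclude all lines below Y
        if (Y <= n && Y > 1)
          do.call(rx_and, unlist(lapply(seq_len(Y - 1), function(L)
            lapply(rec$lines[[L]], function(p)
              rx_not(rx_therapeutic(pattern_variant(p, status = "proposed"))))),
            recursive = FALSE)))
      crit <- join_labels(rec$explanation_labels[Y], rec$advice_labels[X],
                          rec$reference_label)
      rules[[length(rules) + 1]] <- new_rule(
        id = paste0(rec$id, ":X", X, "Y", Y), source = rec$id,
        source_type = "recommendation", condition = cond, criticism = crit,
        X = X, Y = Y, relaxable = Y <= n)
    }
  }
  rules
}

compile_should_not_prescribe <- function(rec) {
  cond <- rx_and(
    rec$conditions,
    rx_therapeutic(pattern_variant(rec$pattern, status = "proposed")))
  list(new_rule(id = rec$id, source = rec$id,
                source_type = "recommendation", condition = cond,
                criticism = rec$criticism_label))
}

compile_increasing_power <- function(rec) {
  n <- length(rec$levels)
  if (n < 2) stop("increasing_power recommendation needs >= 2 levels")
  # one rule per proposed level X below the top: criticize prescribing a
  # weaker level than one that was already ineffective
  lapply(seq_len(n - 1), function(X) {
    proposed_x <- or_over(lapply(rec$levels[[X]], function(p)
      rx_therapeutic(pattern_variant(p, status = "proposed"))))
    failed_higher <- or_over(unlist(lapply(seq(X + 1, n), function(Y)
      lapply(rec$levels[[Y]], function(p)
        rx_therapeutic(pattern_variant(p, status = c("past", "current"),
                                       efficacy = "ineffective")))),
      recursive = FALSE))
    new_rule(id = paste0(rec$id, ":L", X), source = rec$id,
             source_type = "recommendation",
             condition = rx_and(rec$conditions, proposed_x, failed_higher),
             criticism = rec$criticism_label, X = X)
  })
}

#' Compile one recommendation into rules
#'
#' @param rec A recommendation (element of `kb$recommendations`).
#' @param kb The owning knowledge base (currently unused; kept for
#'   interface symmetry with [compile_generics()]).
#' @return A list of rules.
#' @export
compile_recommendation <- function(rec, kb = NULL) {
  switch(rec$type,
         should_prescribe = compile_should_prescribe(rec),
         should_not_prescribe = compile_should_not_prescribe(rec),
         increasing_power = compile_increasing_power(rec),
         stop("unknown recommendation type: ", rec$type))
}

# ---- generic recommendations -----------------------------------------------

GENERIC_WINDOW_YEARS <- 3  # recency bound of generic #5

any_status_pattern <- function(status, ...) {
  rx_pattern(components = list(rx_any()), status = status, ...)
}

# pattern for "the proposal includes <entity>", entity being a drug class or
# a recommendable treatment name
includes_entity_cond <- function(entity, kb, status = "proposed") {
  if (entity %in% names(kb$drug_classes))
    rx_therapeutic(rx_pattern(
      components = list(rx_class_ref(class = entity), rx_any()),
      status = status))
  else
    rx_therapeutic(template_pattern(kb$treatments[[entity]], status = status))
}

generic_scope_cond <- function(id, kb) {
  sc <- unlist(kb$generics$scope[[as.character(id)]])
  if (is.null(sc) || length(sc) == 0) return(NULL)
  or_over(lapply(sc, includes_entity_cond, kb = kb))
}

generic_exception_cond <- function(id, kb) {
  ex <- unlist(kb$generics$exceptions[[as.character(id)]])
  if (is.null(ex) || length(ex) == 0) return(NULL)
  rx_not(or_over(lapply(ex, includes_entity_cond, kb = kb)))
}

filter_items <- function(items, id, kb) {
  sc <- unlist(kb$generics$scope[[as.character(id)]])
  ex <- unlist(kb$generics$exceptions[[as.character(id)]])
  if (!is.null(sc)) items <- intersect(items, sc)
  if (!is.null(ex)) items <- setdiff(items, ex)
  items
}

#' Compile the generic recommendations of a knowledge base
#'
#' Eight guideline-independent generic recommendations capture medical
#' knowledge that guidelines leave implicit:
#' 1. an effective, well-tolerated, guideline-conformant current treatment
#'    should be continued unchanged;
#' 2. the dose of an ineffective (but well tolerated) treatment can be
#'    increased, so a dose reduction is criticized;
#' 3. the dose of a too-effective treatment can be decreased, so a dose
#'    increase is criticized;
#' 4. the dose of a poorly tolerated drug can be decreased, so a dose
#'    increase is criticized;
#' 5. a treatment ineffective in the recent past (last three years) and not
#'    prescribed again since should not be re-prescribed — one rule per
#'    recommendable treatment;
#' 6. a drug class poorly tolerated in the past and stopped should not be
#'    re-prescribed — one rule per drug class;
#' 7. a treatment both ineffective and poorly tolerated follows the
#'    poor-tolerance pathway — produces no rule; it is applied by
#'    [normalize_outcomes()] before matching;
#' 8. two drugs of the same pharmaco-therapeutic class should not be
#'    prescribed in association — one rule per drug class.
#'
#' Rules are omitted for ids marked `not_applicable`; `partial`
#' applicability restricts a rule to the KB-configured `scope`; entities in
#' `exceptions` are excluded from their rule's reach (e.g. a drug whose dose
#' cannot be lowered because of a narrow therapeutic range).
#'
#' @param kb An `rx_kb`.
#' @return A list of rules.
#' @export
compile_generics <- function(kb) {
  app <- kb$generics$applicability
  active <- function(id) !identical(app[[as.character(id)]], "not_applicable")
  rules <- list()
  add <- function(r) rules[[length(rules) + 1]] <<- r
  guard <- function(id, cond) {
    rx_and(cond, generic_scope_cond(id, kb), generic_exception_cond(id, kb))
  }

  if (active(1)) {
    conforms <- or_over(lapply(kb$treatments, function(tmpl)
      rx_therapeutic(template_pattern(tmpl, status = "current"))))
    cond <- rx_and(
      conforms,
      rx_therapeutic(any_status_pattern("current", efficacy = "effective",
                                        all_well_tolerated = TRUE)),
      rx_therapeutic(any_status_pattern("proposed",
                                        changes_any = RX_CHANGES)))
    add(new_rule("generic1", "generic1", "generic", guard(1, cond),
                 "The current treatment is effective, well tolerated and conforms to the guideline; it should be continued unchanged.",
                 generic_id = 1L))
  }
  if (active(2)) {
    cond <- rx_and(
      rx_therapeutic(any_status_pattern("current", efficacy = "ineffective",
                                        all_well_tolerated = TRUE)),
      rx_therapeutic(any_status_pattern("proposed",
                                        changes_any = "dose_decrease")))
    add(new_rule("generic2", "generic2", "generic", guard(2, cond),
                 "The current treatment is ineffective but well tolerated; its dose can be increased, so a dose reduction is not recommended.",
                 generic_id = 2L))
  }
  if (active(3)) {
    cond <- rx_and(
      rx_therapeutic(any_status_pattern("current",
                                        efficacy = "too_effective")),
      rx_therapeutic(any_status_pattern("proposed",
                                        changes_any = "dose_increase")))
    add(new_rule("generic3", "generic3", "generic", guard(3, cond),
                 "The current treatment is too effective; its dose can be decreased, so a dose increase is not recommended.",
                 generic_id = 3L))
  }
  if (active(4)) {
    cond <- rx_and(
      rx_therapeutic(any_status_pattern("current",
                                        any_poor_tolerance = TRUE)),
      rx_therapeutic(any_status_pattern("proposed",
                                        changes_any = "dose_increase")))
    add(new_rule("generic4", "generic4", "generic", guard(4, cond),
                 "A drug of the current treatment is poorly tolerated; its dose can be decreased, so a dose increase is not recommended.",
                 generic_id = 4L))
  }
  if (active(5)) {
    for (tn in filter_items(names(kb$treatments), 5, kb)) {
      cond <- rx_special("no_represcription_ineffective",
                         list(treatment = tn,
                              window_years = GENERIC_WINDOW_YEARS))
      add(new_rule(paste0("generic5:", tn), "generic5", "generic", cond,
                   paste0("Treatment '", tn,
                          "' was ineffective in the recent past and should not be prescribed again."),
                   generic_id = 5L))
    }
  }
  if (active(6)) {
    for (cn in filter_items(names(kb$drug_classes), 6, kb)) {
      cond <- rx_special("no_represcription_intolerance", list(class = cn))
      add(new_rule(paste0("generic6:", cn), "generic6", "generic", cond,
                   paste0("A drug of class '", cn,
                          "' was poorly tolerated in the past and should not be prescribed again."),
                   generic_id = 6L))
    }
  }
  if (active(8)) {
    for (cn in filter_items(names(kb$drug_classes), 8, kb)) {
      cond <- rx_therapeutic(rx_pattern(
        components = list(rx_class_ref(class = cn), rx_class_ref(class = cn),
                          rx_any()),
        status = "proposed"))
      add(new_rule(paste0("generic8:", cn), "generic8", "generic", cond,
                   paste0("Two drugs of the class '", cn,
                          "' should not be prescribed in association."),
                   generic_id = 8L))
    }
  }
  rules
}

#' Compile a knowledge base into an executable rule set
#'
#' Concatenates, in deterministic order, the rules generated from every
#' recommendation (recommendation order, then (X, Y) lexicographic) and from
#' the applicable generic recommendations (generic id, then declaration
#' order of the per-item entities). Compilation is pure: the same knowledge
#' base yields a byte-identical rule dump (see [ruleset_dump()]).
#'
#' @param kb An `rx_kb`.
#' @param generics Include the generic-recommendation rules? Disable to
#'   study a recommendation in isolation.
#' @return An object of class `rx_ruleset`.
#' @export
compile_kb <- function(kb, generics = TRUE) {
  rules <- unlist(lapply(kb$recommendations, compile_recommendation, kb = kb),
                  recursive = FALSE)
  if (generics) rules <- c(rules, compile_generics(kb))
  ns <- vapply(kb$recommendations, function(r)
    if (r$type == "should_prescribe") length(r$lines) else 1L, integer(1))
  structure(list(rules = rules, kb_name = kb$name,
                 kmax = max(0L, max(ns) - 1L)),
            class = "rx_ruleset")
}

#' Serializable audit dump of a rule set
#'
#' JSON rendering of every rule with its full condition tree, criticism
#' text and (source, X, Y) provenance tags. Deterministic, so equal
#' knowledge bases give byte-identical dumps.
#'
#' @param ruleset An `rx_ruleset`.
#' @return A JSON string.
#' @export
ruleset_dump <- function(ruleset) {
  as.character(jsonlite::toJSON(
    lapply(ruleset$rules, function(r)
      drop_null(list(
        id = r$id, source = r$source, source_type = r$source_type,
        generic_id = if (!is.na(r$generic_id)) r$generic_id,
        X = if (!is.na(r$X)) r$X, Y = if (!is.na(r$Y)) r$Y,
        relaxable = r$relaxable,
        condition = cond_to_list(r$condition),
        criticism = r$criticism))),
    auto_unbox = TRUE, pretty = TRUE))
}

#' @export
print.rx_ruleset <- function(x, ...) {
  cat("<rx_ruleset> compiled from '", x$kb_name, "': ",
      length(x$rules), " rules (k_max = ", x$kmax, ")\n", sep = "")
  invisible(x)
}

#' Number of rules in a rule set
#' @param x An `rx_ruleset`.
#' @export
length.rx_ruleset <- function(x) length(x$rules)
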