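#' Match context
#'
#' Bundles the enriched patient record and the knowledge base for condition
#' evaluation, and accumulates missing-data notes as a side channel (a
#' missing attribute value evaluates to `FALSE`, fail-closed, with a note).
#'
#' @param record An enriched `rx_patient` (see [enrich()]).
#' @param kb An `rx_kb`.
#' @return An environment of class `rx_ctx`.
#' @export
match_context <- function(record, kb) {
  ctx <- new.env(parent = emptyenv())
  ctx$record <- record
  ctx$kb <- kb
  ctx$notes <- character()
  class(ctx) <- "rx_ctx"
  ctx
}

#' Missing-data notes accumulated during evaluation
#' @param ctx An `rx_ctx`.
#' @return Character vector of notes.
#' @export
ctx_notes <- function(ctx) ctx$notes

#' Evaluate a clinical predicate
#'
#' Standard comparison semantics over the record's clinical and biological
#' attribute values. A missing value yields `FALSE` (fail-closed) and a
#' missing-data note in the context; a type mismatch is an error naming the
#' attribute.
#'
#' @param pred A predicate `list(attribute, op, value)` (as inside
#'   [rx_clinical()]).
#' @param ctx An [match_context()].
#' @return Logical scalar.
#' @export
eval_predicate <- function(pred, ctx) {
  a <- pred$attribute
  v <- ctx$record$clinical[[a]]
  if (is.null(v)) v <- ctx$record$biological[[a]]
  if (is.null(v)) {
    ctx$notes <- union(ctx$notes, paste0("missing data: ", a))
    return(FALSE)
  }
  if (pred$op %in% c("<", "<=", ">", ">=") &&
      (!is.numeric(v) || !is.numeric(pred$value)))
    stop("type mismatch evaluating attribute `", a,
         "`: ordered comparison needs numeric values")
  switch(pred$op,
         "="  = isTRUE(v == pred$value),
         "!=" = isTRUE(v != pred$value),
         "<"  = v <  pred$value,
         "<=" = v <= pred$value,
         ">"  = v >  pred$value,
         ">=" = v >= pred$value,
         "in" = v %in% unlist(pred$value))
}

resolve_codes <- function(comp, kb) {
  if (!is.null(comp$codes)) return(comp$codes)
  codes <- kb$drug_classes[[comp$class]]
  if (is.null(codes)) stop("unknown drug class: ", comp$class)
  codes
}

component_matches <- function(pc, tc, kb) {
  if (pc$kind == "non_drug")
    return(identical(tc$kind, "non_drug") && identical(tc$name, pc$name))
  if (pc$kind != "class") return(FALSE)
  if (!identical(tc$kind, "drug")) return(FALSE)
  if (!any(startsWith(tc$atc, resolve_codes(pc, kb)))) return(FALSE)
  if (!is.null(pc$dose)) {
    d <- tc$dose
    if (is.null(d)) return(FALSE)
    k <- pc$dose
    if (!identical(d$unit, k$unit)) return(FALSE)  # no unit conversion
    if (!is.null(k$per) && !identical(d$per, k$per)) return(FALSE)
    ok <- switch(k$op,
                 "="  = d$value == k$value, "!=" = d$value != k$value,
                 "<"  = d$value <  k$value, "<=" = d$value <= k$value,
                 ">"  = d$value >  k$value, ">=" = d$value >= k$value)
    if (!isTRUE(ok)) return(FALSE)
  }
  if (!is.null(pc$form) && !identical(tc$form, pc$form)) return(FALSE)
  if (!is.null(pc$tolerance) && !identical(tc$tolerance, pc$tolerance))
    return(FALSE)
  TRUE
}

#' Match a treatment against a treatment pattern
#'
#' True iff an injective assignment maps every non-wildcard component
#' pattern to a distinct treatment component satisfying its class
#' (ATC-prefix), dose, form and tolerance constraints, the leftover
#' components are absorbed by wildcards within their repeat bounds (a
#' pattern without wildcards must cover the treatment exactly), and the
#' pattern's status, efficacy, failure, tolerance-summary, change,
#' cardinality and time-window constraints are all satisfied.
#'
#' @param treatment An `rx_treatment`.
#' @param pattern An `rx_pattern`.
#' @param ctx An [match_context()] (supplies the drug-class dictionary and
#'   the critique date for time windows).
#' @return Logical scalar.
#' @export
match_treatment <- function(treatment, pattern, ctx) {
  t <- treatment; pat <- pattern; kb <- ctx$kb
  if (!is.null(pat$status) && !t$status %in% pat$status) return(FALSE)
  if (!is.null(pat$efficacy) && !identical(t$efficacy, pat$efficacy))
    return(FALSE)
  if (isTRUE(pat$failed) && !treatment_failed(t)) return(FALSE)
  drugs <- drug_components(t)
  if (isTRUE(pat$all_well_tolerated)) {
    if (length(drugs) == 0) return(FALSE)
    if (!all(vapply(drugs, function(d)
      identical(d$tolerance, "well_tolerated"), logical(1)))) return(FALSE)
  }
  if (isTRUE(pat$any_poor_tolerance) &&
      !any(vapply(drugs, function(d)
        identical(d$tolerance, "poorly_tolerated"), logical(1))))
    return(FALSE)
  if (!is.null(pat$cardinality) && length(drugs) != pat$cardinality)
    return(FALSE)
  if (!is.null(pat$changes_any) && !any(pat$changes_any %in% t$changes))
    return(FALSE)
  if (!is.null(pat$window_years) && t$status == "past") {
    if (is.null(t$end)) return(FALSE)
    if (as.numeric(ctx$record$critique_date - t$end) >
        pat$window_years * 365.25) return(FALSE)
  }
  components_cover(pat$components, t$components, kb)
}

# exact-cover component assignment: every fixed component pattern claims a
# distinct treatment component; wildcards absorb the rest within bounds
components_cover <- function(pcomps, tcomps, kb) {
  fixed <- Filter(function(c) c$kind != "any", pcomps)
  wild  <- Filter(function(c) c$kind == "any", pcomps)
  n <- length(tcomps)
  leftover_ok <- function(r) {
    if (length(wild) == 0) return(r == 0)
    mins <- sum(vapply(wild, function(w) w$min, numeric(1)))
    maxs <- sum(vapply(wild, function(w) w$max, numeric(1)))
    r >= mins && r <= maxs
  }
  if (length(fixed) > n) return(FALSE)
  if (!leftover_ok(n - length(fixed))) return(FALSE)
  assign_rec <- function(i, used) {
    if (i > length(fixed)) return(TRUE)
    for (j in seq_len(n)) {
      if (used[j]) next
      if (component_matches(fixed[[i]], tcomps[[j]], kb)) {
        used[j] <- TRUE
        if (assign_rec(i + 1, used)) return(TRUE)
        used[j] <- FALSE
      }
    }
    FALSE
  }
  assign_rec(1, rep(FALSE, n))
}

#' Existential pattern query over the therapeutic history
#'
#' True iff at least one treatment among the history, the current treatment
#' and the proposed prescription — filtered by the pattern's status
#' constraint — matches the pattern. A pattern without a status constraint
#' quantifies over all three.
#'
#' @param pattern An `rx_pattern`.
#' @param ctx An [match_context()].
#' @return Logical scalar.
#' @export
history_exists <- function(pattern, ctx) {
  pool <- ctx$record$history
  if (!is.null(ctx$record$proposed))
    pool <- c(pool, list(ctx$record$proposed))
  if (!is.null(pattern$status))
    pool <- Filter(function(t) t$status %in% pattern$status, pool)
  for (t in pool) if (match_treatment(t, pattern, ctx)) return(TRUE)
  FALSE
}

#' Evaluate a condition expression
#'
#' Recursive boolean evaluation of nested AND/OR/NOT expressions over
#' clinical predicates and therapeutic (treatment-pattern) queries.
#' Short-circuiting is used, but the result is identical to full evaluation.
#'
#' @param cond An `rx_cond` (or `NULL`, which is vacuously `TRUE`).
#' @param ctx An [match_context()].
#' @return Logical scalar.
#' @export
eval_condition <- function(cond, ctx) {
  if (is.null(cond)) return(TRUE)
  switch(cond$op,
    and = {
      for (k in cond$children) if (!eval_condition(k, ctx)) return(FALSE)
      TRUE
    },
    or = {
      for (k in cond$children) if (eval_condition(k, ctx)) return(TRUE)
      FALSE
    },
    not = !eval_condition(cond$children[[1]], ctx),
    clinical = eval_predicate(cond$pred, ctx),
    therapeutic = history_exists(cond$pattern, ctx),
    special = eval_special(cond, ctx),
    stop("unknown condition node: ", cond$op))
}

# Sequence-sensitive generic-recommendation predicates (#5 and #6), which
# quantify over pairs of history treatments and so do not reduce to a single
# existential pattern query.
eval_special <- function(cond, ctx) {
  switch(cond$special,
    no_represcription_ineffective =
      special_represcription_ineffective(cond$args, ctx),
    no_represcription_intolerance =
      special_represcription_intolerance(cond$args, ctx),
    stop("unknown special predicate: ", cond$special))
}

# generic #5: the proposal is recommendable treatment T, and the history
# holds an ineffective T that ended within the last `window_years` years and
# was not followed by another T
special_represcription_ineffective <- function(args, ctx) {
  kb <- ctx$kb
  tmpl <- kb$treatments[[args$treatment]]
  pat <- template_pattern(tmpl)
  prop <- ctx$record$proposed
  if (is.null(prop) ||
      !match_treatment(prop, pattern_variant(pat, status = "proposed"), ctx))
    return(FALSE)
  hist <- ctx$record$history
  win <- args$window_years * 365.25
  for (i in seq_along(hist)) {
    h <- hist[[i]]
    if (h$status != "past") next
    if (!identical(h$efficacy, "ineffective")) next
    if (is.null(h$end) ||
        as.numeric(ctx$record$critique_date - h$end) > win) next
    if (!match_treatment(h, pat, ctx)) next
    followed <- FALSE
    for (j in seq_along(hist)) {       # history is start-date ordered
      if (j <= i) next
      if (match_treatment(hist[[j]], pat, ctx)) { followed <- TRUE; break }
    }
    if (!followed) return(TRUE)
  }
  FALSE
}

# generic #6: the proposal includes a drug of class C, and the history holds
# a past treatment with a poorly tolerated drug of C that was followed by a
# treatment not including any drug of C (i.e. the class was stopped)
special_represcription_intolerance <- function(args, ctx) {
  kb <- ctx$kb
  class_pat <- function(...) rx_pattern(
    components = list(rx_class_ref(class = args$class, ...), rx_any()))
  prop <- ctx$record$proposed
  if (is.null(prop) ||
      !match_treatment(prop, pattern_variant(class_pat(), status = "proposed"),
                       ctx))
    return(FALSE)
  poorly <- class_pat(tolerance = "poorly_tolerated")
  hist <- ctx$record$history
  for (i in seq_along(hist)) {
    h <- hist[[i]]
    if (h$status != "past") next
    if (!match_treatment(h, poorly, ctx)) next
    for (j in seq_along(hist)) {
      if (j <= i) next
      if (!match_treatment(hist[[j]], class_pat(), ctx)) return(TRUE)
    }
  }
  FALSE
}

# exact-match pattern for a recommendable treatment template: same component
# set, same doses, no extras
template_pattern <- function(tmpl, status = NULL) {
  comps <- lapply(tmpl$components, function(c) {
    if (c$kind == "non_drug") return(rx_non_drug(c$name))
    dose <- if (!is.null(c$dose))
      list(op = "=", value = c$dose$value, unit = c$dose$unit, per = c$dose$per)
    rx_class_ref(codes = c$atc, dose = dose, form = c$form)
  })
  rx_pattern(components = comps, status = status)
}

# concrete treatment instantiated from a recommendable treatment template
template_treatment <- function(tmpl, status = "proposed") {
  rx_treatment(components = tmpl$components, status = status)
}
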