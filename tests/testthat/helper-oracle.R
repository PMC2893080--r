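# Independent oracles kept deliberately separate from the package internals:
# a brute-force pattern matcher (explicit enumeration of all injective
# component assignments), a truth-table evaluator for condition expressions,
# and a direct interpreter of should_prescribe recommendations.

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in all_permutations(x[-i]))
      out <- c(out, list(c(x[i], p)))
  out
}

oracle_component_matches <- function(pc, tc, kb) {
  if (pc$kind == "non_drug")
    return(identical(tc$kind, "non_drug") && identical(tc$name, pc$name))
  if (!identical(tc$kind, "drug")) return(FALSE)
  codes <- if (!is.null(pc$codes)) pc$codes else kb$drug_classes[[pc$class]]
  if (!any(startsWith(tc$atc, codes))) return(FALSE)
  if (!is.null(pc$dose)) {
    d <- tc$dose; k <- pc$dose
    if (is.null(d) || !identical(d$unit, k$unit)) return(FALSE)
    if (!is.null(k$per) && !identical(d$per, k$per)) return(FALSE)
    cmp <- switch(k$op, "=" = `==`, "!=" = `!=`, "<" = `<`, "<=" = `<=`,
                  ">" = `>`, ">=" = `>=`)
    if (!cmp(d$value, k$value)) return(FALSE)
  }
  if (!is.null(pc$form) && !identical(tc$form, pc$form)) return(FALSE)
  if (!is.null(pc$tolerance) && !identical(tc$tolerance, pc$tolerance))
    return(FALSE)
  TRUE
}

# enumerates every subset + permutation assignment of treatment components
# to the fixed (non-wildcard) component patterns
oracle_match <- function(treatment, pat, kb, critique_date = "2026-01-01") {
  t <- treatment
  if (!is.null(pat$status) && !t$status %in% pat$status) return(FALSE)
  if (!is.null(pat$efficacy) && !identical(t$efficacy, pat$efficacy))
    return(FALSE)
  drugs <- Filter(function(c) c$kind == "drug", t$components)
  tol <- vapply(drugs, function(d) d$tolerance, character(1))
  if (isTRUE(pat$failed) &&
      !(t$efficacy == "ineffective" || any(tol == "poorly_tolerated")))
    return(FALSE)
  if (isTRUE(pat$all_well_tolerated) &&
      !(length(drugs) > 0 && all(tol == "well_tolerated"))) return(FALSE)
  if (isTRUE(pat$any_poor_tolerance) && !any(tol == "poorly_tolerated"))
    return(FALSE)
  if (!is.null(pat$cardinality) && length(drugs) != pat$cardinality)
    return(FALSE)
  if (!is.null(pat$changes_any) && !any(pat$changes_any %in% t$changes))
    return(FALSE)
  if (!is.null(pat$window_years) && t$status == "past") {
    if (is.null(t$end)) return(FALSE)
    if (as.numeric(as.Date(critique_date) - t$end) >
        pat$window_years * 365.25) return(FALSE)
  }
  fixed <- Filter(function(c) c$kind != "any", pat$components)
  wild <- Filter(function(c) c$kind == "any", pat$components)
  n <- length(t$components); m <- length(fixed)
  leftover_ok <- function(r) {
    if (length(wild) == 0) return(r == 0)
    r >= sum(vapply(wild, function(w) w$min, numeric(1))) &&
      r <= sum(vapply(wild, function(w) w$max, numeric(1)))
  }
  if (m > n || !leftover_ok(n - m)) return(FALSE)
  if (m == 0) return(TRUE)
  subsets <- utils::combn(n, m, simplify = FALSE)
  for (s in subsets) {
    for (perm in all_permutations(s)) {
      ok <- TRUE
      for (i in seq_len(m)) {
        if (!oracle_component_matches(fixed[[i]], t$components[[perm[i]]],
                                      kb)) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
  }
  FALSE
}

# independent recursive evaluation of a condition expression given fixed
# leaf truth values (leaves identified by order of appearance)
oracle_eval_formula <- function(cond, leaf_values) {
  i <- 0
  rec <- function(node) {
    if (node$op %in% c("clinical", "therapeutic", "special")) {
      i <<- i + 1
      return(unname(leaf_values[i]))
    }
    switch(node$op,
           and = all(vapply(node$children, rec, logical(1))),
           or = any(vapply(node$children, rec, logical(1))),
           not = !rec(node$children[[1]]))
  }
  rec(cond)
}

# direct interpreter of the single should_prescribe recommendation of a
# synth_kb() knowledge base (single-class single-component line patterns,
# single-drug treatments); no use of the rule compiler or the matcher
interpret_ladder <- function(kb, record) {
  rec <- kb$recommendations[[1]]
  n <- length(rec$lines)
  codes <- vapply(seq_len(n), function(i)
    kb$drug_classes[[paste0("class", i)]][1], character(1))
  line_of <- function(t) {
    if (length(t$components) != 1) return(NA_integer_)
    c <- t$components[[1]]
    if (!identical(c$kind, "drug")) return(NA_integer_)
    hits <- which(startsWith(c$atc, codes))
    if (length(hits)) min(hits) else NA_integer_
  }
  failed <- function(t) {
    t$efficacy == "ineffective" ||
      any(vapply(t$components, function(c)
        identical(c$kind, "drug") &&
          identical(c$tolerance, "poorly_tolerated"), logical(1)))
  }
  fl <- integer()
  for (t in record$history)
    if (t$status %in% c("past", "current") && failed(t)) {
      l <- line_of(t)
      if (!is.na(l)) fl <- union(fl, l)
    }
  stages <- vapply(seq_len(n), function(X) {
    if (n == 1) return(TRUE)   # a one-line ladder has a single stage
    if (X == 1) return(length(fl) == 0)
    if (X < n) return(!any(fl >= X) && (X - 1) %in% fl)
    any(fl %in% c(n - 1, n))
  }, logical(1))
  stopifnot(sum(stages) == 1)
  X <- which(stages)
  Yl <- line_of(record$proposed)
  Y <- if (is.na(Yl)) n + 1L else Yl
  if (Y <= X) return(list(conforms = TRUE, text = ""))
  list(conforms = FALSE,
       text = paste(rec$explanation_labels[Y], rec$advice_labels[X]))
}
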