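#' @title Treatment patterns and condition expressions
#' @description Constructors for the building blocks of the knowledge base:
#'   component patterns, treatment patterns (granularity-flexible queries over
#'   treatments), clinical predicates, and nested boolean condition
#'   expressions. Patterns are queries, never concrete treatments; concrete
#'   treatments are built with [rx_treatment()].
#' @name rx_pattern_types
NULL

RX_STATUSES   <- c("past", "current", "proposed")
RX_EFFICACIES <- c("ineffective", "effective", "too_effective", "unknown")
RX_TOLERANCES <- c("well_tolerated", "poorly_tolerated", "unknown")
RX_CHANGES    <- c("dose_increase", "dose_decrease", "form_change", "inn_change")
RX_OPERATORS  <- c("=", "!=", "<", "<=", ">", ">=", "in")

#' Component pattern referring to a drug class
#'
#' A drug matches if any of the class's ATC codes is a prefix of the drug's
#' full ATC code (the ATC classification is hierarchical, so a class may be
#' declared at any level).
#'
#' @param class Name of a drug class declared in the knowledge base. Ignored
#'   when `codes` is given.
#' @param dose Optional dose constraint: `list(op, value, unit)` with `op` one
#'   of `=`, `!=`, `<`, `<=`, `>`, `>=`. Units must match the treatment's dose
#'   unit exactly; no unit conversion is performed.
#' @param form Optional pharmaceutical form code that must match exactly.
#' @param tolerance Optional required tolerance, `"well_tolerated"` or
#'   `"poorly_tolerated"`. An `"unknown"` tolerance never satisfies the
#'   constraint.
#' @param codes Optional explicit ATC code prefixes, bypassing the class
#'   dictionary (used when matching against a concrete treatment template).
#' @return A component pattern (plain list, kind `"class"`).
#' @export
rx_class_ref <- function(class = NULL, dose = NULL, form = NULL,
                         tolerance = NULL, codes = NULL) {
  if (is.null(class) && is.null(codes))
    stop("rx_class_ref(): one of `class` or `codes` is required")
  if (!is.null(tolerance))
    tolerance <- match.arg(tolerance, c("well_tolerated", "poorly_tolerated"))
  if (!is.null(dose)) dose <- check_dose_constraint(dose)
  list(kind = "class", class = class, codes = codes, dose = dose,
       form = form, tolerance = tolerance)
}

check_dose_constraint <- function(dose) {
  stopifnot(is.list(dose), !is.null(dose$op), !is.null(dose$value),
            !is.null(dose$unit))
  if (!dose$op %in% setdiff(RX_OPERATORS, "in"))
    stop("invalid dose comparator: ", dose$op)
  dose
}

#' Component pattern for a non-drug component (e.g. diet)
#' @param name Identifier of the non-drug component.
#' @return A component pattern (kind `"non_drug"`).
#' @export
rx_non_drug <- function(name) list(kind = "non_drug", name = name)

#' Wildcard component pattern
#'
#' Absorbs zero, one or more additional treatment components that are not
#' claimed by any other component pattern. A wildcard carries no dose, form or
#' tolerance constraint. A pattern without any wildcard matches only
#' treatments whose components are covered exactly.
#'
#' @param min,max Repeat bounds on the number of components absorbed.
#' @return A component pattern (kind `"any"`).
#' @export
rx_any <- function(min = 0, max = Inf) {
  stopifnot(min >= 0, max >= min)
  list(kind = "any", min = min, max = max)
}

#' Treatment pattern: a granularity-flexible query over treatments
#'
#' A treatment pattern matches a concrete treatment when an injective
#' assignment maps every non-wildcard component pattern to a distinct
#' treatment component satisfying its class/dose/form/tolerance constraints,
#' leftover components are absorbed by wildcards within their repeat bounds,
#' and all treatment-level constraints hold. Patterns can express treatments
#' at any granularity, from "diet + metformin 500 mg" down to "any bitherapy".
#'
#' @param components List of component patterns ([rx_class_ref()],
#'   [rx_non_drug()], [rx_any()]).
#' @param status Optional status filter; one or more of `"past"`,
#'   `"current"`, `"proposed"`. A pattern without a status constraint matches
#'   treatments of every status.
#' @param efficacy Optional required efficacy (`"ineffective"`, `"effective"`,
#'   `"too_effective"`). `"unknown"` never satisfies the constraint.
#' @param failed If `TRUE`, the treatment must have failed: be ineffective or
#'   contain a poorly tolerated drug.
#' @param all_well_tolerated If `TRUE`, every drug component must be
#'   explicitly well tolerated.
#' @param any_poor_tolerance If `TRUE`, at least one drug component must be
#'   poorly tolerated.
#' @param changes_any Optional character vector of change flags
#'   (`"dose_increase"`, `"dose_decrease"`, `"form_change"`, `"inn_change"`);
#'   the treatment must carry at least one of them (computed by [enrich()]
#'   relative to the current treatment).
#' @param cardinality Optional exact number of *drug* components (non-drug
#'   components such as diet are not counted), capturing
#'   "monotherapy"/"bitherapy".
#' @param window_years Optional recency bound: a past treatment matches only
#'   if it ended within this many years of the critique date. Current and
#'   proposed treatments are always within the window.
#' @return An object of class `rx_pattern`.
#' @export
rx_pattern <- function(components = list(rx_any()), status = NULL,
                       efficacy = NULL, failed = NULL,
                       all_well_tolerated = NULL, any_poor_tolerance = NULL,
                       changes_any = NULL, cardinality = NULL,
                       window_years = NULL) {
  if (!is.null(status)) {
    status <- unname(status)
    stopifnot(all(status %in% RX_STATUSES))
  }
  if (!is.null(efficacy))
    efficacy <- match.arg(efficacy, setdiff(RX_EFFICACIES, "unknown"))
  if (!is.null(changes_any)) stopifnot(all(changes_any %in% RX_CHANGES))
  if (length(components) == 0 && is.null(cardinality))
    stop("a treatment pattern needs components or a cardinality constraint")
  structure(
    list(components = components, status = status, efficacy = efficacy,
         failed = failed, all_well_tolerated = all_well_tolerated,
         any_poor_tolerance = any_poor_tolerance, changes_any = changes_any,
         cardinality = cardinality, window_years = window_years),
    class = "rx_pattern")
}

pattern_variant <- function(pat, ...) {
  over <- list(...)
  for (nm in names(over)) pat[[nm]] <- over[[nm]]
  pat
}

#' Clinical predicate leaf
#' @param attribute Attribute identifier declared in the knowledge base.
#' @param op Comparison operator: `=`, `!=`, `<`, `<=`, `>`, `>=`, `in`.
#' @param value Scalar (or set, for `in`) to compare against.
#' @return A condition expression of class `rx_cond`.
#' @export
rx_clinical <- function(attribute, op, value) {
  op <- match.arg(op, RX_OPERATORS)
  structure(list(op = "clinical",
                 pred = list(attribute = attribute, op = op, value = value)),
            class = "rx_cond")
}

#' Therapeutic leaf: existential query over the therapeutic history
#'
#' True iff at least one treatment among the history, the current treatment
#' and the proposed prescription (filtered by the pattern's status
#' constraint) matches the pattern.
#'
#' @param pattern An [rx_pattern()].
#' @return A condition expression of class `rx_cond`.
#' @export
rx_therapeutic <- function(pattern) {
  stopifnot(inherits(pattern, "rx_pattern"))
  structure(list(op = "therapeutic", pattern = pattern), class = "rx_cond")
}

rx_special <- function(name, args) {
  structure(list(op = "special", special = name, args = args),
            class = "rx_cond")
}

#' Boolean combinators for condition expressions
#'
#' `rx_and()` and `rx_or()` take two or more sub-expressions; `rx_not()` takes
#' exactly one. Combinators can be nested without limit.
#'
#' @param ... Condition expressions (`rx_cond` objects).
#' @return A condition expression of class `rx_cond`.
#' @export
rx_and <- function(...) {
  kids <- compact_conds(list(...))
  if (length(kids) == 1) return(kids[[1]])
  stopifnot(length(kids) >= 2)
  structure(list(op = "and", children = kids), class = "rx_cond")
}

#' @rdname rx_and
#' @export
rx_or <- function(...) {
  kids <- compact_conds(list(...))
  if (length(kids) == 1) return(kids[[1]])
  stopifnot(length(kids) >= 2)
  structure(list(op = "or", children = kids), class = "rx_cond")
}

#' @rdname rx_and
#' @param x A single condition expression.
#' @export
rx_not <- function(x) {
  stopifnot(inherits(x, "rx_cond"))
  structure(list(op = "not", children = list(x)), class = "rx_cond")
}

compact_conds <- function(xs) {
  xs <- xs[!vapply(xs, is.null, logical(1))]
  # splice plain lists of conditions
  out <- list()
  for (x in xs) {
    if (inherits(x, "rx_cond")) out <- c(out, list(x))
    else if (is.list(x)) out <- c(out, compact_conds(x))
    else stop("not a condition expression")
  }
  lapply(out, function(k) { stopifnot(inherits(k, "rx_cond")); k })
}

#' Concrete drug line of a treatment
#' @param atc Full ATC code of the drug (1-7 alphanumeric characters,
#'   upper case).
#' @param inn International Nonproprietary Name.
#' @param dose Optional `list(value, unit, per)` with `per` one of `"day"` or
#'   `"intake"`; `value` must be positive.
#' @param form Optional pharmaceutical form code.
#' @param tolerance Tolerance outcome for this drug, as reported by the
#'   physician; defaults to `"unknown"`.
#' @return A concrete treatment component (kind `"drug"`).
#' @export
rx_drug <- function(atc, inn, dose = NULL, form = NULL,
                    tolerance = "unknown") {
  stopifnot(grepl("^[A-Z][0-9A-Z]{0,6}$", atc))
  tolerance <- match.arg(tolerance, RX_TOLERANCES)
  if (!is.null(dose)) {
    stopifnot(is.list(dose), !is.null(dose$value), !is.null(dose$unit),
              dose$value > 0)
    if (is.null(dose$per)) dose$per <- "day"
  }
  list(kind = "drug", atc = atc, inn = inn, dose = dose, form = form,
       tolerance = tolerance)
}

#' Concrete non-drug component of a treatment (e.g. diet)
#' @param name Identifier of the non-drug component.
#' @return A concrete treatment component (kind `"non_drug"`).
#' @export
rx_non_drug_component <- function(name) list(kind = "non_drug", name = name)

#' Concrete treatment
#'
#' @param components List of concrete components ([rx_drug()],
#'   [rx_non_drug_component()]).
#' @param status `"past"`, `"current"` or `"proposed"`.
#' @param efficacy Treatment efficacy outcome; defaults to `"unknown"`.
#'   `"too_effective"` is supplied in the record (e.g. set when an INR exceeds
#'   its therapeutic range), never computed by the engine.
#' @param start,end Calendar dates (coerced with [as.Date()]). `end` is absent
#'   for current and proposed treatments.
#' @return An object of class `rx_treatment`.
#' @export
rx_treatment <- function(components, status, efficacy = "unknown",
                         start = NULL, end = NULL) {
  status <- match.arg(status, RX_STATUSES)
  efficacy <- match.arg(efficacy, RX_EFFICACIES)
  if (status == "past" && is.null(end))
    stop("past treatments must have an end date")
  structure(
    list(components = components, status = status, efficacy = efficacy,
         start = if (!is.null(start)) as.Date(start),
         end = if (!is.null(end)) as.Date(end),
         changes = character(), notes = character()),
    class = "rx_treatment")
}

drug_components <- function(t) {
  t$components[vapply(t$components, function(c) c$kind == "drug", logical(1))]
}

treatment_failed <- function(t) {
  t$efficacy == "ineffective" ||
    any(vapply(drug_components(t),
               function(c) identical(c$tolerance, "poorly_tolerated"),
               logical(1)))
}

#' Patient record
#'
#' @param clinical Named list of clinical attribute values.
#' @param biological Named list of biological results.
#' @param history List of past and current [rx_treatment()]s (at most one
#'   current). Ordered by start date; ties keep record order (stable).
#' @param proposed The proposed prescription (an [rx_treatment()] with status
#'   `"proposed"`), or `NULL` when only suggestions are wanted.
#' @param critique_date Date at which the critique is run.
#' @param id Optional identifier.
#' @return An object of class `rx_patient`.
#' @export
rx_patient <- function(clinical = list(), biological = list(),
                       history = list(), proposed = NULL,
                       critique_date = Sys.Date(), id = NULL) {
  for (t in history) {
    stopifnot(inherits(t, "rx_treatment"))
    if (t$status == "proposed")
      stop("proposed treatments belong in `proposed`, not in the history")
  }
  if (!is.null(proposed)) {
    stopifnot(inherits(proposed, "rx_treatment"),
              proposed$status == "proposed")
  }
  if (sum(vapply(history, function(t) t$status == "current", logical(1))) > 1)
    stop("at most one current treatment")
  structure(
    list(id = id, clinical = clinical, biological = biological,
         history = order_history(history), proposed = proposed,
         critique_date = as.Date(critique_date), enriched = FALSE),
    class = "rx_patient")
}

order_history <- function(history) {
  if (length(history) < 2) return(history)
  starts <- vapply(history, function(t)
    if (is.null(t$start)) as.numeric(as.Date("1900-01-01"))
    else as.numeric(t$start), numeric(1))
  history[order(starts)]  # stable sort: equal starts keep record order
}
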