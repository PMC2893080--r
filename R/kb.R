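#' Read and validate a knowledge base
#'
#' A knowledge base is a YAML document declaring drug classes (sets of ATC
#' code prefixes), recommendable treatments, recommendations of three types
#' (`should_prescribe`, `should_not_prescribe`, `increasing_power`) with
#' their criticism labels, the applicability of the eight generic
#' recommendations, an indication map, attribute declarations with finite
#' value grids, and a verification section (enumerable attributes and
#' history scenarios). All structural invariants are checked on load and
#' every violation is reported, not just the first.
#'
#' @param path Path to a YAML knowledge-base document.
#' @return A validated object of class `rx_kb`.
#' @seealso [validate_kb()], [check_kb()], [write_kb()], [compile_kb()]
#' @export
read_kb <- function(path) {
  doc <- yaml::read_yaml(path)
  kb <- parse_kb(doc)
  validate_kb(kb)
}

#' Build a knowledge base from R objects
#'
#' Programmatic equivalent of [read_kb()]; used by the synthetic generators
#' and tests.
#'
#' @param name Knowledge-base name.
#' @param drug_classes Named list: class name -> character vector of ATC code
#'   prefixes (1-7 characters, upper case).
#' @param treatments Named list of recommendable treatment templates; each a
#'   list with a `components` element (concrete components as built by
#'   [rx_drug()] / [rx_non_drug_component()]).
#' @param recommendations List of recommendation objects (see [read_kb()]
#'   for the fields of each type).
#' @param generics List with elements `applicability` (named by ids
#'   `"1"`..`"8"`; values `"full"`, `"partial"`, `"not_applicable"`),
#'   `exceptions` and `scope` (named lists of class/treatment names).
#' @param indications List of `list(class, indication, dose_min, dose_max,
#'   unit)` entries; dose bounds optional (open when absent).
#' @param attributes Named list of attribute declarations
#'   `list(type, grid)`.
#' @param verification List with `attributes` (names entering the input
#'   vectors), `dose_grid`, and `history_scenarios` (named list of treatment
#'   lists).
#' @return A validated `rx_kb`.
#' @export
rx_kb <- function(name, drug_classes, treatments, recommendations,
                  generics = list(), indications = list(),
                  attributes = list(), verification = list()) {
  kb <- structure(
    list(name = name, drug_classes = drug_classes, treatments = treatments,
         recommendations = recommendations,
         generics = normalize_generics(generics),
         indications = indications, attributes = attributes,
         verification = verification),
    class = "rx_kb")
  validate_kb(kb)
}

normalize_generics <- function(g) {
  app <- stats::setNames(rep("not_applicable", 8), as.character(1:8))
  for (id in names(g$applicability)) app[[id]] <- g$applicability[[id]]
  list(applicability = as.list(app),
       exceptions = if (is.null(g$exceptions)) list() else g$exceptions,
       scope = if (is.null(g$scope)) list() else g$scope)
}

# ---- YAML parsing -----------------------------------------------------------

parse_kb <- function(doc) {
  structure(
    list(
      name = doc$name,
      drug_classes = lapply(doc$drug_classes, function(x) as.character(x)),
      treatments = lapply(doc$treatments, parse_template),
      recommendations = lapply(doc$recommendations, parse_recommendation),
      generics = normalize_generics(doc$generics),
      indications = if (is.null(doc$indications)) list() else doc$indications,
      attributes = if (is.null(doc$attributes)) list() else doc$attributes,
      verification = parse_verification(doc$verification)),
    class = "rx_kb")
}

parse_template <- function(x) {
  list(components = lapply(x$components, parse_concrete_component))
}

parse_concrete_component <- function(c) {
  if (!is.null(c$non_drug)) return(rx_non_drug_component(c$non_drug))
  if (!is.null(c$drug)) {
    d <- c$drug
    return(rx_drug(d$atc, d$inn, dose = d$dose, form = d$form,
                   tolerance = if (is.null(d$tolerance)) "unknown"
                               else d$tolerance))
  }
  stop("treatment component must be `drug:` or `non_drug:`")
}

parse_pattern <- function(x) {
  rx_pattern(
    components = if (is.null(x$components)) list(rx_any())
                 else lapply(x$components, parse_pattern_component),
    status = if (!is.null(x$status)) as.character(x$status),
    efficacy = x$efficacy,
    failed = x$failed,
    all_well_tolerated = x$all_well_tolerated,
    any_poor_tolerance = x$any_poor_tolerance,
    changes_any = if (!is.null(x$changes_any)) as.character(x$changes_any),
    cardinality = x$cardinality,
    window_years = x$window_years)
}

parse_pattern_component <- function(c) {
  if (identical(c, "any")) return(rx_any())
  if (!is.null(c$any) || identical(names(c), "any")) {
    a <- c$any
    return(rx_any(min = if (is.null(a$min)) 0 else a$min,
                  max = if (is.null(a$max)) Inf else a$max))
  }
  if (!is.null(c$non_drug)) return(rx_non_drug(c$non_drug))
  if (!is.null(c$class) || !is.null(c$codes))
    return(rx_class_ref(class = c$class, dose = c$dose, form = c$form,
                        tolerance = c$tolerance,
                        codes = if (!is.null(c$codes)) as.character(c$codes)))
  stop("component pattern must be `class:`, `codes:`, `non_drug:` or `any:`")
}

parse_condition <- function(x) {
  if (is.null(x)) return(NULL)
  if (!is.null(x$and)) return(do.call(rx_and, lapply(x$and, parse_condition)))
  if (!is.null(x$or)) return(do.call(rx_or, lapply(x$or, parse_condition)))
  if (!is.null(x$not)) return(rx_not(parse_condition(x$not)))
  if (!is.null(x$clinical)) {
    p <- x$clinical
    return(rx_clinical(p$attribute, p$op, p$value))
  }
  if (!is.null(x$therapeutic)) return(rx_therapeutic(parse_pattern(x$therapeutic)))
  stop("condition node must be and/or/not/clinical/therapeutic")
}

parse_recommendation <- function(x) {
  rec <- list(id = x$id, type = x$type,
              conditions = parse_condition(x$conditions))
  if (identical(x$type, "should_prescribe")) {
    rec$lines <- lapply(x$lines, function(l) lapply(l, parse_pattern))
    rec$explanation_labels <- as.character(x$explanation_labels)
    rec$advice_labels <- as.character(x$advice_labels)
    rec$reference_label <- if (is.null(x$reference_label)) ""
                           else x$reference_label
  } else if (identical(x$type, "should_not_prescribe")) {
    rec$pattern <- parse_pattern(x$pattern)
    rec$criticism_label <- x$criticism_label
  } else if (identical(x$type, "increasing_power")) {
    rec$levels <- lapply(x$levels, function(l) lapply(l, parse_pattern))
    rec$criticism_label <- x$criticism_label
  }
  rec
}

parse_verification <- function(v) {
  if (is.null(v)) return(list())
  list(attributes = if (!is.null(v$attributes)) as.character(v$attributes),
       dose_grid = v$dose_grid,
       history_scenarios = lapply(v$history_scenarios, function(ts)
         lapply(ts, parse_history_treatment)))
}

parse_history_treatment <- function(t) {
  rx_treatment(components = lapply(t$components, parse_concrete_component),
               status = t$status,
               efficacy = if (is.null(t$efficacy)) "unknown" else t$efficacy,
               start = t$start, end = t$end)
}

# ---- validation -------------------------------------------------------------

rec_n_lines <- function(rec) {
  switch(rec$type,
         should_prescribe = length(rec$lines),
         increasing_power = length(rec$levels),
         1L)
}

#' Validate a knowledge base
#'
#' Checks every structural invariant and stops with a message listing every
#' violation found (not just the first). Returns the knowledge base invisibly
#' unchanged when valid.
#'
#' @param kb An `rx_kb`.
#' @return `kb`, invisibly, if valid; otherwise an error.
#' @export
validate_kb <- function(kb) {
  issues <- kb_issues(kb)
  errs <- issues$message[issues$severity == "error"]
  if (length(errs))
    stop("invalid knowledge base:\n", paste0("- ", errs, collapse = "\n"),
         call. = FALSE)
  invisible(kb)
}

#' Cross-reference and label-coverage report for a knowledge base
#'
#' Report-only companion of [validate_kb()]: lists dangling drug-class
#' references, criticism-label gaps (a line reachable in a criticism without
#' a label), and generic-recommendation exceptions naming undeclared
#' entities. A well-formed knowledge base yields a zero-row tibble.
#'
#' @param kb An `rx_kb` (parsed; need not be valid).
#' @return A tibble with columns `severity`, `location`, `message`.
#' @export
check_kb <- function(kb) kb_issues(kb)

kb_issues <- function(kb) {
  sev <- character(); loc <- character(); msg <- character()
  flag <- function(s, l, m) {
    sev <<- c(sev, s); loc <<- c(loc, l); msg <<- c(msg, m)
  }
  if (is.null(kb$name) || !nzchar(kb$name))
    flag("error", "kb", "knowledge base has no name")
  if (length(kb$drug_classes) == 0)
    flag("error", "drug_classes", "no drug classes declared")
  for (nm in names(kb$drug_classes)) {
    codes <- kb$drug_classes[[nm]]
    if (length(codes) == 0)
      flag("error", paste0("drug_classes/", nm), "empty ATC code set")
    bad <- codes[!grepl("^[A-Z][0-9A-Z]{0,6}$", codes)]
    for (b in bad)
      flag("error", paste0("drug_classes/", nm),
           paste0("malformed ATC code: ", b))
  }
  if (length(kb$treatments) == 0)
    flag("error", "treatments", "recommendable treatments empty")
  if (length(kb$recommendations) == 0)
    flag("error", "recommendations", "recommendations empty")

  class_ok <- function(c) is.null(c$class) || c$class %in% names(kb$drug_classes)
  check_pattern <- function(pat, where) {
    for (c in pat$components) {
      if (identical(c$kind, "class") && !class_ok(c))
        flag("error", where, paste0("dangling drug-class reference: ", c$class))
    }
  }
  check_cond <- function(cond, where) {
    if (is.null(cond)) return(invisible())
    switch(cond$op,
      therapeutic = check_pattern(cond$pattern, where),
      clinical = {
        a <- cond$pred$attribute
        if (length(kb$attributes) && !a %in% names(kb$attributes))
          flag("warning", where, paste0("attribute not declared: ", a))
      },
      for (k in cond$children) check_cond(k, where))
  }

  for (rec in kb$recommendations) {
    where <- paste0("recommendations/", rec$id)
    if (!rec$type %in% c("should_prescribe", "should_not_prescribe",
                         "increasing_power")) {
      flag("error", where, paste0("unknown recommendation type: ", rec$type))
      next
    }
    check_cond(rec$conditions, where)
    if (rec$type == "should_prescribe") {
      n <- length(rec$lines)
      if (n < 1) flag("error", where, "should_prescribe needs >= 1 line")
      for (i in seq_len(n)) {
        if (length(rec$lines[[i]]) == 0)
          flag("error", where, paste0("line ", i, " is empty"))
        for (p in rec$lines[[i]])
          check_pattern(p, paste0(where, "/line", i))
      }
      # line N+1 is implicit ("any other treatment") and needs only an
      # explanation label; reachable labels are explanation 2..N+1 and
      # advice 1..N
      for (y in seq(2, n + 1)) {
        if (length(rec$explanation_labels) < y ||
            !nzchar(rec$explanation_labels[y]))
          flag("error", where,
               paste0("missing explanation label for line ", y))
      }
      for (x in seq_len(n)) {
        if (length(rec$advice_labels) < x || !nzchar(rec$advice_labels[x]))
          flag("error", where, paste0("missing advice label for line ", x))
      }
    } else if (rec$type == "should_not_prescribe") {
      if (is.null(rec$pattern)) flag("error", where, "missing forbidden pattern")
      else check_pattern(rec$pattern, where)
      if (is.null(rec$criticism_label) || !nzchar(rec$criticism_label))
        flag("error", where, "missing criticism label")
    } else {
      if (length(rec$levels) < 2)
        flag("error", where, "increasing_power needs >= 2 power levels")
      for (i in seq_along(rec$levels))
        for (p in rec$levels[[i]])
          check_pattern(p, paste0(where, "/level", i))
      if (is.null(rec$criticism_label) || !nzchar(rec$criticism_label))
        flag("error", where, "missing criticism label")
    }
  }

  app <- kb$generics$applicability
  for (id in names(app)) {
    if (!id %in% as.character(1:8))
      flag("error", "generics", paste0("generic id out of range: ", id))
    if (!app[[id]] %in% c("full", "partial", "not_applicable"))
      flag("error", "generics",
           paste0("invalid applicability for generic #", id, ": ", app[[id]]))
  }
  known <- c(names(kb$drug_classes), names(kb$treatments))
  for (id in names(kb$generics$exceptions)) {
    if (!id %in% as.character(1:8))
      flag("error", "generics/exceptions",
           paste0("generic id out of range: ", id))
    for (ref in kb$generics$exceptions[[id]])
      if (!ref %in% known)
        flag("error", paste0("generics/exceptions/", id),
             paste0("exception names undeclared entity: ", ref))
  }
  for (id in names(kb$generics$scope))
    for (ref in kb$generics$scope[[id]])
      if (!ref %in% known)
        flag("error", paste0("generics/scope/", id),
             paste0("scope names undeclared entity: ", ref))

  for (ind in kb$indications)
    if (!ind$class %in% names(kb$drug_classes))
      flag("error", "indications",
           paste0("dangling drug-class reference: ", ind$class))

  for (a in kb$verification$attributes) {
    if (!a %in% names(kb$attributes))
      flag("error", "verification", paste0("attribute not declared: ", a))
    else if (is.null(kb$attributes[[a]]$grid))
      flag("error", "verification",
           paste0("attribute has no finite value grid: ", a))
  }

  tibble::tibble(severity = sev, location = loc, message = msg)
}

# ---- serialization ----------------------------------------------------------

#' Serialize a knowledge base back to YAML
#'
#' Round-trip guarantee: `read_kb(write_kb(kb, f))` is structurally identical
#' to `kb`.
#'
#' @param kb An `rx_kb`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  yaml::write_yaml(kb_to_list(kb), path)
  invisible(path)
}

kb_to_list <- function(kb) {
  drop_null(list(
    name = kb$name,
    drug_classes = lapply(kb$drug_classes, as.list),
    attributes = kb$attributes,
    treatments = lapply(kb$treatments, function(t)
      list(components = lapply(t$components, concrete_component_to_list))),
    recommendations = lapply(kb$recommendations, rec_to_list),
    generics = list(applicability = kb$generics$applicability,
                    exceptions = kb$generics$exceptions,
                    scope = kb$generics$scope),
    indications = kb$indications,
    verification = verification_to_list(kb$verification)))
}

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

concrete_component_to_list <- function(c) {
  if (c$kind == "non_drug") return(list(non_drug = c$name))
  list(drug = drop_null(list(atc = c$atc, inn = c$inn, dose = c$dose,
                             form = c$form, tolerance = c$tolerance)))
}

pattern_to_list <- function(p) {
  drop_null(list(
    components = lapply(p$components, function(c) {
      switch(c$kind,
             any = list(any = drop_null(list(
               min = if (c$min > 0) c$min,
               max = if (is.finite(c$max)) c$max))),
             non_drug = list(non_drug = c$name),
             class = drop_null(list(class = c$class,
                                    codes = if (!is.null(c$codes)) as.list(c$codes),
                                    dose = c$dose, form = c$form,
                                    tolerance = c$tolerance)))
    }),
    status = if (!is.null(p$status)) as.list(p$status),
    efficacy = p$efficacy, failed = p$failed,
    all_well_tolerated = p$all_well_tolerated,
    any_poor_tolerance = p$any_poor_tolerance,
    changes_any = if (!is.null(p$changes_any)) as.list(p$changes_any),
    cardinality = p$cardinality, window_years = p$window_years))
}

cond_to_list <- function(cond) {
  if (is.null(cond)) return(NULL)
  switch(cond$op,
    and = list(and = lapply(cond$children, cond_to_list)),
    or = list(or = lapply(cond$children, cond_to_list)),
    not = list(not = cond_to_list(cond$children[[1]])),
    clinical = list(clinical = cond$pred),
    therapeutic = list(therapeutic = pattern_to_list(cond$pattern)),
    special = list(special = list(name = cond$special, args = cond$args)))
}

rec_to_list <- function(rec) {
  out <- list(id = rec$id, type = rec$type,
              conditions = cond_to_list(rec$conditions))
  if (rec$type == "should_prescribe") {
    out$lines <- lapply(rec$lines, function(l) lapply(l, pattern_to_list))
    out$explanation_labels <- as.list(rec$explanation_labels)
    out$advice_labels <- as.list(rec$advice_labels)
    out$reference_label <- rec$reference_label
  } else if (rec$type == "should_not_prescribe") {
    out$pattern <- pattern_to_list(rec$pattern)
    out$criticism_label <- rec$criticism_label
  } else {
    out$levels <- lapply(rec$levels, function(l) lapply(l, pattern_to_list))
    out$criticism_label <- rec$criticism_label
  }
  drop_null(out)
}

verification_to_list <- function(v) {
  if (length(v) == 0) return(NULL)
  drop_null(list(
    attributes = if (!is.null(v$attributes)) as.list(v$attributes),
    dose_grid = v$dose_grid,
    history_scenarios = lapply(v$history_scenarios, function(ts)
      lapply(ts, function(t)
        drop_null(list(
          components = lapply(t$components, concrete_component_to_list),
          status = t$status,
          efficacy = if (!identical(t$efficacy, "unknown")) t$efficacy,
          start = if (!is.null(t$start)) format(t$start),
          end = if (!is.null(t$end)) format(t$end)))))))
}

#' @export
print.rx_kb <- function(x, ...) {
  cat("<rx_kb> ", x$name, "\n", sep = "")
  cat("  drug classes:  ", length(x$drug_classes), "\n")
  cat("  treatments:    ", length(x$treatments), "\n")
  cat("  recommendations:", length(x$recommendations), "\n")
  on <- names(Filter(function(a) a != "not_applicable",
                     x$generics$applicability))
  cat("  generics on:   ", if (length(on)) paste(on, collapse = ", ")
                           else "none", "\n")
  invisible(x)
}
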