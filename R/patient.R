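#' Read a patient record
#'
#' Patient records are YAML (or JSON, which YAML subsumes) documents with
#' clinical attribute values, biological results, an ordered therapeutic
#' history with per-drug tolerance and per-treatment efficacy outcomes, and
#' a proposed prescription. Dates are ISO-8601; doses are
#' `{value, unit, per}` with `per` one of `day` or `intake`.
#'
#' @param path Path to the document.
#' @return An object of class `rx_patient`.
#' @export
read_patient <- function(path) {
  doc <- yaml::read_yaml(path)
  history <- lapply(doc$history, parse_history_treatment)
  proposed <- if (!is.null(doc$proposed)) {
    t <- doc$proposed
    t$status <- "proposed"
    parse_history_treatment(t)
  }
  rx_patient(
    clinical = if (is.null(doc$clinical)) list() else doc$clinical,
    biological = if (is.null(doc$biological)) list() else doc$biological,
    history = history, proposed = proposed,
    critique_date = if (is.null(doc$critique_date)) Sys.Date()
                    else doc$critique_date,
    id = doc$id)
}

current_treatment <- function(record) {
  cur <- Filter(function(t) t$status == "current", record$history)
  if (length(cur)) cur[[1]] else NULL
}

#' Enrich a patient record with derived data
#'
#' Computes the medical abstractions the critiquing engine relies on:
#' * body mass index from `height` (m) and `weight` (kg), stored as the
#'   clinical attribute `bmi` (missing height or weight leaves `bmi` absent,
#'   without failure);
#' * relative posology: for each proposed drug sharing an INN with the
#'   current treatment, a change flag among `dose_increase`, `dose_decrease`,
#'   `form_change`, `unchanged`; a proposed drug whose INN does not occur in
#'   a non-empty current treatment is flagged `inn_change`. Flags are stored
#'   per component (`$change`) and aggregated on the proposed treatment
#'   (`$changes`, the set of non-`unchanged` flags).
#'
#' Enrichment is idempotent: derived fields are recomputed from the original
#' fields, which are never modified.
#'
#' @param record An `rx_patient`.
#' @param kb The knowledge base (reserved for KB-informed abstractions;
#'   currently unused by the derivations above).
#' @return The enriched `rx_patient`.
#' @export
enrich <- function(record, kb = NULL) {
  h <- record$clinical$height
  w <- record$clinical$weight
  if (!is.null(h) && !is.null(w) && h > 0)
    record$clinical$bmi <- w / h^2

  if (!is.null(record$proposed)) {
    cur <- current_treatment(record)
    cur_drugs <- if (is.null(cur)) list() else drug_components(cur)
    cur_inns <- vapply(cur_drugs, function(d) d$inn, character(1))
    flags <- character()
    comps <- record$proposed$components
    for (i in seq_along(comps)) {
      c <- comps[[i]]
      if (!identical(c$kind, "drug")) next
      if (length(cur_inns) && c$inn %in% cur_inns) {
        m <- cur_drugs[[match(c$inn, cur_inns)]]
        f <- compare_drug(m, c)
      } else if (length(cur_inns)) {
        f <- "inn_change"
      } else {
        f <- "unchanged"
      }
      comps[[i]]$change <- f
      if (f != "unchanged") flags <- union(flags, f)
    }
    record$proposed$components <- comps
    record$proposed$changes <- flags
  }
  record$enriched <- TRUE
  record
}

# relative posology of a re-prescribed INN; dose comparison requires
# identical units and periods (no conversion)
compare_drug <- function(current, proposed) {
  if (!is.null(proposed$form) && !is.null(current$form) &&
      !identical(proposed$form, current$form))
    return("form_change")
  dc <- current$dose; dp <- proposed$dose
  if (!is.null(dc) && !is.null(dp) &&
      identical(dc$unit, dp$unit) && identical(dc$per, dp$per)) {
    if (dp$value > dc$value) return("dose_increase")
    if (dp$value < dc$value) return("dose_decrease")
  }
  "unchanged"
}

#' Normalize dual-failure treatment outcomes
#'
#' A treatment that is both ineffective and contains a poorly tolerated drug
#' is re-labelled so that only the poor-tolerance pathway fires during
#' matching: its efficacy is set to `unknown` and the rationale is recorded
#' in the treatment's audit notes. In case of poor tolerance the patient's
#' adherence is often low, so the efficacy cannot be rigorously evaluated;
#' the poor-tolerance recommendations are therefore the ones to apply.
#' Tolerance values are never altered, and the transformation is idempotent.
#'
#' @param record An `rx_patient`.
#' @return The record with normalized history outcomes.
#' @export
normalize_outcomes <- function(record) {
  record$history <- lapply(record$history, function(t) {
    poorly <- any(vapply(drug_components(t),
                         function(c) identical(c$tolerance, "poorly_tolerated"),
                         logical(1)))
    if (identical(t$efficacy, "ineffective") && poorly) {
      t$efficacy <- "unknown"
      t$notes <- union(t$notes,
        "dual failure: ineffective and poorly tolerated; poor-tolerance pathway applies")
    }
    t
  })
  record
}

#' Group the proposed drugs by indication
#'
#' Determines the indication of each proposed drug from the knowledge base's
#' `(drug class, dose range)` indication map and regroups the prescription by
#' indication, duplicating drugs that have several indications (e.g. a
#' beta-blocking agent indicated for both arterial hypertension and atrial
#' fibrillation). The critique is then run once per indication group.
#'
#' @param record An `rx_patient` with a proposed prescription.
#' @param kb An `rx_kb` whose `indications` map covers the proposed drugs.
#' @return A named list of `rx_patient` records, one per indication, whose
#'   proposed prescription is restricted to the drugs carrying that
#'   indication (non-drug components are kept in every group). Drugs with no
#'   mapping are dropped with a warning and listed in the `"unmapped"`
#'   attribute.
#' @export
assign_indications <- function(record, kb) {
  if (is.null(record$proposed) || length(record$proposed$components) == 0)
    return(structure(list(), unmapped = character()))
  comps <- record$proposed$components
  non_drug <- Filter(function(c) c$kind != "drug", comps)
  groups <- list()
  unmapped <- character()
  for (c in comps) {
    if (c$kind != "drug") next
    inds <- drug_indications(c, kb)
    if (length(inds) == 0) {
      unmapped <- c(unmapped, c$inn)
      next
    }
    for (ind in inds) groups[[ind]] <- c(groups[[ind]], list(c))
  }
  if (length(unmapped))
    warning("unmapped drug(s) excluded from critique: ",
            paste(unmapped, collapse = ", "))
  out <- lapply(groups, function(drugs) {
    r <- record
    r$proposed$components <- c(non_drug, drugs)
    r
  })
  structure(out, unmapped = unmapped)
}

drug_indications <- function(drug, kb) {
  inds <- character()
  for (e in kb$indications) {
    codes <- kb$drug_classes[[e$class]]
    if (!any(startsWith(drug$atc, codes))) next
    if (!is.null(e$unit) && !is.null(drug$dose)) {
      if (!identical(e$unit, drug$dose$unit)) next
      if (!is.null(e$dose_min) && drug$dose$value < e$dose_min) next
      if (!is.null(e$dose_max) && drug$dose$value > e$dose_max) next
    }
    inds <- union(inds, e$indication)
  }
  inds
}

#' @export
print.rx_patient <- function(x, ...) {
  cat("<rx_patient>", if (!is.null(x$id)) x$id else "", "\n")
  cat("  clinical:  ", paste(names(x$clinical), collapse = ", "), "\n")
  cat("  biological:", paste(names(x$biological), collapse = ", "), "\n")
  cat("  history:   ", length(x$history), "treatment(s)\n")
  cat("  proposed:  ", if (is.null(x$proposed)) "none"
      else paste(vapply(drug_components(x$proposed),
                        function(d) d$inn, character(1)), collapse = " + "),
      "\n")
  invisible(x)
}
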