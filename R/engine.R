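#' Critique a proposed prescription against a knowledge base
#'
#' Runs the four-step critiquing procedure:
#' 1. every compiled rule is evaluated against the proposed prescription;
#'    any firing rule makes the prescription non-conformant;
#' 2. the textual criticism is composed by concatenating the criticisms of
#'    all fired rules (in deterministic rule order, exact duplicates emitted
#'    once);
#' 3. treatment suggestions are computed by re-running the rules with each
#'    recommendable treatment substituted as the proposal and retaining the
#'    treatments that fire no rule;
#' 4. if no suggestion survives, the rules are relaxed step by step —
#'    at relaxation level `k` the line-of-treatment rules with `Y - X <= k`
#'    are suppressed, so a line X+k treatment becomes acceptable for a
#'    patient at stage X — until a suggestion survives or the maximum level
#'    is reached. "Any other treatment" rules (line N+1) are never relaxed,
#'    so a non-recommended treatment can never become a suggestion. If the
#'    suggestion list is still empty at maximal relaxation, the guideline
#'    does not provide enough information (`insufficient_guidance`).
#'
#' The verdict on the proposal itself is always the strict (k = 0) one;
#' relaxation only widens the suggestion list.
#'
#' The record is enriched ([enrich()]) and outcome-normalized
#' ([normalize_outcomes()]) before evaluation; both are idempotent, so
#' pre-processed records are accepted as-is. When a prescription spans
#' several indications, run [assign_indications()] first and critique each
#' group.
#'
#' @param record An `rx_patient` with a proposed prescription.
#' @param kb An `rx_kb`.
#' @param ruleset Optional pre-compiled `rx_ruleset` (defaults to
#'   `compile_kb(kb)`).
#' @return An object of class `rx_critique` with fields `conforms`,
#'   `criticisms` (tibble of fired rules), `composed_text`, `suggestions`,
#'   `relaxation_level`, `insufficient_guidance`, `missing_data_notes`.
#' @seealso [suggest_treatments()], [tidy.rx_critique()],
#'   [glance.rx_critique()]
#' @export
critique <- function(record, kb, ruleset = NULL) {
  if (is.null(record$proposed))
    stop("the record has no proposed prescription to critique")
  if (is.null(ruleset)) ruleset <- compile_kb(kb)
  record <- normalize_outcomes(enrich(record, kb))

  ctx <- match_context(record, kb)
  fired <- fired_rules(ruleset, ctx, k = 0)
  conforms <- length(fired) == 0

  sug <- list(treatments = character(), k = 0L, insufficient = FALSE)
  for (k in 0:ruleset$kmax) {
    s <- suggest_treatments(record, kb, ruleset, k = k)
    if (length(s)) { sug <- list(treatments = s, k = k,
                                 insufficient = FALSE); break }
    if (k == ruleset$kmax) sug <- list(treatments = character(), k = k,
                                       insufficient = TRUE)
  }

  structure(
    list(conforms = conforms,
         criticisms = fired_tibble(fired),
         composed_text = compose_text(fired),
         suggestions = sug$treatments,
         relaxation_level = sug$k,
         insufficient_guidance = sug$insufficient,
         missing_data_notes = ctx_notes(ctx),
         kb_name = kb$name, record_id = record$id),
    class = "rx_critique")
}

fired_rules <- function(ruleset, ctx, k = 0) {
  Filter(function(r) {
    if (r$relaxable && !is.na(r$gap) && r$gap <= k) return(FALSE)
    eval_condition(r$condition, ctx)
  }, ruleset$rules)
}

fired_tibble <- function(fired) {
  tibble::tibble(
    rule_id = vapply(fired, function(r) r$id, character(1)),
    source = vapply(fired, function(r) r$source, character(1)),
    X = vapply(fired, function(r) as.integer(r$X), integer(1)),
    Y = vapply(fired, function(r) as.integer(r$Y), integer(1)),
    text = vapply(fired, function(r) r$criticism, character(1)))
}

#' Compose the textual criticism of a set of fired rules
#'
#' Per-rule criticisms are already composed at compile time (explanation +
#' advice + reference labels); across rules the texts are concatenated in
#' rule order, with exact duplicates emitted once.
#'
#' @param fired A list of fired rules (as selected by [critique()]).
#' @return A single string (empty when nothing fired).
#' @export
compose_text <- function(fired) {
  texts <- unique(vapply(fired, function(r) r$criticism, character(1)))
  paste(texts, collapse = " ")
}

#' Treatment suggestions at a given relaxation level
#'
#' Substitutes each recommendable treatment of the knowledge base as the
#' proposed prescription (recomputing the relative-posology change flags
#' against the current treatment) and retains the treatments that fire no
#' rule. Rules from `should_prescribe` recommendations with `Y - X <= k`
#' (for `Y <= N`) are suppressed at relaxation level `k`.
#'
#' @param record An `rx_patient` (a proposal is not required).
#' @param kb An `rx_kb`.
#' @param ruleset An `rx_ruleset` (defaults to `compile_kb(kb)`).
#' @param k Relaxation level, `k >= 0` (0 = strict).
#' @return Character vector of treatment names, in knowledge-base
#'   declaration order.
#' @export
suggest_treatments <- function(record, kb, ruleset = NULL, k = 0) {
  if (is.null(ruleset)) ruleset <- compile_kb(kb)
  record <- normalize_outcomes(record)
  keep <- character()
  for (tn in names(kb$treatments)) {
    cand <- record
    cand$proposed <- template_treatment(kb$treatments[[tn]])
    cand <- enrich(cand, kb)
    ctx <- match_context(cand, kb)
    if (length(fired_rules(ruleset, ctx, k = k)) == 0)
      keep <- c(keep, tn)
  }
  keep
}

#' Critique a prescription once per indication
#'
#' Convenience wrapper: regroups the proposed drugs by indication with
#' [assign_indications()] and critiques each group separately.
#'
#' @inheritParams critique
#' @return Named list of `rx_critique` objects, one per indication.
#' @export
critique_by_indication <- function(record, kb, ruleset = NULL) {
  groups <- assign_indications(record, kb)
  lapply(groups, critique, kb = kb, ruleset = ruleset)
}

#' @export
print.rx_critique <- function(x, ...) {
  cat("<rx_critique> kb '", x$kb_name, "'",
      if (!is.null(x$record_id)) paste0(", patient '", x$record_id, "'"),
      "\n", sep = "")
  if (x$conforms) {
    cat("  conforms: the prescription is not criticized\n")
  } else {
    cat("  does NOT conform (", nrow(x$criticisms), " rule(s) fired)\n",
        sep = "")
    cat("  criticism: ", x$composed_text, "\n", sep = "")
  }
  if (x$insufficient_guidance) {
    cat("  the guideline does not provide enough information for a suggestion\n")
  } else {
    cat("  suggestions",
        if (x$relaxation_level > 0)
          paste0(" (relaxation level ", x$relaxation_level, ")"),
        ": ", paste(x$suggestions, collapse = ", "), "\n", sep = "")
  }
  for (n in x$missing_data_notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}
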