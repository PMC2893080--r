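#' Enumerate the knowledge base's input-vector space
#'
#' Quasi-exhaustive verification treats the critiquing engine as a black
#' box: a limited set of patient attributes, each with a finite value grid
#' declared in the knowledge base, is combined with a set of named
#' therapeutic-history scenarios, and the full cartesian product of values
#' is generated in deterministic order.
#'
#' @param kb An `rx_kb` whose `verification` section declares the
#'   enumerable attributes (each with a finite grid) and, optionally,
#'   `history_scenarios`.
#' @return A tibble with one column per attribute plus a `history` column
#'   (scenario name); `nrow` equals the product of the grid sizes.
#' @export
enumerate_vectors <- function(kb) {
  attrs <- kb$verification$attributes
  if (is.null(attrs) || length(attrs) == 0)
    stop("the knowledge base declares no enumerable attributes")
  grids <- lapply(attrs, function(a) {
    g <- kb$attributes[[a]]$grid
    if (is.null(g)) stop("attribute without a finite value grid: ", a)
    unlist(g)
  })
  names(grids) <- attrs
  scen <- names(kb$verification$history_scenarios)
  if (is.null(scen) || length(scen) == 0) scen <- "none"
  grids$history <- scen
  tibble::as_tibble(expand.grid(grids, stringsAsFactors = FALSE,
                                KEEP.OUT.ATTRS = FALSE))
}

# default critique date used when materializing enumerated vectors: the
# scenarios in a verification section carry absolute dates, so a fixed
# anchor keeps window arithmetic (generic #5) deterministic
RX_VERIFICATION_DATE <- as.Date("2026-01-01")

#' Materialize one input vector as a patient record
#'
#' @param kb An `rx_kb`.
#' @param vec One row of [enumerate_vectors()] (list or one-row data frame).
#' @param critique_date Critique date anchoring time windows.
#' @return An `rx_patient` without a proposal.
#' @export
vector_record <- function(kb, vec, critique_date = RX_VERIFICATION_DATE) {
  vec <- as.list(vec)
  hist <- list()
  if (!is.null(vec$history)) {
    hist <- kb$verification$history_scenarios[[vec$history]]
    if (is.null(hist)) hist <- list()
    vec$history <- NULL
  }
  rx_patient(clinical = vec, history = hist, critique_date = critique_date)
}

# treatments recommended only as second-line (or later): their minimal line
# across should_prescribe recommendations is >= 2; rendered in brackets
second_line_only <- function(kb) {
  ctx <- match_context(rx_patient(), kb)
  out <- logical(0)
  for (tn in names(kb$treatments)) {
    t <- template_treatment(kb$treatments[[tn]], status = "proposed")
    min_line <- Inf
    for (rec in kb$recommendations) {
      if (rec$type != "should_prescribe") next
      for (L in seq_along(rec$lines)) {
        for (p in rec$lines[[L]]) {
          if (match_treatment(t, pattern_variant(p, status = NULL), ctx)) {
            min_line <- min(min_line, L)
            break
          }
        }
      }
    }
    out[[tn]] <- is.finite(min_line) && min_line >= 2
  }
  out
}

suggestion_label <- function(record, kb, ruleset, bracketed) {
  s <- character(); k <- 0
  repeat {
    s <- suggest_treatments(record, kb, ruleset, k = k)
    if (length(s) || k >= ruleset$kmax) break
    k <- k + 1
  }
  if (length(s) == 0) return("no treatment")
  paste(ifelse(bracketed[s], paste0("[", s, "]"), s), collapse = ", ")
}

#' Label every input vector with the engine's accepted treatments
#'
#' Runs the critiquing engine on each enumerated input vector and records,
#' as a single categorical label, the list of recommendable treatments that
#' are not criticized for that patient profile (at the smallest relaxation
#' level yielding a non-empty list; `"no treatment"` when none survives).
#' Treatments recommended as second-line only are bracketed. The engine is
#' deterministic, so the labelling is reproducible.
#'
#' @param kb An `rx_kb`.
#' @param vectors Tibble from [enumerate_vectors()] (the default).
#' @param ruleset Optional pre-compiled `rx_ruleset`.
#' @param critique_date Critique date anchoring time windows.
#' @return `vectors` with an added `label` column.
#' @export
build_dataset <- function(kb, vectors = enumerate_vectors(kb),
                          ruleset = NULL,
                          critique_date = RX_VERIFICATION_DATE) {
  if (is.null(ruleset)) ruleset <- compile_kb(kb)
  bracketed <- second_line_only(kb)
  vectors$label <- vapply(seq_len(nrow(vectors)), function(i) {
    rec <- vector_record(kb, vectors[i, , drop = FALSE], critique_date)
    suggestion_label(rec, kb, ruleset, bracketed)
  }, character(1))
  vectors
}

# ---- decision-tree induction ------------------------------------------------

entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

#' Induce an unpruned decision tree from a labelled dataset
#'
#' Greedy top-down induction with the gain-ratio splitting criterion over
#' categorical attributes (multiway splits, one branch per value), recursing
#' until every leaf is label-pure. Pruning is disabled so the training error
#' is 0% by construction; ties between attributes are broken by declaration
#' order, making induction deterministic. The resulting tree regenerates
#' the knowledge base's behaviour in a human-reviewable form: each
#' root-to-leaf path is a patient profile and the leaf holds the treatments
#' accepted for it.
#'
#' @param data A labelled tibble (e.g. from [build_dataset()]).
#' @param label Name of the label column.
#' @param attributes Attribute columns to split on; defaults to every
#'   non-label column, in declaration order.
#' @return An object of class `rx_tree` with fields `root`, `attributes`,
#'   `training_error`.
#' @export
induce_tree <- function(data, label = "label",
                        attributes = setdiff(names(data), label)) {
  stopifnot(nrow(data) > 0, label %in% names(data))
  df <- as.data.frame(lapply(data[c(attributes, label)], as.character),
                      stringsAsFactors = FALSE)
  grow <- function(rows) {
    y <- df[[label]][rows]
    if (length(unique(y)) == 1)
      return(list(leaf = TRUE, label = y[1], n = length(rows)))
    base <- entropy(y)
    best <- NULL; best_ratio <- 0
    for (a in attributes) {
      v <- df[[a]][rows]
      vals <- unique(v)
      if (length(vals) < 2) next
      cond_info <- 0
      for (val in vals) {
        sub <- y[v == val]
        cond_info <- cond_info + length(sub) / length(y) * entropy(sub)
      }
      gain <- base - cond_info
      if (gain <= 1e-12) next
      ratio <- gain / entropy(v)
      if (ratio > best_ratio + 1e-12) {  # strict: ties keep earlier attribute
        best_ratio <- ratio
        best <- a
      }
    }
    if (is.null(best))
      stop("contradictory records: identical vectors with different labels")
    v <- df[[best]][rows]
    kids <- lapply(unique(v), function(val) grow(rows[v == val]))
    names(kids) <- unique(v)
    list(leaf = FALSE, attr = best, children = kids, n = length(rows))
  }
  tree <- structure(list(root = grow(seq_len(nrow(df))),
                         attributes = attributes, label_col = label),
                    class = "rx_tree")
  pred <- predict(tree, data)
  tree$training_error <- mean(pred != df[[label]])
  tree
}

#' Route observations through an induced tree
#' @param object An `rx_tree`.
#' @param newdata A data frame with the tree's attribute columns.
#' @param ... Unused.
#' @return Character vector of leaf labels, one per row.
#' @export
predict.rx_tree <- function(object, newdata, ...) {
  walk <- function(node, row) {
    if (node$leaf) return(node$label)
    val <- as.character(row[[node$attr]])
    child <- node$children[[val]]
    if (is.null(child))
      stop("no branch for ", node$attr, " = ", val)
    walk(child, row)
  }
  vapply(seq_len(nrow(newdata)), function(i)
    walk(object$root, newdata[i, , drop = FALSE]), character(1))
}

#' Render an induced tree as indented text or a Graphviz description
#'
#' The text and graph renderings contain identical path sets; treatments
#' recommended as second-line only appear bracketed in the leaf labels
#' (they are bracketed in the dataset labels themselves).
#'
#' @param tree An `rx_tree`.
#' @param format `"text"` (indented outline) or `"dot"` (Graphviz digraph).
#' @return A single string.
#' @export
render_tree <- function(tree, format = c("text", "dot")) {
  format <- match.arg(format)
  if (format == "text") {
    lines <- character()
    rec <- function(node, indent) {
      pad <- strrep("  ", indent)
      if (node$leaf) {
        lines <<- c(lines, paste0(pad, "-> ", node$label))
        return(invisible())
      }
      for (val in names(node$children)) {
        child <- node$children[[val]]
        if (child$leaf)
          lines <<- c(lines, paste0(pad, node$attr, " = ", val, ": ",
                                    child$label))
        else {
          lines <<- c(lines, paste0(pad, node$attr, " = ", val, ":"))
          rec(child, indent + 1)
        }
      }
    }
    if (tree$root$leaf) lines <- paste0("-> ", tree$root$label)
    else rec(tree$root, 0)
    return(paste(lines, collapse = "\n"))
  }
  # dot
  lines <- c("digraph tree {", "  node [shape=box];")
  counter <- 0
  rec <- function(node) {
    counter <<- counter + 1
    id <- paste0("n", counter)
    if (node$leaf) {
      lines <<- c(lines, paste0("  ", id, " [label=\"", node$label,
                                "\", style=filled];"))
      return(id)
    }
    lines <<- c(lines, paste0("  ", id, " [label=\"", node$attr, "\"];"))
    for (val in names(node$children)) {
      cid <- rec(node$children[[val]])
      lines <<- c(lines, paste0("  ", id, " -> ", cid, " [label=\"",
                                val, "\"];"))
    }
    id
  }
  rec(tree$root)
  paste(c(lines, "}"), collapse = "\n")
}

#' Root-to-leaf paths of an induced tree
#' @param tree An `rx_tree`.
#' @return A tibble with columns `path` (conjunction of attribute tests) and
#'   `label`.
#' @export
tree_paths <- function(tree) {
  paths <- character(); labels <- character()
  rec <- function(node, tests) {
    if (node$leaf) {
      paths <<- c(paths, paste(tests, collapse = " & "))
      labels <<- c(labels, node$label)
      return(invisible())
    }
    for (val in names(node$children))
      rec(node$children[[val]],
          c(tests, paste0(node$attr, " = ", val)))
  }
  rec(tree$root, character())
  tibble::tibble(path = paths, label = labels)
}

#' @export
print.rx_tree <- function(x, ...) {
  cat("<rx_tree> unpruned, gain-ratio splits; training error ",
      100 * x$training_error, "%\n", sep = "")
  cat(render_tree(x), "\n")
  invisible(x)
}

# ---- test-base generation ---------------------------------------------------

#' Generate a seeded test base for a knowledge base
#'
#' For each patient profile the base contains one positive test case per
#' treatment recommended for that profile (expected to conform) and up to
#' `n_negative` random non-recommended prescriptions drawn from
#' (drug class, grid dose) pairs (expected to be criticized). Candidate
#' negatives are checked against the engine, so every emitted negative
#' fires at least one rule; if fewer than `n_negative` can be constructed a
#' warning is raised and as many as exist are emitted. Identical seeds give
#' identical bases.
#'
#' @param kb An `rx_kb`.
#' @param seed Integer seed for negative-case sampling.
#' @param profiles Optional list of `rx_patient` profiles (no proposal);
#'   defaults to the materialized rows of [enumerate_vectors()].
#' @param n_negative Number of random negative cases per profile.
#' @param ruleset Optional pre-compiled `rx_ruleset`.
#' @return An object of class `rx_testbase`: a tibble with columns
#'   `profile`, `case`, `kind`, `treatment`, `expected_conforms`, carrying
#'   the materialized case records in the `"records"` attribute and the
#'   seed in `"seed"`.
#' @export
generate_test_base <- function(kb, seed, profiles = NULL, n_negative = 5,
                               ruleset = NULL) {
  if (is.null(ruleset)) ruleset <- compile_kb(kb)
  if (is.null(profiles)) {
    vecs <- enumerate_vectors(kb)
    profiles <- lapply(seq_len(nrow(vecs)), function(i)
      vector_record(kb, vecs[i, , drop = FALSE]))
    names(profiles) <- paste0("profile", seq_along(profiles))
  }
  if (is.null(names(profiles)))
    names(profiles) <- paste0("profile", seq_along(profiles))

  dose_grid <- kb$verification$dose_grid
  if (is.null(dose_grid)) dose_grid <- list(NULL)
  # non-drug context shared by the recommendable treatments (e.g. diet)
  base_nondrug <- Filter(function(c) c$kind != "drug",
                         kb$treatments[[1]]$components)
  candidates <- list()
  for (cn in names(kb$drug_classes)) {
    for (d in dose_grid) {
      candidates[[length(candidates) + 1]] <- list(
        name = paste0(cn, if (!is.null(d)) paste0(" ", d$value, d$unit)),
        treatment = rx_treatment(
          c(base_nondrug,
            list(rx_drug(atc = kb$drug_classes[[cn]][1], inn = cn,
                         dose = d))),
          status = "proposed"))
    }
  }

  rows <- list(); records <- list()
  set.seed(seed)
  for (pn in names(profiles)) {
    prof <- profiles[[pn]]
    pos <- suggest_treatments(prof, kb, ruleset, k = 0)
    for (tn in pos) {
      r <- prof
      r$proposed <- template_treatment(kb$treatments[[tn]])
      cid <- paste0(pn, ":pos:", tn)
      rows[[length(rows) + 1]] <- list(profile = pn, case = cid,
                                       kind = "positive", treatment = tn,
                                       expected_conforms = TRUE)
      records[[cid]] <- r
    }
    ord <- sample(length(candidates))
    found <- 0
    for (i in ord) {
      if (found >= n_negative) break
      cand <- candidates[[i]]
      r <- prof
      r$proposed <- cand$treatment
      res <- critique(r, kb, ruleset)
      if (res$conforms) next
      found <- found + 1
      cid <- paste0(pn, ":neg", found)
      rows[[length(rows) + 1]] <- list(profile = pn, case = cid,
                                       kind = "negative",
                                       treatment = cand$name,
                                       expected_conforms = FALSE)
      records[[cid]] <- r
    }
    if (found < n_negative)
      warning("profile ", pn, ": only ", found,
              " constructible negative case(s)")
  }
  tb <- tibble::as_tibble(do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE))))
  structure(tb, records = records, seed = seed,
            class = c("rx_testbase", class(tb)))
}

#' Run a test base against the engine
#'
#' @param testbase An `rx_testbase` from [generate_test_base()].
#' @param kb The `rx_kb` it was generated from.
#' @param ruleset Optional pre-compiled `rx_ruleset`.
#' @return The test-base tibble with added `observed_conforms` and `pass`
#'   columns; overall success in the `"all_pass"` attribute.
#' @export
run_test_base <- function(testbase, kb, ruleset = NULL) {
  if (is.null(ruleset)) ruleset <- compile_kb(kb)
  records <- attr(testbase, "records")
  obs <- vapply(testbase$case, function(cid)
    critique(records[[cid]], kb, ruleset)$conforms, logical(1))
  out <- tibble::as_tibble(testbase)
  out$observed_conforms <- unname(obs)
  out$pass <- out$observed_conforms == out$expected_conforms
  structure(out, all_pass = all(out$pass))
}
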