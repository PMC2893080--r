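#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a compiled rule set
#'
#' One row per rule: identifiers, provenance (source recommendation or
#' generic id), the (X, Y) line pair for line-of-treatment rules, the
#' relaxation gap, and the criticism text.
#'
#' @param x An `rx_ruleset`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy rx_ruleset
#' @export
tidy.rx_ruleset <- function(x, ...) {
  r <- x$rules
  tibble::tibble(
    rule_id = vapply(r, function(z) z$id, character(1)),
    source = vapply(r, function(z) z$source, character(1)),
    source_type = vapply(r, function(z) z$source_type, character(1)),
    generic_id = vapply(r, function(z) as.integer(z$generic_id), integer(1)),
    X = vapply(r, function(z) as.integer(z$X), integer(1)),
    Y = vapply(r, function(z) as.integer(z$Y), integer(1)),
    gap = vapply(r, function(z) as.integer(z$gap), integer(1)),
    relaxable = vapply(r, function(z) z$relaxable, logical(1)),
    criticism = vapply(r, function(z) z$criticism, character(1)))
}

#' Tidy a critique result
#'
#' One row per fired rule with its composed criticism text.
#'
#' @param x An `rx_critique`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy rx_critique
#' @export
tidy.rx_critique <- function(x, ...) x$criticisms

#' One-row summary of a critique result
#'
#' @param x An `rx_critique`.
#' @param ... Unused.
#' @return A one-row tibble with `conforms`, `n_fired`, `n_suggestions`,
#'   `relaxation_level`, `insufficient_guidance`, `n_missing_data`.
#' @method glance rx_critique
#' @export
glance.rx_critique <- function(x, ...) {
  tibble::tibble(
    conforms = x$conforms,
    n_fired = nrow(x$criticisms),
    n_suggestions = length(x$suggestions),
    relaxation_level = x$relaxation_level,
    insufficient_guidance = x$insufficient_guidance,
    n_missing_data = length(x$missing_data_notes))
}

#' Tidy an induced decision tree
#'
#' One row per root-to-leaf path.
#'
#' @param x An `rx_tree`.
#' @param ... Unused.
#' @return A tibble with columns `path` and `label`.
#' @method tidy rx_tree
#' @export
tidy.rx_tree <- function(x, ...) tree_paths(x)

#' One-row summary of an induced decision tree
#'
#' @param x An `rx_tree`.
#' @param ... Unused.
#' @return A one-row tibble with `n_leaves`, `n_labels`, `depth`,
#'   `training_error`.
#' @method glance rx_tree
#' @export
glance.rx_tree <- function(x, ...) {
  depth <- function(node) {
    if (node$leaf) return(0L)
    1L + max(vapply(node$children, depth, integer(1)))
  }
  p <- tree_paths(x)
  tibble::tibble(n_leaves = nrow(p), n_labels = length(unique(p$label)),
                 depth = depth(x$root), training_error = x$training_error)
}

#' Plot an induced decision tree
#'
#' Dendrogram-style rendering: internal nodes show the split attribute,
#' edges the attribute value, leaves the accepted-treatment label
#' (bracketed treatments are second-line only).
#'
#' @param object An `rx_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rx_tree
#' @export
autoplot.rx_tree <- function(object, ...) {
  nodes <- list(); edges <- list()
  leaf_x <- 0
  place <- function(node, depth) {
    id <- length(nodes) + 1
    if (node$leaf) {
      leaf_x <<- leaf_x + 1
      nodes[[id]] <<- data.frame(id = id, x = leaf_x, y = -depth,
                                 text = node$label, leaf = TRUE)
      return(id)
    }
    nodes[[id]] <<- data.frame(id = id, x = NA, y = -depth,
                               text = node$attr, leaf = FALSE)
    kid_ids <- integer()
    for (val in names(node$children)) {
      cid <- place(node$children[[val]], depth + 1)
      kid_ids <- c(kid_ids, cid)
      edges[[length(edges) + 1]] <<- data.frame(from = id, to = cid,
                                                label = val)
    }
    nodes[[id]]$x <<- mean(vapply(kid_ids, function(k) nodes[[k]]$x,
                                  numeric(1)))
    id
  }
  place(object$root, 0)
  nd <- do.call(rbind, nodes)
  ed <- do.call(rbind, edges)
  seg <- data.frame(
    x = nd$x[ed$from], y = nd$y[ed$from],
    xend = nd$x[ed$to], yend = nd$y[ed$to],
    label = ed$label)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey60") +
    ggplot2::geom_label(
      data = seg,
      ggplot2::aes(x = (.data$x + .data$xend) / 2,
                   y = (.data$y + .data$yend) / 2, label = .data$label),
      size = 3, colour = "grey30") +
    ggplot2::geom_label(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$text,
                   fill = .data$leaf),
      size = 3, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white",
                                          `TRUE` = "#d9ead3")) +
    ggplot2::theme_void()
}

#' @importFrom rlang .data
NULL
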