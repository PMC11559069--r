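#' List the categories directly under a root term
#'
#' In the HPO organ-system analysis a "category" is a direct subclass of
#' Phenotypic abnormality (HP:0000118) — e.g. "Abnormality of the ear" —
#' of which there were 23 at the time of the motivating study. Obsolete
#' children are skipped. Output order is by label under a fixed byte-wise
#' (radix) sort so runs are deterministic across locales.
#'
#' @param graph An `ontology_graph`.
#' @param root_id Term id of the root whose direct children define the
#'   category layer (default `"HP:0000118"`).
#' @param root_label If non-`NULL`, the root's label must match this string
#'   (case-insensitively, after whitespace normalization); guards against
#'   running the extraction from the wrong root.
#' @return A tibble with columns `term_id`, `label`, one row per category;
#'   zero rows if the root is a leaf.
#' @export
list_categories <- function(graph, root_id = "HP:0000118",
                            root_label = NULL) {
  i <- term_row(graph, root_id)
  if (graph$terms$obsolete[i]) {
    stop("root term ", root_id, " is obsolete", call. = FALSE)
  }
  if (!is.null(root_label)) {
    have <- norm_header(graph$terms$label[i])
    want <- norm_header(root_label)
    if (!identical(have, want)) {
      stop("root ", root_id, " is labelled '", graph$terms$label[i],
           "', expected '", root_label, "'", call. = FALSE)
    }
  }
  kids <- ont_children(graph, root_id)
  out <- tibble::tibble(term_id = kids, label = term_labels(graph, kids))
  out[order(out$label, out$term_id, method = "radix"), ]
}

#' Extract a category's descendant closure and leaf set
#'
#' The members of a category are its full descendant closure under
#' subclass edges; the leaves are the members with no non-obsolete
#' subclass child anywhere in the graph. Because subclass closures are
#' downward closed (every child of a member is itself a member), a
#' member's leaf status within the closure coincides with its global leaf
#' status — the property tests assert this. The leaf set is what a
#' TogoDX-style per-category download contains.
#'
#' @param graph An `ontology_graph`.
#' @param category_id Term id of the category (any term works; categories
#'   are the intended case).
#' @return An object of class `category_extract`: a list with `category`
#'   (`term_id`, `label`), `members` and `leaves` (sorted character
#'   vectors of term ids; `members` excludes the category term itself).
#' @export
extract_category <- function(graph, category_id) {
  members <- ont_descendants(graph, category_id)
  obsolete <- graph$terms$obsolete
  idx <- graph$index[members]
  is_leaf <- vapply(idx, function(i) {
    kids <- graph$children[[i]]
    !any(!obsolete[kids])
  }, logical(1))
  structure(
    list(
      category = list(term_id = category_id,
                      label = term_labels(graph, category_id)),
      members = members,
      leaves = members[is_leaf]
    ),
    class = "category_extract"
  )
}

#' @export
print.category_extract <- function(x, ...) {
  cat("<category_extract> ", x$category$label, " (", x$category$term_id,
      "): ", length(x$members), " members, ", length(x$leaves),
      " leaves\n", sep = "")
  invisible(x)
}

#' Map every leaf under a root to the categories containing it
#'
#' HPO is a DAG: a term with multiple parents can descend from several
#' categories at once, and per-category counts then count it once per
#' category. This map makes that multiplicity explicit.
#'
#' @param graph An `ontology_graph`.
#' @param root_id Root term id (default `"HP:0000118"`).
#' @param categories Optional tibble from [list_categories()]; computed if
#'   `NULL`.
#' @return A tibble with columns `term_id`, `category_id`,
#'   `category_label`: one row per (leaf, containing category) pair. A
#'   multi-parent leaf contributes one row per category containing it.
#' @export
membership_map <- function(graph, root_id = "HP:0000118",
                           categories = NULL) {
  if (is.null(categories)) categories <- list_categories(graph, root_id)
  rows <- lapply(seq_len(nrow(categories)), function(k) {
    ex <- extract_category(graph, categories$term_id[k])
    if (length(ex$leaves) == 0) return(NULL)
    tibble::tibble(
      term_id = ex$leaves,
      category_id = categories$term_id[k],
      category_label = categories$label[k]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(term_id = character(), category_id = character(),
                          category_label = character())
  }
  out[order(out$term_id, out$category_id, method = "radix"), ]
}

#' Per-category term list as a tibble
#'
#' The shape of a per-category download: every member term with a flag
#' marking the leaves.
#'
#' @param extract A `category_extract`.
#' @param graph The `ontology_graph` the extract came from (for labels).
#' @return A tibble with columns `term_id`, `label`, `is_leaf`, ordered by
#'   term id.
#' @export
extract_table <- function(extract, graph) {
  stopifnot(inherits(extract, "category_extract"))
  tibble::tibble(
    term_id = extract$members,
    label = term_labels(graph, extract$members),
    is_leaf = extract$members %in% extract$leaves
  )
}
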