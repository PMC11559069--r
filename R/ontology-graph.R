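#' Construct an ontology graph
#'
#' Builds the central data structure of the package: a rooted directed
#' acyclic graph of ontology terms connected child-to-parent by subclass
#' (`is_a`) edges. The Human Phenotype Ontology is the motivating instance,
#' but any CURIE-identified subclass hierarchy fits.
#'
#' Structural problems that a corrupted export can exhibit (duplicate ids,
#' parents that resolve to no term, self loops, cycles) are deliberately
#' representable so that [validate_ontology()] can report them as data;
#' only malformed identifiers and missing labels are rejected outright.
#'
#' @param terms A data frame with columns `id` (character CURIE), `label`
#'   (character), `parents` (list of character vectors of parent ids), and
#'   optionally `definition` (character), `synonyms` (list of character
#'   vectors), `obsolete` (logical). Missing optional columns are filled.
#' @param id_prefix CURIE prefix every id must carry (default `"HP"`).
#'   Use `NULL` to accept any `<prefix>:<digits>` identifier.
#' @return An object of class `ontology_graph`.
#' @examples
#' g <- ontology_graph(tibble::tibble(
#'   id = c("HP:0000001", "HP:0000002"),
#'   label = c("root", "child"),
#'   parents = list(character(), "HP:0000001")
#' ))
#' ont_descendants(g, "HP:0000001")
#' @export
ontology_graph <- function(terms, id_prefix = "HP") {
  stopifnot(is.data.frame(terms))
  required <- c("id", "label", "parents")
  missing_cols <- setdiff(required, names(terms))
  if (length(missing_cols) > 0) {
    stop("terms is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  terms <- tibble::as_tibble(terms)
  if (!"definition" %in% names(terms)) terms$definition <- NA_character_
  if (!"synonyms" %in% names(terms)) {
    terms$synonyms <- rep(list(character()), nrow(terms))
  }
  if (!"obsolete" %in% names(terms)) terms$obsolete <- FALSE
  terms$obsolete[is.na(terms$obsolete)] <- FALSE

  bad_id <- !is_valid_term_id(terms$id, prefix = id_prefix)
  if (any(bad_id)) {
    stop("malformed term id(s): ",
         paste(utils::head(terms$id[bad_id], 5), collapse = ", "),
         call. = FALSE)
  }
  no_label <- !terms$obsolete & (is.na(terms$label) | !nzchar(terms$label))
  if (any(no_label)) {
    stop("non-obsolete term(s) with empty label: ",
         paste(utils::head(terms$id[no_label], 5), collapse = ", "),
         call. = FALSE)
  }
  # normalize parent lists: character, unique, no NA; self loops and
  # dangling references are preserved for validate_ontology() to report
  terms$parents <- lapply(terms$parents, function(p) {
    p <- as.character(p)
    unique(p[!is.na(p) & nzchar(p)])
  })
  terms <- terms[, c("id", "label", "definition", "synonyms",
                     "obsolete", "parents")]

  g <- structure(
    list(terms = terms, children = NULL, index = NULL),
    class = "ontology_graph"
  )
  rebuild_indexes(g)
}

# children adjacency (integer indexes) and id -> row lookup; parents that
# do not resolve or point at the term itself contribute no child edge
rebuild_indexes <- function(g) {
  ids <- g$terms$id
  idx <- seq_along(ids)
  names(idx) <- ids
  children <- vector("list", length(ids))
  for (i in idx) {
    for (p in g$terms$parents[[i]]) {
      j <- idx[p]
      if (!is.na(j) && j != i) children[[j]] <- c(children[[j]], i)
    }
  }
  g$children <- lapply(children, function(x) sort(unique(x)))
  g$index <- idx
  g
}

#' @export
print.ontology_graph <- function(x, ...) {
  n_obs <- sum(x$terms$obsolete)
  cat("<ontology_graph> ", nrow(x$terms), " terms (",
      n_obs, " obsolete), ",
      sum(lengths(x$terms$parents)), " subclass edges\n", sep = "")
  invisible(x)
}

#' Check CURIE syntax of term identifiers
#'
#' @param ids Character vector of candidate identifiers.
#' @param prefix Required CURIE prefix, or `NULL` for any alphanumeric
#'   prefix.
#' @return Logical vector.
#' @export
is_valid_term_id <- function(ids, prefix = "HP") {
  pat <- if (is.null(prefix)) {
    "^[A-Za-z][A-Za-z0-9_]*:[0-9]+$"
  } else {
    paste0("^", prefix, ":[0-9]+$")
  }
  !is.na(ids) & grepl(pat, ids)
}

#' Number of terms in a graph
#' @param graph An `ontology_graph`.
#' @export
n_terms <- function(graph) nrow(graph$terms)

#' Term identifiers of a graph
#' @param graph An `ontology_graph`.
#' @param drop_obsolete Drop obsolete terms (default `FALSE`).
#' @export
term_ids <- function(graph, drop_obsolete = FALSE) {
  ids <- graph$terms$id
  if (drop_obsolete) ids <- ids[!graph$terms$obsolete]
  ids
}

term_row <- function(graph, id) {
  i <- graph$index[id]
  if (is.na(i)) stop("unknown term id: ", id, call. = FALSE)
  unname(i)
}

#' Labels for term ids
#' @param graph An `ontology_graph`.
#' @param ids Character vector of term ids (all must exist).
#' @export
term_labels <- function(graph, ids) {
  i <- graph$index[ids]
  if (anyNA(i)) {
    stop("unknown term id: ", paste(ids[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  graph$terms$label[i]
}

#' Direct non-obsolete children of a term
#' @param graph An `ontology_graph`.
#' @param id A term id present in the graph.
#' @return Character vector of child term ids (obsolete children omitted).
#' @export
ont_children <- function(graph, id) {
  i <- term_row(graph, id)
  kids <- graph$children[[i]]
  kids <- kids[!graph$terms$obsolete[kids]]
  graph$terms$id[kids]
}

#' Descendant closure of a term
#'
#' All terms reachable downward from `id` along subclass edges, excluding
#' `id` itself. Obsolete terms are excluded entirely: they neither appear
#' in the result nor transmit reachability. Each term appears once no
#' matter how many paths lead to it (HPO is a DAG; multi-parent terms are
#' common).
#'
#' @param graph An `ontology_graph`.
#' @param id A term id present in the graph.
#' @return Character vector of descendant term ids, sorted.
#' @export
ont_descendants <- function(graph, id) {
  start <- term_row(graph, id)
  n <- nrow(graph$terms)
  seen <- logical(n)
  obsolete <- graph$terms$obsolete
  queue <- graph$children[[start]]
  queue <- queue[!obsolete[queue]]
  while (length(queue) > 0) {
    fresh <- queue[!seen[queue]]
    seen[fresh] <- TRUE
    queue <- unlist(graph$children[fresh], use.names = FALSE)
    if (length(queue) > 0) queue <- queue[!obsolete[queue] & !seen[queue]]
  }
  seen[start] <- FALSE
  sort(graph$terms$id[seen])
}

#' Global leaf terms of a graph
#'
#' A leaf is a non-obsolete term with no non-obsolete subclass child
#' anywhere in the graph — the terms a leaf-node extraction (as done by
#' TogoDX for HPO categories) reports.
#'
#' @param graph An `ontology_graph`.
#' @return Character vector of leaf term ids, sorted.
#' @export
global_leaves <- function(graph) {
  obsolete <- graph$terms$obsolete
  has_live_child <- vapply(
    graph$children,
    function(kids) any(!obsolete[kids]),
    logical(1)
  )
  sort(graph$terms$id[!obsolete & !has_live_child])
}

#' Validate an ontology graph
#'
#' Checks the structural invariants the rest of the pipeline relies on and
#' returns the violations as data rather than raising: callers decide
#' whether to escalate. Issue types: `duplicate_id`, `self_loop`,
#' `dangling_parent`, `cycle`.
#'
#' Cycle detection delegates to [igraph::components()] on the subclass
#' edge set: every term inside a non-trivial strongly connected component
#' lies on a cycle.
#'
#' @param graph An `ontology_graph`.
#' @return A tibble with columns `type`, `ids` (list column of the term
#'   ids involved), `message`; zero rows iff the graph is valid.
#' @export
validate_ontology <- function(graph) {
  issues <- list()
  add_issue <- function(type, ids, msg) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      type = type, ids = list(sort(unique(ids))), message = msg
    )
  }

  dup <- unique(graph$terms$id[duplicated(graph$terms$id)])
  for (d in dup) add_issue("duplicate_id", d, paste0("duplicate term id ", d))

  ids <- graph$terms$id
  for (i in seq_along(ids)) {
    pars <- graph$terms$parents[[i]]
    if (ids[i] %in% pars) {
      add_issue("self_loop", ids[i], paste0(ids[i], " lists itself as parent"))
    }
    missing <- setdiff(pars, ids)
    if (length(missing) > 0) {
      add_issue("dangling_parent", c(ids[i], missing),
                paste0(ids[i], " references absent parent(s): ",
                       paste(missing, collapse = ", ")))
    }
  }

  edges <- ontology_edges(graph, resolved_only = TRUE, keep_self = FALSE)
  if (nrow(edges) > 0) {
    ig <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                        vertices = unique(ids))
    comp <- igraph::components(ig, mode = "strong")
    sizes <- tabulate(comp$membership, comp$no)
    cyc <- which(sizes > 1)
    for (k in cyc) {
      members <- names(comp$membership)[comp$membership == k]
      add_issue("cycle", members,
                paste0("cycle through: ", paste(sort(members), collapse = " -> ")))
    }
  }

  if (length(issues) == 0) {
    tibble::tibble(type = character(), ids = list(), message = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Subclass edge list of a graph
#'
#' @param graph An `ontology_graph`.
#' @param resolved_only Drop edges whose parent id has no term row.
#' @param keep_self Keep self-referential edges (only useful when feeding
#'   diagnostics).
#' @return A tibble with columns `child`, `parent`.
#' @export
ontology_edges <- function(graph, resolved_only = FALSE, keep_self = TRUE) {
  np <- lengths(graph$terms$parents)
  child <- rep(graph$terms$id, np)
  parent <- unlist(graph$terms$parents, use.names = FALSE)
  if (is.null(parent)) parent <- character()
  keep <- rep(TRUE, length(child))
  if (resolved_only) keep <- keep & parent %in% graph$terms$id
  if (!keep_self) keep <- keep & child != parent
  tibble::tibble(child = child[keep], parent = parent[keep])
}

#' Stop unless a graph validates cleanly
#'
#' @param graph An `ontology_graph`.
#' @return `graph`, invisibly.
#' @export
assert_valid_ontology <- function(graph) {
  iss <- validate_ontology(graph)
  if (nrow(iss) > 0) {
    stop("ontology failed validation:\n",
         paste0("  [", iss$type, "] ", iss$message, collapse = "\n"),
         call. = FALSE)
  }
  invisible(graph)
}
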