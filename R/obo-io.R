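#' Read an ontology from an OBO flat file
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 document into an
#' [ontology_graph()]. Only the fields the downstream analysis uses are
#' retained: `id`, `name`, `def`, `synonym`, `is_a`, `is_obsolete`.
#' Relationship lines other than `is_a` (e.g. `part_of`) are counted and
#' ignored — category membership in this package is subclass-based, which
#' is how the HPO organ-system hierarchy is defined — and the count is
#' reported via a message so silently dropped structure is visible.
#' Obsolete terms are kept in the graph, flagged, and excluded from all
#' traversal.
#'
#' @param path Path to an OBO file (or a character vector of lines).
#' @param id_prefix Expected CURIE prefix of term ids (default `"HP"`);
#'   `NULL` accepts any prefix.
#' @param prune_dangling Drop parent references that resolve to no term
#'   instead of failing validation (default `FALSE`: corrupted exports
#'   should fail loudly).
#' @param quiet Suppress informational messages.
#' @return An `ontology_graph`.
#' @export
read_obo <- function(path, id_prefix = "HP", prune_dangling = FALSE,
                     quiet = FALSE) {
  lines <- if (length(path) == 1 && !grepl("\n", path) && file.exists(path)) {
    readLines(path, encoding = "UTF-8", warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE))
  }

  stanzas <- list()
  current <- NULL
  current_start <- NA_integer_
  in_term <- FALSE
  n_rel_ignored <- 0L

  flush_stanza <- function() {
    if (is.null(current)) return()
    if (is.null(current$id)) {
      stop("malformed [Term] stanza starting at line ", current_start,
           ": no id tag", call. = FALSE)
    }
    stanzas[[length(stanzas) + 1]] <<- current
    current <<- NULL
  }

  for (ln in seq_along(lines)) {
    line <- sub("\\s+$", "", lines[ln])
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush_stanza()
      in_term <- identical(line, "[Term]")
      if (in_term) {
        current <- list(id = NULL, name = NA_character_,
                        def = NA_character_, synonyms = character(),
                        parents = character(), obsolete = FALSE)
        current_start <- ln
      }
      next
    }
    if (!in_term || is.null(current)) next  # header or non-Term stanza body
    m <- regmatches(line, regexec("^([A-Za-z_-]+):\\s*(.*)$", line))[[1]]
    if (length(m) == 0) {
      stop("malformed line ", ln, " in [Term] stanza: ", line, call. = FALSE)
    }
    tag <- m[2]
    value <- m[3]
    if (tag == "id") {
      current$id <- trimws(value)
    } else if (tag == "name") {
      current$name <- trimws(value)
    } else if (tag == "is_a") {
      # strip trailing "! label" comment
      current$parents <- c(current$parents,
                           trimws(sub("\\s*!.*$", "", value)))
    } else if (tag == "is_obsolete") {
      current$obsolete <- identical(trimws(value), "true")
    } else if (tag == "def") {
      current$def <- obo_quoted(value, ln)
    } else if (tag == "synonym") {
      current$synonyms <- c(current$synonyms, obo_quoted(value, ln))
    } else if (tag == "relationship") {
      n_rel_ignored <- n_rel_ignored + 1L
    }
    # other tags (xref, comment, subset, ...) are ignored without counting
  }
  flush_stanza()

  if (length(stanzas) == 0) {
    stop("no [Term] stanzas found", call. = FALSE)
  }
  ids <- vapply(stanzas, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate term id(s) in OBO input: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  terms <- tibble::tibble(
    id = ids,
    label = vapply(stanzas, `[[`, character(1), "name"),
    definition = vapply(stanzas, `[[`, character(1), "def"),
    synonyms = lapply(stanzas, `[[`, "synonyms"),
    obsolete = vapply(stanzas, `[[`, logical(1), "obsolete"),
    parents = lapply(stanzas, `[[`, "parents")
  )
  if (prune_dangling) {
    known <- terms$id
    terms$parents <- lapply(terms$parents, intersect, known)
  }
  if (!quiet) {
    message("read_obo: ", nrow(terms), " terms (",
            sum(terms$obsolete), " obsolete); ignored ",
            n_rel_ignored, " non-is_a relationship line(s)")
  }
  ontology_graph(terms, id_prefix = id_prefix)
}

# first double-quoted string of an OBO tag value
obo_quoted <- function(value, ln) {
  m <- regmatches(value, regexec('^"((?:[^"\\\\]|\\\\.)*)"', value))[[1]]
  if (length(m) == 0) {
    stop("malformed quoted value at line ", ln, ": ", value, call. = FALSE)
  }
  gsub('\\\\(.)', "\\1", m[2])
}

obo_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub('"', '\\"', x, fixed = TRUE)
}

#' Write an ontology as an OBO flat file
#'
#' Emits the retained fields (`id`, `name`, `def`, `synonym`, `is_a`,
#' `is_obsolete`) as a minimal OBO 1.2 document. Stanzas are ordered by
#' term id and `is_a` lines by parent id, so the output is byte-stable for
#' a given graph: `read_obo(write_obo(g))` reproduces `g` exactly on the
#' retained fields.
#'
#' @param graph An `ontology_graph`.
#' @param path Output file path; `NULL` returns the lines invisibly
#'   without writing.
#' @return The character vector of lines, invisibly.
#' @export
write_obo <- function(graph, path = NULL) {
  terms <- graph$terms[order(graph$terms$id, method = "radix"), ]
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(terms))) {
    stanza <- c("[Term]", paste0("id: ", terms$id[i]))
    if (!is.na(terms$label[i])) {
      stanza <- c(stanza, paste0("name: ", terms$label[i]))
    }
    if (!is.na(terms$definition[i])) {
      stanza <- c(stanza,
                  paste0('def: "', obo_escape(terms$definition[i]), '" []'))
    }
    for (s in terms$synonyms[[i]]) {
      stanza <- c(stanza, paste0('synonym: "', obo_escape(s), '" EXACT []'))
    }
    for (p in sort(terms$parents[[i]], method = "radix")) {
      stanza <- c(stanza, paste0("is_a: ", p))
    }
    if (terms$obsolete[i]) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza, "")
  }
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
  }
  invisible(out)
}
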