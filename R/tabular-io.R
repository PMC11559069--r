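#' @importFrom rlang %||%
NULL

# read a delimited or Excel table as all-character tibble, by extension
read_table_any <- function(path) {
  if (is.data.frame(path)) {
    df <- tibble::as_tibble(path)
    df[] <- lapply(df, as.character)
    return(df)
  }
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (ext == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE)
  } else if (ext %in% c("tsv", "txt")) {
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE)
  } else if (ext %in% c("xlsx", "xls")) {
    df <- readxl::read_excel(path, sheet = 1, col_types = "text")
    tibble::as_tibble(df)
  } else {
    stop("unsupported table format: .", ext,
         " (expected csv, tsv, or xlsx)", call. = FALSE)
  }
}

write_table_any <- function(df, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    readr::write_csv(df, path, progress = FALSE)
  } else if (ext %in% c("tsv", "txt")) {
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    stop("unsupported output format: .", ext,
         " (csv and tsv are written; xlsx is read-only)", call. = FALSE)
  }
  invisible(path)
}

norm_header <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

# locate one column by normalized aliases; error names the table
find_column <- function(df, aliases, what, table_name, required = TRUE) {
  hit <- which(norm_header(names(df)) %in% norm_header(aliases))
  if (length(hit) == 0) {
    if (!required) return(NA_integer_)
    stop("table '", table_name, "' is missing required column '", what,
         "' (accepted headers: ", paste(aliases, collapse = ", "), ")",
         call. = FALSE)
  }
  hit[1]
}

split_multi <- function(x, delim) {
  lapply(x, function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character())
    trimws(strsplit(cell, delim, fixed = TRUE)[[1]])
  })
}

join_multi <- function(xs, delim) {
  vapply(xs, function(x) paste(x, collapse = delim), character(1))
}

#' Read an ontology from the two-table spreadsheet dialect
#'
#' An alternative to OBO input: a definitions table (columns `HPO id`,
#' `Label`, `Definition`, `Synonyms`) and a parent-child table (columns
#' `HPO id`, `Label`, `Parent`, `Child`), the export format in which HPO
#' circulates among curators as `Definition.xlsx` / `Parent_Child.xlsx`.
#' Multi-valued cells (several parents, children, or synonyms) are
#' delimiter-joined. The `Parent` and `Child` columns are redundant by
#' construction and are cross-checked: if term X lists Y as a child then
#' Y must list X as a parent and vice versa; any asymmetry fails with the
#' offending pairs listed.
#'
#' @param definitions Path (csv/tsv/xlsx) or data frame.
#' @param parent_child Path (csv/tsv/xlsx) or data frame.
#' @param delim Delimiter inside multi-valued cells (default `"|"`).
#' @param id_prefix Expected CURIE prefix (default `"HP"`).
#' @return An `ontology_graph`.
#' @export
read_ontology_tables <- function(definitions, parent_child, delim = "|",
                                 id_prefix = "HP") {
  defs <- read_table_any(definitions)
  pc <- read_table_any(parent_child)

  d_id <- find_column(defs, c("HPO id", "term id", "id"), "HPO id", "definitions")
  d_lab <- find_column(defs, "Label", "Label", "definitions")
  d_def <- find_column(defs, "Definition", "Definition", "definitions")
  d_syn <- find_column(defs, "Synonyms", "Synonyms", "definitions")
  p_id <- find_column(pc, c("HPO id", "term id", "id"), "HPO id", "parent_child")
  p_par <- find_column(pc, "Parent", "Parent", "parent_child")
  p_chi <- find_column(pc, "Child", "Child", "parent_child")

  def_ids <- trimws(defs[[d_id]])
  pc_ids <- trimws(pc[[p_id]])
  dup <- unique(c(def_ids[duplicated(def_ids)], pc_ids[duplicated(pc_ids)]))
  if (length(dup) > 0) {
    stop("duplicate term id(s) in tabular input: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }

  parents <- split_multi(pc[[p_par]], delim)
  children <- split_multi(pc[[p_chi]], delim)
  names(parents) <- pc_ids
  names(children) <- pc_ids

  # cross-check: the two redundant columns must agree edge for edge
  edge_pc <- function(map) {
    if (length(map) == 0) return(character())
    paste(rep(names(map), lengths(map)), unlist(map, use.names = FALSE))
  }
  from_parent <- edge_pc(parents)                     # "child parent"
  from_child <- unlist(lapply(names(children), function(p) {
    if (length(children[[p]]) == 0) return(character())
    paste(children[[p]], p)
  }), use.names = FALSE) %||% character()
  bad <- sort(unique(c(setdiff(from_parent, from_child),
                       setdiff(from_child, from_parent))))
  if (length(bad) > 0) {
    stop("inconsistent Parent/Child cross-references (child parent pairs ",
         "present on one side only): ",
         paste(utils::head(bad, 10), collapse = "; "), call. = FALSE)
  }

  all_ids <- union(def_ids, pc_ids)
  di <- match(all_ids, def_ids)
  terms <- tibble::tibble(
    id = all_ids,
    label = ifelse(is.na(di), NA_character_, trimws(defs[[d_lab]])[di]),
    definition = ifelse(is.na(di), NA_character_, defs[[d_def]][di]),
    synonyms = lapply(seq_along(all_ids), function(k) {
      if (is.na(di[k])) character() else
        split_multi(defs[[d_syn]][di[k]], delim)[[1]]
    }),
    obsolete = FALSE,
    parents = lapply(all_ids, function(id) parents[[id]] %||% character())
  )
  # a term present only in parent_child still needs a label for the graph
  miss <- is.na(terms$label)
  if (any(miss)) {
    pl <- trimws(pc[[find_column(pc, "Label", "Label", "parent_child")]])
    terms$label[miss] <- pl[match(terms$id[miss], pc_ids)]
  }
  ontology_graph(terms, id_prefix = id_prefix)
}

#' Write an ontology in the two-table spreadsheet dialect
#'
#' Inverse of [read_ontology_tables()] on the fields the dialect carries
#' (id, label, definition, synonyms, subclass edges). Obsolescence has no
#' column in this dialect, so obsolete terms are omitted. Rows are ordered
#' by term id; output is byte-stable.
#'
#' @param graph An `ontology_graph`.
#' @param definitions_path Output path (csv/tsv) for the definitions table.
#' @param parent_child_path Output path (csv/tsv) for the parent-child table.
#' @param delim Delimiter for multi-valued cells (default `"|"`).
#' @return Invisibly, a list of the two tibbles written.
#' @export
write_ontology_tables <- function(graph, definitions_path, parent_child_path,
                                  delim = "|") {
  terms <- graph$terms[!graph$terms$obsolete, ]
  terms <- terms[order(terms$id, method = "radix"), ]
  live <- terms$id

  defs <- tibble::tibble(
    `HPO id` = terms$id,
    Label = terms$label,
    Definition = ifelse(is.na(terms$definition), "", terms$definition),
    Synonyms = join_multi(terms$synonyms, delim)
  )
  kids <- lapply(terms$id, function(id) {
    sort(intersect(ont_children(graph, id), live), method = "radix")
  })
  pars <- lapply(terms$parents, function(p) sort(intersect(p, live),
                                                method = "radix"))
  pc <- tibble::tibble(
    `HPO id` = terms$id,
    Label = terms$label,
    Parent = join_multi(pars, delim),
    Child = join_multi(kids, delim)
  )
  write_table_any(defs, definitions_path)
  write_table_any(pc, parent_child_path)
  invisible(list(definitions = defs, parent_child = pc))
}
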