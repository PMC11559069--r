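#' The four curation attributes
#'
#' The clinician curation schema tags each phenotype term with any
#' combination of four attributes: Disease Name (the term is really the
#' name of a disease), Condition (a clinical state), Test Data (a value or
#' finding produced by a test), and Symptoms and Findings (abnormalities
#' revealable by physical examination). Multiple attributes per term are
#' allowed, as is none.
#'
#' @return Named character vector mapping internal flag names to canonical
#'   column headers.
#' @export
attribute_flags <- function() {
  c(disease_name = "Disease Names",
    condition = "Conditions",
    test_data = "Test Data",
    symptoms_findings = "Symptoms and Findings")
}

#' Recognized Test Data subtypes
#'
#' Test Data divides into findings detectable with tools and specialized
#' equipment, biochemical tests of body fluids, physiological tests,
#' imaging tests, and pathological tests.
#'
#' @return Character vector of subtype tokens.
#' @export
test_data_subtypes <- function() {
  c("findings_with_tools", "biochemical", "physiological",
    "imaging", "pathological")
}

attr_aliases <- list(
  term_id = c("HPO id", "term id", "id"),
  label = "Label",
  disease_name = c("Disease Names", "Disease Name"),
  condition = c("Conditions", "Condition"),
  test_data = c("Test Data"),
  symptoms_findings = c("Symptoms and Findings", "Symptoms/Findings",
                        "Symptoms Findings"),
  test_data_subtypes = c("Test Data Subtypes", "Test Data Subtype"),
  source = "Source",
  note = "Note"
)

# "+" is presence; Unicode minus, ASCII hyphen, en dash or an empty cell
# is absence — real spreadsheets mix all of them
parse_marker <- function(x, column, rows) {
  v <- trimws(ifelse(is.na(x), "", x))
  truth <- v == "+"
  falsy <- v %in% c("−", "-", "–", "")
  bad <- !truth & !falsy
  if (any(bad)) {
    stop("unrecognized marker '", v[which(bad)[1]], "' in column '", column,
         "', row ", rows[which(bad)[1]],
         " (expected '+', '−', '-' or empty)", call. = FALSE)
  }
  truth
}

#' Read a clinician curation table
#'
#' A curation table has the term id and label on the left followed by four
#' attribute columns whose cells carry `+` (attribute present) or `−`
#' (absent). An optional `Test Data Subtypes` column holds
#' delimiter-joined subtype tokens (see [test_data_subtypes()]). Headers
#' are matched case-insensitively against singular/plural aliases.
#'
#' @param path Path to a csv/tsv/xlsx file, or a data frame.
#' @param delim Delimiter inside the subtype column (default `"|"`).
#' @param source Provenance string stored on every record; defaults to the
#'   file name.
#' @param id_prefix Expected CURIE prefix of term ids (default `"HP"`).
#' @return A tibble with columns `term_id`, `label`, the four logical
#'   attribute flags, `test_data_subtypes` (list column), `source`,
#'   `note`.
#' @export
read_curation <- function(path, delim = "|", source = NULL,
                          id_prefix = "HP") {
  df <- read_table_any(path)
  if (is.null(source)) {
    source <- if (is.character(path)) basename(path) else "data.frame"
  }
  get <- function(key, required = TRUE) {
    find_column(df, attr_aliases[[key]], attr_aliases[[key]][1],
                "curation", required = required)
  }
  ci <- get("term_id"); cl <- get("label")
  flag_cols <- vapply(names(attribute_flags()), get, integer(1))
  cs <- get("test_data_subtypes", required = FALSE)
  cn <- get("note", required = FALSE)

  rows <- seq_len(nrow(df)) + 1L  # +1 for the header row in messages
  term_id <- trimws(df[[ci]])
  bad_id <- !is_valid_term_id(term_id, prefix = id_prefix)
  if (any(bad_id)) {
    stop("invalid term id '", term_id[which(bad_id)[1]], "' at row ",
         rows[which(bad_id)[1]], call. = FALSE)
  }
  dup <- unique(term_id[duplicated(term_id)])
  if (length(dup) > 0) {
    stop("duplicate term id(s) in curation table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }

  out <- tibble::tibble(term_id = term_id, label = trimws(df[[cl]]))
  for (flag in names(attribute_flags())) {
    header <- names(df)[flag_cols[[flag]]]
    out[[flag]] <- parse_marker(df[[flag_cols[[flag]]]], header, rows)
  }
  out$test_data_subtypes <- if (is.na(cs)) {
    rep(list(character()), nrow(out))
  } else {
    split_multi(df[[cs]], delim)
  }
  bad_tok <- vapply(out$test_data_subtypes,
                    function(s) any(!s %in% test_data_subtypes()),
                    logical(1))
  if (any(bad_tok)) {
    k <- which(bad_tok)[1]
    stop("unknown Test Data subtype token(s) at row ", rows[k], ": ",
         paste(setdiff(out$test_data_subtypes[[k]], test_data_subtypes()),
               collapse = ", "), call. = FALSE)
  }
  # subtypes imply the Test Data flag; a contradiction is a curation error
  contradict <- lengths(out$test_data_subtypes) > 0 & !out$test_data
  if (any(contradict)) {
    stop("row ", rows[which(contradict)[1]], ": Test Data subtypes given ",
         "but Test Data marked absent", call. = FALSE)
  }
  out$source <- source
  out$note <- if (is.na(cn)) NA_character_ else as.character(df[[cn]])
  out
}

#' Write a curation table
#'
#' Inverse of [read_curation()]: emits the canonical headers with `+` /
#' `−` markers (the Unicode minus, as curation spreadsheets print it).
#' Only csv/tsv output is supported.
#'
#' @param curation A curation tibble as returned by [read_curation()] or
#'   [curation_template()].
#' @param path Output path (.csv or .tsv).
#' @param delim Delimiter for the subtype column (default `"|"`).
#' @return `path`, invisibly.
#' @export
write_curation <- function(curation, path, delim = "|") {
  mark <- function(x) ifelse(x, "+", "−")
  flags <- attribute_flags()
  df <- tibble::tibble(`HPO id` = curation$term_id, Label = curation$label)
  for (flag in names(flags)) df[[flags[[flag]]]] <- mark(curation[[flag]])
  df$`Test Data Subtypes` <-
    join_multi(curation$test_data_subtypes %||% rep(list(character()),
                                                    nrow(curation)),
               delim)
  write_table_any(df, path)
}

#' Blank curation template for a category extract
#'
#' One row per leaf term with id and label filled in and every attribute
#' marked absent — the draft a curating clinician starts from. Rows are
#' label-sorted (byte-wise) so regeneration is bit-stable.
#'
#' @param extract A `category_extract`.
#' @param graph The `ontology_graph` the extract came from.
#' @return A curation tibble with all flags `FALSE`.
#' @export
curation_template <- function(extract, graph) {
  stopifnot(inherits(extract, "category_extract"))
  leaves <- extract$leaves
  labels <- term_labels(graph, leaves)
  ord <- order(labels, leaves, method = "radix")
  n <- length(leaves)
  tibble::tibble(
    term_id = leaves[ord],
    label = labels[ord],
    disease_name = logical(n),
    condition = logical(n),
    test_data = logical(n),
    symptoms_findings = logical(n),
    test_data_subtypes = rep(list(character()), n),
    source = "template",
    note = NA_character_
  )
}

#' Merge a curation table onto a category extract
#'
#' Aligns curated records with the extract's leaf set. Leaves without a
#' record are reported as `uncurated` (they count as all-false in
#' downstream statistics, keeping the full leaf count in percentage
#' denominators); curated ids absent from the leaf set are reported as
#' `stale` (e.g. from an older ontology release) and excluded from
#' statistics. Gaps are data, not errors.
#'
#' @param extract A `category_extract`.
#' @param curation A curation tibble.
#' @return An object of class `annotated_extract`: a list with `extract`,
#'   `annotations` (curation rows restricted to leaves, term-id ordered),
#'   `uncurated` and `stale` (sorted character vectors).
#' @export
merge_curation <- function(extract, curation) {
  stopifnot(inherits(extract, "category_extract"))
  leaves <- extract$leaves
  ann <- curation[curation$term_id %in% leaves, , drop = FALSE]
  ann <- ann[order(ann$term_id, method = "radix"), ]
  structure(
    list(
      extract = extract,
      annotations = ann,
      uncurated = sort(setdiff(leaves, curation$term_id)),
      stale = sort(setdiff(curation$term_id, leaves))
    ),
    class = "annotated_extract"
  )
}

#' @export
print.annotated_extract <- function(x, ...) {
  cat("<annotated_extract> ", x$extract$category$label, ": ",
      length(x$extract$leaves), " leaves, ",
      nrow(x$annotations), " curated, ",
      length(x$uncurated), " uncurated, ",
      length(x$stale), " stale\n", sep = "")
  invisible(x)
}
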