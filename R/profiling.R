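#' Percentage with half-up rounding to one decimal
#'
#' Computes `100 * k / n` rounded to one decimal with ties rounding away
#' from zero, the convention of the curation reports this package
#' reproduces (e.g. 895 of 961 terms is 93.1; 1 of 16 is 6.25 and rounds
#' to 6.3). The computation is exact integer arithmetic —
#' `tenths = (2000 k + n) %/% (2 n)` — so the tie rule is bit-stable and
#' immune to binary floating-point artefacts in `100*k/n`.
#'
#' @param k Count of items with the property, `0 <= k <= n` (vectorized).
#' @param n Total count, `> 0`.
#' @return Numeric vector of percentages with one decimal of resolution.
#' @export
percent_half_up <- function(k, n) {
  if (length(n) == 1) n <- rep(n, length(k))
  stopifnot(length(k) == length(n))
  if (any(is.na(k) | is.na(n))) stop("k and n must be non-missing",
                                     call. = FALSE)
  if (any(n == 0)) stop("undefined denominator: n = 0", call. = FALSE)
  if (any(k < 0 | n < 0 | k > n)) {
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  if (any(k != floor(k) | n != floor(n))) {
    stop("k and n must be whole numbers", call. = FALSE)
  }
  tenths <- (2000 * k + n) %/% (2 * n)
  tenths / 10
}

# mean of integer counts, half-up to one decimal, exact
mean_half_up1 <- function(counts) {
  s <- sum(counts)
  n <- length(counts)
  ((20 * s + n) %/% (2 * n)) / 10
}

#' Per-category leaf count table
#'
#' The "number of terms in each category" report: one row per category
#' extract with the size of its leaf set, in input order.
#'
#' @param extracts A list of `category_extract` objects.
#' @return A tibble with columns `category_label`, `n_total`.
#' @export
count_table <- function(extracts) {
  stopifnot(all(vapply(extracts, inherits, logical(1), "category_extract")))
  tibble::tibble(
    category_label = vapply(extracts, function(e) e$category$label,
                            character(1)),
    n_total = vapply(extracts, function(e) length(e$leaves), integer(1))
  )
}

#' Summary statistics over per-category counts
#'
#' @param counts A data frame with a `n_total` column (as from
#'   [count_table()]), or a bare numeric vector of counts.
#' @return A one-row tibble: `n_categories`, `mean_count` (half-up to one
#'   decimal), `min_count`, `max_count`.
#' @export
summarize_counts <- function(counts) {
  x <- if (is.data.frame(counts)) counts$n_total else counts
  if (length(x) == 0) stop("no counts to summarize", call. = FALSE)
  tibble::tibble(
    n_categories = length(x),
    mean_count = mean_half_up1(x),
    min_count = as.integer(min(x)),
    max_count = as.integer(max(x))
  )
}

#' Per-category attribute composition profile
#'
#' For each annotated extract, counts the leaf terms whose curation flags
#' the chosen attribute and expresses it as a percentage of the full leaf
#' count. Uncurated leaves count as not-flagged but stay in the
#' denominator, so a category curated 895-of-961 with all 895 flagged
#' reports 93.1. Stale records (ids outside the leaf set) are ignored. An
#' empty category reports `NA` percent — distinct from an observed 0.0.
#'
#' @param annotated A list of `annotated_extract` objects (or a single
#'   one).
#' @param attribute One of `"disease_name"`, `"condition"`, `"test_data"`,
#'   `"symptoms_findings"`.
#' @return A tibble with columns `category_label`, `n_total`,
#'   `n_attribute`, `percent`.
#' @export
attribute_profile <- function(annotated, attribute = "symptoms_findings") {
  if (inherits(annotated, "annotated_extract")) annotated <- list(annotated)
  attribute <- match.arg(attribute, names(attribute_flags()))
  rows <- lapply(annotated, function(a) {
    stopifnot(inherits(a, "annotated_extract"))
    n_total <- length(a$extract$leaves)
    n_attr <- if (nrow(a$annotations) == 0) 0L else
      sum(a$annotations[[attribute]])
    tibble::tibble(
      category_label = a$extract$category$label,
      n_total = n_total,
      n_attribute = as.integer(n_attr),
      percent = if (n_total > 0) percent_half_up(n_attr, n_total) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Category overlap matrix
#'
#' Because HPO is a DAG, a multi-parent leaf can belong to several
#' categories and per-category counts double-count it across rows. This
#' matrix quantifies the double counting: entry (i, j) is the number of
#' leaves in both category i and category j; the diagonal holds each
#' category's leaf count, so the diagonal sum equals the [count_table()]
#' total.
#'
#' @param membership Tibble from [membership_map()].
#' @param categories Optional tibble (`term_id`, `label`) fixing the
#'   row/column set and order; defaults to the categories present in
#'   `membership`.
#' @return A symmetric integer matrix with category labels as dimnames.
#' @export
overlap_matrix <- function(membership, categories = NULL) {
  labs <- if (is.null(categories)) {
    sort(unique(membership$category_label), method = "radix")
  } else {
    categories$label
  }
  inc <- matrix(0L, nrow = length(unique(membership$term_id)),
                ncol = length(labs),
                dimnames = list(NULL, labs))
  if (nrow(membership) > 0) {
    ti <- match(membership$term_id, sort(unique(membership$term_id)))
    ci <- match(membership$category_label, labs)
    ok <- !is.na(ci)
    inc[cbind(ti[ok], ci[ok])] <- 1L
  }
  m <- crossprod(inc)
  storage.mode(m) <- "integer"
  m
}

#' Render a data frame as a Markdown table
#'
#' Minimal pipe-table renderer for the human-facing reports; numeric
#' columns with a `percent` name are printed with one decimal, `NA` as
#' `"NA"`.
#'
#' @param df A data frame.
#' @return Character vector of Markdown lines.
#' @export
render_markdown_table <- function(df) {
  fmt_col <- function(x, name) {
    if (is.numeric(x) && grepl("percent|mean", name)) {
      ifelse(is.na(x), "NA", sprintf("%.1f", x))
    } else {
      ifelse(is.na(x), "NA", as.character(x))
    }
  }
  cells <- mapply(fmt_col, df, names(df), SIMPLIFY = FALSE)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- if (nrow(df) == 0) character() else {
    apply(do.call(cbind, cells), 1, function(r) {
      paste0("| ", paste(r, collapse = " | "), " |")
    })
  }
  c(header, sep, body)
}
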