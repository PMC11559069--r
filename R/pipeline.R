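#' Assemble a pipeline run configuration
#'
#' A `run_config` captures everything a pipeline run depends on; every
#' `run_*()` function serializes the resolved configuration to
#' `config.json` in its output directory, so any report can be reproduced
#' from the artifacts alone. No run mutates its inputs; outputs go only to
#' `out_dir`.
#'
#' @param out_dir Output directory (created if absent).
#' @param input Path to an OBO file (when `format = "obo"`).
#' @param format Input format: `"obo"` or `"tabular"`.
#' @param definitions,parent_child Paths for the two-table dialect (when
#'   `format = "tabular"`).
#' @param root_id Root term whose direct children are the categories.
#' @param root_label Optional label check for the root (e.g. `"Phenotypic
#'   abnormality"`); `NULL` skips the check.
#' @param categories `"all"` or a character vector of category labels or
#'   ids; labels match case-insensitively after whitespace normalization,
#'   and an unknown selection fails listing the available labels (no fuzzy
#'   matching — silently wrong categories are dangerous in curation work).
#' @param curation Named character vector of curation table paths, names
#'   being category labels.
#' @param attribute Attribute to profile (default `"symptoms_findings"`).
#' @param out_formats Subset of `c("tsv", "md")`.
#' @param delim Multi-value cell delimiter.
#' @param id_prefix CURIE prefix of term ids.
#' @param seed Seed for [run_simulate()].
#' @param sim Named list of [synthetic_spec()] arguments overriding its
#'   defaults (besides `seed`).
#' @param quiet Suppress progress messages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, input = NULL, format = c("obo", "tabular"),
                       definitions = NULL, parent_child = NULL,
                       root_id = "HP:0000118", root_label = NULL,
                       categories = "all", curation = NULL,
                       attribute = "symptoms_findings",
                       out_formats = c("tsv", "md"), delim = "|",
                       id_prefix = "HP", seed = 1L, sim = list(),
                       quiet = FALSE) {
  format <- match.arg(format)
  attribute <- match.arg(attribute, names(attribute_flags()))
  stopifnot(all(out_formats %in% c("tsv", "md")))
  structure(
    list(out_dir = out_dir, input = input, format = format,
         definitions = definitions, parent_child = parent_child,
         root_id = root_id, root_label = root_label,
         categories = categories, curation = curation,
         attribute = attribute, out_formats = out_formats, delim = delim,
         id_prefix = id_prefix, seed = as.integer(seed), sim = sim,
         quiet = quiet),
    class = "run_config"
  )
}

cfg_inform <- function(config, ...) {
  if (!isTRUE(config$quiet)) message(...)
}

write_config_json <- function(config, out_dir) {
  cfg <- unclass(config)
  cfg$sim <- if (length(cfg$sim) == 0) NULL else cfg$sim
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
}

slugify <- function(x) {
  s <- gsub("[^a-z0-9]+", "_", tolower(x))
  gsub("^_+|_+$", "", s)
}

load_graph <- function(config) {
  if (config$format == "obo") {
    if (is.null(config$input)) stop("config$input required for OBO format",
                                    call. = FALSE)
    read_obo(config$input, id_prefix = config$id_prefix,
             quiet = config$quiet)
  } else {
    if (is.null(config$definitions) || is.null(config$parent_child)) {
      stop("config$definitions and config$parent_child required for ",
           "tabular format", call. = FALSE)
    }
    read_ontology_tables(config$definitions, config$parent_child,
                         delim = config$delim,
                         id_prefix = config$id_prefix)
  }
}

select_categories <- function(categories_tbl, selection) {
  if (identical(selection, "all")) return(categories_tbl)
  want <- norm_header(selection)
  have_lab <- norm_header(categories_tbl$label)
  hit <- match(want, have_lab)
  by_id <- match(selection, categories_tbl$term_id)
  hit[is.na(hit)] <- by_id[is.na(hit)]
  if (anyNA(hit)) {
    stop("unknown category selection: ",
         paste(selection[is.na(hit)], collapse = ", "),
         "\navailable labels: ",
         paste(categories_tbl$label, collapse = "; "), call. = FALSE)
  }
  categories_tbl[hit, ]
}

#' Extract category leaf lists and count reports
#'
#' Runs the extraction stage end to end: load and validate the ontology,
#' find the categories under the root, compute each selected category's
#' member/leaf sets, and write one term-list TSV per category plus the
#' per-category leaf-count report and its summary statistics. Rerunning
#' with the same config writes byte-identical files.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `graph`, `categories`, `extracts`,
#'   `counts`, `summary`.
#' @export
run_extract <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  graph <- load_graph(config)
  assert_valid_ontology(graph)
  cfg_inform(config, "parsed ", n_terms(graph), " terms (",
             sum(graph$terms$obsolete), " obsolete skipped in traversal)")
  cats <- list_categories(graph, config$root_id, config$root_label)
  cfg_inform(config, "found ", nrow(cats), " categories under ",
             config$root_id)
  sel <- select_categories(cats, config$categories)

  extracts <- lapply(sel$term_id, function(id) extract_category(graph, id))
  for (ex in extracts) {
    f <- file.path(config$out_dir,
                   paste0(slugify(ex$category$label), ".terms.tsv"))
    readr::write_tsv(extract_table(ex, graph), f, progress = FALSE)
    cfg_inform(config, "  ", ex$category$label, ": ",
               length(ex$members), " members, ", length(ex$leaves),
               " leaves")
  }
  counts <- count_table(extracts)
  summary <- summarize_counts(counts)
  if ("tsv" %in% config$out_formats) {
    readr::write_tsv(counts, file.path(config$out_dir,
                                       "category_counts.tsv"),
                     progress = FALSE)
    readr::write_tsv(summary, file.path(config$out_dir,
                                        "summary_stats.tsv"),
                     progress = FALSE)
  }
  if ("md" %in% config$out_formats) {
    md <- c("# Leaf-term counts per category", "",
            render_markdown_table(counts), "",
            "# Summary", "", render_markdown_table(summary))
    writeLines(md, file.path(config$out_dir, "category_counts.md"),
               useBytes = TRUE)
  }
  write_config_json(config, config$out_dir)
  invisible(list(graph = graph, categories = sel, extracts = extracts,
                 counts = counts, summary = summary))
}

#' Profile attribute composition of curated categories
#'
#' Merges curation tables onto their categories' leaf sets and writes the
#' attribute composition report (per-category totals, flagged counts, and
#' half-up one-decimal percentages) together with curation-coverage
#' diagnostics (uncurated and stale term counts). All curation files are
#' checked before anything is written, so a failed run leaves no partial
#' report.
#'
#' @param config A [run_config()] whose `curation` names category labels
#'   and maps them to table paths.
#' @return Invisibly, a list with `annotated`, `profile`, `diagnostics`.
#' @export
run_profile <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$curation) || length(config$curation) == 0) {
    stop("config$curation must name at least one curation table",
         call. = FALSE)
  }
  if (is.null(names(config$curation)) ||
      any(!nzchar(names(config$curation)))) {
    stop("config$curation must be named by category label", call. = FALSE)
  }
  missing <- config$curation[!file.exists(config$curation)]
  if (length(missing) > 0) {
    stop("curation file(s) not found: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  graph <- load_graph(config)
  assert_valid_ontology(graph)
  cats <- list_categories(graph, config$root_id, config$root_label)
  sel <- select_categories(cats, names(config$curation))

  annotated <- lapply(seq_len(nrow(sel)), function(k) {
    cur <- read_curation(config$curation[[k]], delim = config$delim,
                         id_prefix = config$id_prefix)
    merge_curation(extract_category(graph, sel$term_id[k]), cur)
  })
  profile <- attribute_profile(annotated, config$attribute)
  diagnostics <- tibble::tibble(
    category_label = profile$category_label,
    n_leaves = profile$n_total,
    n_curated = vapply(annotated, function(a) nrow(a$annotations),
                       integer(1)),
    n_uncurated = vapply(annotated, function(a) length(a$uncurated),
                         integer(1)),
    n_stale = vapply(annotated, function(a) length(a$stale), integer(1))
  )
  for (k in seq_along(annotated)) {
    cfg_inform(config, "  ", diagnostics$category_label[k], ": ",
               diagnostics$n_curated[k], " curated, ",
               diagnostics$n_uncurated[k], " uncurated, ",
               diagnostics$n_stale[k], " stale")
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if ("tsv" %in% config$out_formats) {
    readr::write_tsv(profile, file.path(config$out_dir,
                                        "attribute_profile.tsv"),
                     progress = FALSE)
    readr::write_tsv(diagnostics,
                     file.path(config$out_dir,
                               "curation_diagnostics.tsv"),
                     progress = FALSE)
  }
  if ("md" %in% config$out_formats) {
    md <- c(paste0("# ", attribute_flags()[[config$attribute]],
                   " per category"), "",
            render_markdown_table(profile), "",
            "# Curation coverage", "",
            render_markdown_table(diagnostics))
    writeLines(md, file.path(config$out_dir, "attribute_profile.md"),
               useBytes = TRUE)
  }
  write_config_json(config, config$out_dir)
  invisible(list(annotated = annotated, profile = profile,
                 diagnostics = diagnostics))
}

#' Write blank curation templates for selected categories
#'
#' @param config A [run_config()].
#' @return Invisibly, the list of template tibbles (named by category
#'   label).
#' @export
run_template <- function(config) {
  stopifnot(inherits(config, "run_config"))
  graph <- load_graph(config)
  assert_valid_ontology(graph)
  cats <- list_categories(graph, config$root_id, config$root_label)
  sel <- select_categories(cats, config$categories)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  templates <- lapply(seq_len(nrow(sel)), function(k) {
    ex <- extract_category(graph, sel$term_id[k])
    tpl <- curation_template(ex, graph)
    write_curation(tpl, file.path(config$out_dir,
                                  paste0(slugify(sel$label[k]),
                                         ".template.csv")),
                   delim = config$delim)
    tpl
  })
  names(templates) <- sel$label
  write_config_json(config, config$out_dir)
  invisible(templates)
}

#' Simulate a synthetic ontology and curation fixture set
#'
#' Generates a seeded synthetic ontology plus matching curation tables
#' and writes the full fixture set: the OBO file, the two-table dialect,
#' one curation CSV per category, the generator spec, and the recorded
#' ground truth (category list, leaf sets, true tag counts) as JSON.
#' The fixtures parse back cleanly through [run_extract()] and
#' [run_profile()], and identical seeds yield byte-identical files.
#'
#' @param config A [run_config()]; `seed` and `sim` parameterize
#'   [synthetic_spec()].
#' @return Invisibly, a list with `synth`, `curation`, `paths`.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- do.call(synthetic_spec,
                  c(list(seed = config$seed,
                         id_prefix = config$id_prefix), config$sim))
  synth <- generate_ontology(spec)
  curation <- generate_curation(synth)
  cfg_inform(config, "simulated ", n_terms(synth$graph), " terms in ",
             nrow(synth$categories), " categories")

  out <- config$out_dir
  dir.create(file.path(out, "curation"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- list(
    obo = file.path(out, "synthetic.obo"),
    definitions = file.path(out, "definitions.csv"),
    parent_child = file.path(out, "parent_child.csv"),
    ground_truth = file.path(out, "ground_truth.json"),
    spec = file.path(out, "spec.json")
  )
  write_obo(synth$graph, paths$obo)
  write_ontology_tables(synth$graph, paths$definitions, paths$parent_child,
                        delim = config$delim)
  paths$curation <- vapply(names(curation$tables), function(lab) {
    f <- file.path(out, "curation", paste0(slugify(lab), ".csv"))
    write_curation(curation$tables[[lab]], f, delim = config$delim)
    f
  }, character(1))

  jsonlite::write_json(
    list(root_id = synth$root_id,
         categories = synth$categories,
         leaf_sets = synth$leaf_sets,
         member_sets = synth$member_sets,
         true_counts = curation$true_counts),
    paths$ground_truth, pretty = TRUE, digits = NA
  )
  jsonlite::write_json(
    unclass(spec)[c("seed", "n_categories", "depth", "branching_mean",
                    "multi_parent_prob", "id_prefix")],
    paths$spec, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_config_json(config, out)
  invisible(list(synth = synth, curation = curation, paths = paths))
}
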