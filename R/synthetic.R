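#' Specification of a synthetic test ontology
#'
#' Parameterizes a seeded generator of rooted DAGs shaped like the HPO
#' Phenotypic-abnormality branch: a root, a layer of categories directly
#' under it, layered trees below the categories, and extra child-to-parent
#' cross-links that make some terms multi-parent (so they descend from
#' more than one category, as in the real ontology). Generation is a pure
#' function of the spec: the same spec yields byte-identical artifacts.
#'
#' Defaults mirror the profiled study conditions: 23 categories, four
#' layers of terms below them, Poisson(2.5) branching, a 10% chance of an
#' extra parent per eligible term, and Symptoms-and-Findings tagging
#' probabilities spread over \[0, 0.93\] across categories (the published
#' curation found per-category proportions from 0 to 93.1%).
#'
#' @param seed Integer seed; three per-concern substreams (topology,
#'   labels, tags) are derived from it, so e.g. changing tag proportions
#'   never perturbs topology.
#' @param n_categories Number of direct children of the root.
#' @param depth Number of term layers below the category layer (>= 1).
#' @param branching_mean Mean of the Poisson child count per internal
#'   term.
#' @param multi_parent_prob Probability that a term at least two layers
#'   deep gains one extra parent in a strictly shallower layer. Links
#'   only ever point from deeper to shallower layers, so acyclicity is
#'   structural, not checked-and-rejected (rejection would bias the
#'   seeded stream).
#' @param attribute_proportions Data frame with one row per category
#'   (recycled or matched by position) and columns `disease_name`,
#'   `condition`, `test_data`, `symptoms_findings` of per-attribute
#'   tagging probabilities; `NULL` for the defaults described above.
#' @param id_prefix CURIE prefix for generated ids (default `"HP"`).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_categories = 23L, depth = 4L,
                           branching_mean = 2.5, multi_parent_prob = 0.1,
                           attribute_proportions = NULL,
                           id_prefix = "HP") {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (depth < 1) stop("degenerate spec: depth must be >= 1", call. = FALSE)
  if (n_categories < 1) stop("n_categories must be >= 1", call. = FALSE)
  if (branching_mean <= 0) stop("branching_mean must be > 0", call. = FALSE)
  if (multi_parent_prob < 0 || multi_parent_prob > 1) {
    stop("multi_parent_prob must be in [0, 1]", call. = FALSE)
  }
  if (is.null(attribute_proportions)) {
    attribute_proportions <- tibble::tibble(
      disease_name = rep(0.2, n_categories),
      condition = rep(0.3, n_categories),
      test_data = rep(0.25, n_categories),
      symptoms_findings = seq(0, 0.93, length.out = n_categories)
    )
  }
  attribute_proportions <- tibble::as_tibble(attribute_proportions)
  needed <- names(attribute_flags())
  if (!all(needed %in% names(attribute_proportions))) {
    stop("attribute_proportions needs columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (nrow(attribute_proportions) == 1) {
    attribute_proportions <-
      attribute_proportions[rep(1, n_categories), ]
  }
  if (nrow(attribute_proportions) != n_categories) {
    stop("attribute_proportions must have 1 or n_categories rows",
         call. = FALSE)
  }
  probs <- unlist(attribute_proportions[needed])
  if (any(probs < 0 | probs > 1)) {
    stop("attribute proportions must be probabilities in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_categories = as.integer(n_categories),
         depth = as.integer(depth), branching_mean = branching_mean,
         multi_parent_prob = multi_parent_prob,
         attribute_proportions = attribute_proportions,
         id_prefix = id_prefix),
    class = "synthetic_spec"
  )
}

# evaluate expr under a temporary RNG state; never leaks into the caller
with_rng <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

# one fixed sub-seed per concern, derived from the spec seed
sub_seeds <- function(seed) {
  with_rng(seed, {
    s <- sample.int(.Machine$integer.max - 1L, 3L)
    names(s) <- c("topology", "labels", "tags")
    s
  })
}

syllables <- c("bra", "cor", "dex", "fal", "gly", "hep", "lim", "mur",
               "nex", "oss", "pel", "qua", "ren", "sol", "tor", "uln",
               "vas", "xan", "zon")

random_words <- function(n) {
  vapply(seq_len(n), function(i) {
    k <- sample(2:3, 1)
    paste(sample(syllables, k, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a synthetic ontology with recorded ground truth
#'
#' Builds the DAG described by a [synthetic_spec()] and records, during
#' construction and with its own reachability loop (never by calling the
#' traversal code under test), the ground truth every pipeline stage can
#' be checked against: the category list, each category's member and leaf
#' sets.
#'
#' @param spec A `synthetic_spec`.
#' @return An object of class `synthetic_ontology`: a list with `graph`
#'   (an `ontology_graph`), `categories` (tibble `term_id`, `label`, in
#'   label order), `member_sets` and `leaf_sets` (named lists, category
#'   term id -> sorted character vectors), and `spec`.
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seeds <- sub_seeds(spec$seed)

  # --- topology -----------------------------------------------------------
  topo <- with_rng(seeds[["topology"]], {
    layer <- c(0L, rep(1L, spec$n_categories))
    parent_of <- c(NA_integer_, rep(1L, spec$n_categories))
    extra_parent <- rep(NA_integer_, 1L + spec$n_categories)
    n_nodes <- 1L + spec$n_categories
    current <- 2L:(1L + spec$n_categories)
    for (d in seq_len(spec$depth)) {
      next_layer <- integer()
      for (p in current) {
        nk <- stats::rpois(1, spec$branching_mean)
        if (nk > 0) {
          new_ids <- n_nodes + seq_len(nk)
          layer[new_ids] <- d + 1L
          parent_of[new_ids] <- p
          extra_parent[new_ids] <- NA_integer_
          n_nodes <- n_nodes + nk
          next_layer <- c(next_layer, new_ids)
        }
      }
      current <- next_layer
      if (length(current) == 0) break
    }
    # cross-links: deeper -> strictly shallower, never to the root
    if (spec$multi_parent_prob > 0) {
      for (v in which(layer >= 3L)) {
        if (stats::runif(1) < spec$multi_parent_prob) {
          pool <- which(layer >= 1L & layer < layer[v])
          pool <- setdiff(pool, parent_of[v])
          if (length(pool) > 0) {
            extra_parent[v] <- pool[sample.int(length(pool), 1)]
          }
        }
      }
    }
    list(layer = layer, parent_of = parent_of, extra_parent = extra_parent,
         n = n_nodes)
  })
  n <- topo$n
  ids <- sprintf("%s:%07d", spec$id_prefix, seq_len(n))

  # --- labels -------------------------------------------------------------
  labels <- with_rng(seeds[["labels"]], {
    words <- random_words(n)
    lab <- character(n)
    lab[1] <- "Phenotypic abnormality"
    cat_idx <- which(topo$layer == 1L)
    lab[cat_idx] <- make.unique(
      paste0("Abnormality of the ", words[cat_idx], " system"), sep = " ")
    rest <- which(topo$layer >= 2L)
    lab[rest] <- sprintf("%s phenotype %05d", words[rest], rest)
    lab
  })

  parents <- lapply(seq_len(n), function(v) {
    p <- c(topo$parent_of[v], topo$extra_parent[v])
    ids[p[!is.na(p)]]
  })
  terms <- tibble::tibble(
    id = ids, label = labels, definition = NA_character_,
    synonyms = rep(list(character()), n), obsolete = FALSE,
    parents = parents
  )
  graph <- ontology_graph(terms, id_prefix = spec$id_prefix)

  # --- ground truth, via the generator's own adjacency --------------------
  kids <- vector("list", n)
  for (v in seq_len(n)) {
    for (p in c(topo$parent_of[v], topo$extra_parent[v])) {
      if (!is.na(p)) kids[[p]] <- c(kids[[p]], v)
    }
  }
  is_leaf <- lengths(kids) == 0
  reach <- function(start) {
    seen <- logical(n)
    frontier <- kids[[start]]
    while (length(frontier) > 0) {
      frontier <- unique(frontier[!seen[frontier]])
      seen[frontier] <- TRUE
      frontier <- unlist(kids[frontier], use.names = FALSE)
    }
    which(seen)
  }
  cat_idx <- which(topo$layer == 1L)
  member_sets <- lapply(cat_idx, function(ci) sort(ids[reach(ci)]))
  leaf_sets <- lapply(cat_idx, function(ci) {
    r <- reach(ci)
    sort(ids[r[is_leaf[r]]])
  })
  names(member_sets) <- ids[cat_idx]
  names(leaf_sets) <- ids[cat_idx]

  categories <- tibble::tibble(term_id = ids[cat_idx],
                               label = labels[cat_idx])
  categories <- categories[order(categories$label, categories$term_id,
                                 method = "radix"), ]

  structure(
    list(graph = graph, root_id = ids[1], categories = categories,
         member_sets = member_sets, leaf_sets = leaf_sets, spec = spec),
    class = "synthetic_ontology"
  )
}

#' @export
print.synthetic_ontology <- function(x, ...) {
  cat("<synthetic_ontology> seed ", x$spec$seed, ": ",
      n_terms(x$graph), " terms, ", nrow(x$categories),
      " categories, ", length(unique(unlist(x$leaf_sets))),
      " distinct leaves\n", sep = "")
  invisible(x)
}

#' Generate synthetic curation tables with recorded true flag counts
#'
#' Draws each leaf's four attribute flags independently with its
#' category's stated probabilities, producing one curation table per
#' category (a leaf under several categories is curated independently in
#' each, as separate per-category files would be). The true number of
#' flags drawn per category and attribute is recorded at draw time — the
#' oracle for proportion-recovery checks. Terms flagged Test Data also
#' receive one random subtype so subtype round-trips are exercised.
#'
#' @param synth A `synthetic_ontology`.
#' @param proportions Data frame of per-category probabilities (columns
#'   `disease_name`, `condition`, `test_data`, `symptoms_findings`), one
#'   row per category in `synth$categories` order; `NULL` uses the spec's
#'   `attribute_proportions`.
#' @param seed Seed for the tag draws; `NULL` uses the spec's tags
#'   substream.
#' @return A list with `tables` (named list, category label -> curation
#'   tibble) and `true_counts` (tibble `category_id`, `category_label`,
#'   `attribute`, `n_true`, `n_leaves`).
#' @export
generate_curation <- function(synth, proportions = NULL, seed = NULL) {
  stopifnot(inherits(synth, "synthetic_ontology"))
  spec <- synth$spec
  if (is.null(seed)) seed <- sub_seeds(spec$seed)[["tags"]]
  cats <- synth$categories
  if (is.null(proportions)) {
    # spec proportions are indexed by generation order; align to the
    # label-sorted category table by term id
    gen_order <- match(cats$term_id, names(synth$leaf_sets))
    proportions <- spec$attribute_proportions[gen_order, ]
  }
  proportions <- tibble::as_tibble(proportions)
  if (nrow(proportions) == 1) proportions <- proportions[rep(1, nrow(cats)), ]
  stopifnot(nrow(proportions) == nrow(cats))

  flags <- names(attribute_flags())
  with_rng(seed, {
    tables <- vector("list", nrow(cats))
    truth <- list()
    for (k in seq_len(nrow(cats))) {
      leaves <- synth$leaf_sets[[cats$term_id[k]]]
      nl <- length(leaves)
      tab <- tibble::tibble(term_id = leaves,
                            label = term_labels(synth$graph, leaves))
      for (flag in flags) {
        p <- proportions[[flag]][k]
        drawn <- if (nl > 0) stats::runif(nl) < p else logical()
        tab[[flag]] <- drawn
        truth[[length(truth) + 1]] <- tibble::tibble(
          category_id = cats$term_id[k], category_label = cats$label[k],
          attribute = flag, n_true = sum(drawn), n_leaves = nl
        )
      }
      picks <- if (nl > 0) sample(test_data_subtypes(), nl, replace = TRUE)
               else character()
      tab$test_data_subtypes <- lapply(seq_len(nl), function(i) {
        if (tab$test_data[i]) picks[i] else character()
      })
      tab$source <- "synthetic"
      tab$note <- NA_character_
      tables[[k]] <- tab
    }
    names(tables) <- cats$label
    list(tables = tables, true_counts = dplyr::bind_rows(truth))
  })
}
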