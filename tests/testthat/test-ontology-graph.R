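test_that("descendants walks subclass edges downward and de-duplicates", {
  g <- chain_graph()
  expect_equal(ont_descendants(g, "HP:0000010"),
               c("HP:0000011", "HP:0000012", "HP:0000013"))
  expect_equal(ont_descendants(g, "HP:0000013"), character())

  d <- diamond_graph()
  # shared grandchild reached via two paths appears once
  expect_equal(ont_descendants(d, "HP:0000001"),
               c("HP:0000002", "HP:0000003", "HP:0000004", "HP:0000005"))
  expect_equal(ont_descendants(d, "HP:0000002"),
               c("HP:0000004", "HP:0000005"))
  expect_error(ont_descendants(d, "HP:9999999"), "unknown term id")
})

test_that("obsolete terms are flagged but excluded from traversal and leaves", {
  g <- ontology_graph(tibble::tibble(
    id = c("HP:0000001", "HP:0000002", "HP:0000003"),
    label = c("root", "live child", "dead child"),
    obsolete = c(FALSE, FALSE, TRUE),
    parents = list(character(), "HP:0000001", "HP:0000001")
  ))
  expect_equal(n_terms(g), 3)
  expect_equal(ont_descendants(g, "HP:0000001"), "HP:0000002")
  expect_equal(global_leaves(g), "HP:0000002")
  # a term whose only child is obsolete is itself a leaf
  g2 <- ontology_graph(tibble::tibble(
    id = c("HP:0000001", "HP:0000002"),
    label = c("root", "dead"),
    obsolete = c(FALSE, TRUE),
    parents = list(character(), "HP:0000001")
  ))
  expect_equal(global_leaves(g2), "HP:0000001")
})

test_that("validate reports cycles, dangling parents, self loops, duplicates as data", {
  loop <- ontology_graph(tibble::tibble(
    id = c("HP:0000001", "HP:0000002"),
    label = c("A", "B"),
    parents = list("HP:0000002", "HP:0000001")
  ))
  iss <- validate_ontology(loop)
  expect_equal(iss$type, "cycle")
  expect_setequal(iss$ids[[1]], c("HP:0000001", "HP:0000002"))

  dang <- ontology_graph(tibble::tibble(
    id = "HP:0000001", label = "A", parents = list("HP:0000099")
  ))
  iss <- validate_ontology(dang)
  expect_equal(iss$type, "dangling_parent")
  expect_true("HP:0000099" %in% iss$ids[[1]])

  selfy <- ontology_graph(tibble::tibble(
    id = "HP:0000001", label = "A", parents = list("HP:0000001")
  ))
  expect_equal(validate_ontology(selfy)$type, "self_loop")

  dup <- ontology_graph(tibble::tibble(
    id = c("HP:0000001", "HP:0000001"), label = c("A", "A again"),
    parents = list(character(), character())
  ))
  expect_true("duplicate_id" %in% validate_ontology(dup)$type)

  expect_equal(nrow(validate_ontology(chain_graph())), 0)
  expect_error(assert_valid_ontology(loop), "cycle")
})

test_that("constructor rejects malformed ids and empty labels, checks prefix", {
  expect_error(
    ontology_graph(tibble::tibble(id = "notacurie", label = "x",
                                  parents = list(character()))),
    "malformed term id")
  expect_error(
    ontology_graph(tibble::tibble(id = "HP:0000001", label = "",
                                  parents = list(character()))),
    "empty label")
  # obsolete terms may lack a label
  expect_silent(
    ontology_graph(tibble::tibble(id = "HP:0000001", label = NA_character_,
                                  obsolete = TRUE,
                                  parents = list(character()))))
  # configurable prefix
  expect_error(
    ontology_graph(tibble::tibble(id = "MP:0000001", label = "x",
                                  parents = list(character()))),
    "malformed")
  g <- ontology_graph(tibble::tibble(id = "MP:0000001", label = "x",
                                     parents = list(character())),
                      id_prefix = "MP")
  expect_equal(term_ids(g), "MP:0000001")
})

test_that("descendants agree with the brute-force path oracle on seeded DAGs", {
  for (seed in c(11, 12, 13)) {
    so <- generate_ontology(synthetic_spec(
      seed = seed, n_categories = 4, depth = 3, branching_mean = 2,
      multi_parent_prob = 0.3))
    for (cid in so$categories$term_id) {
      expect_equal(ont_descendants(so$graph, cid),
                   brute_descendants(so$graph, cid))
    }
    # igraph reachability as a second, independent implementation
    edges <- ontology_edges(so$graph, resolved_only = TRUE)
    ig <- igraph::graph_from_data_frame(
      edges[, c("parent", "child")], directed = TRUE,
      vertices = term_ids(so$graph))
    cid <- so$categories$term_id[1]
    reach <- igraph::subcomponent(ig, cid, mode = "out")
    expect_equal(ont_descendants(so$graph, cid),
                 sort(setdiff(names(reach), cid)))
  }
})

test_that("descendant sets are monotone along subclass edges", {
  so <- generate_ontology(synthetic_spec(seed = 5, n_categories = 3,
                                         depth = 3,
                                         multi_parent_prob = 0.2))
  g <- so$graph
  edges <- ontology_edges(g, resolved_only = TRUE)
  edges <- edges[edges$parent != g$terms$id[1], ]  # skip root for speed
  for (k in seq_len(nrow(edges))) {
    child_desc <- ont_descendants(g, edges$child[k])
    parent_desc <- ont_descendants(g, edges$parent[k])
    expect_true(all(child_desc %in% parent_desc))
    expect_true(edges$child[k] %in% parent_desc)
  }
})
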