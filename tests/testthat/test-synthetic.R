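test_that("spec validation rejects degenerate parameters", {
  expect_error(synthetic_spec(depth = 0), "depth")
  expect_error(synthetic_spec(n_categories = 0), "n_categories")
  expect_error(synthetic_spec(branching_mean = 0), "branching_mean")
  expect_error(synthetic_spec(multi_parent_prob = 1.5), "multi_parent_prob")
  expect_error(
    synthetic_spec(attribute_proportions = tibble::tibble(
      disease_name = 2, condition = 0, test_data = 0,
      symptoms_findings = 0)),
    "probabilities")
})

test_that("a depth-1 tree yields leaf sets equal to the categories' direct children", {
  so <- generate_ontology(synthetic_spec(seed = 1, n_categories = 3,
                                         depth = 1, branching_mean = 2,
                                         multi_parent_prob = 0))
  expect_equal(nrow(so$categories), 3)
  for (cid in so$categories$term_id) {
    expect_equal(so$leaf_sets[[cid]],
                 sort(ont_children(so$graph, cid)))
  }
})

test_that("generated graphs always validate cleanly (acyclicity is structural)", {
  for (mpp in c(0, 0.1, 0.5, 1)) {
    so <- generate_ontology(synthetic_spec(seed = 77, n_categories = 4,
                                           depth = 4,
                                           multi_parent_prob = mpp))
    expect_equal(nrow(validate_ontology(so$graph)), 0)
  }
})

test_that("identical specs reproduce identical artifacts; seeds change topology", {
  sp <- synthetic_spec(seed = 42, n_categories = 23, depth = 4)
  a <- generate_ontology(sp)
  b <- generate_ontology(sp)
  expect_identical(a$graph$terms, b$graph$terms)
  expect_identical(a$leaf_sets, b$leaf_sets)
  expect_identical(generate_curation(a), generate_curation(b))
  other <- generate_ontology(synthetic_spec(seed = 43, n_categories = 23,
                                            depth = 4))
  expect_false(identical(a$graph$terms$id, other$graph$terms$id) &&
                 identical(a$graph$terms$parents, other$graph$terms$parents))
})

test_that("tag proportions never perturb topology at a fixed seed", {
  p1 <- tibble::tibble(disease_name = 0.1, condition = 0.1,
                       test_data = 0.1, symptoms_findings = 0.1)
  p2 <- tibble::tibble(disease_name = 0.9, condition = 0.9,
                       test_data = 0.9, symptoms_findings = 0.9)
  a <- generate_ontology(synthetic_spec(seed = 5, n_categories = 3,
                                        depth = 3,
                                        attribute_proportions = p1))
  b <- generate_ontology(synthetic_spec(seed = 5, n_categories = 3,
                                        depth = 3,
                                        attribute_proportions = p2))
  expect_identical(a$graph$terms, b$graph$terms)
})

test_that("degenerate tag probabilities give all-or-nothing profiles", {
  so <- generate_ontology(synthetic_spec(seed = 3, n_categories = 2,
                                         depth = 2))
  for (p in c(0, 1)) {
    probs <- tibble::tibble(disease_name = p, condition = p,
                            test_data = p, symptoms_findings = p)
    cur <- generate_curation(so, proportions = probs, seed = 11)
    annotated <- lapply(seq_len(nrow(so$categories)), function(k) {
      merge_curation(extract_category(so$graph, so$categories$term_id[k]),
                     cur$tables[[so$categories$label[k]]])
    })
    prof <- attribute_profile(annotated)
    expect_true(all(prof$percent[prof$n_total > 0] == 100 * p))
  }
})

test_that("pipeline leaf sets equal the generator's recorded ground truth", {
  for (seed in c(1, 2, 3)) {
    so <- generate_ontology(synthetic_spec(seed = seed, n_categories = 5,
                                           depth = 3,
                                           multi_parent_prob = 0.2))
    cats <- list_categories(so$graph, so$root_id)
    expect_setequal(cats$term_id, so$categories$term_id)
    for (cid in cats$term_id) {
      ex <- extract_category(so$graph, cid)
      expect_identical(ex$leaves, so$leaf_sets[[cid]])
      expect_identical(ex$members, so$member_sets[[cid]])
    }
  }
})
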