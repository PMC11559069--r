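test_that("percent uses half-up rounding to one decimal, exactly", {
  expect_equal(percent_half_up(895, 961), 93.1)
  expect_equal(percent_half_up(0, 435), 0.0)
  expect_equal(percent_half_up(26, 570), 4.6)
  # ties round away from zero: 1/16 = 6.25% -> 6.3
  expect_equal(percent_half_up(1, 16), 6.3)
  expect_equal(percent_half_up(1, 400), 0.3)   # 0.25 -> 0.3
  expect_equal(percent_half_up(7, 2000), 0.4)  # 0.35 -> 0.4
  expect_equal(percent_half_up(16, 16), 100)
  expect_error(percent_half_up(1, 0), "undefined denominator")
  expect_error(percent_half_up(5, 3), "0 <= k <= n")
  expect_error(percent_half_up(1.5, 3), "whole numbers")
  # never further than half a tenth from the unrounded value
  set.seed(99)
  n <- sample(1:5000, 500, replace = TRUE)
  k <- vapply(n, function(m) sample(0:m, 1), integer(1))
  p <- percent_half_up(k, n)
  expect_true(all(abs(p - 100 * k / n) <= 0.05 + 1e-9))
  expect_true(all(p == round(p * 10) / 10))
})

test_that("count_table and summarize report per-category leaf counts", {
  g <- chain_graph()
  exA <- extract_category(g, "HP:0000010")
  ex0 <- extract_category(g, "HP:0000013")
  ct <- count_table(list(exA, ex0))
  expect_equal(ct$n_total, c(2L, 0L))
  expect_equal(ct$category_label, c("cat A", "a3"))
  expect_equal(nrow(count_table(list())), 0)

  s <- summarize_counts(7)
  expect_equal(unlist(s), c(n_categories = 1, mean_count = 7,
                            min_count = 7, max_count = 7))
  expect_error(summarize_counts(integer()), "no counts")
  # mean agrees with plain arithmetic to half a tenth
  set.seed(17)
  x <- sample(0:3000, 1000, replace = TRUE)
  s <- summarize_counts(x)
  expect_true(abs(s$mean_count - mean(x)) <= 0.05 + 1e-9)
  expect_equal(s$min_count, min(x))
  expect_equal(s$max_count, max(x))
})

test_that("attribute profiles count flags over the full leaf denominator", {
  so <- generate_ontology(synthetic_spec(seed = 6, n_categories = 3,
                                         depth = 2))
  cur <- generate_curation(so)
  annotated <- lapply(seq_len(nrow(so$categories)), function(k) {
    merge_curation(extract_category(so$graph, so$categories$term_id[k]),
                   cur$tables[[so$categories$label[k]]])
  })
  for (flag in names(attribute_flags())) {
    prof <- attribute_profile(annotated, flag)
    truth <- cur$true_counts[cur$true_counts$attribute == flag, ]
    expect_equal(prof$n_attribute, truth$n_true)
    expect_equal(prof$n_total, truth$n_leaves)
    # stored percent is reproducible from its own counts
    ok <- prof$n_total > 0
    expect_equal(prof$percent[ok],
                 percent_half_up(prof$n_attribute[ok], prof$n_total[ok]))
  }
  # all-uncurated category: percent observed 0.0, not NA
  blank <- lapply(annotated, function(a)
    merge_curation(a$extract, a$annotations[0, ]))
  prof0 <- attribute_profile(blank)
  expect_true(all(prof0$percent[prof0$n_total > 0] == 0))
  # all-true curation gives 100.0 everywhere non-empty
  full <- lapply(annotated, function(a) {
    a$annotations$symptoms_findings <- TRUE
    merge_curation(a$extract, a$annotations)
  })
  prof1 <- attribute_profile(full)
  expect_true(all(prof1$percent[prof1$n_total > 0] == 100))
  # empty category renders NA percent, distinct from an observed 0.0
  g <- chain_graph()
  ex_leaf <- extract_category(g, "HP:0000013")
  a0 <- merge_curation(ex_leaf, annotated[[1]]$annotations[0, ])
  expect_true(is.na(attribute_profile(list(a0))$percent))
})

test_that("overlap matrix counts shared leaves; diagonal matches leaf counts", {
  # tree: off-diagonal all zero
  tree <- generate_ontology(synthetic_spec(seed = 14, n_categories = 4,
                                           depth = 3,
                                           multi_parent_prob = 0))
  mm <- membership_map(tree$graph, tree$root_id)
  m <- overlap_matrix(mm, tree$categories)
  expect_true(all(m[upper.tri(m)] == 0))

  # one shared leaf in the diamond
  d <- diamond_graph()
  md <- overlap_matrix(membership_map(d, "HP:0000001"))
  expect_equal(md["cat one", "cat two"], 1L)

  # seeded DAG: equals brute-force pairwise set intersections, and the
  # diagonal sum equals the count_table total (the double-counting bound)
  dag <- generate_ontology(synthetic_spec(seed = 14, n_categories = 4,
                                          depth = 3,
                                          multi_parent_prob = 0.3))
  mmd <- membership_map(dag$graph, dag$root_id)
  m2 <- overlap_matrix(mmd, dag$categories)
  expect_true(isSymmetric(m2))
  leafsets <- lapply(dag$categories$term_id, function(cid)
    mmd$term_id[mmd$category_id == cid])
  for (i in seq_along(leafsets)) {
    for (j in seq_along(leafsets)) {
      expect_equal(m2[i, j],
                   length(intersect(leafsets[[i]], leafsets[[j]])))
    }
  }
  extracts <- lapply(dag$categories$term_id,
                     function(id) extract_category(dag$graph, id))
  expect_equal(sum(diag(m2)), sum(count_table(extracts)$n_total))
})

test_that("profiles are invariant to curation record order", {
  so <- generate_ontology(synthetic_spec(seed = 6, n_categories = 2,
                                         depth = 2))
  cur <- generate_curation(so)
  tab <- cur$tables[[1]]
  ex <- extract_category(so$graph,
                         so$categories$term_id[so$categories$label ==
                                                 names(cur$tables)[1]])
  shuffled <- tab[rev(seq_len(nrow(tab))), ]
  p1 <- attribute_profile(merge_curation(ex, tab))
  p2 <- attribute_profile(merge_curation(ex, shuffled))
  expect_equal(p1, p2)
})

test_that("markdown rendering prints one-decimal percents and NA cells", {
  df <- tibble::tibble(category_label = c("a", "b"), n_total = c(10L, 0L),
                       n_attribute = c(3L, 0L), percent = c(30, NA))
  md <- render_markdown_table(df)
  expect_match(md[3], "\\| 30.0 \\|")
  expect_match(md[4], "\\| NA \\|")
})
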