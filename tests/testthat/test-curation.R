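test_that("markers map to flags in column order, with both minus signs accepted", {
  df <- tibble::tibble(
    `HPO id` = c("HP:0000218", "HP:0000219"),
    Label = c("High palate", "Thin upper lip"),
    `Disease Names` = c("+", "−"),
    Conditions = c("−", "-"),
    `Test Data` = c("-", ""),
    `Symptoms and Findings` = c(" + ", "+")
  )
  cur <- read_curation(df)
  expect_equal(cur$disease_name, c(TRUE, FALSE))
  expect_equal(cur$condition, c(FALSE, FALSE))
  expect_equal(cur$test_data, c(FALSE, FALSE))
  expect_equal(cur$symptoms_findings, c(TRUE, TRUE))
})

test_that("header aliases are case-insensitive and singular/plural tolerant", {
  df <- tibble::tibble(
    `hpo ID` = "HP:0000001", label = "x",
    `disease name` = "+", Condition = "-", `TEST DATA` = "+",
    `symptoms/findings` = "-"
  )
  cur <- read_curation(df)
  expect_true(cur$disease_name)
  expect_true(cur$test_data)
  expect_false(cur$symptoms_findings)
})

test_that("load errors carry row numbers: bad markers, duplicates, bad subtypes", {
  base <- tibble::tibble(
    `HPO id` = c("HP:0000001", "HP:0000002"), Label = c("a", "b"),
    `Disease Names` = c("-", "yes"), Conditions = "-",
    `Test Data` = "-", `Symptoms and Findings` = "-"
  )
  expect_error(read_curation(base), "row 3.*expected")
  dup <- base
  dup$`Disease Names` <- "-"
  dup$`HPO id` <- c("HP:0000001", "HP:0000001")
  expect_error(read_curation(dup), "duplicate term id")
  sub <- base
  sub$`Disease Names` <- "-"
  sub$`Test Data` <- c("+", "-")
  sub$`Test Data Subtypes` <- c("imaging", "radiomics")
  expect_error(read_curation(sub), "unknown Test Data subtype")
  # subtypes without the Test Data flag contradict the schema
  sub$`Test Data Subtypes` <- c("", "imaging")
  expect_error(read_curation(sub), "marked absent")
  # an empty table (header only) is fine
  expect_equal(nrow(read_curation(base[0, ])), 0)
})

test_that("write_curation / read_curation is identity on records", {
  so <- generate_ontology(synthetic_spec(seed = 4, n_categories = 3,
                                         depth = 2))
  cur <- generate_curation(so)
  for (ext in c(".csv", ".tsv")) {
    tab <- cur$tables[[1]]
    f <- withr::local_tempfile(fileext = ext)
    write_curation(tab, f)
    back <- read_curation(f)
    for (col in c("term_id", "label", names(attribute_flags()),
                  "test_data_subtypes")) {
      expect_equal(back[[col]], tab[[col]], info = paste(ext, col))
    }
  }
})

test_that("templates list every leaf all-false and survive read-back", {
  g <- chain_graph()
  ex <- extract_category(g, "HP:0000010")
  tpl <- curation_template(ex, g)
  expect_setequal(tpl$term_id, ex$leaves)
  expect_false(any(tpl$disease_name | tpl$condition | tpl$test_data |
                     tpl$symptoms_findings))
  # rows are label-sorted and regeneration is bit-stable
  expect_identical(tpl, curation_template(ex, g))
  expect_equal(tpl$label, sort(tpl$label, method = "radix"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_curation(tpl, f)
  back <- read_curation(f)
  expect_setequal(back$term_id, ex$leaves)
  expect_false(any(back$symptoms_findings))
  # empty extract gives a header-only template
  ex0 <- extract_category(g, "HP:0000013")
  expect_equal(nrow(curation_template(ex0, g)), 0)
})

test_that("merge partitions leaves into curated and uncurated, flags stale ids", {
  g <- chain_graph()
  ex <- extract_category(g, "HP:0000010")  # leaves a1, a3
  cur <- tibble::tibble(
    term_id = c("HP:0000011", "HP:0000099"),
    label = c("a1", "ghost"),
    disease_name = FALSE, condition = FALSE, test_data = FALSE,
    symptoms_findings = c(TRUE, TRUE),
    test_data_subtypes = list(character(), character()),
    source = "test", note = NA_character_
  )
  a <- merge_curation(ex, cur)
  expect_equal(a$annotations$term_id, "HP:0000011")
  expect_equal(a$uncurated, "HP:0000013")
  expect_equal(a$stale, "HP:0000099")
  # partition invariant: annotations + uncurated = leaves, disjoint
  expect_setequal(c(a$annotations$term_id, a$uncurated), ex$leaves)
  expect_length(intersect(a$annotations$term_id, a$uncurated), 0)
  # stale records do not leak into statistics
  prof <- attribute_profile(a)
  expect_equal(prof$n_attribute, 1L)
  expect_equal(prof$n_total, 2L)
})

test_that("a full synthetic curation leaves nothing uncurated or stale", {
  so <- generate_ontology(synthetic_spec(seed = 2, n_categories = 3,
                                         depth = 2))
  cur <- generate_curation(so)
  for (k in seq_len(nrow(so$categories))) {
    ex <- extract_category(so$graph, so$categories$term_id[k])
    a <- merge_curation(ex, cur$tables[[so$categories$label[k]]])
    expect_length(a$uncurated, 0)
    expect_length(a$stale, 0)
  }
})
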