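# Hand-built fixture graphs, constructed in code at test time.

# root -> {A, B}; A -> {a1, a2}; a2 -> a3; B -> b1
chain_graph <- function() {
  ontology_graph(tibble::tibble(
    id = c("HP:0000001", "HP:0000010", "HP:0000020",
           "HP:0000011", "HP:0000012", "HP:0000013", "HP:0000021"),
    label = c("root", "cat A", "cat B", "a1", "a2", "a3", "b1"),
    parents = list(character(), "HP:0000001", "HP:0000001",
                   "HP:0000010", "HP:0000010", "HP:0000012", "HP:0000020")
  ))
}

# diamond: root -> {C1, C2}; C1 -> X, C2 -> X; X -> leaf
diamond_graph <- function() {
  ontology_graph(tibble::tibble(
    id = c("HP:0000001", "HP:0000002", "HP:0000003", "HP:0000004",
           "HP:0000005"),
    label = c("root", "cat one", "cat two", "shared", "leaf"),
    parents = list(character(), "HP:0000001", "HP:0000001",
                   c("HP:0000002", "HP:0000003"), "HP:0000004")
  ))
}

# Path-enumerating descendant oracle, independent of the package's BFS:
# walks every downward path from `id` over a child map built directly
# from the parents column, then de-duplicates.
brute_descendants <- function(graph, id) {
  terms <- graph$terms
  live <- terms$id[!terms$obsolete]
  edges_child <- rep(terms$id, lengths(terms$parents))
  edges_parent <- unlist(terms$parents, use.names = FALSE)
  keep <- edges_child %in% live & edges_parent %in% live
  kids <- split(edges_child[keep], edges_parent[keep])
  acc <- new.env(parent = emptyenv())
  walk <- function(x) {
    for (k in kids[[x]]) {
      assign(k, TRUE, envir = acc)
      walk(k)
    }
  }
  walk(id)
  sort(ls(acc))
}

# Iterative depth-first search with visited marking — a second independent
# traversal that stays linear on large DAGs. Builds its own child map from
# the parents column; never touches the package's children index.
dfs_descendants <- function(graph, id) {
  terms <- graph$terms
  n <- nrow(terms)
  live <- !terms$obsolete
  row_of <- seq_len(n)
  names(row_of) <- terms$id
  kids <- vector("list", n)
  for (v in seq_len(n)) {
    if (!live[v]) next
    for (p in terms$parents[[v]]) {
      j <- row_of[p]
      if (!is.na(j) && live[j]) kids[[j]] <- c(kids[[j]], v)
    }
  }
  start <- row_of[[id]]
  seen <- logical(n)
  stack <- kids[[start]]
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, kids[[v]])
  }
  sort(terms$id[seen])
}

# leaf filter independent of the package's children index
brute_leaves <- function(graph, members) {
  terms <- graph$terms
  live <- terms$id[!terms$obsolete]
  parents_flat <- unlist(terms$parents[!terms$obsolete], use.names = FALSE)
  has_child <- unique(parents_flat)
  sort(setdiff(intersect(members, live), has_child))
}

# single category with exactly n leaf children, wrapped as a synthetic
# ontology so generate_curation() can draw tags for it
star_synth <- function(n_leaves, seed = 1) {
  leaf_ids <- sprintf("HP:%07d", 2 + seq_len(n_leaves))
  g <- ontology_graph(tibble::tibble(
    id = c("HP:0000001", "HP:0000002", leaf_ids),
    label = c("root", "star category",
              sprintf("star leaf %04d", seq_len(n_leaves))),
    parents = c(list(character(), "HP:0000001"),
                rep(list("HP:0000002"), n_leaves))
  ))
  structure(
    list(graph = g, root_id = "HP:0000001",
         categories = tibble::tibble(term_id = "HP:0000002",
                                     label = "star category"),
         member_sets = list("HP:0000002" = sort(leaf_ids)),
         leaf_sets = list("HP:0000002" = sort(leaf_ids)),
         spec = synthetic_spec(seed = seed, n_categories = 1, depth = 1)),
    class = "synthetic_ontology"
  )
}
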