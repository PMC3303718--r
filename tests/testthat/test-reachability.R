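motif_pipeline <- function(intermediates = 1, seed = 1) {
  fx <- generate_alternative_path_motif(intermediates, seed, dir = tempfile("motif"))
  agg <- assemble(ingest_models(fx$files))
  cl <- build_equivalence_classes(agg)
  dup <- detect_duplicate_reactions(agg, cl)
  g <- build_graph(agg, cl)
  list(fx = fx, agg = agg, cl = cl, dup = dup, g = g)
}

test_that("a single irreversible reaction gives the minimal two-vertex graph", {
  m <- mem_model("m.xml", list(A = mem_species("A", "urn:miriam:testdb:A1"),
                               B = mem_species("B", "urn:miriam:testdb:B1"),
                               C = mem_species("C", "urn:miriam:testdb:C1")),
                 list(r = mem_reaction("r", c("A", "B"), "C")))
  agg <- assemble(m)
  cl <- build_equivalence_classes(agg)
  g <- build_graph(agg, cl)
  expect_length(g$vertices, 2)
  expect_length(g$edges, 1)
  expect_identical(edge_vertex_ratio(g), 0.5)
})

test_that("duplicate reactions collapse onto one edge: never a multigraph", {
  p <- motif_pipeline(intermediates = 2, seed = 21)
  # direct edge carries both supporters; chain contributes 3 more edges
  keys <- vapply(p$g$edges, function(e) paste0(e$source, "->", e$target), "")
  expect_false(any(duplicated(keys)))
  supp <- unname(vapply(p$g$edges, function(e) length(e$supporting), 0L))
  expect_identical(sort(supp), c(1L, 1L, 1L, 2L))
  dup_keys <- vapply(p$dup, function(g) paste0(g$source_set, "->", g$target_set), "")
  for (e in p$g$edges) {
    has_group <- paste0(e$source, "->", e$target) %in% dup_keys
    expect_identical(length(e$supporting) >= 2, has_group)
    expect_true(e$representative %in% e$supporting)
    expect_true(all(c(e$source, e$target) %in% p$g$vertices))
  }

  # property holds on random fixtures too
  fx <- generate_models(n_models = 5, n_species_per_model = 6, share_prob = 0.5,
                        seed = 5, dir = tempfile("nm"))
  agg <- assemble(ingest_models(fx$files))
  cl <- build_equivalence_classes(agg)
  g2 <- build_graph(agg, cl)
  keys2 <- vapply(g2$edges, function(e) paste0(e$source, "->", e$target), "")
  expect_false(any(duplicated(keys2)))
  # edge set equals the distinct (source, target) keys of a brute-force pass
  brute <- unique(unlist(lapply(names(agg$reactions), function(rk) {
    rx <- agg$reactions[[rk]]
    sides <- pathblocks:::reaction_side_keys(rx, rx$pathway)
    paste0(as.character(species_set_of(sides$reactants, cl)), "->",
           as.character(species_set_of(sides$products, cl)))
  })))
  expect_setequal(keys2, brute)
})

test_that("reachability grows with N exactly as path lengths dictate", {
  g <- sset_graph(c("u", "v", "w"),
                  data.frame(source = c("u", "v"), target = c("v", "w")))
  r1 <- reachability_matrix(g, 1)
  expect_false(r1["u", "w"])
  expect_true(r1["u", "v"])
  r2 <- reachability_matrix(g, 2)
  expect_true(r2["u", "w"])
  expect_error(reachability_matrix(g, 0), class = "pb_argument_error")

  empty <- sset_graph(c("a", "b"))
  expect_false(any(reachability_matrix(empty, 3)))
})

test_that("full-order reachability equals Floyd-Warshall closure, monotonically", {
  for (s in 1:30) {
    set.seed(s)
    A <- rand_adjacency(n = sample(2:8, 1), p = 0.3, self_loops = (s %% 5 == 0))
    g <- graph_from_adjacency(A)
    n <- length(g$vertices)
    W <- warshall_closure(A)
    # length n covers every simple path and every cycle, so this is the
    # full closure; off-diagonal entries are already complete at n - 1
    R <- reachability_matrix(g, n)
    expect_identical(R, W[rownames(R), colnames(R)])
    if (n >= 2) {
      R1 <- reachability_matrix(g, n - 1L)
      off <- !diag(TRUE, n)
      expect_identical(R1[off], W[rownames(R), colnames(R)][off])
    }
    N <- n
    prev <- reachability_matrix(g, 1)
    for (k in seq_len(N)[-1]) {
      cur <- reachability_matrix(g, k)
      expect_true(all(cur[prev]))  # true entries never turn false
      prev <- cur
    }
  }
})

test_that("alternative-path enumeration is ordered, bounded and flagged", {
  # diamond with a long detour: a->d direct, via b, via c, via b->c
  g <- sset_graph(letters[1:4],
                  data.frame(source = c("a", "a", "a", "b", "b", "c"),
                             target = c("b", "c", "d", "c", "d", "d")))
  e <- find_alternative_paths(g, "a", "d")
  expect_identical(e$order, c(1L, 2L, 2L, 3L))           # shortest first
  expect_identical(e$paths[[2]], c("a", "b", "d"))       # then lexicographic
  expect_identical(e$paths[[3]], c("a", "c", "d"))
  expect_identical(e$paths[[4]], c("a", "b", "c", "d"))
  expect_false(e$truncated)

  capped <- find_alternative_paths(g, "a", "d", max_paths = 2)
  expect_length(capped$paths, 2)
  expect_true(capped$truncated)
  expect_identical(capped$order, c(1L, 2L))

  short <- find_alternative_paths(g, "a", "d", max_len = 1)
  expect_identical(short$order, 1L)

  expect_length(find_alternative_paths(g, "d", "a")$paths, 0)   # no outgoing
  expect_length(find_alternative_paths(g, "a", "a")$paths, 0)   # self pair
  expect_error(find_alternative_paths(g, "a", "zz"), class = "pb_lookup_error")
})

test_that("path enumeration matches exhaustive igraph enumeration on random digraphs", {
  skip_if_not_installed("igraph")
  for (s in 1:30) {
    set.seed(100 + s)
    n <- sample(3:8, 1)
    A <- rand_adjacency(n, p = 0.35)
    g <- graph_from_adjacency(A)
    uv <- sample(rownames(A), 2)
    mine <- find_alternative_paths(g, uv[1], uv[2], max_len = n, max_paths = 10000)
    expect_false(mine$truncated)
    expect_identical(path_set(mine), igraph_path_set(A, uv[1], uv[2], max_len = n))
  }
})

test_that("path structure is invariant under vertex relabeling", {
  set.seed(77)
  A <- rand_adjacency(6, p = 0.4)
  g <- graph_from_adjacency(A)
  perm <- sample(6)
  B <- A[perm, perm]
  rename <- sprintf("Z%02d", seq_len(6))           # new ids, same structure
  dimnames(B) <- list(rename, rename)
  g2 <- graph_from_adjacency(B)
  map <- stats::setNames(rename, rownames(A)[perm])
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    u <- rownames(A)[i]; v <- rownames(A)[j]
    e1 <- find_alternative_paths(g, u, v, max_len = 5)
    e2 <- find_alternative_paths(g2, map[[u]], map[[v]], max_len = 5)
    relabeled <- sort(vapply(e1$paths, function(p) paste(map[p], collapse = " -> "), ""))
    expect_identical(sort(path_set(e2)), relabeled)
  }
})

test_that("edge/vertex ratio is plain arithmetic and rejects the empty graph", {
  v3 <- c("a", "b", "c")
  full <- expand.grid(source = v3, target = v3, stringsAsFactors = FALSE)
  full <- full[full$source != full$target, ]
  expect_identical(edge_vertex_ratio(sset_graph(v3, full)), 2)
  expect_error(edge_vertex_ratio(sset_graph(character(0))), class = "pb_argument_error")
})

test_that("the dictionary has its three sections and the motif fills them", {
  p <- motif_pipeline(intermediates = 1, seed = 31)
  dict <- build_dictionary(p$g, p$dup)
  expect_identical(nrow(dict$building_blocks), length(p$g$edges))
  expect_length(dict$equivalent_reactions, 1)
  expect_length(dict$compositions, 1)
  expect_identical(dict$compositions[[1]]$order, c(1L, 2L))
  # building blocks are ordered and carry provenance through element keys
  bb <- dict$building_blocks
  expect_equal(bb, bb[order(bb$source_set, bb$target_set, method = "radix"), ],
               ignore_attr = TRUE)
  expect_true(any(grepl("motifA.xml::", bb$representative)))

  # a pure linear chain has no alternative compositions
  chain <- mem_model("chain.xml",
    list(A = mem_species("A", "urn:miriam:testdb:A1"),
         B = mem_species("B", "urn:miriam:testdb:B1"),
         C = mem_species("C", "urn:miriam:testdb:C1")),
    list(r1 = mem_reaction("r1", "A", "B"), r2 = mem_reaction("r2", "B", "C")))
  agg <- assemble(chain)
  cl <- build_equivalence_classes(agg)
  dict2 <- build_dictionary(build_graph(agg, cl), detect_duplicate_reactions(agg, cl))
  expect_length(dict2$compositions, 0)
})

test_that("dictionary serialization is deterministic byte-for-byte", {
  p <- motif_pipeline(intermediates = 2, seed = 41)
  dict <- build_dictionary(p$g, p$dup)
  d1 <- tempfile(); d2 <- tempfile()
  dictionary_write(dict, d1)
  dictionary_write(dict, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     info = f)
  }
  expect_setequal(list.files(d1),
                  c("dictionary.json", "building_blocks.tsv",
                    "equivalent_reactions.tsv", "compositions.tsv"))
})
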