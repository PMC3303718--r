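two_model_agg <- function(uri_a, uri_b) {
  assemble(list(
    mem_model("a.xml", list(X = mem_species("X", uri_a)), list()),
    mem_model("b.xml", list(X = mem_species("X", uri_b)), list())
  ))
}

test_that("species sharing a resource are co-classed, across URI syntaxes", {
  agg <- two_model_agg("urn:miriam:uniprot:P00533",
                       "http://identifiers.org/uniprot/P00533")
  cl <- build_equivalence_classes(agg)
  expect_length(cl$classes, 1)
  expect_identical(cl$classes[[1]]$members, c("a.xml::X", "b.xml::X"))
  expect_identical(cl$classes[[1]]$resources, "uniprot:P00533")
})

test_that("equivalence is the transitive closure of resource sharing", {
  agg <- assemble(list(mem_model("m.xml", list(
    x = mem_species("x", "urn:miriam:testdb:R1"),
    y = structure_species_multi("y", c("urn:miriam:testdb:R1", "urn:miriam:testdb:R2")),
    z = mem_species("z", "urn:miriam:testdb:R2"),
    w = mem_species("w", "urn:miriam:testdb:R9")
  ), list())))
  cl <- build_equivalence_classes(agg)
  sizes <- sort(unname(vapply(cl$classes, function(c) length(c$members), 0L)))
  expect_identical(sizes, c(1L, 3L))
  expect_identical(cl$membership[["m.xml::x"]], cl$membership[["m.xml::z"]])
  expect_false(cl$membership[["m.xml::w"]] == cl$membership[["m.xml::x"]])
})

test_that("classes equal connected components from an independent graph oracle", {
  skip_if_not_installed("igraph")
  fx <- generate_models(n_models = 6, n_species_per_model = 5, share_prob = 0.5,
                        seed = 3, dir = tempfile("cc"))
  agg <- assemble(ingest_models(fx$files))
  cl <- build_equivalence_classes(agg)

  # oracle: bipartite species/resource graph -> connected components
  keys <- sort(names(agg$species))
  res <- lapply(agg$species[keys], function(sp)
    unlist(lapply(sp$annotations, function(a)
      if (!is.na(a$namespace) && a$type %in% pb_default_policy)
        paste0("res|", a$namespace, ":", a$identifier) else NULL)))
  edges <- do.call(rbind, lapply(keys, function(k)
    if (length(res[[k]])) cbind(k, res[[k]]) else NULL))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- g + igraph::vertices(setdiff(keys, igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  oracle <- split(names(comp)[!startsWith(names(comp), "res|")],
                  comp[!startsWith(names(comp), "res|")])
  expect_identical(canon_groups(unname(lapply(cl$classes, `[[`, "members"))),
                   canon_groups(unname(oracle)))
})

test_that("partition and determinism invariants hold", {
  fx <- generate_models(n_models = 5, n_species_per_model = 6, share_prob = 0.4,
                        seed = 13, dir = tempfile("part"))
  models <- ingest_models(fx$files)
  agg <- assemble(models)
  cl <- build_equivalence_classes(agg)
  all_members <- unlist(lapply(cl$classes, `[[`, "members"), use.names = FALSE)
  expect_identical(sort(all_members), sort(names(agg$species)))  # partition
  expect_false(any(duplicated(all_members)))                     # disjoint
  # input order must not matter
  cl_rev <- build_equivalence_classes(assemble(rev(models)))
  expect_identical(cl_rev$classes, cl$classes)
})

test_that("lookalike names with distinct annotations are never merged", {
  agg <- two_model_agg("urn:miriam:testdb:LEFT", "urn:miriam:testdb:RIGHT")
  cl <- build_equivalence_classes(agg)
  expect_length(cl$classes, 2)  # same internal id "X" twice, still apart

  # weaker qualifiers are excluded by the default policy but can be opted in
  a <- mem_species("X", "urn:miriam:testdb:SHARED")
  a$annotations[[1]]$type <- "isVersionOf"
  b <- mem_species("X", "urn:miriam:testdb:SHARED")
  b$annotations[[1]]$type <- "isVersionOf"
  agg2 <- assemble(list(mem_model("a.xml", list(X = a), list()),
                        mem_model("b.xml", list(X = b), list())))
  expect_length(build_equivalence_classes(agg2)$classes, 2)
  cl_opt <- build_equivalence_classes(agg2, policy = c("is", "unqualified", "isVersionOf"))
  expect_length(cl_opt$classes, 1)
})

test_that("species-set identity deduplicates classes and handles empty sides", {
  agg <- two_model_agg("urn:miriam:uniprot:P11111", "urn:miriam:uniprot:P11111")
  cl <- build_equivalence_classes(agg)
  s <- species_set_of(c("a.xml::X", "b.xml::X"), cl)
  expect_length(attr(s, "classes"), 1)   # two species, one class, one-element set
  expect_identical(as.character(species_set_of(character(0), cl)), "{}")
  expect_error(species_set_of("a.xml::GHOST", cl), class = "pb_alignment_error")
})

test_that("a model is never its own duplicate, but a renamed copy duplicates everywhere", {
  fx <- generate_models(n_models = 1, n_species_per_model = 5, share_prob = 1,
                        seed = 5, dir = tempfile("self"))
  m <- parse_sbml(fx$files[1])
  agg1 <- assemble(m)
  cl1 <- build_equivalence_classes(agg1)
  expect_length(detect_duplicate_reactions(agg1, cl1), 0)

  copy <- m
  copy$pathway$fullname <- "copy.xml"
  agg2 <- assemble(list(m, copy))
  cl2 <- build_equivalence_classes(agg2)
  dup <- detect_duplicate_reactions(agg2, cl2)
  expect_length(dup, length(m$reactions))
  for (g in dup) {
    expect_length(g$reactions, 2)
    expect_false(g$kinetics_conflict)
    expect_identical(g$representative, g$reactions[1])
  }
})

test_that("planted duplicate groups are recovered exactly from the manifest", {
  fx <- generate_models(n_models = 6, n_species_per_model = 5, share_prob = 0.6,
                        seed = 11, dir = tempfile("plant"))
  agg <- assemble(ingest_models(fx$files))
  cl <- build_equivalence_classes(agg)
  dup <- detect_duplicate_reactions(agg, cl)
  expect_identical(canon_groups(lapply(dup, `[[`, "reactions")),
                   canon_groups(lapply(fx$manifest$planted_duplicates, `[[`, "reactions")))
})

test_that("kinetics and catalyst mismatches raise the conflict flag", {
  fx <- generate_duplicate_pair(seed = 2, dir = tempfile("kin"), kinetics_differ = TRUE)
  agg <- assemble(ingest_models(fx$files))
  cl <- build_equivalence_classes(agg)
  dup <- detect_duplicate_reactions(agg, cl)
  expect_length(dup, 1)
  expect_true(dup[[1]]$kinetics_conflict)

  # same kinetics but one copy is catalysed -> conflict, same vertex key
  sp <- function() list(A = mem_species("A", "urn:miriam:testdb:A1"),
                        B = mem_species("B", "urn:miriam:testdb:B1"),
                        E = mem_species("E", "urn:miriam:testdb:E1"))
  m1 <- mem_model("c1.xml", sp(), list(r = mem_reaction("r", "A", "B", k = 2)))
  m2 <- mem_model("c2.xml", sp(), list(r = mem_reaction("r", "A", "B", k = 2, catalysts = "E")))
  agg2 <- assemble(list(m1, m2))
  cl2 <- build_equivalence_classes(agg2)
  dup2 <- detect_duplicate_reactions(agg2, cl2)
  expect_length(dup2, 1)
  expect_true(dup2[[1]]$kinetics_conflict)

  # differently named rate constants with equal values are not a conflict
  m3 <- mem_model("c3.xml", sp(), list(r = mem_reaction("r", "A", "B", k = 2)))
  m3$reactions$r$kinetics <- "kf * A"
  m3$reactions$r$parameters <- c(kf = 2)
  agg3 <- assemble(list(m1, m3))
  cl3 <- build_equivalence_classes(agg3)
  expect_false(detect_duplicate_reactions(agg3, cl3)[[1]]$kinetics_conflict)
})

test_that("reversible reactions contribute forward and reverse keys", {
  sp <- function() list(A = mem_species("A", "urn:miriam:testdb:A1"),
                        B = mem_species("B", "urn:miriam:testdb:B1"))
  rev_rx <- function() { r <- mem_reaction("r", "A", "B"); r$reversible <- TRUE; r }
  agg <- assemble(list(mem_model("a.xml", sp(), list(r = rev_rx())),
                       mem_model("b.xml", sp(), list(r = rev_rx()))))
  cl <- build_equivalence_classes(agg)
  expect_length(detect_duplicate_reactions(agg, cl), 2)  # one group per direction
  expect_length(detect_duplicate_reactions(agg, cl, reversible_edges = FALSE), 1)
})
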