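# Independent oracles used to cross-check the package's graph algorithms.

# Transitive closure by the Floyd-Warshall recurrence (path existence,
# diagonal true only via a cycle) — independent of the boolean-power
# implementation under test.
warshall_closure <- function(A) {
  n <- nrow(A)
  R <- A
  if (n == 0) return(R)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (R[i, k] && R[k, j]) R[i, j] <- TRUE
  R
}

# Random adjacency matrix over n named vertices (no self-loops unless
# asked); caller controls the RNG seed.
rand_adjacency <- function(n, p, self_loops = FALSE) {
  A <- matrix(stats::runif(n * n) < p, n, n)
  if (!self_loops) diag(A) <- FALSE
  v <- sprintf("V%02d", seq_len(n))
  dimnames(A) <- list(v, v)
  A
}

graph_from_adjacency <- function(A) {
  idx <- which(A, arr.ind = TRUE)
  sset_graph(rownames(A),
             data.frame(source = rownames(A)[idx[, 1]],
                        target = colnames(A)[idx[, 2]],
                        stringsAsFactors = FALSE))
}

# Exhaustive simple-path enumeration through igraph, as an oracle for
# find_alternative_paths (paths canonicalized to sorted strings).
igraph_path_set <- function(A, from, to, max_len) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  ps <- igraph::all_simple_paths(g, from = from, to = to, mode = "out",
                                 cutoff = max_len)
  sort(vapply(ps, function(p) paste(names(p), collapse = " -> "), ""))
}

path_set <- function(entry) {
  sort(vapply(entry$paths, paste, "", collapse = " -> "))
}

canon_groups <- function(groups_members) {
  sort(vapply(groups_members, function(m) paste(sort(m), collapse = "|"), ""))
}
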