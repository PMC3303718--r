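# Species-set connectivity graph and N-order reachability.  Vertices are
# species-sets (one per distinct reaction side), edges are reactions
# collapsed per ordered (source, target) pair — the graph is never a
# multigraph: one representative reaction stands for all duplicates of
# an edge.  Reachability and alternative-path enumeration over this
# graph produce the three-section dictionary of pathway building blocks.

#' Construct a species-set graph from plain vertex/edge tables
#'
#' Low-level constructor (also used by [build_graph()]): takes the vertex
#' ids and an edge table and returns the graph object the reachability
#' and path-enumeration functions operate on.  Collapses repeated
#' (source, target) rows so the result is never a multigraph.
#'
#' @param vertices Character vector of vertex (species-set) ids.
#' @param edges Data frame with character columns `source` and `target`
#'   (and optionally `representative`); endpoints must appear in
#'   `vertices`.
#' @return A `pb_graph`: sorted `vertices`, named list `edges` (one entry
#'   per ordered pair, with `supporting` reaction keys), and a
#'   sorted-neighbor adjacency list `adj`.
#' @export
sset_graph <- function(vertices, edges = data.frame(source = character(0), target = character(0))) {
  vertices <- pb_sort(unique(as.character(vertices)))
  if (nrow(edges) > 0) {
    bad <- setdiff(c(edges$source, edges$target), vertices)
    if (length(bad))
      pb_stop("pb_lookup_error", "edge endpoint(s) not in vertex set: %s",
              paste(unique(bad), collapse = ", "))
  }
  elist <- list()
  if (nrow(edges) > 0) {
    if (is.null(edges$representative)) edges$representative <- NA_character_
    for (i in seq_len(nrow(edges))) {
      k <- paste0(edges$source[i], " -> ", edges$target[i])
      e <- elist[[k]]
      if (is.null(e))
        e <- list(source = edges$source[i], target = edges$target[i],
                  supporting = character(0), representative = NA_character_)
      if (!is.na(edges$representative[i]))
        e$supporting <- c(e$supporting, edges$representative[i])
      elist[[k]] <- e
    }
    for (k in names(elist)) {
      e <- elist[[k]]
      e$supporting <- pb_sort(unique(e$supporting))
      e$representative <- if (length(e$supporting)) e$supporting[1] else NA_character_
      elist[[k]] <- e
    }
    elist <- elist[pb_sort(names(elist))]
  }
  adj <- lapply(stats::setNames(vertices, vertices), function(v) character(0))
  for (e in elist) adj[[e$source]] <- c(adj[[e$source]], e$target)
  adj <- lapply(adj, pb_sort)
  structure(list(vertices = vertices, edges = elist, adj = adj), class = "pb_graph")
}

#' Build the species-set graph of an aggregate
#'
#' One vertex per distinct species-set occurring as any reaction side,
#' one edge per distinct ordered (source set, target set) pair carrying
#' all its supporting reactions; the representative is the supporting
#' reaction with the lexicographically smallest element key.  Reversible
#' reactions contribute both directions.
#'
#' @param aggregate A `pb_aggregate`.
#' @param classes A `pb_classes`.
#' @param duplicates Optional `pb_duplicates` (only used to inherit the
#'   reversible-edge setting when `reversible_edges` is missing).
#' @param reversible_edges Treat reversible reactions as two directed
#'   edges (default `TRUE`).
#' @return A `pb_graph`.
#' @export
build_graph <- function(aggregate, classes, duplicates = NULL, reversible_edges = NULL) {
  stopifnot(inherits(aggregate, "pb_aggregate"), inherits(classes, "pb_classes"))
  if (is.null(reversible_edges)) {
    reversible_edges <- if (!is.null(duplicates)) {
      isTRUE(attr(duplicates, "reversible_edges"))
    } else TRUE
  }
  src <- character(0); tgt <- character(0); rep <- character(0)
  for (rk in pb_sort(names(aggregate$reactions))) {
    rx <- aggregate$reactions[[rk]]
    for (ek in reaction_edge_keys(rx, rx$pathway, classes, reversible_edges)) {
      src <- c(src, ek$source); tgt <- c(tgt, ek$target); rep <- c(rep, rk)
    }
  }
  sset_graph(unique(c(src, tgt)),
             data.frame(source = src, target = tgt, representative = rep,
                        stringsAsFactors = FALSE))
}

#' @export
print.pb_graph <- function(x, ...) {
  cat(sprintf("<species-set graph: %d vertices, %d edges>\n",
              length(x$vertices), length(x$edges)))
  invisible(x)
}

#' N-order reachability matrix
#'
#' Boolean matrix over the graph's vertices: entry (u, v) is `TRUE` iff a
#' directed path of length at most `N` leads from u to v.  Computed as
#' the boolean union of the first `N` boolean powers of the adjacency
#' matrix.  A diagonal entry is `TRUE` only when the vertex lies on a
#' cycle (paths have length >= 1).  Off-diagonal reachability is
#' complete at `N = |V| - 1`; the diagonal may need `N = |V|` (a
#' Hamiltonian cycle), so `N = |V|` gives the full transitive closure.
#'
#' @param graph A `pb_graph`.
#' @param N Maximum path length, a positive integer.
#' @return Logical matrix with vertex ids as dimnames.
#' @export
reachability_matrix <- function(graph, N) {
  stopifnot(inherits(graph, "pb_graph"))
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1)
    pb_stop("pb_argument_error", "N must be a positive integer (got %s)", deparse(N))
  N <- as.integer(N)
  v <- graph$vertices
  n <- length(v)
  A <- matrix(FALSE, n, n, dimnames = list(v, v))
  for (e in graph$edges) A[e$source, e$target] <- TRUE
  if (n == 0L) return(A)
  acc <- A
  cur <- A
  k <- 1L
  while (k < N) {
    cur <- (cur %*% A) > 0
    k <- k + 1L
    # Reachability-within-k is monotone and plateaus only at its fixpoint
    # (a first-witness walk of length k+1 would imply a new pair at k),
    # so an iteration adding nothing ends the recursion early.
    if (!any(cur & !acc)) break
    acc <- acc | cur
  }
  acc
}

#' Enumerate alternative simple paths between two species-sets
#'
#' All simple directed paths (no repeated vertex) from `source` to
#' `target` of length at most `max_len`, in deterministic order: shortest
#' first, then lexicographic by vertex ids.  At most `max_paths` paths
#' are returned; hitting the cap sets `truncated` on the entry, never
#' silently.  `source == target` yields zero paths (self-circuits are
#' not composition candidates).
#'
#' @param graph A `pb_graph`.
#' @param source,target Vertex ids.
#' @param max_len Maximum path length in edges (default 6).
#' @param max_paths Cap on the number of returned paths (default 1000).
#' @return A `pb_paths` entry: `source`, `target`, `paths` (list of
#'   vertex-id vectors, each of length path length + 1), `order`
#'   (integer path lengths), `truncated`.
#' @export
find_alternative_paths <- function(graph, source, target, max_len = 6L, max_paths = 1000L) {
  stopifnot(inherits(graph, "pb_graph"))
  for (v in c(source, target)) {
    if (!v %in% graph$vertices)
      pb_stop("pb_lookup_error", "vertex '%s' is not in the graph", v)
  }
  paths <- list()
  truncated <- FALSE
  if (!identical(source, target) && max_len >= 1L) {
    adj <- graph$adj
    # Iterative deepening: enumerate paths of exact length L in
    # lexicographic neighbor order, so output is shortest-first and
    # deterministic without a global sort.
    for (L in seq_len(max_len)) {
      if (truncated) break
      visited <- stats::setNames(logical(length(graph$vertices)), graph$vertices)
      dfs <- function(v, depth, trail) {
        if (truncated) return()
        if (depth == L) {
          if (identical(v, target)) {
            if (length(paths) >= max_paths) truncated <<- TRUE
            else paths[[length(paths) + 1L]] <<- trail
          }
          return()
        }
        visited[[v]] <<- TRUE
        for (w in adj[[v]]) {
          if (!visited[[w]] && !identical(w, source))
            dfs(w, depth + 1L, c(trail, w))
        }
        visited[[v]] <<- FALSE
      }
      dfs(source, 0L, source)
    }
  }
  structure(list(source = source, target = target, paths = paths,
                 order = vapply(paths, function(p) length(p) - 1L, 0L),
                 truncated = truncated),
            class = "pb_paths")
}

#' @export
print.pb_paths <- function(x, ...) {
  cat(sprintf("<%d path(s) %s -> %s%s>\n", length(x$paths), x$source, x$target,
              if (x$truncated) ", truncated" else ""))
  invisible(x)
}

#' Edge/vertex ratio of the species-set graph
#'
#' A connectivity-density summary comparable across pathway databases.
#'
#' @param graph A `pb_graph` with at least one vertex.
#' @return `|edges| / |vertices|` as a real number.
#' @export
edge_vertex_ratio <- function(graph) {
  stopifnot(inherits(graph, "pb_graph"))
  if (length(graph$vertices) == 0L)
    pb_stop("pb_argument_error", "edge/vertex ratio is undefined for an empty graph")
  length(graph$edges) / length(graph$vertices)
}

#' Build the three-section dictionary of pathway building blocks
#'
#' Section 1, *building blocks*: every edge of the species-set graph
#' with its representative and supporting reactions (ordered by source
#' then target set id).  Section 2, *equivalent reactions*: all duplicate
#' groups.  Section 3, *compositions*: every ordered vertex pair joined
#' by two or more distinct simple paths of length at most `max_len` —
#' the alternative reaction compositions.  Every record carries element
#' keys, which embed the source pathway file names.
#'
#' @param graph A `pb_graph`.
#' @param duplicates A `pb_duplicates`.
#' @param max_len,max_paths Path-enumeration bounds, see
#'   [find_alternative_paths()].
#' @param include_self Include self-loop pairs (source = target) as
#'   composition candidates (default `FALSE`).
#' @return A `pb_dictionary` with `building_blocks` (data frame),
#'   `equivalent_reactions` (the duplicate groups), `compositions`
#'   (list of `pb_paths` entries with >= 2 paths), and the enumeration
#'   parameters.
#' @export
build_dictionary <- function(graph, duplicates, max_len = 6L, max_paths = 1000L,
                             include_self = FALSE) {
  stopifnot(inherits(graph, "pb_graph"), inherits(duplicates, "pb_duplicates"))
  blocks <- if (length(graph$edges)) {
    data.frame(
      source_set = vapply(graph$edges, `[[`, "", "source"),
      target_set = vapply(graph$edges, `[[`, "", "target"),
      representative = vapply(graph$edges, `[[`, "", "representative"),
      n_supporting = vapply(graph$edges, function(e) length(e$supporting), 0L),
      supporting = vapply(graph$edges, function(e) paste(e$supporting, collapse = "; "), ""),
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else {
    data.frame(source_set = character(0), target_set = character(0),
               representative = character(0), n_supporting = integer(0),
               supporting = character(0), stringsAsFactors = FALSE)
  }
  ord <- order(blocks$source_set, blocks$target_set, method = "radix")
  blocks <- blocks[ord, , drop = FALSE]
  rownames(blocks) <- NULL

  compositions <- list()
  if (length(graph$vertices) >= 1L && length(graph$edges) >= 1L) {
    reach <- reachability_matrix(graph, max(1L, min(as.integer(max_len), length(graph$vertices))))
    for (u in graph$vertices) for (v in graph$vertices) {
      if (!include_self && identical(u, v)) next
      if (!reach[u, v]) next
      entry <- find_alternative_paths(graph, u, v, max_len = max_len, max_paths = max_paths)
      if (length(entry$paths) >= 2L)
        compositions[[length(compositions) + 1L]] <- entry
    }
  }
  structure(list(building_blocks = blocks,
                 equivalent_reactions = duplicates,
                 compositions = compositions,
                 max_len = as.integer(max_len), max_paths = as.integer(max_paths),
                 include_self = include_self),
            class = "pb_dictionary")
}

#' @export
print.pb_dictionary <- function(x, ...) {
  cat(sprintf(paste0("<dictionary: %d building block(s), %d equivalent-reaction group(s), ",
                     "%d composition entrie(s); max_len=%d>\n"),
              nrow(x$building_blocks), length(x$equivalent_reactions),
              length(x$compositions), x$max_len))
  invisible(x)
}

#' Write a dictionary to JSON and per-section TSV files
#'
#' Writes `dictionary.json` plus `building_blocks.tsv`,
#' `equivalent_reactions.tsv` and `compositions.tsv` into `dir`.  The
#' enumeration parameters (including the path-length bound N) are
#' recorded in the JSON header.  Output is deterministic: byte-identical
#' across runs on the same input.
#'
#' @param dictionary A `pb_dictionary`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
dictionary_write <- function(dictionary, dir) {
  stopifnot(inherits(dictionary, "pb_dictionary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comp_rows <- lapply(dictionary$compositions, function(e) {
    list(source_set = e$source, target_set = e$target,
         n_paths = length(e$paths), path_lengths = e$order,
         paths = lapply(e$paths, identity), truncated = e$truncated)
  })
  doc <- list(schema = "pb-dictionary", schema_version = PB_SCHEMA_VERSION,
              max_len = dictionary$max_len, max_paths = dictionary$max_paths,
              include_self = dictionary$include_self,
              building_blocks = dictionary$building_blocks,
              equivalent_reactions = unclass(dictionary$equivalent_reactions),
              compositions = comp_rows)
  jsonlite::write_json(doc, file.path(dir, "dictionary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.table(dictionary$building_blocks, file.path(dir, "building_blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(duplicate_report(dictionary$equivalent_reactions),
                     file.path(dir, "equivalent_reactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comp_df <- data.frame(
    source_set = vapply(dictionary$compositions, `[[`, "", "source"),
    target_set = vapply(dictionary$compositions, `[[`, "", "target"),
    n_paths = vapply(dictionary$compositions, function(e) length(e$paths), 0L),
    path_lengths = vapply(dictionary$compositions, function(e) paste(e$order, collapse = ","), ""),
    paths = vapply(dictionary$compositions, function(e)
      paste(vapply(e$paths, paste, "", collapse = " -> "), collapse = " | "), ""),
    truncated = vapply(dictionary$compositions, `[[`, NA, "truncated"),
    stringsAsFactors = FALSE
  )
  utils::write.table(comp_df, file.path(dir, "compositions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
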