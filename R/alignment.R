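# Cross-model species alignment.  Two species are the same biological
# entity iff they are connected (transitively) through shared normalized
# annotation resources whose qualifier the policy admits.  No name-based
# matching is ever performed.

#' Default annotation-qualifier policy
#'
#' Qualifier values whose resources participate in species identity.
#' Identity-qualified (`"is"`) and unqualified resources are admitted by
#' default; `isVersionOf`/`hasPart`-style qualifiers are excluded because
#' they assert weaker relations and would over-merge.
#' @export
pb_default_policy <- c("is", "unqualified")

admissible_resources <- function(element, policy) {
  keys <- character(0)
  for (a in element$annotations) {
    if (annotation_is_mapped(a) && a$type %in% policy)
      keys <- c(keys, annotation_res_key(a))
  }
  unique(keys)
}

# Plain array union-find with path compression.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Build cross-model species equivalence classes
#'
#' Partitions all species of the aggregate: two species share a class iff
#' they are linked, directly or transitively, by at least one normalized
#' resource admitted by the qualifier policy.  Species with no admissible
#' resources form singleton classes.  Class ids are deterministic: the
#' lexicographically smallest resource key of the class (prefixed `"r:"`),
#' or the species' own element key (prefixed `"s:"`) for unannotated
#' singletons.
#'
#' @param aggregate A `pb_aggregate`.
#' @param policy Character vector of admitted qualifier values; see
#'   [pb_default_policy].
#' @return A `pb_classes` object: `membership` (named character, species
#'   key -> class id) and `classes` (named list with `members` and
#'   `resources`, both sorted).
#' @export
build_equivalence_classes <- function(aggregate, policy = pb_default_policy) {
  stopifnot(inherits(aggregate, "pb_aggregate"))
  keys <- pb_sort(names(aggregate$species))
  n <- length(keys)
  res_of <- lapply(aggregate$species[keys], admissible_resources, policy = policy)
  names(res_of) <- keys

  parent <- uf_new(n)
  seen <- new.env(parent = emptyenv())  # resource key -> first species index
  for (i in seq_len(n)) {
    for (rk in res_of[[i]]) {
      j <- seen[[rk]]
      if (is.null(j)) assign(rk, i, envir = seen)
      else {
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }

  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
  groups <- split(seq_len(n), roots)
  membership <- character(n); names(membership) <- keys
  classes <- list()
  for (g in groups) {
    members <- keys[g]
    resources <- pb_sort(unique(unlist(res_of[members], use.names = FALSE)))
    cid <- if (length(resources)) {
      paste0("r:", resources[1])
    } else {
      paste0("s:", members[1])
    }
    cid <- gsub("[,{}|]", ".", cid)
    classes[[cid]] <- list(class_id = cid, members = pb_sort(members), resources = resources)
    membership[members] <- cid
  }
  classes <- classes[pb_sort(names(classes))]
  structure(list(membership = membership, classes = classes, policy = policy),
            class = "pb_classes")
}

#' @export
print.pb_classes <- function(x, ...) {
  sizes <- lengths(lapply(x$classes, `[[`, "members"))
  cat(sprintf("<species classes: %d species in %d classes (%d cross-species)>\n",
              length(x$membership), length(x$classes), sum(sizes >= 2)))
  invisible(x)
}

# Reserved vertex for reactions with an empty side (pure synthesis or
# degradation); keeps the species-set graph total over all reactions.
PB_EMPTY_SET <- "{}"

#' Species-set of a list of species
#'
#' Maps one side of a reaction to its species-set vertex id: the sorted,
#' de-duplicated class ids of the given species, rendered
#' `"{c1,c2,...}"`.  An empty input maps to the reserved empty-set vertex
#' `"{}"` used by synthesis/degradation reactions.  Stoichiometry plays
#' no role: a species-set is a set, not a multiset.
#'
#' @param species_keys Character vector of species element keys.
#' @param classes A `pb_classes` object.
#' @return The set id (character scalar), with the member class ids in
#'   attribute `"classes"`.
#' @export
species_set_of <- function(species_keys, classes) {
  stopifnot(inherits(classes, "pb_classes"))
  if (length(species_keys) == 0L)
    return(structure(PB_EMPTY_SET, classes = character(0)))
  cids <- classes$membership[species_keys]
  if (anyNA(cids))
    pb_stop("pb_alignment_error", "species not covered by the equivalence classes: %s",
            paste(species_keys[is.na(cids)], collapse = ", "))
  cids <- pb_sort(unique(unname(cids)))
  structure(paste0("{", paste(cids, collapse = ","), "}"), classes = cids)
}

# Side sets of one reaction, keyed in the aggregate's pathway context.
reaction_side_keys <- function(rx, fullname) {
  list(reactants = vapply(rx$reactants, function(s) element_key(fullname, s), "", USE.NAMES = FALSE),
       products = vapply(rx$products, function(s) element_key(fullname, s), "", USE.NAMES = FALSE),
       catalysts = vapply(rx$catalysts, function(s) element_key(fullname, s), "", USE.NAMES = FALSE))
}

# Canonical kinetics for comparison: local parameter names substituted by
# their values (token-wise), so two mass-action laws written with
# differently named rate constants of equal value compare equal, while
# equal-named constants of different value do not.
comparable_kinetics <- function(rx) {
  k <- rx$kinetics
  if (is.na(k)) return(NA_character_)
  for (pid in names(rx$parameters)) {
    k <- gsub(paste0("(?<![A-Za-z0-9_])", pid, "(?![A-Za-z0-9_])"),
              pb_num(rx$parameters[[pid]]), k, perl = TRUE)
  }
  k
}

# Directed (source set, target set) keys contributed by one reaction.
reaction_edge_keys <- function(rx, fullname, classes, reversible_edges = TRUE) {
  sides <- reaction_side_keys(rx, fullname)
  src <- species_set_of(sides$reactants, classes)
  tgt <- species_set_of(sides$products, classes)
  out <- list(list(source = as.character(src), target = as.character(tgt)))
  if (reversible_edges && isTRUE(rx$reversible))
    out[[2]] <- list(source = as.character(tgt), target = as.character(src))
  out
}

#' Detect first-order duplicate reactions
#'
#' Groups all reactions of the aggregate by their directed
#' (reactant species-set, product species-set) key; every group holding
#' two or more distinct reactions is a duplicate group.  A reversible
#' reaction contributes both its forward and its reverse key.  The group
#' representative is the reaction with the lexicographically smallest
#' element key.  `kinetics_conflict` is `TRUE` when the members'
#' canonical kinetics strings (local parameters substituted by value)
#' are not all identical, or when their catalyst class-sets differ.
#'
#' @param aggregate A `pb_aggregate`.
#' @param classes A `pb_classes` from [build_equivalence_classes()].
#' @param reversible_edges Treat reversible reactions as two directed
#'   edges (default `TRUE`).
#' @return A `pb_duplicates` object: list of groups, each with
#'   `source_set`, `target_set`, `reactions` (sorted keys),
#'   `representative`, `kinetics_conflict`.
#' @export
detect_duplicate_reactions <- function(aggregate, classes, reversible_edges = TRUE) {
  stopifnot(inherits(aggregate, "pb_aggregate"), inherits(classes, "pb_classes"))
  buckets <- new.env(parent = emptyenv())
  rx_keys <- pb_sort(names(aggregate$reactions))
  for (rk in rx_keys) {
    rx <- aggregate$reactions[[rk]]
    for (ek in reaction_edge_keys(rx, rx$pathway, classes, reversible_edges)) {
      bk <- paste0(ek$source, " -> ", ek$target)
      buckets[[bk]] <- c(buckets[[bk]], rk)
    }
  }
  groups <- list()
  for (bk in pb_sort(ls(buckets))) {
    members <- pb_sort(unique(buckets[[bk]]))
    if (length(members) < 2L) next
    rxs <- aggregate$reactions[members]
    kin <- vapply(rxs, comparable_kinetics, "")
    cat_sets <- vapply(rxs, function(rx) {
      as.character(species_set_of(reaction_side_keys(rx, rx$pathway)$catalysts, classes))
    }, "")
    conflict <- length(unique(kin)) > 1L || length(unique(cat_sets)) > 1L
    st <- strsplit(bk, " -> ", fixed = TRUE)[[1]]
    groups[[length(groups) + 1L]] <- list(
      source_set = st[1], target_set = st[2],
      reactions = members, representative = members[1],
      kinetics_conflict = conflict
    )
  }
  structure(groups, class = "pb_duplicates",
            reversible_edges = reversible_edges)
}

#' @export
print.pb_duplicates <- function(x, ...) {
  cat(sprintf("<duplicate reactions: %d group(s)>\n", length(x)))
  for (g in x)
    cat(sprintf("  %s -> %s : %s%s\n", g$source_set, g$target_set,
                paste(g$reactions, collapse = ", "),
                if (g$kinetics_conflict) "  [kinetics conflict]" else ""))
  invisible(x)
}

#' Duplicate report as a data frame
#'
#' Flat table of all duplicate groups for reporting (one row per group),
#' with member reactions and their pathway provenance.
#'
#' @param duplicates A `pb_duplicates` object.
#' @return A data frame with columns `group`, `source_set`, `target_set`,
#'   `n_reactions`, `reactions`, `representative`, `kinetics_conflict`.
#' @export
duplicate_report <- function(duplicates) {
  stopifnot(inherits(duplicates, "pb_duplicates"))
  if (length(duplicates) == 0L)
    return(data.frame(group = integer(0), source_set = character(0),
                      target_set = character(0), n_reactions = integer(0),
                      reactions = character(0), representative = character(0),
                      kinetics_conflict = logical(0), stringsAsFactors = FALSE))
  data.frame(
    group = seq_along(duplicates),
    source_set = vapply(duplicates, `[[`, "", "source_set"),
    target_set = vapply(duplicates, `[[`, "", "target_set"),
    n_reactions = vapply(duplicates, function(g) length(g$reactions), 0L),
    reactions = vapply(duplicates, function(g) paste(g$reactions, collapse = "; "), ""),
    representative = vapply(duplicates, `[[`, "", "representative"),
    kinetics_conflict = vapply(duplicates, `[[`, NA, "kinetics_conflict"),
    stringsAsFactors = FALSE
  )
}
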