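# Seeded synthetic SBML generators with ground-truth manifests.  Each
# generator writes valid SBML Level 2 files (through the package's own
# writer, so they parse by construction) plus a machine-checkable answer
# key recording the planted equivalence classes, duplicate groups and
# alternative-path compositions.  Same seed => byte-identical files and
# manifest.
#
# Annotations are drawn from a synthetic registry ("urn:miriam:testdb:…")
# with a sprinkling of realistic namespaces written in different URI
# syntaxes (urn / identifiers.org), so cross-model alignment exercises
# the normalizer.  Kinetics are mass action with rate constants drawn
# log-uniform in [1e-3, 1e3]; kinetics content is stored and compared but
# never simulated.

new_manifest <- function(kind, seed, models, files, planted_classes,
                         planted_duplicates, planted_compositions) {
  structure(list(kind = kind, seed = seed, models = models, files = files,
                 planted_classes = planted_classes,
                 planted_duplicates = planted_duplicates,
                 planted_compositions = planted_compositions),
            class = "pb_manifest")
}

#' @export
print.pb_manifest <- function(x, ...) {
  cat(sprintf("<fixture manifest '%s' (seed %d): %d model(s), %d class(es), %d duplicate group(s), %d composition(s)>\n",
              x$kind, x$seed, nrow(x$models), length(x$planted_classes),
              length(x$planted_duplicates), length(x$planted_compositions)))
  invisible(x)
}

#' Write a fixture manifest as JSON
#' @param manifest A `pb_manifest`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
manifest_write <- function(manifest, path) {
  stopifnot(inherits(manifest, "pb_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

rand_rate <- function(n = 1) 10^stats::runif(n, -3, 3)

fx_species <- function(id, uri, initial) {
  list(internal_id = id, name = id, initial_value = initial,
       annotations = list(make_annotation("is", uri)))
}

mass_action_mathml <- function(param, reactant_ids) {
  cis <- paste0("<ci> ", reactant_ids, " </ci>", collapse = "")
  sprintf('<math xmlns="http://www.w3.org/1998/Math/MathML"><apply><times/><ci> %s </ci>%s</apply></math>',
          param, cis)
}

fx_reaction <- function(id, reactants, products, k, catalysts = character(0)) {
  list(internal_id = id,
       reactants = reactants, catalysts = catalysts, products = products,
       reversible = FALSE,
       kinetics = paste(c("k1", reactants), collapse = " * "),
       mathml = mass_action_mathml("k1", reactants),
       parameters = c(k1 = k),
       annotations = list())
}

fx_model <- function(fullname, species, reactions) {
  structure(list(pathway = list(fullname = fullname, annotations = list()),
                 species = species, reactions = reactions,
                 global_parameters = numeric(0)),
            class = "pb_model")
}

# Generator-local simple-path enumerator over a planted edge list (the
# answer key is computed from generation bookkeeping, not by the
# pipeline under test).
plant_paths <- function(edges, max_len = 6L) {
  verts <- sort(unique(c(edges$source, edges$target)))
  adj <- lapply(stats::setNames(verts, verts), function(v)
    sort(edges$target[edges$source == v]))
  out <- list()
  for (u in verts) for (v in verts) {
    if (u == v) next
    found <- list()
    rec <- function(node, trail) {
      if (length(trail) - 1L > max_len) return()
      if (node == v) { found[[length(found) + 1L]] <<- trail; return() }
      for (w in adj[[node]]) if (!w %in% trail) rec(w, c(trail, w))
    }
    rec2 <- function() {
      for (w in adj[[u]]) if (w != u) rec(w, c(u, w))
    }
    rec2()
    if (length(found) >= 2L)
      out[[length(out) + 1L]] <- list(source = u, target = v,
                                      path_lengths = sort(vapply(found, length, 0L) - 1L))
  }
  out
}

plant_groups <- function(keys_by_edge) {
  groups <- list()
  for (bk in sort(names(keys_by_edge))) {
    members <- sort(unique(keys_by_edge[[bk]]))
    if (length(members) >= 2L) groups[[length(groups) + 1L]] <-
        list(edge = bk, reactions = members)
  }
  groups
}

#' Generate a random multi-model SBML fixture set
#'
#' Writes `n_models` SBML files into `dir`.  Model i's species j shares a
#' cross-model annotation (the j-th entry of a global synthetic entity
#' registry) with probability `share_prob`, otherwise it receives a
#' model-private resource; with `share_prob = 1` and aligned species
#' lists every cross-model pair of same-index species is co-classed,
#' with `share_prob = 0` all classes are singletons.  Each model gets
#' `n_species_per_model - 1` random irreversible mass-action reactions.
#' The manifest records the realized classes, duplicate groups and
#' alternative-path compositions.
#'
#' @param n_models Number of models (>= 1).
#' @param n_species_per_model Species per model (>= 2).
#' @param share_prob Cross-model sharing probability in `[0, 1]`.
#' @param seed Integer seed; same seed reproduces byte-identical output.
#' @param dir Output directory (created if missing).
#' @return List with `files` (SBML paths) and `manifest` (`pb_manifest`).
#' @export
generate_models <- function(n_models = 5L, n_species_per_model = 6L,
                            share_prob = 0.3, seed = 1L, dir = tempfile("fixtures")) {
  if (!is.numeric(n_models) || n_models < 1)
    pb_stop("pb_argument_error", "n_models must be >= 1")
  if (!is.numeric(share_prob) || is.na(share_prob) || share_prob < 0 || share_prob > 1)
    pb_stop("pb_argument_error", "share_prob must be a probability in [0, 1]")
  if (n_species_per_model < 2)
    pb_stop("pb_argument_error", "n_species_per_model must be >= 2")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  shared_uri <- function(j) {
    switch((j %% 3L) + 1L,
           sprintf("urn:miriam:testdb:T%04d", j),
           sprintf("urn:miriam:uniprot:P%05d", 90000L + j),
           sprintf("http://identifiers.org/chebi/CHEBI:%d", 10000L + j))
  }
  shared_label <- function(j) {
    r <- normalize_annotation(shared_uri(j))
    resource_key(r)
  }

  with_seed(seed, {
    files <- character(0)
    rows <- list()
    label_of <- character(0)        # species element key -> entity label
    edge_members <- list()          # "src -> tgt" -> reaction keys
    edge_df <- data.frame(source = character(0), target = character(0),
                          stringsAsFactors = FALSE)
    for (i in seq_len(n_models)) {
      fullname <- sprintf("m%02d.xml", i)
      sp_ids <- sprintf("s%d", seq_len(n_species_per_model))
      species <- list()
      for (j in seq_len(n_species_per_model)) {
        shared <- stats::runif(1) <= share_prob
        uri <- if (shared) shared_uri(j) else sprintf("urn:miriam:testdb:U%02d.%02d", i, j)
        lbl <- if (shared) shared_label(j) else
          resource_key(normalize_annotation(uri))
        key <- element_key(fullname, sp_ids[j])
        label_of[[key]] <- lbl
        species[[sp_ids[j]]] <- fx_species(sp_ids[j], uri, signif(rand_rate(1), 6))
      }
      reactions <- list()
      for (r in seq_len(n_species_per_model - 1L)) {
        rid <- sprintf("r%d", r)
        reactants <- sample(sp_ids, sample(1:2, 1))
        rest <- setdiff(sp_ids, reactants)
        products <- sample(rest, min(sample(1:2, 1), length(rest)))
        reactions[[rid]] <- fx_reaction(rid, reactants, products, signif(rand_rate(1), 6))
        src <- paste0("{", paste(sort(unique(label_of[element_key(fullname, reactants)])), collapse = ","), "}")
        tgt <- paste0("{", paste(sort(unique(label_of[element_key(fullname, products)])), collapse = ","), "}")
        bk <- paste0(src, " -> ", tgt)
        edge_members[[bk]] <- c(edge_members[[bk]], element_key(fullname, rid))
        edge_df <- rbind(edge_df, data.frame(source = src, target = tgt,
                                             stringsAsFactors = FALSE))
      }
      path <- file.path(dir, fullname)
      write_sbml(fx_model(fullname, species, reactions), path)
      files <- c(files, path)
      rows[[i]] <- data.frame(fullname = fullname,
                              n_species = length(species),
                              n_reactions = length(reactions),
                              n_annotations = length(species),
                              stringsAsFactors = FALSE)
    }
    planted_classes <- unname(lapply(split(names(label_of), unname(label_of)),
                                     function(m) sort(m)))
    edge_df <- edge_df[!duplicated(edge_df), , drop = FALSE]
    manifest <- new_manifest(
      kind = "random-models", seed = as.integer(seed),
      models = do.call(rbind, rows), files = basename(files),
      planted_classes = planted_classes,
      planted_duplicates = plant_groups(edge_members),
      planted_compositions = plant_paths(edge_df)
    )
    manifest_write(manifest, file.path(dir, "manifest.json"))
    list(files = files, manifest = manifest)
  })
}

#' Generate two models overlapping in exactly one reaction
#'
#' Two SBML models share three annotated species (written in different
#' URI syntaxes of the same resources across the two files) and both
#' declare the reaction A + B -> C over them — one planted first-order
#' duplicate pair.  Each model adds one private follow-up reaction so
#' the overlap is exactly one group.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param kinetics_differ If `TRUE` the two copies get different rate
#'   constants, so the duplicate group carries a kinetics conflict.
#' @return List with `files` and `manifest`.
#' @export
generate_duplicate_pair <- function(seed = 1L, dir = tempfile("duppair"),
                                    kinetics_differ = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    acc <- sample(10000:99999, 3)
    uris1 <- sprintf("urn:miriam:uniprot:P%05d", acc)
    uris2 <- sprintf("http://identifiers.org/uniprot/P%05d", acc)
    k_shared <- signif(rand_rate(1), 6)
    k_other <- if (kinetics_differ) signif(k_shared * 3.7, 6) else k_shared
    iv <- signif(rand_rate(8), 6)

    m1 <- fx_model("dupA.xml",
      list(A = fx_species("A", uris1[1], iv[1]),
           B = fx_species("B", uris1[2], iv[2]),
           C = fx_species("C", uris1[3], iv[3]),
           D = fx_species("D", sprintf("urn:miriam:testdb:D%04d", sample(1000:9999, 1)), iv[4])),
      list(r1 = fx_reaction("r1", c("A", "B"), "C", k_shared),
           r2 = fx_reaction("r2", "C", "D", signif(rand_rate(1), 6))))
    m2 <- fx_model("dupB.xml",
      list(A = fx_species("A", uris2[1], iv[5]),
           B = fx_species("B", uris2[2], iv[6]),
           C = fx_species("C", uris2[3], iv[7]),
           E = fx_species("E", sprintf("urn:miriam:testdb:E%04d", sample(1000:9999, 1)), iv[8])),
      list(r1 = fx_reaction("r1", c("A", "B"), "C", k_other),
           r2 = fx_reaction("r2", "C", "E", signif(rand_rate(1), 6))))

    files <- c(file.path(dir, "dupA.xml"), file.path(dir, "dupB.xml"))
    write_sbml(m1, files[1]); write_sbml(m2, files[2])
    manifest <- new_manifest(
      kind = "duplicate-pair", seed = as.integer(seed),
      models = data.frame(fullname = c("dupA.xml", "dupB.xml"),
                          n_species = c(4L, 4L), n_reactions = c(2L, 2L),
                          n_annotations = c(4L, 4L), stringsAsFactors = FALSE),
      files = basename(files),
      planted_classes = c(
        lapply(1:3, function(i) sort(c(element_key("dupA.xml", c("A", "B", "C")[i]),
                                       element_key("dupB.xml", c("A", "B", "C")[i])))),
        list(element_key("dupA.xml", "D"), element_key("dupB.xml", "E"))),
      planted_duplicates = list(list(
        reactions = c("dupA.xml::r1", "dupB.xml::r1"),
        kinetics_conflict = kinetics_differ)),
      planted_compositions = list()
    )
    manifest_write(manifest, file.path(dir, "manifest.json"))
    list(files = files, manifest = manifest)
  })
}

#' Generate the direct-versus-indirect overlap motif
#'
#' Two models realize the two ways a pair of species-sets can be
#' connected: both declare the direct reaction X -> Y (a first-order
#' duplicate pair), and the second also routes X to Y through
#' `intermediates` private species.  The planted dictionary answer is
#' one duplicate group and one composition entry with exactly two paths,
#' of lengths 1 and `intermediates + 1`.
#'
#' @param intermediates Number of intermediate species on the long route
#'   (>= 1).  `intermediates = 2` reproduces the shape of the classic
#'   EGFR-internalization alternative (direct conversion versus a
#'   three-step route through internalized receptor states).
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return List with `files` and `manifest`.
#' @export
generate_alternative_path_motif <- function(intermediates = 1L, seed = 1L,
                                            dir = tempfile("motif")) {
  if (!is.numeric(intermediates) || intermediates < 1)
    pb_stop("pb_argument_error", "intermediates must be >= 1")
  intermediates <- as.integer(intermediates)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    acc <- sample(10000:99999, 2)
    x_uri <- sprintf("urn:miriam:testdb:X%05d", acc[1])
    y_uri <- sprintf("urn:miriam:testdb:Y%05d", acc[2])
    k_direct <- signif(rand_rate(1), 6)
    iv <- signif(rand_rate(4 + intermediates), 6)

    m1 <- fx_model("motifA.xml",
      list(X = fx_species("X", x_uri, iv[1]),
           Y = fx_species("Y", y_uri, iv[2])),
      list(r1 = fx_reaction("r1", "X", "Y", k_direct)))

    ids <- c("X", sprintf("I%d", seq_len(intermediates)), "Y")
    species2 <- list(X = fx_species("X", x_uri, iv[3]),
                     Y = fx_species("Y", y_uri, iv[4]))
    for (j in seq_len(intermediates)) {
      iid <- sprintf("I%d", j)
      species2[[iid]] <- fx_species(iid, sprintf("urn:miriam:testdb:I%05d.%d", acc[1], j),
                                    iv[4 + j])
    }
    reactions2 <- list(r1 = fx_reaction("r1", "X", "Y", k_direct))
    for (j in seq_len(intermediates + 1L)) {
      cid <- sprintf("c%d", j)
      reactions2[[cid]] <- fx_reaction(cid, ids[j], ids[j + 1L], signif(rand_rate(1), 6))
    }
    m2 <- fx_model("motifB.xml", species2, reactions2)

    files <- c(file.path(dir, "motifA.xml"), file.path(dir, "motifB.xml"))
    write_sbml(m1, files[1]); write_sbml(m2, files[2])
    manifest <- new_manifest(
      kind = "alternative-path-motif", seed = as.integer(seed),
      models = data.frame(
        fullname = c("motifA.xml", "motifB.xml"),
        n_species = c(2L, 2L + intermediates),
        n_reactions = c(1L, 2L + intermediates),
        n_annotations = c(2L, 2L + intermediates), stringsAsFactors = FALSE),
      files = basename(files),
      planted_classes = c(
        list(sort(c("motifA.xml::X", "motifB.xml::X")),
             sort(c("motifA.xml::Y", "motifB.xml::Y"))),
        lapply(seq_len(intermediates), function(j) sprintf("motifB.xml::I%d", j))),
      planted_duplicates = list(list(
        reactions = c("motifA.xml::r1", "motifB.xml::r1"),
        kinetics_conflict = FALSE)),
      planted_compositions = list(list(
        source = "X", target = "Y",
        path_lengths = c(1L, intermediates + 1L)))
    )
    manifest_write(manifest, file.path(dir, "manifest.json"))
    list(files = files, manifest = manifest)
  })
}
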