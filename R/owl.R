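# OWL2 export in RDF/XML.  The writer is a pure function of a sorted,
# de-duplicated triple set, so export -> parse -> re-export is
# byte-identical, and the exported triple count has a closed form
# (owl_triple_count) checked against independent re-parsing in tests.
#
# Triple count formula (after de-duplication), with U() = unique:
#   schema:      1 ontology + 5 classes + 9 object + 5 data properties = 20
#   pathway:     2 typing + 1 fullname                                 =  3
#   species:     2 typing + 1 inPathway + [initial value present]
#                + |sets containing its class| + |annotations|
#   reaction:    2 typing + 1 inPathway + |U(reactants)| + |U(products)|
#                + |U(catalysts)| + [kinetics present] + |annotations|
#   annotation:  2 typing + 1 uri + [information non-empty]
#   set vertex:  2 typing + 1 informationText (carries the set id)
#   edge:        2 representativeOf (1 for a self-loop)
#   duplicates:  |U(member != representative pairs)| duplicateOf
#   composition: 1 alternativePathTo per entry

RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"
PB_BASE_IRI <- "http://pathblocks.local/ontology#"

OWL_CLASSES <- c("Annotation", "Pathway", "Reaction", "Species", "SpeciesSet")
OWL_OBJ_PROPS <- c("alternativePathTo", "duplicateOf", "hasAnnotation", "hasCatalyst",
                   "hasProduct", "hasReactant", "inPathway", "memberOfSet",
                   "representativeOf")
OWL_DATA_PROPS <- c("fullname", "informationText", "initialValue", "kineticFormula", "uri")

pct_encode <- function(x, keep_regex) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    if (grepl(keep_regex, ch)) ch
    else paste0("%", paste(sprintf("%02X", as.integer(charToRaw(ch))), collapse = "%"))
  }, "", USE.NAMES = FALSE), collapse = "")
}

#' IRI-safe individual name for a model element
#'
#' `"<fullname>_<local id>"` with characters outside the IRI-safe set
#' percent-encoded.  Underscores inside the *fullname* component are
#' percent-encoded too (local ids keep theirs verbatim), which makes the
#' mapping injective: the first bare underscore always separates the
#' pathway file name from the local id.
#'
#' @param pathway_fullname Pathway file name, non-empty.
#' @param local_id Model-local element id, non-empty.
#' @return Character scalar name (no base IRI attached).
#' @examples
#' individual_name("BIOMOD0000000049.xml", "re2")
#' @export
individual_name <- function(pathway_fullname, local_id) {
  if (!nzchar(pathway_fullname) || !nzchar(local_id))
    pb_stop("pb_argument_error", "individual_name: both components must be non-empty")
  paste0(pct_encode(pathway_fullname, "^[A-Za-z0-9.~-]$"), "_",
         pct_encode(local_id, "^[A-Za-z0-9._~-]$"))
}

triple <- function(subject, predicate, object, kind) {
  data.frame(subject = subject, predicate = predicate, object = object,
             kind = kind, stringsAsFactors = FALSE)
}

# ---- triple assembly -------------------------------------------------------

owl_triples <- function(aggregate, classes = NULL, graph = NULL, dictionary = NULL,
                        base_iri = PB_BASE_IRI) {
  stopifnot(inherits(aggregate, "pb_aggregate"))
  iri <- function(local) paste0(base_iri, local)
  rdf_type <- paste0(RDF_NS, "type")
  rows <- list()
  add <- function(s, p, o, kind) rows[[length(rows) + 1L]] <<- triple(s, p, o, kind)
  typed <- function(ind, cls) {
    add(ind, rdf_type, paste0(OWL_NS, "NamedIndividual"), "iri")
    add(ind, rdf_type, iri(cls), "iri")
  }

  add(sub("#$", "", base_iri), rdf_type, paste0(OWL_NS, "Ontology"), "iri")
  for (cl in OWL_CLASSES) add(iri(cl), rdf_type, paste0(OWL_NS, "Class"), "iri")
  for (p in OWL_OBJ_PROPS) add(iri(p), rdf_type, paste0(OWL_NS, "ObjectProperty"), "iri")
  for (p in OWL_DATA_PROPS) add(iri(p), rdf_type, paste0(OWL_NS, "DatatypeProperty"), "iri")

  add_annotations <- function(host_ind, fullname, host_local, annotations) {
    for (i in seq_along(annotations)) {
      a <- annotations[[i]]
      ann_ind <- iri(individual_name(fullname, paste0(host_local, ".ann", i)))
      typed(ann_ind, "Annotation")
      add(ann_ind, iri("uri"), a$uri, "literal")
      if (nzchar(a$information)) add(ann_ind, iri("informationText"), a$information, "literal")
      add(host_ind, iri("hasAnnotation"), ann_ind, "iri")
    }
  }

  # vertex individuals, named by rank of their sorted set ids
  set_ind <- character(0)
  class_to_sets <- list()
  if (!is.null(graph)) {
    vs <- graph$vertices  # already sorted
    set_ind <- stats::setNames(iri(sprintf("SpeciesSet_%05d", seq_along(vs))), vs)
    for (v in vs) {
      typed(set_ind[[v]], "SpeciesSet")
      add(set_ind[[v]], iri("informationText"), v, "literal")
      for (cid in set_id_classes(v)) class_to_sets[[cid]] <- c(class_to_sets[[cid]], set_ind[[v]])
    }
  }

  for (fn in pb_sort(names(aggregate$pathways))) {
    pw <- aggregate$pathways[[fn]]
    ind <- iri(pct_encode(fn, "^[A-Za-z0-9.~-]$"))
    typed(ind, "Pathway")
    add(ind, iri("fullname"), fn, "literal")
    add_annotations(ind, fn, "pathway", pw$annotations)
  }

  for (sk in pb_sort(names(aggregate$species))) {
    sp <- aggregate$species[[sk]]
    ind <- iri(individual_name(sp$pathway, sp$internal_id))
    typed(ind, "Species")
    add(ind, iri("inPathway"), iri(pct_encode(sp$pathway, "^[A-Za-z0-9.~-]$")), "iri")
    if (!is.na(sp$initial_value)) add(ind, iri("initialValue"), pb_num(sp$initial_value), "literal")
    if (!is.null(classes)) {
      cid <- classes$membership[[sk]]
      for (si in class_to_sets[[cid]]) add(ind, iri("memberOfSet"), si, "iri")
    }
    add_annotations(ind, sp$pathway, sp$internal_id, sp$annotations)
  }

  for (rk in pb_sort(names(aggregate$reactions))) {
    rx <- aggregate$reactions[[rk]]
    ind <- iri(individual_name(rx$pathway, rx$internal_id))
    typed(ind, "Reaction")
    add(ind, iri("inPathway"), iri(pct_encode(rx$pathway, "^[A-Za-z0-9.~-]$")), "iri")
    for (s in unique(rx$reactants))
      add(ind, iri("hasReactant"), iri(individual_name(rx$pathway, s)), "iri")
    for (s in unique(rx$products))
      add(ind, iri("hasProduct"), iri(individual_name(rx$pathway, s)), "iri")
    for (s in unique(rx$catalysts))
      add(ind, iri("hasCatalyst"), iri(individual_name(rx$pathway, s)), "iri")
    if (!is.na(rx$kinetics)) add(ind, iri("kineticFormula"), rx$kinetics, "literal")
    add_annotations(ind, rx$pathway, rx$internal_id, rx$annotations)
  }

  rx_ind <- function(key) {
    parts <- split_key(key)
    iri(individual_name(parts$fullname, parts$internal_id))
  }
  if (!is.null(graph)) {
    for (e in graph$edges) {
      add(rx_ind(e$representative), iri("representativeOf"), set_ind[[e$source]], "iri")
      add(rx_ind(e$representative), iri("representativeOf"), set_ind[[e$target]], "iri")
    }
  }
  if (!is.null(dictionary)) {
    for (g in dictionary$equivalent_reactions) {
      for (m in setdiff(g$reactions, g$representative))
        add(rx_ind(m), iri("duplicateOf"), rx_ind(g$representative), "iri")
    }
    for (entry in dictionary$compositions)
      add(set_ind[[entry$source]], iri("alternativePathTo"), set_ind[[entry$target]], "iri")
  }

  df <- do.call(rbind, rows)
  df <- df[!duplicated(df), , drop = FALSE]
  df[order(df$subject, df$predicate, df$kind, df$object, method = "radix"), , drop = FALSE]
}

set_id_classes <- function(set_id) {
  inner <- sub("^\\{", "", sub("\\}$", "", set_id))
  if (!nzchar(inner)) return(character(0))
  strsplit(inner, ",", fixed = TRUE)[[1]]
}

# ---- writer / reader -------------------------------------------------------

owl_qname <- function(p, base_iri) {
  if (startsWith(p, base_iri)) paste0("pb:", substring(p, nchar(base_iri) + 1L))
  else if (startsWith(p, RDF_NS)) paste0("rdf:", substring(p, nchar(RDF_NS) + 1L))
  else if (startsWith(p, OWL_NS)) paste0("owl:", substring(p, nchar(OWL_NS) + 1L))
  else pb_stop("pb_argument_error", "predicate outside known namespaces: %s", p)
}

owl_write <- function(triples, path, base_iri = PB_BASE_IRI) {
  triples <- triples[!duplicated(triples), , drop = FALSE]
  triples <- triples[order(triples$subject, triples$predicate, triples$kind,
                           triples$object, method = "radix"), , drop = FALSE]
  L <- c('<?xml version="1.0" encoding="UTF-8"?>',
         paste0('<rdf:RDF xmlns:rdf="', RDF_NS, '" xmlns:owl="', OWL_NS,
                '" xmlns:pb="', xml_escape_attr(base_iri), '">'))
  for (s in unique(triples$subject)) {
    L <- c(L, paste0('  <rdf:Description rdf:about="', xml_escape_attr(s), '">'))
    sub_rows <- triples[triples$subject == s, , drop = FALSE]
    for (i in seq_len(nrow(sub_rows))) {
      qn <- owl_qname(sub_rows$predicate[i], base_iri)
      if (sub_rows$kind[i] == "iri") {
        L <- c(L, paste0('    <', qn, ' rdf:resource="',
                         xml_escape_attr(sub_rows$object[i]), '"/>'))
      } else {
        L <- c(L, paste0('    <', qn, '>', xml_escape_text(sub_rows$object[i]),
                         '</', qn, '>'))
      }
    }
    L <- c(L, "  </rdf:Description>")
  }
  L <- c(L, "</rdf:RDF>")
  writeLines(L, path)
  invisible(path)
}

#' Export the pipeline results as an OWL2 ontology (RDF/XML)
#'
#' One named individual per pathway, species, reaction, species-set and
#' annotation.  Reactions carry `hasReactant`/`hasProduct`/`hasCatalyst`
#' links to species of their own model and `inPathway` to their pathway
#' (model identity survives export); duplicate-group members point
#' `duplicateOf` at their representative; composition entries become
#' `alternativePathTo` links between species-set individuals.  The
#' document declares its class/property schema, is plain RDF/XML any RDF
#' tool can parse, and is byte-deterministic (sorted triples).
#'
#' @param aggregate A `pb_aggregate`.
#' @param classes Optional `pb_classes` (enables `memberOfSet` links).
#' @param graph Optional `pb_graph` (enables species-set individuals).
#' @param dictionary Optional `pb_dictionary` (enables `duplicateOf` and
#'   `alternativePathTo` links).
#' @param path Output `.owl` file path.
#' @param base_iri Base IRI for all minted names.
#' @return `path`, invisibly.
#' @export
export_owl <- function(aggregate, classes = NULL, graph = NULL, dictionary = NULL,
                       path, base_iri = PB_BASE_IRI) {
  tr <- owl_triples(aggregate, classes, graph, dictionary, base_iri)
  owl_write(tr, path, base_iri)
}

#' Read an RDF/XML ontology back into a triple table
#'
#' Companion reader used for round-trip checks; understands the subset
#' of RDF/XML the exporter emits (one `rdf:Description` per subject,
#' `rdf:resource` objects or plain literals).
#'
#' @param path Path to an RDF/XML file.
#' @return A `pb_owl` object: `triples` data frame (subject, predicate,
#'   object, kind) and the `base_iri` declared by the document.
#' @export
read_owl <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  base_iri <- if ("pb" %in% names(ns)) unname(ns[["pb"]]) else PB_BASE_IRI
  rows <- list()
  for (desc in xml2::xml_find_all(doc, "/*/*[local-name()='Description']")) {
    s <- attr_any(desc, "about")
    for (child in xml2::xml_children(desc)) {
      qn <- xml2::xml_name(child, ns = ns)
      parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
      pred <- if (length(parts) == 2L) paste0(unname(ns[[parts[1]]]), parts[2]) else parts[1]
      res <- attr_any(child, "resource")
      if (!is.na(res)) rows[[length(rows) + 1L]] <- triple(s, pred, res, "iri")
      else rows[[length(rows) + 1L]] <- triple(s, pred, xml2::xml_text(child), "literal")
    }
  }
  triples <- if (length(rows)) do.call(rbind, rows) else
    triple(character(0), character(0), character(0), character(0))
  structure(list(triples = triples, base_iri = base_iri), class = "pb_owl")
}

#' Re-serialize a parsed ontology
#'
#' Writing back the triples read by [read_owl()] reproduces the original
#' export byte-for-byte (the writer is canonical).
#'
#' @param owl A `pb_owl` from [read_owl()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_owl <- function(owl, path) {
  stopifnot(inherits(owl, "pb_owl"))
  owl_write(owl$triples, path, owl$base_iri)
}

#' Closed-form triple count of an export
#'
#' Predicts, from element/edge/group tallies alone, how many distinct
#' triples [export_owl()] emits for these inputs (formula documented in
#' the writer source).  Used to cross-check exports against independent
#' re-parsing.
#'
#' @inheritParams export_owl
#' @return Integer triple count.
#' @export
owl_triple_count <- function(aggregate, classes = NULL, graph = NULL, dictionary = NULL) {
  stopifnot(inherits(aggregate, "pb_aggregate"))
  n <- 20L  # schema declarations
  count_ann <- function(annotations) {
    sum(vapply(annotations, function(a) 4L + as.integer(nzchar(a$information)), 0L))
  }
  class_to_nsets <- list()
  if (!is.null(graph)) {
    n <- n + 3L * length(graph$vertices)
    for (v in graph$vertices) for (cid in set_id_classes(v))
      class_to_nsets[[cid]] <- c(class_to_nsets[[cid]], v)
    for (e in graph$edges)
      n <- n + if (identical(e$source, e$target)) 1L else 2L
  }
  for (pw in aggregate$pathways) n <- n + 3L + count_ann(pw$annotations)
  for (sk in names(aggregate$species)) {
    sp <- aggregate$species[[sk]]
    n <- n + 3L + as.integer(!is.na(sp$initial_value)) + count_ann(sp$annotations)
    if (!is.null(classes)) {
      cid <- classes$membership[[sk]]
      n <- n + length(unique(class_to_nsets[[cid]]))
    }
  }
  for (rx in aggregate$reactions) {
    n <- n + 3L + length(unique(rx$reactants)) + length(unique(rx$products)) +
      length(unique(rx$catalysts)) + as.integer(!is.na(rx$kinetics)) +
      count_ann(rx$annotations)
  }
  if (!is.null(dictionary)) {
    pairs <- character(0)
    for (g in dictionary$equivalent_reactions)
      for (m in setdiff(g$reactions, g$representative))
        pairs <- c(pairs, paste0(m, "|", g$representative))
    n <- n + length(unique(pairs)) + length(dictionary$compositions)
  }
  n
}
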