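# SBML Level 2 reader/writer targeting the minimal quantitative
# meta-format: Pathway, Species, KineticReaction, Parameter, Annotation.
# Only the quantitative skeleton is extracted (species, reactions,
# kinetic laws, parameters, RDF resource annotations); rules, events,
# units and function definitions are out of scope.

xp_local <- function(node, name) {
  xml2::xml_find_all(node, sprintf("./*[local-name()='%s']", name))
}

attr_any <- function(node, local) {
  a <- xml2::xml_attrs(node)
  hit <- grepl(paste0("(^|:)", local, "$"), names(a))
  if (any(hit)) a[[which(hit)[1]]] else NA_character_
}

local_name <- function(node) sub("^.*:", "", xml2::xml_name(node))

# ---- MathML -> canonical infix formula -------------------------------------

.mathml_ops <- c(plus = "+", times = "*", minus = "-", divide = "/", power = "^")

mathml_expr <- function(node) {
  nm <- local_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) == 0L) return(list(text = "", compound = FALSE))
    return(mathml_expr(kids[[1]]))
  }
  if (nm == "ci" || nm == "csymbol")
    return(list(text = trimws(xml2::xml_text(node)), compound = FALSE))
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    kids <- xml2::xml_contents(node)
    parts <- trimws(vapply(kids, xml2::xml_text, ""))
    parts <- parts[nzchar(parts)]
    if (identical(type, "e-notation") && length(parts) == 2L)
      return(list(text = paste0(parts[1], "e", parts[2]), compound = FALSE))
    if (identical(type, "rational") && length(parts) == 2L)
      return(list(text = paste0(parts[1], "/", parts[2]), compound = TRUE))
    return(list(text = trimws(xml2::xml_text(node)), compound = FALSE))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    if (length(kids) == 0L) return(list(text = "", compound = FALSE))
    op <- local_name(kids[[1]])
    args <- lapply(kids[-1], mathml_expr)
    wrap <- function(a) if (a$compound) paste0("(", a$text, ")") else a$text
    if (op %in% names(.mathml_ops)) {
      sym <- .mathml_ops[[op]]
      if (op == "minus" && length(args) == 1L)
        return(list(text = paste0("-", wrap(args[[1]])), compound = TRUE))
      txt <- paste(vapply(args, wrap, ""), collapse = paste0(" ", sym, " "))
      return(list(text = txt, compound = TRUE))
    }
    # generic function application (exp, ln, root, user-defined, ...)
    fname <- if (op == "csymbol") trimws(xml2::xml_text(kids[[1]])) else op
    txt <- paste0(fname, "(", paste(vapply(args, function(a) a$text, ""), collapse = ", "), ")")
    return(list(text = txt, compound = FALSE))
  }
  # unknown leaf (true/false/pi/exponentiale/...)
  list(text = nm, compound = FALSE)
}

# Serialize a MathML <math> node to an infix formula string.  Source
# operand order is preserved (commutative reordering could claim false
# kinetics equality); whitespace is normalized to single spaces.
mathml_to_infix <- function(math_node) {
  txt <- mathml_expr(math_node)$text
  gsub("[[:space:]]+", " ", trimws(txt))
}

# ---- annotation extraction -------------------------------------------------

# An RDF resource inside an <annotation> block becomes one Annotation.
# The MIRIAM qualifier is the nearest ancestor element that is not an RDF
# container ("is", "isVersionOf", "hasPart", ...); resources sitting
# directly under rdf:Description are recorded as "unqualified".
extract_annotations <- function(element) {
  anns <- list()
  for (ann_node in xp_local(element, "annotation")) {
    for (node in xml2::xml_find_all(ann_node, ".//*[local-name()='li']")) {
      uri <- attr_any(node, "resource")
      if (is.na(uri) || !nzchar(uri)) next
      qual <- "unqualified"
      p <- xml2::xml_parent(node)
      while (!inherits(p, "xml_missing")) {
        nm <- local_name(p)
        if (!nm %in% c("Bag", "Seq", "Alt", "li")) {
          if (!nm %in% c("Description", "RDF", "annotation")) qual <- nm
          break
        }
        p <- xml2::xml_parent(p)
      }
      anns[[length(anns) + 1L]] <- make_annotation(qual, uri)
    }
  }
  anns
}

# ---- parser ----------------------------------------------------------------

#' Parse one SBML Level 2 file into the meta-format
#'
#' Every SBML species becomes one meta-format species (`internal_id` =
#' SBML id, `name` = SBML name or the id when absent, `initial_value`
#' from `initialConcentration`, else `initialAmount`, else `NA`); every
#' reaction becomes one kinetic reaction with reactants/products from its
#' species references, catalysts from modifier species references, the
#' kinetic law serialized both verbatim (MathML) and as a canonical infix
#' formula, and local parameters attached.  Every RDF resource URI inside
#' an annotation block becomes one annotation on the enclosing element.
#'
#' @param path SBML file path.
#' @param fullname Pathway name carried by every element; defaults to the
#'   file basename.
#' @return A `pb_model`.
#' @export
parse_sbml <- function(path, fullname = basename(path)) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    pb_stop("pb_parse_error", "malformed XML in '%s': %s", path, conditionMessage(e)))
  root <- xml2::xml_root(doc)
  if (!identical(sub("^.*:", "", xml2::xml_name(root)), "sbml") ||
      !identical(xml2::xml_attr(root, "level"), "2"))
    pb_stop("pb_parse_error", "'%s' is not an SBML Level 2 document", path)

  model_node <- xp_local(root, "model")
  if (length(model_node) == 0L)
    pb_stop("pb_parse_error", "'%s' has no model element", path)
  model_node <- model_node[[1]]

  pathway <- list(fullname = fullname, annotations = extract_annotations(model_node))

  species <- list()
  for (lo in xp_local(model_node, "listOfSpecies")) for (sp in xp_local(lo, "species")) {
    id <- xml2::xml_attr(sp, "id")
    if (is.na(id)) pb_stop("pb_parse_error", "species without id in '%s'", path)
    name <- xml2::xml_attr(sp, "name")
    conc <- xml2::xml_attr(sp, "initialConcentration")
    amt <- xml2::xml_attr(sp, "initialAmount")
    iv <- if (!is.na(conc)) as.numeric(conc) else if (!is.na(amt)) as.numeric(amt) else NA_real_
    species[[id]] <- list(
      internal_id = id,
      name = if (is.na(name)) id else name,
      initial_value = iv,
      annotations = extract_annotations(sp)
    )
  }

  global_parameters <- numeric(0)
  for (lo in xp_local(model_node, "listOfParameters")) for (pa in xp_local(lo, "parameter")) {
    pid <- xml2::xml_attr(pa, "id")
    global_parameters[[pid]] <- as.numeric(xml2::xml_attr(pa, "value"))
  }

  ref_ids <- function(rxn, list_name, ref_name) {
    out <- character(0)
    for (lo in xp_local(rxn, list_name)) for (ref in xp_local(lo, ref_name))
      out <- c(out, xml2::xml_attr(ref, "species"))
    out
  }

  reactions <- list()
  for (lo in xp_local(model_node, "listOfReactions")) for (rxn in xp_local(lo, "reaction")) {
    rid <- xml2::xml_attr(rxn, "id")
    if (is.na(rid)) pb_stop("pb_parse_error", "reaction without id in '%s'", path)
    rev_attr <- xml2::xml_attr(rxn, "reversible")
    reversible <- if (is.na(rev_attr)) TRUE else identical(rev_attr, "true")  # SBML L2 default
    reactants <- ref_ids(rxn, "listOfReactants", "speciesReference")
    products <- ref_ids(rxn, "listOfProducts", "speciesReference")
    catalysts <- ref_ids(rxn, "listOfModifiers", "modifierSpeciesReference")
    for (sid in c(reactants, products, catalysts)) {
      if (!sid %in% names(species))
        pb_stop("pb_consistency_error",
                "reaction '%s' in '%s' references undeclared species '%s'", rid, path, sid)
    }
    kinetics <- NA_character_
    mathml <- NA_character_
    parameters <- numeric(0)
    for (kl in xp_local(rxn, "kineticLaw")) {
      for (math in xp_local(kl, "math")) {
        mathml <- as.character(math)
        kinetics <- mathml_to_infix(math)
      }
      for (lp in xp_local(kl, "listOfParameters")) for (pa in xp_local(lp, "parameter")) {
        pid <- xml2::xml_attr(pa, "id")
        parameters[[pid]] <- as.numeric(xml2::xml_attr(pa, "value"))
      }
    }
    reactions[[rid]] <- list(
      internal_id = rid,
      reactants = reactants, catalysts = catalysts, products = products,
      reversible = reversible,
      kinetics = kinetics, mathml = mathml,
      parameters = parameters,
      annotations = extract_annotations(rxn)
    )
  }

  structure(list(
    pathway = pathway,
    species = species,
    reactions = reactions,
    global_parameters = global_parameters
  ), class = "pb_model")
}

#' @export
print.pb_model <- function(x, ...) {
  cat(sprintf("<pathway model '%s': %d species, %d reactions>\n",
              x$pathway$fullname, length(x$species), length(x$reactions)))
  invisible(x)
}

# ---- writer ----------------------------------------------------------------

write_rdf_block <- function(lines, indent, about, annotations) {
  if (length(annotations) == 0L) return(lines)
  pad <- strrep(" ", indent)
  lines <- c(lines, paste0(pad, "<annotation>"),
             paste0(pad, '  <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">'),
             paste0(pad, '    <rdf:Description rdf:about="#', xml_escape_attr(about), '">'))
  types <- unique(vapply(annotations, function(a) a$type, ""))
  for (type in types) {
    uris <- vapply(Filter(function(a) identical(a$type, type), annotations),
                   function(a) a$uri, "")
    lis <- paste0(pad, '        <rdf:li rdf:resource="', xml_escape_attr(uris), '"/>')
    if (identical(type, "unqualified")) {
      lines <- c(lines, paste0(pad, "      <rdf:Bag>"), lis, paste0(pad, "      </rdf:Bag>"))
    } else {
      lines <- c(lines,
                 paste0(pad, "      <bqbiol:", type, ">"),
                 paste0(pad, "       <rdf:Bag>"), lis, paste0(pad, "       </rdf:Bag>"),
                 paste0(pad, "      </bqbiol:", type, ">"))
    }
  }
  c(lines, paste0(pad, "    </rdf:Description>"),
    paste0(pad, "  </rdf:RDF>"),
    paste0(pad, "</annotation>"))
}

#' Write a parsed model back out as SBML Level 2
#'
#' Regenerates an SBML Level 2 Version 4 document from the meta-format
#' content.  Kinetic laws are re-emitted from the verbatim MathML
#' captured at parse time, so parse -> write -> parse round-trips the
#' meta-format field-for-field.  Initial values are written as
#' `initialConcentration`.
#'
#' @param model A `pb_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "pb_model"))
  mid <- gsub("[^A-Za-z0-9_]", "_", tools::file_path_sans_ext(model$pathway$fullname))
  if (!grepl("^[A-Za-z_]", mid)) mid <- paste0("m_", mid)
  L <- c('<?xml version="1.0" encoding="UTF-8"?>',
         '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
         sprintf('  <model id="%s">', mid))
  L <- write_rdf_block(L, 4L, mid, model$pathway$annotations)
  L <- c(L, '    <listOfCompartments>',
         '      <compartment id="default" size="1"/>',
         '    </listOfCompartments>')
  if (length(model$species)) {
    L <- c(L, "    <listOfSpecies>")
    for (sp in model$species) {
      iv <- if (is.na(sp$initial_value)) "" else sprintf(' initialConcentration="%s"', pb_num(sp$initial_value))
      open <- sprintf('      <species id="%s" name="%s" compartment="default"%s',
                      xml_escape_attr(sp$internal_id), xml_escape_attr(sp$name), iv)
      if (length(sp$annotations)) {
        L <- c(L, paste0(open, ">"))
        L <- write_rdf_block(L, 8L, sp$internal_id, sp$annotations)
        L <- c(L, "      </species>")
      } else L <- c(L, paste0(open, "/>"))
    }
    L <- c(L, "    </listOfSpecies>")
  }
  if (length(model$global_parameters)) {
    L <- c(L, "    <listOfParameters>")
    for (pid in names(model$global_parameters))
      L <- c(L, sprintf('      <parameter id="%s" value="%s"/>', pid, pb_num(model$global_parameters[[pid]])))
    L <- c(L, "    </listOfParameters>")
  }
  if (length(model$reactions)) {
    L <- c(L, "    <listOfReactions>")
    for (rx in model$reactions) {
      L <- c(L, sprintf('      <reaction id="%s" reversible="%s">',
                        xml_escape_attr(rx$internal_id), if (rx$reversible) "true" else "false"))
      L <- write_rdf_block(L, 8L, rx$internal_id, rx$annotations)
      refs <- function(ids, list_name, ref_name) {
        if (!length(ids)) return(character(0))
        c(sprintf("        <%s>", list_name),
          sprintf('          <%s species="%s"/>', ref_name, ids),
          sprintf("        </%s>", list_name))
      }
      L <- c(L, refs(rx$reactants, "listOfReactants", "speciesReference"),
             refs(rx$products, "listOfProducts", "speciesReference"),
             refs(rx$catalysts, "listOfModifiers", "modifierSpeciesReference"))
      if (!is.na(rx$mathml) || length(rx$parameters)) {
        L <- c(L, "        <kineticLaw>")
        if (!is.na(rx$mathml)) L <- c(L, paste0("          ", rx$mathml))
        if (length(rx$parameters)) {
          L <- c(L, "          <listOfParameters>")
          for (pid in names(rx$parameters))
            L <- c(L, sprintf('            <parameter id="%s" value="%s"/>', pid, pb_num(rx$parameters[[pid]])))
          L <- c(L, "          </listOfParameters>")
        }
        L <- c(L, "        </kineticLaw>")
      }
      L <- c(L, "      </reaction>")
    }
    L <- c(L, "    </listOfReactions>")
  }
  L <- c(L, "  </model>", "</sbml>")
  writeLines(L, path)
  invisible(path)
}
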