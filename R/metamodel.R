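# Aggregate assembly.  Assembly is purely additive: no merging or
# rewriting of species/reactions happens here — cross-model logic lives
# in the alignment layer, which is a pure function of the aggregate and
# therefore fully reversible.  Element identity is the pair
# (pathway fullname, model-local id); every element keeps its pathway
# link through every later stage.

PB_SCHEMA_VERSION <- "1"

#' Assemble parsed models into one aggregate
#'
#' Takes the union of all parsed content.  Every species and reaction is
#' keyed by `"<fullname>::<internal id>"` and carries its pathway name,
#' so any later conflict can be traced back to its source file.
#'
#' @param models List of `pb_model` objects (from [ingest_models()] or
#'   [parse_sbml()]).
#' @return A `pb_aggregate` with `pathways`, `species` and `reactions`.
#' @export
assemble <- function(models) {
  if (inherits(models, "pb_model")) models <- list(models)
  fullnames <- vapply(models, function(m) m$pathway$fullname, "")
  dup <- fullnames[duplicated(fullnames)]
  if (length(dup))
    pb_stop("pb_assembly_error",
            "duplicate pathway fullname(s): %s — rename the input files to disambiguate",
            paste(unique(dup), collapse = ", "))

  pathways <- list(); species <- list(); reactions <- list()
  for (m in models) {
    fn <- m$pathway$fullname
    pathways[[fn]] <- m$pathway
    pathways[[fn]]$global_parameters <- m$global_parameters
    for (sp in m$species) {
      sp$pathway <- fn
      species[[element_key(fn, sp$internal_id)]] <- sp
    }
    for (rx in m$reactions) {
      rx$pathway <- fn
      reactions[[element_key(fn, rx$internal_id)]] <- rx
    }
  }
  structure(list(pathways = pathways, species = species, reactions = reactions),
            class = "pb_aggregate")
}

#' @export
print.pb_aggregate <- function(x, ...) {
  cat(sprintf("<aggregate: %d pathways, %d species, %d reactions>\n",
              length(x$pathways), length(x$species), length(x$reactions)))
  invisible(x)
}

#' Trace an element back to its source pathway
#'
#' @param aggregate A `pb_aggregate`.
#' @param key Element key `"<fullname>::<internal id>"` of a species or
#'   reaction in the aggregate (for an annotation, pass its host
#'   element's key).
#' @return The owning pathway record (with `fullname`).
#' @export
trace_to_source <- function(aggregate, key) {
  stopifnot(inherits(aggregate, "pb_aggregate"))
  el <- aggregate$species[[key]]
  if (is.null(el)) el <- aggregate$reactions[[key]]
  if (is.null(el))
    pb_stop("pb_lookup_error", "element '%s' is not part of this aggregate", key)
  aggregate$pathways[[el$pathway]]
}

# ---- JSON interchange ------------------------------------------------------

#' Serialize an aggregate to a JSON interchange document
#'
#' Intermediate artifact used by the command-line pipeline; the schema
#' version is recorded in the document.
#'
#' @param aggregate A `pb_aggregate`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
aggregate_to_json <- function(aggregate, path) {
  stopifnot(inherits(aggregate, "pb_aggregate"))
  # named numeric vectors go out as JSON objects (a length-1 named vector
  # would otherwise unbox to a bare number and lose its name)
  pathways <- lapply(aggregate$pathways, function(pw) {
    pw$global_parameters <- as.list(pw$global_parameters); pw
  })
  reactions <- lapply(aggregate$reactions, function(rx) {
    rx$parameters <- as.list(rx$parameters); rx
  })
  doc <- list(schema = "pb-aggregate", schema_version = PB_SCHEMA_VERSION,
              pathways = pathways,
              species = aggregate$species,
              reactions = reactions)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read an aggregate back from its JSON interchange document
#'
#' @param path Path written by [aggregate_to_json()].
#' @return A `pb_aggregate`.
#' @export
aggregate_from_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$schema, "pb-aggregate"))
    pb_stop("pb_parse_error", "'%s' is not an aggregate interchange document", path)
  num_vec <- function(l) if (length(l) == 0L) numeric(0) else vapply(l, as.numeric, 0)
  fix_ann <- function(a) {
    a$namespace <- if (is.null(a$namespace)) NA_character_ else a$namespace
    a$identifier <- if (is.null(a$identifier)) NA_character_ else a$identifier
    a
  }
  fix_sp <- function(sp) {
    sp$initial_value <- if (is.null(sp$initial_value)) NA_real_ else as.numeric(sp$initial_value)
    sp$annotations <- lapply(sp$annotations, fix_ann)
    sp
  }
  fix_rx <- function(rx) {
    rx$reactants <- as.character(unlist(rx$reactants))
    rx$products <- as.character(unlist(rx$products))
    rx$catalysts <- as.character(unlist(rx$catalysts))
    rx$reversible <- isTRUE(rx$reversible)
    rx$kinetics <- if (is.null(rx$kinetics)) NA_character_ else rx$kinetics
    rx$mathml <- if (is.null(rx$mathml)) NA_character_ else rx$mathml
    rx$parameters <- num_vec(rx$parameters)
    rx$annotations <- lapply(rx$annotations, fix_ann)
    rx
  }
  fix_pw <- function(pw) {
    pw$annotations <- lapply(pw$annotations, fix_ann)
    pw$global_parameters <- num_vec(pw$global_parameters)
    pw
  }
  structure(list(pathways = lapply(doc$pathways, fix_pw),
                 species = lapply(doc$species, fix_sp),
                 reactions = lapply(doc$reactions, fix_rx)),
            class = "pb_aggregate")
}
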