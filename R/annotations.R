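#' Normalize a MIRIAM-style resource URI
#'
#' Model vintages write the same database cross-reference in several URI
#' syntaxes.  This maps the common variants onto one canonical
#' (namespace, identifier) pair so that species annotated with different
#' renderings of the same resource can still be aligned:
#'
#' * `urn:miriam:<namespace>:<identifier>` (identifier percent-decoded),
#' * `http://identifiers.org/<namespace>/<identifier>` (also the
#'   `<namespace>:<identifier>` compact form, and https),
#' * `http://www.<namespace>.org/.../<identifier>` legacy host-style URIs
#'   (namespace taken from the host, identifier from the last path segment).
#'
#' The namespace is lower-cased; identifier case is preserved.  Any other
#' syntax returns the string `"unmappable"`: the annotation is kept
#' verbatim on its element but takes no part in species alignment.
#'
#' @param uri Non-empty character scalar.
#' @return A `pb_resource` (list with `namespace` and `identifier`), or
#'   the character scalar `"unmappable"`.
#' @examples
#' normalize_annotation("urn:miriam:uniprot:P00533")
#' normalize_annotation("http://identifiers.org/uniprot/P00533")
#' normalize_annotation("some-free-text-note")
#' @export
normalize_annotation <- function(uri) {
  if (!is.character(uri) || length(uri) != 1L || is.na(uri) || !nzchar(uri))
    pb_stop("pb_argument_error", "normalize_annotation: uri must be a non-empty string")

  res <- NULL
  if (grepl("^urn:miriam:", uri, ignore.case = TRUE)) {
    rest <- sub("^urn:miriam:", "", uri, ignore.case = TRUE)
    i <- regexpr(":", rest, fixed = TRUE)
    if (i > 1L && i < nchar(rest)) {
      res <- list(namespace = substr(rest, 1L, i - 1L),
                  identifier = utils::URLdecode(substr(rest, i + 1L, nchar(rest))))
    }
  } else if (grepl("^https?://(www\\.)?identifiers\\.org/", uri, ignore.case = TRUE)) {
    rest <- sub("^https?://(www\\.)?identifiers\\.org/", "", uri, ignore.case = TRUE)
    i <- regexpr("/", rest, fixed = TRUE)
    if (i < 0L) i <- regexpr(":", rest, fixed = TRUE)
    if (i > 1L && i < nchar(rest)) {
      res <- list(namespace = substr(rest, 1L, i - 1L),
                  identifier = utils::URLdecode(substr(rest, i + 1L, nchar(rest))))
    }
  } else if (grepl("^https?://www\\.[^./]+\\.org/.+", uri, ignore.case = TRUE)) {
    ns <- sub("^https?://www\\.([^./]+)\\.org/.*$", "\\1", uri, ignore.case = TRUE)
    path <- sub("^https?://[^/]+/", "", uri)
    segs <- strsplit(path, "[/#]")[[1]]
    segs <- segs[nzchar(segs)]
    if (length(segs) >= 1L && nzchar(ns))
      res <- list(namespace = ns, identifier = utils::URLdecode(segs[length(segs)]))
  }

  if (is.null(res) || !nzchar(res$namespace) || !nzchar(res$identifier))
    return("unmappable")
  res$namespace <- tolower(res$namespace)
  class(res) <- "pb_resource"
  res
}

#' Canonical key of a normalized resource
#'
#' @param res A `pb_resource` as returned by [normalize_annotation()].
#' @return `"<namespace>:<identifier>"`.
#' @export
resource_key <- function(res) {
  stopifnot(inherits(res, "pb_resource"))
  paste0(res$namespace, ":", res$identifier)
}

#' Canonical URN rendering of a normalized resource
#'
#' Renders the pair back in `urn:miriam` syntax (colons in the identifier
#' percent-encoded).  [normalize_annotation()] is idempotent on this
#' rendering.
#'
#' @inheritParams resource_key
#' @return A character scalar URN.
#' @export
resource_urn <- function(res) {
  stopifnot(inherits(res, "pb_resource"))
  paste0("urn:miriam:", res$namespace, ":", gsub(":", "%3A", res$identifier, fixed = TRUE))
}

#' @export
print.pb_resource <- function(x, ...) {
  cat("<resource ", resource_key(x), ">\n", sep = "")
  invisible(x)
}

# Constructor for one annotation record (Table-style meta-format slot:
# type / uri / information, plus the normalized pair when mappable).
make_annotation <- function(type, uri, information = "") {
  norm <- normalize_annotation(uri)
  list(
    type = type,
    uri = uri,
    information = information,
    namespace = if (inherits(norm, "pb_resource")) norm$namespace else NA_character_,
    identifier = if (inherits(norm, "pb_resource")) norm$identifier else NA_character_
  )
}

annotation_is_mapped <- function(ann) !is.na(ann$namespace)

annotation_res_key <- function(ann) {
  if (!annotation_is_mapped(ann)) return(NA_character_)
  paste0(ann$namespace, ":", ann$identifier)
}
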