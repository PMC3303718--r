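# Internal helpers shared across the pipeline.

# Locale-independent sort: all deterministic orderings in the package go
# through this so artifacts are byte-identical across platforms.
pb_sort <- function(x) {
  if (length(x) == 0L) return(character(0))
  sort(x, method = "radix")
}

pb_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "pb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Run `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Element key used everywhere: one species/reaction is identified by the
# pair (pathway fullname, model-local id), never by the local id alone.
element_key <- function(fullname, internal_id) paste0(fullname, "::", internal_id)

split_key <- function(key) {
  i <- regexpr("::", key, fixed = TRUE)
  list(fullname = substr(key, 1L, i - 1L),
       internal_id = substr(key, i + 2L, nchar(key)))
}

# Deterministic numeric rendering (used in kinetics substitution and in
# generated SBML attributes).
pb_num <- function(x) sprintf("%.15g", x)

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xml_escape_attr <- function(x) {
  x <- xml_escape_text(x)
  gsub('"', "&quot;", x, fixed = TRUE)
}
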