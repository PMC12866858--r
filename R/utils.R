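# Internal helpers shared across modules.

stopf <- function(fmt, ..., class = "msifuse_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Promote a matrix to an H x W x 1 array; pass 3-d arrays through.
as_cube <- function(x) {
  if (is.matrix(x)) {
    array(x, dim = c(dim(x), 1L))
  } else if (is.array(x) && length(dim(x)) == 3L) {
    x
  } else {
    stopf("expected a matrix or H x W x C array")
  }
}

# Run an expression with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Canonicalize a (possibly nested) named list: sort names recursively so the
# hash is invariant to key order.
canonicalize <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, canonicalize)
  } else if (is.list(x)) {
    lapply(x, canonicalize)
  } else {
    x
  }
}

#' Stable short hash of a configuration object
#'
#' Serializes the canonicalized (recursively key-sorted) object to JSON and
#' hashes the bytes with FNV-1a.  Used to stamp every run artifact so that
#' mixed-provenance inputs can be refused.
#'
#' @param x a (nested) list or other JSON-serializable object.
#' @return an 8-character lowercase hex string.
#' @export
#' @examples
#' config_hash(list(a = 1, b = "x")) == config_hash(list(b = "x", a = 1))
config_hash <- function(x) {
  js <- jsonlite::toJSON(canonicalize(x), auto_unbox = TRUE, digits = 15,
                         null = "null")
  cpp_fnv1a32(charToRaw(as.character(js)))
}
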