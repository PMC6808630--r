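# Shared internal helpers.

# Locale-independent (byte-wise) sort; output order must not depend on the
# host collation, or serialization stops being reproducible across machines.
sort_c <- function(x) sort(x, method = "radix")

squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Minimal XML text/attribute escaping for emitted (templated) XML.
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

is_absolute_iri <- function(x) {
  is.character(x) && length(x) == 1 && !is.na(x) &&
    (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", x) || grepl("^urn:", x))
}

# A property value counts as "missing" when absent, NULL, NA, an empty
# string, or an empty list -- markup consumers treat all of these as absent.
is_empty_value <- function(v) {
  if (is.null(v)) return(TRUE)
  if (is.list(v)) return(length(v) == 0)
  if (length(v) == 0) return(TRUE)
  if (length(v) == 1 && is.na(v)) return(TRUE)
  if (is.character(v) && length(v) == 1 && !nzchar(trimws(v))) return(TRUE)
  FALSE
}

# Run code under a temporary RNG state so generators never disturb (or
# depend on) the caller's global random state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
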