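#' @keywords internal
"_PACKAGE"

# -- small shared helpers ----------------------------------------------------

#' Slugify a label into a CURIE-local name
#'
#' Lowercases, strips punctuation and joins words with hyphens, then prefixes
#' the `cco:` namespace. Deterministic, so labels round-trip to ids.
#'
#' @param label character vector of human-readable labels.
#' @return character vector of CURIE-like ids (`cco:` prefix).
#' @examples
#' cco_id("Mood Process")
#' @export
cco_id <- function(label) {
  x <- tolower(trimws(label))
  x <- gsub("[^a-z0-9]+", "-", x)
  x <- gsub("^-|-$", "", x)
  paste0("cco:", x)
}

# label normalization used for uniqueness checks and loose name lookup:
# case-insensitive, whitespace/punctuation-insensitive
norm_name <- function(x) gsub("[^a-z0-9]+", "", tolower(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a 32-bit hash over a string; used to stamp output artifacts with a
# provenance hash of the configuration they were produced under.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); h is kept as a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by 16777619, split to stay within exact doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + hi * (16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

stop_psychonto <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "psychonto_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
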