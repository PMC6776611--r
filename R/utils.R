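# Internal helpers shared across modules.

# Structured conditions: every user-facing failure carries a subclass so
# callers (and the CLI) can distinguish usage errors from data errors.
odmlStop <- function(subclass, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(subclass, "odmlError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Scalar-or-absent slots are encoded as length-0 vectors when absent.
chr0 <- character(0)
num0 <- numeric(0)

asScalarChr <- function(x) {
  if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x))) return(character(0))
  as.character(x)[1]
}

asScalarNum <- function(x) {
  if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x))) return(numeric(0))
  as.numeric(x)[1]
}

# length-0 -> NA_character_ (for tabular cells), else the value.
orNA <- function(x) if (length(x) == 0) NA_character_ else as.character(x)[1]

# NA/"" cell -> length-0, else character scalar.
cellToSlot <- function(x) {
  if (length(x) == 0 || is.na(x) || identical(x, "")) character(0) else as.character(x)
}

isUuid <- function(x) {
  length(x) == 1 && grepl(
    "^[0-9a-fA-F]{8}-[0-9a-fA-F]{4}-[0-9a-fA-F]{4}-[0-9a-fA-F]{4}-[0-9a-fA-F]{12}$",
    x
  )
}

# Version-4 UUID drawn from R's RNG stream: inside withSeed() this makes
# entity ids (and hence whole generated documents) reproducible.
mintUuid <- function() {
  b <- sample.int(256L, 16L, replace = TRUE) - 1L
  b[7] <- bitwOr(bitwAnd(b[7], 0x0FL), 0x40L)   # version 4
  b[9] <- bitwOr(bitwAnd(b[9], 0x3FL), 0x80L)   # RFC 4122 variant
  h <- sprintf("%02x", b)
  paste(
    paste(h[1:4], collapse = ""), paste(h[5:6], collapse = ""),
    paste(h[7:8], collapse = ""), paste(h[9:10], collapse = ""),
    paste(h[11:16], collapse = ""),
    sep = "-"
  )
}

# Deterministic RNG scope: runs `expr` under the given seed and restores the
# caller's RNG state, so generators are pure functions of their parameters.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}
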