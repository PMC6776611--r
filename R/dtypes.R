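# Data-type registry: canonical types, synonyms, defaults, coercions.

.CANONICAL_DTYPES <- c(
  "int", "float", "string", "text", "boolean",
  "date", "time", "datetime", "url", "person"
)

.DEFAULT_SYNONYMS <- c(
  integer = "int",
  bool = "boolean",
  str = "string",
  double = "float",
  real = "float",
  number = "float"
)

# Sortable, unambiguous sentinels; user-overridable via dtypeRegistry().
.DEFAULT_DEFAULTS <- list(
  int = 0L,
  float = 0.0,
  string = "",
  text = "",
  url = "",
  person = "",
  boolean = FALSE,
  date = as.Date("1900-01-01"),
  time = "00:00:00",
  datetime = "1900-01-01T00:00:00"
)

#' Create a data-type registry
#'
#' The registry fixes, for each canonical odML data type, the default value
#' substituted for empty cells, the accepted synonym tokens, and the
#' string/typed coercion pair used by every serializer in the package.
#' Defaults and synonyms can be overridden or extended.
#'
#' @param defaults Named list of per-type default values overriding the
#'   built-in table (\code{int} 0, \code{float} 0.0, text-like types
#'   \code{""}, \code{boolean} \code{FALSE}, \code{date} 1900-01-01,
#'   \code{time} \code{"00:00:00"}, \code{datetime}
#'   \code{"1900-01-01T00:00:00"}).
#' @param synonyms Named character vector of extra synonym tokens mapping to
#'   canonical types.
#' @return A \linkS4class{DtypeRegistry}.
#' @examples
#' reg <- dtypeRegistry()
#' defaultValue("float", reg)
#' @export
dtypeRegistry <- function(defaults = list(), synonyms = character(0)) {
  defs <- .DEFAULT_DEFAULTS
  for (nm in names(defaults)) {
    canon <- .resolveToken(nm, .DEFAULT_SYNONYMS)
    defs[[canon]] <- defaults[[nm]]
  }
  syn <- .DEFAULT_SYNONYMS
  if (length(synonyms)) {
    bad <- setdiff(unname(synonyms), .CANONICAL_DTYPES)
    if (length(bad)) {
      odmlStop("odmlDtypeError", "synonym target(s) not canonical: %s",
               paste(bad, collapse = ", "))
    }
    syn[names(synonyms)] <- synonyms
  }
  new("DtypeRegistry", synonyms = syn, defaults = defs)
}

.resolveToken <- function(token, synonyms) {
  if (length(token) != 1 || is.na(token)) {
    odmlStop("odmlDtypeError", "data type token must be a single string")
  }
  if (token %in% .CANONICAL_DTYPES) return(token)
  if (token %in% names(synonyms)) return(unname(synonyms[[token]]))
  odmlStop(
    "odmlDtypeError",
    "unknown data type '%s'; known tokens: %s",
    token,
    paste(c(.CANONICAL_DTYPES, names(synonyms)), collapse = ", ")
  )
}

#' Resolve a data-type token to its canonical form
#'
#' Synonym resolution is idempotent: resolving a canonical token returns it
#' unchanged.
#'
#' @param token A canonical type or registered synonym (e.g. \code{"integer"}).
#' @param registry A \linkS4class{DtypeRegistry}.
#' @return The canonical type token.
#' @export
resolveDtype <- function(token, registry = dtypeRegistry()) {
  .resolveToken(token, registry@synonyms)
}

#' Default value for a data type
#'
#' @param dtype Canonical type or synonym.
#' @param registry A \linkS4class{DtypeRegistry}.
#' @return The registry's default value for the type; deterministic for a
#'   given registry.
#' @export
defaultValue <- function(dtype, registry = dtypeRegistry()) {
  registry@defaults[[resolveDtype(dtype, registry)]]
}

.parseFuns <- list(
  int = function(s) {
    if (!grepl("^[+-]?[0-9]+$", s)) return(NULL)
    v <- suppressWarnings(as.integer(s))
    if (is.na(v)) NULL else v
  },
  float = function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) NULL else v
  },
  string = function(s) s,
  text = function(s) s,
  url = function(s) s,
  person = function(s) s,
  boolean = function(s) {
    if (s %in% c("True", "true", "1")) TRUE
    else if (s %in% c("False", "false", "0")) FALSE
    else NULL
  },
  date = function(s) {
    if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", s)) return(NULL)
    v <- as.Date(s, format = "%Y-%m-%d")
    if (is.na(v)) NULL else v
  },
  time = function(s) {
    if (!grepl("^([01][0-9]|2[0-3]):[0-5][0-9]:[0-5][0-9]$", s)) return(NULL)
    s
  },
  datetime = function(s) {
    if (!grepl(
      "^[0-9]{4}-[0-9]{2}-[0-9]{2}T([01][0-9]|2[0-3]):[0-5][0-9]:[0-5][0-9]$", s
    )) {
      return(NULL)
    }
    d <- as.Date(substr(s, 1, 10), format = "%Y-%m-%d")
    if (is.na(d)) NULL else s
  }
)

.formatFloat <- function(v) {
  s <- as.character(v)
  # as.character() uses 15 significant digits, which does not always
  # round-trip; fall back to 17 digits when it does not.
  if (is.finite(v) && as.numeric(s) != v) s <- sprintf("%.17g", v)
  if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
  s
}

.formatFuns <- list(
  int = function(v) as.character(as.integer(v)),
  float = .formatFloat,
  string = function(v) as.character(v),
  text = function(v) as.character(v),
  url = function(v) as.character(v),
  person = function(v) as.character(v),
  boolean = function(v) if (isTRUE(v)) "True" else "False",
  date = function(v) format(v, "%Y-%m-%d"),
  time = function(v) as.character(v),
  datetime = function(v) as.character(v)
)

#' Coerce text to a typed value
#'
#' Parses a string into the typed value of the given data type. Empty text
#' yields the registry default for the type, marked with the attribute
#' \code{odml_default = TRUE} so callers can highlight default entries.
#'
#' @param raw A single character string.
#' @param dtype Canonical type or synonym.
#' @param registry A \linkS4class{DtypeRegistry}.
#' @return The typed value.
#' @examples
#' coerceValue("5.5", "float")
#' coerceValue("2000-01-01", "date")
#' @export
coerceValue <- function(raw, dtype, registry = dtypeRegistry()) {
  canon <- resolveDtype(dtype, registry)
  if (length(raw) != 1 || is.na(raw)) {
    odmlStop("odmlCoerceError", "value text must be a single string")
  }
  if (!nzchar(raw)) {
    v <- registry@defaults[[canon]]
    attr(v, "odml_default") <- TRUE
    return(v)
  }
  v <- .parseFuns[[canon]](raw)
  if (is.null(v)) {
    odmlStop("odmlCoerceError", "cannot coerce '%s' to type '%s'", raw, canon)
  }
  v
}

#' Format a typed value as dialect text
#'
#' Inverse of \code{\link{coerceValue}} for in-range values:
#' \code{coerceValue(formatValue(v, t), t)} equals \code{v}. Floats always
#' carry a decimal point (\code{5} renders as \code{"5.0"}), booleans render
#' as \code{"True"}/\code{"False"}, dates as ISO \code{YYYY-MM-DD}.
#'
#' @param value A typed value.
#' @param dtype Canonical type or synonym; when absent (length 0 or NULL)
#'   the value is rendered with \code{as.character}.
#' @param registry A \linkS4class{DtypeRegistry}.
#' @return A single character string.
#' @export
formatValue <- function(value, dtype = NULL, registry = dtypeRegistry()) {
  if (is.null(dtype) || length(dtype) == 0) return(as.character(value))
  canon <- resolveDtype(dtype, registry)
  .formatFuns[[canon]](value)
}

#' Check that a typed value conforms to a data type
#'
#' @param value A typed value.
#' @param dtype Canonical type or synonym.
#' @param registry A \linkS4class{DtypeRegistry}.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
conformsTo <- function(value, dtype, registry = dtypeRegistry()) {
  canon <- resolveDtype(dtype, registry)
  switch(canon,
    int = is.integer(value) && length(value) == 1 && !is.na(value),
    float = is.numeric(value) && length(value) == 1 && !is.na(value),
    boolean = is.logical(value) && length(value) == 1 && !is.na(value),
    date = inherits(value, "Date") && length(value) == 1 && !is.na(value),
    time = is.character(value) && length(value) == 1 &&
      !is.null(.parseFuns$time(value)),
    datetime = is.character(value) && length(value) == 1 &&
      !is.null(.parseFuns$datetime(value)),
    # string/text/url/person
    is.character(value) && length(value) == 1 && !is.na(value)
  )
}
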