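# Machine-readable schema emission.  The schema is generated from the type
# registry (a single source of truth, never hand-maintained) in a JSON
# Schema dialect, together with a small evaluator so that documents can be
# checked against the *emitted document* independently of the registry.

.schema_primitive <- function(kind) {
  switch(kind,
    curie = list(type = "string", pattern = .vrs_patterns$curie),
    string = list(type = "string"),
    sequence = list(type = "string", pattern = .vrs_patterns$sequence),
    cytoband = list(type = "string", pattern = .vrs_patterns$cytoband),
    comparator = list(type = "string", enum = list("<=", ">=")),
    integer = list(type = "integer"),
    boolean = list(type = "boolean"),
    stop("unknown primitive: ", kind))
}

.schema_field <- function(fld, positional = FALSE) {
  kind <- fld$kind
  if (length(kind) == 1L && kind %in% .vrs_primitives) {
    sch <- .schema_primitive(kind)
  } else {
    alts <- lapply(kind, function(k) {
      ref <- list(`$ref` = paste0("#/definitions/", k))
      if (positional && k == "Number") {
        # inter-residue coordinates are non-negative
        list(allOf = list(ref),
             properties = list(value = list(minimum = 0L)))
      } else {
        ref
      }
    })
    if (fld$or_curie) alts <- c(alts, list(.schema_primitive("curie")))
    sch <- if (length(alts) == 1L) alts[[1]] else list(oneOf = alts)
  }
  if (fld$list) sch <- list(type = "array", items = sch)
  sch
}

#' Emit the machine-readable schema of the information model
#'
#' Generates a JSON Schema-dialect document with one definition per
#' released VRS class: required fields, value kinds, regular-expression
#' patterns for CURIEs, sequences and cytobands, and the polymorphic
#' unions.  Emission is deterministic — two calls produce identical
#' documents — and validating a document against the emitted schema (see
#' [schema_validate()]) agrees with [vrs_validate()] on structural
#' violations.
#'
#' @return A nested list; serialize with [jsonlite::toJSON()] to obtain
#'   the JSON Schema text.
#' @export
emit_schema <- function() {
  defs <- lapply(.vrs_type_names(), function(tn) {
    info <- .vrs_registry[[tn]]
    props <- list(type = list(type = "string", const = tn))
    req <- list("type")
    for (f in names(info$fields)) {
      positional <- tn == "SequenceInterval"
      props[[f]] <- .schema_field(info$fields[[f]], positional)
      if (info$fields[[f]]$required) req <- c(req, list(f))
    }
    list(type = "object", properties = props, required = req,
         additionalProperties = FALSE)
  })
  names(defs) <- .vrs_type_names()
  list(
    `$schema` = "http://json-schema.org/draft-07/schema#",
    title = "Released variation-representation classes",
    oneOf = lapply(.vrs_type_names(),
                   function(tn) list(`$ref` = paste0("#/definitions/", tn))),
    definitions = defs)
}

#' Validate a document against an emitted schema
#'
#' A small evaluator for the schema subset used by [emit_schema()]:
#' `$ref`, `type`, `const`, `enum`, `pattern`, `minimum`, `required`,
#' `properties`, `additionalProperties: false`, `items`, `oneOf`,
#' `allOf`.  It interprets only the schema document, making it an
#' independent check on [vrs_validate()].
#'
#' @param document Parsed JSON-like map.
#' @param schema Output of [emit_schema()] (the default).
#' @return `TRUE` if the document satisfies the schema, else `FALSE`.
#' @export
schema_validate <- function(document, schema = emit_schema()) {
  .schema_eval(document, schema, schema)
}

.schema_eval <- function(x, sch, root) {
  if (!is.null(sch$`$ref`)) {
    path <- strsplit(sub("^#/", "", sch$`$ref`), "/", fixed = TRUE)[[1]]
    sch <- root[[path]]
  }
  if (!is.null(sch$oneOf)) {
    hits <- sum(vapply(sch$oneOf, function(s) .schema_eval(x, s, root),
                       logical(1)))
    if (hits != 1L) return(FALSE)
  }
  if (!is.null(sch$allOf)) {
    if (!all(vapply(sch$allOf, function(s) .schema_eval(x, s, root),
                    logical(1)))) {
      return(FALSE)
    }
  }
  if (!is.null(sch$type)) {
    ok <- switch(sch$type,
      object = is.list(x) && (length(x) == 0L || !is.null(names(x))),
      array = is.list(x) && is.null(names(x)),
      string = .is_scalar_chr(x),
      integer = length(x) == 1L && is.numeric(x) && !is.na(x) &&
        x == trunc(x),
      boolean = is.logical(x) && length(x) == 1L && !is.na(x),
      FALSE)
    if (!ok) return(FALSE)
  }
  if (!is.null(sch$const) && !identical(as.character(x), sch$const)) {
    return(FALSE)
  }
  if (!is.null(sch$enum) && !any(vapply(sch$enum, identical, logical(1), x))) {
    return(FALSE)
  }
  if (!is.null(sch$pattern) &&
      (!.is_scalar_chr(x) || !grepl(sch$pattern, x, perl = TRUE))) {
    return(FALSE)
  }
  if (!is.null(sch$minimum) && is.numeric(x) && x < sch$minimum) {
    return(FALSE)
  }
  if (!is.null(sch$required)) {
    if (!all(unlist(sch$required) %in% names(x))) return(FALSE)
  }
  if (!is.null(sch$properties)) {
    for (f in intersect(names(x), names(sch$properties))) {
      if (!.schema_eval(x[[f]], sch$properties[[f]], root)) return(FALSE)
    }
    if (isFALSE(sch$additionalProperties) &&
        length(setdiff(names(x), names(sch$properties))) > 0L) {
      return(FALSE)
    }
  }
  if (!is.null(sch$items) && is.list(x) && is.null(names(x))) {
    for (el in x) {
      if (!.schema_eval(el, sch$items, root)) return(FALSE)
    }
  }
  TRUE
}
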