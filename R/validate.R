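# Structural validation of VRS documents against the type registry, plus
# parsing of plain JSON-derived lists into typed objects.

.report <- function(path = character(), code = character(),
                    message = character()) {
  df <- data.frame(path = path, code = code, message = message,
                   stringsAsFactors = FALSE)
  class(df) <- c("vrs_validation_report", "data.frame")
  df
}

.is_scalar_chr <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x)
}

.pattern_ok <- function(value, kind) {
  pat <- .vrs_patterns[[kind]]
  is.null(pat) || grepl(pat, value, perl = TRUE)
}

#' Validate a VRS document
#'
#' Checks a parsed JSON-like map (or a constructed object) against the
#' released VRS classes: the `type` discriminator must name a known class,
#' required fields must be present, unexpected fields are rejected, string
#' primitives must match their patterns (CURIEs, IUPAC sequences, cytoband
#' designators), and class invariants must hold (e.g. interval
#' `start <= end`, non-empty haplotypes, member uniqueness).  An empty
#' report means the document constructs a valid typed object.
#'
#' @param document A named list with a `type` field, typically from
#'   [jsonlite::fromJSON()] with `simplifyVector = FALSE`, or a
#'   `vrs_object`.
#' @return A data frame of violations with columns `path`, `code`
#'   (`malformed`, `unknown_type`, `missing_field`, `extra_field`,
#'   `bad_value`, `invariant`) and `message`; zero rows when valid.
#' @examples
#' doc <- list(type = "SequenceInterval",
#'             start = list(type = "Number", value = 5),
#'             end = list(type = "Number", value = 2))
#' vrs_validate(doc)  # one "start must be <= end" violation
#' @export
vrs_validate <- function(document) {
  viol <- list()
  add <- function(path, code, message) {
    viol[[length(viol) + 1L]] <<- list(path = path, code = code,
                                       message = message)
  }

  walk <- function(doc, path) {
    if (!is.list(doc) || is.null(doc[["type"]]) ||
        !.is_scalar_chr(doc[["type"]])) {
      add(path, "malformed", "document lacks a 'type' discriminator")
      return(invisible())
    }
    type <- doc[["type"]]
    info <- .vrs_registry[[type]]
    if (is.null(info)) {
      add(path, "unknown_type", paste0("unknown type '", type, "'"))
      return(invisible())
    }
    n_before <- length(viol)
    fields <- info$fields
    nms <- setdiff(names(doc), "type")
    for (f in names(fields)) {
      fld <- fields[[f]]
      if (fld$required && !(f %in% nms)) {
        add(path, "missing_field", paste0("missing required field '", f, "'"))
      }
    }
    for (f in setdiff(nms, names(fields))) {
      add(path, "extra_field", paste0("unexpected field '", f, "'"))
    }
    for (f in intersect(nms, names(fields))) {
      check_value(doc[[f]], fields[[f]], paste0(path, ".", f))
    }
    if (length(viol) == n_before && !is.null(info$check)) {
      for (msg in info$check(doc)) add(path, "invariant", msg)
    }
    if (length(viol) == n_before && type %in% c("Haplotype", "VariationSet")) {
      keys <- vapply(doc$members, .member_key, character(1))
      if (anyDuplicated(keys)) {
        add(path, "invariant", "duplicate members after identification")
      }
    }
    invisible()
  }

  check_value <- function(v, fld, path) {
    if (fld$list) {
      if (!is.list(v) || !is.null(names(v))) {
        add(path, "bad_value", "expected an array of members")
        return(invisible())
      }
      elem <- fld
      elem$list <- FALSE
      for (i in seq_along(v)) {
        check_value(v[[i]], elem, paste0(path, "[", i, "]"))
      }
      return(invisible())
    }
    if (fld$or_curie && .is_scalar_chr(v)) {
      if (!.pattern_ok(v, "curie")) {
        add(path, "bad_value", "not a valid CURIE reference")
      }
      return(invisible())
    }
    kind <- fld$kind
    if (length(kind) == 1L && kind %in% .vrs_primitives) {
      ok <- switch(kind,
        integer = length(v) == 1L && is.numeric(v) && !is.na(v) &&
          v == trunc(v),
        boolean = is.logical(v) && length(v) == 1L && !is.na(v),
        .is_scalar_chr(v) && .pattern_ok(v, kind))
      if (!ok) add(path, "bad_value", paste0("expected ", kind, " value"))
      return(invisible())
    }
    # polymorphic union of class names
    if (!is.list(v) || !.is_scalar_chr(v[["type"]])) {
      add(path, "bad_value",
          paste0("expected one of: ", paste(kind, collapse = ", ")))
      return(invisible())
    }
    if (!(v[["type"]] %in% kind)) {
      add(path, "bad_value",
          paste0("type '", v[["type"]], "' not allowed here (expected ",
                 paste(kind, collapse = "|"), ")"))
      return(invisible())
    }
    walk(v, path)
    invisible()
  }

  walk(document, "$")
  if (length(viol) == 0L) return(.report())
  .report(path = vapply(viol, `[[`, "", "path"),
          code = vapply(viol, `[[`, "", "code"),
          message = vapply(viol, `[[`, "", "message"))
}

# Identity key for set/haplotype member de-duplication: the computed digest
# when obtainable, otherwise the canonical display form.  A member given
# inline and the same member given as its ga4gh CURIE collide, as intended.
.member_key <- function(m) {
  if (.is_scalar_chr(m)) {
    if (grepl("^ga4gh:[A-Z]+\\.", m)) return(sub("^ga4gh:[A-Z]+\\.", "", m))
    return(m)
  }
  dg <- tryCatch(ga4gh_digest(m), error = function(e) NULL)
  if (!is.null(dg)) return(dg)
  paste(deparse(.canonical_display(m)), collapse = "")
}

#' Parse and render VRS documents as JSON
#'
#' `vrs_parse()` turns a parsed JSON map into a validated, typed
#' `vrs_object` (integer fields coerced, classes applied recursively);
#' `vrs_from_json()` does the same from a JSON string, and `vrs_to_json()`
#' is the display serialization — it keeps `_id` and is *not* the digest
#' serialization (see [digest_serialize()]).  Any valid object survives a
#' `vrs_to_json()` / `vrs_from_json()` round trip unchanged.
#'
#' @param document Named list with a `type` discriminator.
#' @param txt JSON text for a single object.
#' @param x A `vrs_object`.
#' @param pretty Pretty-print the JSON?
#' @return `vrs_parse()` / `vrs_from_json()` return a `vrs_object` (or
#'   raise an error carrying the validation report in
#'   `attr(, "report")`); `vrs_to_json()` returns a JSON string.
#' @export
vrs_parse <- function(document) {
  rep <- vrs_validate(document)
  if (nrow(rep) > 0L) {
    err <- simpleError(paste0("invalid VRS document: ",
                              paste(rep$message, collapse = "; ")))
    attr(err, "report") <- rep
    stop(err)
  }
  .typify(document)
}

.typify <- function(doc) {
  if (!is.list(doc)) return(doc)
  type <- doc[["type"]]
  info <- if (.is_scalar_chr(type)) .vrs_registry[[type]] else NULL
  out <- lapply(doc, .typify)
  if (!is.null(info)) {
    for (f in names(info$fields)) {
      if (identical(info$fields[[f]]$kind, "integer") && !is.null(out[[f]])) {
        out[[f]] <- as.integer(out[[f]])
      }
      if (identical(info$fields[[f]]$kind, "boolean") && !is.null(out[[f]])) {
        out[[f]] <- as.logical(out[[f]])
      }
    }
    class(out) <- "vrs_object"
  }
  out
}

#' @rdname vrs_parse
#' @export
vrs_from_json <- function(txt) {
  vrs_parse(jsonlite::fromJSON(txt, simplifyVector = FALSE))
}

#' @rdname vrs_parse
#' @export
vrs_to_json <- function(x, pretty = FALSE) {
  as.character(jsonlite::toJSON(.untypify(x), auto_unbox = TRUE,
                                pretty = pretty, digits = NA))
}

.untypify <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, .untypify)
  } else {
    x
  }
}
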