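# Digest serialization: the deterministic canonical byte rendering of an
# identifiable object that feeds the truncated-digest identifier.  This is
# deliberately NOT the display JSON produced by vrs_to_json(); the two are
# not interchangeable and give different digests.

#' Replace nested identifiable objects with their digests
#'
#' Produces the message content for digest serialization: nested
#' identifiable objects (locations inside alleles, members of haplotypes
#' and sets) are replaced by their bare 32-character digests; arrays of
#' digests/ids are sorted by Unicode code point; underscore-prefixed
#' fields (`_id`) and null fields are dropped; `ga4gh` CURIEs referencing
#' sequences or objects are reduced to their digest segment.  Object
#' references (including `sequence_id`) must already be in the `ga4gh`
#' namespace — resolve other accessions through a sequence store first
#' (see [ga4gh_identify()]).
#'
#' @param obj An identifiable `vrs_object`.
#' @return A plain named list ready for canonical JSON encoding.
#' @export
replace_nested_identifiable <- function(obj) {
  if (!is.list(obj) || !.is_scalar_chr(obj[["type"]])) {
    stop("not a typed VRS object", call. = FALSE)
  }
  if (!is_identifiable(obj$type)) {
    stop(obj$type, " is not identifiable", call. = FALSE)
  }
  .digest_doc(obj)
}

.digest_doc <- function(obj) {
  info <- .vrs_type_info(obj$type)
  out <- list(type = obj$type)
  for (f in names(info$fields)) {
    if (startsWith(f, "_")) next   # underscore filter removes _id
    v <- obj[[f]]
    if (is.null(v)) next           # null filter
    fld <- info$fields[[f]]
    if (fld$list) {
      vals <- vapply(v, function(el) {
        r <- .digest_field(el, fld, f)
        if (!.is_scalar_chr(r)) {
          stop("array members must reduce to digests", call. = FALSE)
        }
        r
      }, character(1))
      out[[f]] <- as.list(sort(vals, method = "radix"))
    } else {
      out[[f]] <- .digest_field(v, fld, f)
    }
  }
  out
}

.digest_field <- function(v, fld, fname) {
  if (is.list(v) && .is_scalar_chr(v[["type"]])) {
    if (is_identifiable(v$type)) return(ga4gh_digest(v))
    return(.digest_doc(v))
  }
  is_ref <- fld$or_curie || fname == "sequence_id"
  if (.is_scalar_chr(v) && is_ref) {
    return(.curie_digest_ref(v, fname))
  }
  v
}

.curie_digest_ref <- function(curie, fname) {
  if (!startsWith(curie, "ga4gh:")) {
    stop("'", fname, "' must be a ga4gh-namespace identifier before ",
         "digesting (got '", curie, "'); resolve aliases through a ",
         "sequence store first", call. = FALSE)
  }
  sub("^ga4gh:([A-Z0-9]{2,3}\\.)?", "", curie)
}

#' Serialize an object to its canonical digest form
#'
#' A raw sequence string serializes to its UTF-8 bytes.  A composite
#' identifiable object serializes to canonical JSON bytes: UTF-8, no
#' insignificant whitespace, keys in Unicode code-point order, two-char
#' escape codes where RFC 8259 defines them, integers in minimal decimal
#' form.  The result is a pure function of the object's value — field
#' construction order never matters.
#'
#' @param obj An identifiable `vrs_object`, or a character scalar taken
#'   as a sequence.
#' @return A raw vector (the serialized blob).
#' @examples
#' rawToChar(digest_serialize(vrs_text("del Phe508")))
#' @export
digest_serialize <- function(obj) {
  if (.is_scalar_chr(obj)) {
    seq <- toupper(obj)
    .check_iupac(seq, "sequence")
    return(charToRaw(seq))
  }
  charToRaw(.canonical_json(replace_nested_identifiable(obj)))
}

.canonical_json <- function(x) {
  if (is.list(x)) {
    nms <- names(x)
    if (is.null(nms)) {
      return(paste0("[", paste(vapply(x, .canonical_json, character(1)),
                               collapse = ","), "]"))
    }
    ord <- sort(nms, method = "radix")
    paste0("{", paste0(vapply(ord, .json_string, character(1)), ":",
                       vapply(x[ord], .canonical_json, character(1)),
                       collapse = ","), "}")
  } else if (is.character(x)) {
    .json_string(x)
  } else if (is.logical(x)) {
    if (x) "true" else "false"
  } else if (is.numeric(x)) {
    format(trunc(x), scientific = FALSE)
  } else {
    stop("cannot serialize value of class ", class(x)[1], call. = FALSE)
  }
}

.json_string <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  two_char <- c("\b" = "\\b", "\f" = "\\f", "\n" = "\\n",
                "\r" = "\\r", "\t" = "\\t")
  for (ch in names(two_char)) {
    s <- gsub(ch, two_char[[ch]], s, fixed = TRUE)
  }
  if (grepl("[\x01-\x1f]", s, useBytes = TRUE)) {
    for (code in setdiff(1:31, c(8L, 9L, 10L, 12L, 13L))) {
      s <- gsub(rawToChar(as.raw(code)), sprintf("\\u%04x", code), s,
                fixed = TRUE, useBytes = TRUE)
    }
  }
  paste0("\"", s, "\"")
}
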