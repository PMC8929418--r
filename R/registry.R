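# Internal registry of released VRS classes.  This is the single source of
# truth for structural validation, identifiability, identifier prefixes and
# schema emission.  Field kinds are either a primitive token (lowercase) or a
# character vector of admissible class names (a polymorphic union).

.vrs_primitives <- c("curie", "string", "sequence", "integer", "boolean",
                     "cytoband", "comparator")

# Patterns for string-valued primitives.  The released schema validates
# compact URIs and cytoband designators by regular expression; the exact
# patterns are an implementation choice here.
.vrs_patterns <- list(
  curie      = "^[A-Za-z0-9._~-]+:\\S+$",
  sequence   = "^[A-Z*]*$",
  cytoband   = "^(pter|qter|[pq][1-9][0-9]*(\\.[0-9]+)*)$",
  comparator = "^(<=|>=)$"
)

.vrs_union <- list(
  range     = c("Number", "DefiniteRange", "IndefiniteRange"),
  location  = c("SequenceLocation", "ChromosomeLocation"),
  seq_expr  = c("LiteralSequenceExpression", "DerivedSequenceExpression",
                "RepeatedSequenceExpression"),
  variation = c("Allele", "Haplotype", "Text", "VariationSet", "CopyNumber")
)

.fld <- function(kind, required = TRUE, or_curie = FALSE, list = FALSE) {
  list(kind = kind, required = required, or_curie = or_curie, list = list)
}

# identifiable = Variation and Location subclasses (and, separately, raw
# Sequence strings); intervals, ranges and sequence expressions are not
# meaningful in isolation and carry no identifier prefix.
.vrs_registry <- list(
  Number = list(
    identifiable = FALSE, prefix = NA_character_,
    fields = list(value = .fld("integer"))
  ),
  DefiniteRange = list(
    identifiable = FALSE, prefix = NA_character_,
    fields = list(min = .fld("integer"), max = .fld("integer")),
    check = function(x) {
      if (x$min > x$max) "min must be <= max" else character()
    }
  ),
  IndefiniteRange = list(
    identifiable = FALSE, prefix = NA_character_,
    fields = list(value = .fld("integer"), comparator = .fld("comparator"))
  ),
  SequenceInterval = list(
    identifiable = FALSE, prefix = NA_character_,
    fields = list(start = .fld(.vrs_union$range), end = .fld(.vrs_union$range)),
    check = function(x) {
      out <- character()
      if (identical(x$start$type, "Number") && x$start$value < 0L) {
        out <- c(out, "start must be >= 0")
      }
      if (identical(x$end$type, "Number") && x$end$value < 0L) {
        out <- c(out, "end must be >= 0")
      }
      if (identical(x$start$type, "Number") && identical(x$end$type, "Number") &&
          x$start$value > x$end$value) {
        out <- c(out, "start must be <= end")
      }
      out
    }
  ),
  CytobandInterval = list(
    identifiable = FALSE, prefix = NA_character_,
    fields = list(start = .fld("cytoband"), end = .fld("cytoband"))
  ),
  SequenceLocation = list(
    identifiable = TRUE, prefix = "VSL",
    fields = list(`_id` = .fld("curie", required = FALSE),
                  sequence_id = .fld("curie"),
                  interval = .fld("SequenceInterval"))
  ),
  ChromosomeLocation = list(
    identifiable = TRUE, prefix = "VCL",
    fields = list(`_id` = .fld("curie", required = FALSE),
                  species_id = .fld("curie"),
                  chr = .fld("string"),
                  interval = .fld("CytobandInterval")),
    check = function(x) {
      out <- character()
      if (!nzchar(x$chr)) out <- c(out, "chr must be non-empty")
      if (grepl("^chr", x$chr)) out <- c(out, "chr must not carry a 'chr' prefix")
      out
    }
  ),
  LiteralSequenceExpression = list(
    identifiable = FALSE, prefix = NA_character_,
    fields = list(sequence = .fld("sequence"))
  ),
  DerivedSequenceExpression = list(
    identifiable = FALSE, prefix = NA_character_,
    fields = list(location = .fld("SequenceLocation"),
                  reverse_complement = .fld("boolean"))
  ),
  RepeatedSequenceExpression = list(
    identifiable = FALSE, prefix = NA_character_,
    fields = list(seq_expr = .fld(c("LiteralSequenceExpression",
                                    "DerivedSequenceExpression")),
                  count = .fld(.vrs_union$range)),
    check = function(x) {
      cnt <- x$count
      bad <- switch(cnt$type,
        Number = cnt$value < 0L,
        DefiniteRange = cnt$min < 0L,
        IndefiniteRange = cnt$value < 0L && identical(cnt$comparator, "<="),
        FALSE)
      if (isTRUE(bad)) "count must be >= 0" else character()
    }
  ),
  Allele = list(
    identifiable = TRUE, prefix = "VA",
    fields = list(`_id` = .fld("curie", required = FALSE),
                  location = .fld(.vrs_union$location, or_curie = TRUE),
                  state = .fld(.vrs_union$seq_expr))
  ),
  Haplotype = list(
    identifiable = TRUE, prefix = "VH",
    fields = list(`_id` = .fld("curie", required = FALSE),
                  members = .fld("Allele", or_curie = TRUE, list = TRUE)),
    check = function(x) {
      if (length(x$members) == 0L) "members must be non-empty" else character()
    }
  ),
  Text = list(
    identifiable = TRUE, prefix = "VT",
    fields = list(`_id` = .fld("curie", required = FALSE),
                  definition = .fld("string")),
    check = function(x) {
      if (!nzchar(x$definition)) "definition must be non-empty" else character()
    }
  ),
  VariationSet = list(
    identifiable = TRUE, prefix = "VS",
    fields = list(`_id` = .fld("curie", required = FALSE),
                  members = .fld(.vrs_union$variation, or_curie = TRUE,
                                 list = TRUE))
  ),
  CopyNumber = list(
    identifiable = TRUE, prefix = "VCN",
    fields = list(`_id` = .fld("curie", required = FALSE),
                  subject = .fld(c(.vrs_union$location, "Gene",
                                   "DerivedSequenceExpression"),
                                 or_curie = TRUE),
                  copies = .fld(.vrs_union$range))
  ),
  Gene = list(
    identifiable = FALSE, prefix = NA_character_,
    fields = list(gene_id = .fld("curie"))
  )
)

.vrs_type_names <- function() names(.vrs_registry)

.vrs_type_info <- function(type_name) {
  info <- .vrs_registry[[type_name]]
  if (is.null(info)) {
    stop("unknown VRS type: ", type_name, call. = FALSE)
  }
  info
}

#' Is a VRS class identifiable?
#'
#' Identifiable classes are those meaningful in isolation and therefore
#' eligible for a computed identifier: the Variation subclasses (`Allele`,
#' `Haplotype`, `Text`, `VariationSet`, `CopyNumber`) and the Location
#' subclasses (`SequenceLocation`, `ChromosomeLocation`).  Intervals, ranges
#' and sequence expressions exist only as parts of other objects.  Raw
#' sequences are also identifiable but are plain strings, not classes; see
#' [ga4gh_identify()].
#'
#' @param type_name Name of a released VRS class, e.g. `"Allele"`.
#' @return `TRUE` or `FALSE`; unknown class names are an error.
#' @examples
#' is_identifiable("Allele")           # TRUE
#' is_identifiable("SequenceInterval") # FALSE
#' @export
is_identifiable <- function(type_name) {
  stopifnot(is.character(type_name), length(type_name) == 1L)
  .vrs_type_info(type_name)$identifiable
}

#' Identifier prefixes of the released VRS classes
#'
#' Each identifiable class has a short persistent prefix used in computed
#' identifiers (`ga4gh:<prefix>.<digest>`), e.g. `VA` for Allele.  `SQ`, the
#' prefix for raw sequences, is included.
#'
#' @return Named character vector mapping class name to prefix.
#' @export
vrs_prefixes <- function() {
  pfx <- vapply(.vrs_registry, function(i) i$prefix, character(1))
  pfx <- pfx[!is.na(pfx)]
  c(pfx, Sequence = "SQ")
}
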