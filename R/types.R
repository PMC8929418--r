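# Value-object constructors.  Every object is a named list carrying a "type"
# discriminator and the class "vrs_object"; R's copy-on-modify semantics make
# the objects effectively immutable, and no function in this package mutates
# one in place.

.vrs_new <- function(type, fields) {
  fields <- fields[!vapply(fields, is.null, logical(1))]
  obj <- c(list(type = type), fields)
  class(obj) <- "vrs_object"
  rep <- vrs_validate(obj)
  if (nrow(rep) > 0L) {
    stop("invalid ", type, ": ",
         paste(rep$message, collapse = "; "), call. = FALSE)
  }
  obj
}

.as_int <- function(x, what) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != trunc(x)) {
    stop(what, " must be a single integer", call. = FALSE)
  }
  as.integer(x)
}

#' @export
print.vrs_object <- function(x, ...) {
  cat("<", x$type, ">\n", sep = "")
  cat(vrs_to_json(x, pretty = TRUE), "\n")
  invisible(x)
}

#' Construct VRS general-purpose types
#'
#' `vrs_number()`, `vrs_definite_range()` and `vrs_indefinite_range()` build
#' the three interchangeable quantity types used for interval endpoints and
#' copy counts.  An `IndefiniteRange` couples a value with a comparator
#' (`"<="` or `">="`) to express half-bounded quantities.
#'
#' @param value Integer value.
#' @param min,max Integer bounds, `min <= max`.
#' @param comparator `"<="` or `">="`.
#' @return A VRS value object.
#' @examples
#' vrs_number(5)
#' vrs_indefinite_range(2, ">=")
#' @export
vrs_number <- function(value) {
  .vrs_new("Number", list(value = .as_int(value, "value")))
}

#' @rdname vrs_number
#' @export
vrs_definite_range <- function(min, max) {
  .vrs_new("DefiniteRange",
           list(min = .as_int(min, "min"), max = .as_int(max, "max")))
}

#' @rdname vrs_number
#' @export
vrs_indefinite_range <- function(value, comparator) {
  .vrs_new("IndefiniteRange",
           list(value = .as_int(value, "value"), comparator = comparator))
}

# Accept a bare integer where a Number|Range union is expected.
.as_quantity <- function(x) {
  if (inherits(x, "vrs_object")) return(x)
  vrs_number(x)
}

#' Construct a sequence interval (inter-residue coordinates)
#'
#' Coordinates count the spaces *between* residues, so an interval
#' `(a, b)` spans `b - a` residues and `(a, a)` is the insertion point
#' between residues `a` and `a + 1`.  This decouples a location from the
#' kind of edit applied there: the same interval serves substitutions,
#' deletions and insertions.  Bare integers are wrapped into `Number`s;
#' ranges may be passed for fuzzy endpoints.
#'
#' @param start,end Inter-residue coordinates (integer, `Number`,
#'   `DefiniteRange` or `IndefiniteRange`); for definite endpoints
#'   `0 <= start <= end`.
#' @return A `SequenceInterval` value object.
#' @examples
#' vrs_sequence_interval(1, 2)  # the second residue
#' @export
vrs_sequence_interval <- function(start, end) {
  .vrs_new("SequenceInterval",
           list(start = .as_quantity(start), end = .as_quantity(end)))
}

#' @rdname vrs_chromosome_location
#' @export
vrs_cytoband_interval <- function(start, end) {
  .vrs_new("CytobandInterval", list(start = start, end = end))
}

#' Construct a location on an identified sequence
#'
#' A `SequenceLocation` names a sequence (by CURIE) and an inter-residue
#' interval on it.  For digest-stable identification the `sequence_id`
#' should be a `ga4gh:SQ.*` identifier; [ga4gh_identify()] resolves other
#' namespaces through a sequence store before digesting.
#'
#' @param sequence_id CURIE identifying the sequence (e.g.
#'   `"ga4gh:SQ.hB3n..."` or `"local:tiny1"`).
#' @param interval A `SequenceInterval`, or anything accepted by
#'   [vrs_sequence_interval()] when given as `c(start, end)`.
#' @param id Optional CURIE stored as the non-digested `_id` field.
#' @return A `SequenceLocation` value object.
#' @export
vrs_sequence_location <- function(sequence_id, interval, id = NULL) {
  if (!inherits(interval, "vrs_object")) {
    stopifnot(length(interval) == 2L)
    interval <- vrs_sequence_interval(interval[[1]], interval[[2]])
  }
  .vrs_new("SequenceLocation",
           list(`_id` = id, sequence_id = sequence_id, interval = interval))
}

#' Construct a cytogenetic location
#'
#' Locates a region by species, chromosome and cytoband interval (e.g.
#' bands `q22.2` to `q22.3`).  The chromosome is stored without any
#' `"chr"` prefix.
#'
#' @param species_id CURIE for the species (e.g. `"taxonomy:9606"`).
#' @param chr Chromosome name, e.g. `"11"` or `"X"`.
#' @param interval A `CytobandInterval` or `c(start, end)` designators.
#' @param id Optional CURIE stored as `_id`.
#' @param start,end Cytoband designators such as `"q22.3"`, `"pter"`.
#' @return A `ChromosomeLocation` / `CytobandInterval` value object.
#' @export
vrs_chromosome_location <- function(species_id, chr, interval, id = NULL) {
  if (!inherits(interval, "vrs_object")) {
    stopifnot(length(interval) == 2L)
    interval <- vrs_cytoband_interval(interval[[1]], interval[[2]])
  }
  .vrs_new("ChromosomeLocation",
           list(`_id` = id, species_id = species_id, chr = chr,
                interval = interval))
}

#' Construct sequence expressions
#'
#' A `LiteralSequenceExpression` is an explicit string of IUPAC residue
#' codes (folded to uppercase on construction, since computed identifiers
#' are byte-sensitive).  A `DerivedSequenceExpression` describes the
#' sequence at a location, optionally reverse-complemented.  A
#' `RepeatedSequenceExpression` repeats a subsequence a (possibly ranged)
#' number of times.
#'
#' @param sequence IUPAC residue string (may be empty, e.g. for deletions).
#' @param location A `SequenceLocation`.
#' @param reverse_complement Logical flag.
#' @param seq_expr A literal or derived sequence expression.
#' @param count Repeat count: integer, `Number`, `DefiniteRange` or
#'   `IndefiniteRange`; non-negative.
#' @return A sequence-expression value object.
#' @examples
#' vrs_literal_sequence_expression("acgt")  # stored as "ACGT"
#' @export
vrs_literal_sequence_expression <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  .vrs_new("LiteralSequenceExpression", list(sequence = toupper(sequence)))
}

#' @rdname vrs_literal_sequence_expression
#' @export
vrs_derived_sequence_expression <- function(location, reverse_complement = FALSE) {
  .vrs_new("DerivedSequenceExpression",
           list(location = location,
                reverse_complement = isTRUE(reverse_complement)))
}

#' @rdname vrs_literal_sequence_expression
#' @export
vrs_repeated_sequence_expression <- function(seq_expr, count) {
  .vrs_new("RepeatedSequenceExpression",
           list(seq_expr = seq_expr, count = .as_quantity(count)))
}

#' Construct an Allele
#'
#' The central molecular-variation value object: the state of a contiguous
#' molecule at a location.  Substitutions, insertions and deletions are all
#' expressed the same way — a location plus the sequence asserted there —
#' so an empty literal state is a deletion and a zero-width interval an
#' insertion.
#'
#' @param location A `SequenceLocation`, `ChromosomeLocation`, or a CURIE
#'   string referencing one.
#' @param state A sequence expression, or a bare string taken as a
#'   `LiteralSequenceExpression`.
#' @param id Optional CURIE stored as `_id`.
#' @return An `Allele` value object.
#' @examples
#' store <- vrs_sequence_store(c(tiny1 = "CCTAC"))
#' al <- vrs_allele(vrs_sequence_location("local:tiny1", c(1, 2)), "T")
#' @export
vrs_allele <- function(location, state, id = NULL) {
  if (is.character(state)) state <- vrs_literal_sequence_expression(state)
  .vrs_new("Allele", list(`_id` = id, location = location, state = state))
}

#' Construct composite and systemic variation objects
#'
#' `vrs_haplotype()` groups phased alleles on one molecule;
#' `vrs_variation_set()` is an unordered, de-duplicated collection of any
#' variation; `vrs_copy_number()` asserts a systemic copy count of a
#' subject (location, gene or derived sequence); `vrs_text()` wraps an
#' otherwise unrepresentable description; `vrs_gene()` references a gene
#' concept by CURIE.  Members may be given inline or as CURIE references;
#' duplicates (by value, after identification) are rejected.
#'
#' @param members List of member objects or CURIE strings.
#' @param definition Free-text description, non-empty.
#' @param subject Location, `Gene`, `DerivedSequenceExpression`, or CURIE.
#' @param copies Copy count: integer, `Number` or range object.
#' @param gene_id CURIE for the gene concept (e.g. `"hgnc:1097"`).
#' @param id Optional CURIE stored as `_id`.
#' @return A variation value object.
#' @export
vrs_haplotype <- function(members, id = NULL) {
  .vrs_new("Haplotype", list(`_id` = id, members = members))
}

#' @rdname vrs_haplotype
#' @export
vrs_text <- function(definition, id = NULL) {
  .vrs_new("Text", list(`_id` = id, definition = definition))
}

#' @rdname vrs_haplotype
#' @export
vrs_variation_set <- function(members, id = NULL) {
  .vrs_new("VariationSet", list(`_id` = id, members = members))
}

#' @rdname vrs_haplotype
#' @export
vrs_copy_number <- function(subject, copies, id = NULL) {
  .vrs_new("CopyNumber",
           list(`_id` = id, subject = subject, copies = .as_quantity(copies)))
}

#' @rdname vrs_haplotype
#' @export
vrs_gene <- function(gene_id) {
  .vrs_new("Gene", list(gene_id = gene_id))
}

#' Value-object equality
#'
#' Two VRS objects are equal exactly when their significant content is
#' equal: the optional `_id` field and field construction order are
#' ignored.  Comparison is by canonical display serialization.
#'
#' @param a,b VRS objects.
#' @return `TRUE` or `FALSE`.
#' @export
vrs_equal <- function(a, b) {
  identical(.canonical_display(a), .canonical_display(b))
}

# canonical display form: _id dropped, keys sorted; used only for equality
.canonical_display <- function(x) {
  if (is.list(x)) {
    nms <- names(x)
    if (!is.null(nms)) {
      keep <- !startsWith(nms, "_")
      x <- x[keep]
      x <- x[sort(names(x), method = "radix")]
    }
    lapply(unclass(x), .canonical_display)
  } else {
    x
  }
}
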