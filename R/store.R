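# In-memory sequence store implementing the DataProxy contract: sequence
# slices, metadata, and alias <-> ga4gh:SQ identifier translation.  All
# coordinates at this interface are inter-residue; there are deliberately no
# residue-numbered entry points anywhere in the package.

.IUPAC_CHARS <- c(LETTERS, "*")

.check_iupac <- function(seq, what) {
  if (grepl("[^A-Z*]", seq)) {
    bad <- unique(strsplit(gsub("[A-Z*]", "", seq), "")[[1]])
    stop("non-IUPAC characters in ", what, ": ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  invisible(seq)
}

#' Build an in-memory sequence store
#'
#' A store maps `ga4gh:SQ` sequence digests to sequence bytes and
#' metadata, with an alias index so any known CURIE (e.g. `local:tiny1`,
#' `refseq:NM_000551.3`) resolves to the same record.  Sequences are
#' uppercase-folded on ingestion and their `ga4gh:SQ` identifiers are
#' precomputed from the raw residue bytes, so identifier lookups never
#' re-hash.
#'
#' @param sequences Named character vector of sequences; names become
#'   aliases in `namespace`.
#' @param namespace Namespace for the supplied names (default `"local"`).
#' @return A `vrs_sequence_store`.
#' @examples
#' store <- vrs_sequence_store(c(tiny1 = "CCTAC"))
#' get_sequence(store, "local:tiny1", 1, 2)  # "C"
#' @export
vrs_sequence_store <- function(sequences = character(), namespace = "local") {
  store <- structure(
    list(records = new.env(parent = emptyenv()),
         aliases = new.env(parent = emptyenv())),
    class = "vrs_sequence_store")
  for (nm in names(sequences)) {
    store_add_sequence(store, sequences[[nm]], paste0(namespace, ":", nm))
  }
  store
}

#' @export
print.vrs_sequence_store <- function(x, ...) {
  n <- length(ls(x$records))
  cat("<vrs_sequence_store> ", n, " sequence(s), ",
      length(ls(x$aliases)), " alias(es)\n", sep = "")
  invisible(x)
}

#' @rdname vrs_sequence_store
#' @param store A `vrs_sequence_store`.
#' @param sequence Residue string (IUPAC codes; folded to uppercase).
#' @param aliases Character vector of alias CURIEs for the sequence.
#' @export
store_add_sequence <- function(store, sequence, aliases = character()) {
  stopifnot(inherits(store, "vrs_sequence_store"))
  sequence <- toupper(sequence)
  .check_iupac(sequence, "sequence")
  dg <- sha512t24u(charToRaw(sequence))
  sq <- paste0("ga4gh:SQ.", dg)
  aliases <- unique(c(aliases))
  for (a in c(aliases, sq)) {
    known <- get0(a, envir = store$aliases)
    if (!is.null(known) && known != dg) {
      stop("alias '", a, "' already bound to a different sequence",
           call. = FALSE)
    }
  }
  rec <- get0(dg, envir = store$records)
  if (is.null(rec)) {
    rec <- list(sequence = sequence, length = nchar(sequence),
                aliases = sq)
  }
  rec$aliases <- unique(c(rec$aliases, aliases))
  assign(dg, rec, envir = store$records)
  for (a in c(aliases, sq)) assign(a, dg, envir = store$aliases)
  invisible(store)
}

#' Load FASTA files into a sequence store
#'
#' Each FASTA record becomes one store record; the first whitespace-
#' delimited header token becomes an alias in the `local:` namespace (a
#' deliberate namespace so toy fixtures never masquerade as real
#' accessions).  An optional two-column TSV (`alias` CURIE, header token)
#' registers additional aliases, e.g. real accessions, against the same
#' records.
#'
#' @param paths One or more FASTA file paths (wrapped lines and multiple
#'   records supported).
#' @param alias_table Optional TSV path with columns `alias`, `token`.
#' @param namespace Namespace for header-token aliases.
#' @return A `vrs_sequence_store`.
#' @export
vrs_read_fasta <- function(paths, alias_table = NULL, namespace = "local") {
  sets <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("FASTA file not found: ", p, call. = FALSE)
    Biostrings::readBStringSet(p)
  })
  seqs <- unlist(lapply(sets, as.character))
  tokens <- unlist(lapply(sets, function(s) {
    sub("\\s.*$", "", names(s))
  }))
  if (anyDuplicated(tokens)) {
    stop("duplicate FASTA header token(s): ",
         paste(unique(tokens[duplicated(tokens)]), collapse = ", "),
         call. = FALSE)
  }
  store <- vrs_sequence_store()
  for (i in seq_along(seqs)) {
    store_add_sequence(store, seqs[[i]], paste0(namespace, ":", tokens[[i]]))
  }
  if (!is.null(alias_table)) {
    tab <- utils::read.delim(alias_table, header = FALSE,
                             col.names = c("alias", "token"),
                             stringsAsFactors = FALSE, comment.char = "#")
    for (i in seq_len(nrow(tab))) {
      tok <- paste0(namespace, ":", tab$token[i])
      dg <- get0(tok, envir = store$aliases)
      if (is.null(dg)) {
        stop("alias table refers to unknown record '", tab$token[i], "'",
             call. = FALSE)
      }
      rec <- get(dg, envir = store$records)
      store_add_sequence(store, rec$sequence, tab$alias[i])
    }
  }
  store
}

.resolve_digest <- function(store, identifier) {
  stopifnot(inherits(store, "vrs_sequence_store"))
  dg <- get0(identifier, envir = store$aliases)
  if (is.null(dg)) {
    stop("unknown sequence identifier: ", identifier, call. = FALSE)
  }
  dg
}

#' DataProxy operations: slices, metadata, identifier translation
#'
#' `get_sequence()` returns the residues between inter-residue positions
#' `start` and `end` (so the result has `end - start` characters and
#' `(a, a)` is empty); `get_metadata()` returns length, alphabet and the
#' full alias list; `translate_sequence_identifier()` returns all aliases
#' of a sequence in a target namespace (zero or more — an unknown
#' *identifier*, by contrast, is an error).  Results are identical through
#' any alias of the same sequence.
#'
#' @param store A `vrs_sequence_store`.
#' @param identifier Any known alias CURIE of the sequence.
#' @param start,end Inter-residue coordinates,
#'   `0 <= start <= end <= length`; omitted means the full sequence.
#' @param namespace Target namespace token, e.g. `"ga4gh"`.
#' @return `get_sequence()`: a character scalar; `get_metadata()`: a list
#'   with `length`, `alphabet`, `aliases`; `translate_sequence_identifier()`:
#'   a character vector of CURIEs.
#' @export
get_sequence <- function(store, identifier, start = NULL, end = NULL) {
  rec <- get(.resolve_digest(store, identifier), envir = store$records)
  if (is.null(start)) start <- 0L
  if (is.null(end)) end <- rec$length
  start <- .as_int(start, "start")
  end <- .as_int(end, "end")
  if (start < 0L || start > end || end > rec$length) {
    stop("coordinates (", start, ", ", end, ") out of bounds for sequence ",
         "of length ", rec$length, call. = FALSE)
  }
  substr(rec$sequence, start + 1L, end)
}

#' @rdname get_sequence
#' @export
get_metadata <- function(store, identifier) {
  rec <- get(.resolve_digest(store, identifier), envir = store$records)
  chars <- sort(unique(strsplit(rec$sequence, "")[[1]]), method = "radix")
  list(length = rec$length,
       alphabet = paste(chars, collapse = ""),
       aliases = sort(rec$aliases, method = "radix"))
}

#' @rdname get_sequence
#' @export
translate_sequence_identifier <- function(store, identifier, namespace) {
  rec <- get(.resolve_digest(store, identifier), envir = store$records)
  hits <- rec$aliases[startsWith(rec$aliases, paste0(namespace, ":"))]
  sort(hits, method = "radix")
}
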