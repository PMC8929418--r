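# Translation between VRS alleles and the SPDI and HGVS variant
# nomenclatures, over a sequence store.  SPDI positions are already
# inter-residue; HGVS uses 1-based inclusive residue numbering and a
# 3'-shifting convention, both converted here.

#' Parse an SPDI expression into an Allele
#'
#' SPDI (`sequence:position:deletion:insertion`) uses inter-residue
#' positions directly: the allele spans `[position, position +
#' deletion_length)` and asserts the insertion as its literal state.  The
#' deletion field may be a length or the deleted sequence itself; a
#' sequence-form deletion is checked against the store.
#'
#' @param expr SPDI string, e.g. `"local:tiny1:1:1:T"`.  The accession
#'   may itself contain colons (a CURIE); the last three fields are
#'   position, deletion, insertion.
#' @param store A [vrs_sequence_store()].
#' @return An `Allele` with the accession's `ga4gh:SQ` sequence id.
#' @export
parse_spdi <- function(expr, store) {
  parts <- strsplit(expr, ":", fixed = TRUE)[[1]]
  if (endsWith(expr, ":")) parts <- c(parts, "")  # empty insertion field
  if (length(parts) < 4L) {
    stop("malformed SPDI expression: ", expr, call. = FALSE)
  }
  n <- length(parts)
  accession <- paste(parts[1:(n - 3L)], collapse = ":")
  pos <- parts[[n - 2L]]
  del <- parts[[n - 1L]]
  ins <- toupper(parts[[n]])
  if (!grepl("^[0-9]+$", pos)) {
    stop("malformed SPDI position: ", pos, call. = FALSE)
  }
  pos <- as.integer(pos)
  if (grepl("^[0-9]+$", del)) {
    del_len <- as.integer(del)
    del_seq <- NULL
  } else if (grepl("^[A-Za-z]*$", del)) {
    del_seq <- toupper(del)
    del_len <- nchar(del_seq)
  } else {
    stop("malformed SPDI deletion field: ", del, call. = FALSE)
  }
  if (!grepl("^[A-Za-z]*$", ins)) {
    stop("malformed SPDI insertion field: ", ins, call. = FALSE)
  }
  sq <- translate_sequence_identifier(store, accession, "ga4gh")[[1]]
  if (!is.null(del_seq)) {
    actual <- get_sequence(store, sq, pos, pos + del_len)
    if (actual != del_seq) {
      stop("SPDI deletion sequence '", del_seq, "' does not match the ",
           "stored sequence '", actual, "' at (", pos, ", ",
           pos + del_len, ")", call. = FALSE)
    }
  }
  vrs_allele(vrs_sequence_location(sq, c(pos, pos + del_len)), ins)
}

#' Format an Allele as an SPDI expression
#'
#' The inverse of [parse_spdi()] (an identity on normalized alleles):
#' emits `alias:start:deletion_length:insertion` using an alias of the
#' allele's sequence in the requested namespace.
#'
#' @param allele A literal-state `Allele` on a `SequenceLocation`.
#' @param store A [vrs_sequence_store()].
#' @param namespace Namespace for the accession (default `"local"`).
#' @return An SPDI string.
#' @export
format_spdi <- function(allele, store, namespace = "local") {
  p <- .literal_parts(allele, store, namespace)
  paste(p$alias, p$start, p$end - p$start, p$alt, sep = ":")
}

.literal_parts <- function(allele, store, namespace) {
  stopifnot(identical(allele$type, "Allele"))
  loc <- allele$location
  if (!is.list(loc) || !identical(loc$type, "SequenceLocation")) {
    stop("allele location must be a SequenceLocation", call. = FALSE)
  }
  if (!identical(allele$state$type, "LiteralSequenceExpression")) {
    stop("allele state must be a LiteralSequenceExpression", call. = FALSE)
  }
  iv <- loc$interval
  if (!identical(iv$start$type, "Number") ||
      !identical(iv$end$type, "Number")) {
    stop("allele interval must have definite endpoints", call. = FALSE)
  }
  alias <- translate_sequence_identifier(store, loc$sequence_id, namespace)
  if (length(alias) == 0L) {
    stop("no alias in namespace '", namespace, "' for ", loc$sequence_id,
         call. = FALSE)
  }
  list(alias = alias[[1]], sequence_id = loc$sequence_id,
       start = iv$start$value, end = iv$end$value,
       alt = allele$state$sequence)
}

.HGVS_RE <- "^(.+):([gmn])\\.(.+)$"

#' Parse an HGVS expression into an Allele
#'
#' Supports linear-coordinate HGVS (`g.`, `m.`, `n.`) substitutions,
#' identities (`=`), deletions, insertions, deletion-insertions and
#' duplications with explicit positions.  Residue `n` (1-based,
#' inclusive) maps to the inter-residue interval `(n - 1, n)`.  Asserted
#' reference residues (e.g. the `C` of `g.2C>T`, or `delAA`) are checked
#' against the store.  A duplication is translated as a molecular
#' insertion of the duplicated span's literal sequence immediately after
#' that span — a systemic copy-number claim requires an explicit
#' `CopyNumber` from the caller.  Uncertain breakpoints (`(?_123)`) are
#' rejected.
#'
#' @param expr HGVS string, e.g. `"local:tiny1:g.2C>T"`.
#' @param store A [vrs_sequence_store()].
#' @param normalize Fully justify the result via [vrs_normalize()]?
#' @return An `Allele` with the accession's `ga4gh:SQ` sequence id.
#' @export
parse_hgvs <- function(expr, store, normalize = FALSE) {
  if (grepl("[(?]", expr)) {
    stop("uncertain-breakpoint HGVS syntax is not supported: ", expr,
         call. = FALSE)
  }
  m <- regmatches(expr, regexec(.HGVS_RE, expr))[[1]]
  if (length(m) == 0L) {
    stop("cannot parse HGVS expression: ", expr, call. = FALSE)
  }
  accession <- m[[2]]
  edit <- m[[4]]
  sq <- translate_sequence_identifier(store, accession, "ga4gh")[[1]]
  seq_len <- get_metadata(store, sq)$length

  span <- function(s, e) {
    s <- as.integer(s)
    e <- if (nzchar(e)) as.integer(e) else s
    if (s < 1L || e < s || e > seq_len) {
      stop("HGVS positions ", s, "_", e, " out of bounds", call. = FALSE)
    }
    c(s - 1L, e)  # 1-based inclusive -> inter-residue half-open
  }
  check_ref <- function(iv, asserted) {
    if (!nzchar(asserted)) return(invisible())
    actual <- get_sequence(store, sq, iv[1], iv[2])
    if (actual != toupper(asserted)) {
      stop("asserted reference '", toupper(asserted), "' does not match ",
           "stored sequence '", actual, "'", call. = FALSE)
    }
  }
  build <- function(iv, alt) {
    al <- vrs_allele(vrs_sequence_location(sq, c(iv[1], iv[2])), alt)
    if (normalize) vrs_normalize(al, store) else al
  }

  g <- function(re) regmatches(edit, regexec(re, edit))[[1]]

  if (length(p <- g("^([0-9]+)([A-Za-z])>([A-Za-z])$"))) {
    iv <- span(p[2], "")
    check_ref(iv, p[3])
    return(build(iv, toupper(p[4])))
  }
  if (length(p <- g("^([0-9]+)(_([0-9]+))?([A-Za-z]*)=$"))) {
    iv <- span(p[2], p[4])
    check_ref(iv, p[5])
    return(build(iv, get_sequence(store, sq, iv[1], iv[2])))
  }
  if (length(p <- g("^([0-9]+)(_([0-9]+))?delins([A-Za-z]+)$"))) {
    iv <- span(p[2], p[4])
    return(build(iv, toupper(p[5])))
  }
  if (length(p <- g("^([0-9]+)(_([0-9]+))?del([A-Za-z]*)$"))) {
    iv <- span(p[2], p[4])
    check_ref(iv, p[5])
    return(build(iv, ""))
  }
  if (length(p <- g("^([0-9]+)_([0-9]+)ins([A-Za-z]+)$"))) {
    s <- as.integer(p[2])
    e <- as.integer(p[3])
    if (e != s + 1L) {
      stop("HGVS insertion positions must be adjacent residues: ", edit,
           call. = FALSE)
    }
    return(build(c(s, s), toupper(p[4])))
  }
  if (length(p <- g("^([0-9]+)(_([0-9]+))?dup([A-Za-z]*)$"))) {
    iv <- span(p[2], p[4])
    dup_seq <- get_sequence(store, sq, iv[1], iv[2])
    check_ref(iv, p[5])
    return(build(c(iv[2], iv[2]), dup_seq))
  }
  stop("unsupported HGVS edit: ", edit, call. = FALSE)
}

#' Format an Allele as an HGVS expression
#'
#' Emits the minimal, 3'-most-shifted form required by the HGVS
#' convention, re-derived from the (possibly fully justified) allele:
#' common prefix then suffix are trimmed, which right-shifts ambiguous
#' indels; an insertion whose sequence equals the span immediately
#' preceding it becomes a `dup`.  `parse_hgvs(format_hgvs(a))` identifies
#' identically to `a`.
#'
#' @param allele A literal-state `Allele` on a `SequenceLocation`.
#' @param store A [vrs_sequence_store()].
#' @param namespace Namespace for the accession (default `"local"`).
#' @param coordinate_type One of `"g"`, `"m"`, `"n"`.
#' @return An HGVS string.
#' @export
format_hgvs <- function(allele, store, namespace = "local",
                        coordinate_type = "g") {
  stopifnot(coordinate_type %in% c("g", "m", "n"))
  p <- .literal_parts(allele, store, namespace)
  ref <- get_sequence(store, p$sequence_id, p$start, p$end)
  alt <- p$alt

  # right-shift: trim the common prefix first, then the common suffix
  np <- 0L
  while (np < nchar(ref) && np < nchar(alt) &&
         substr(ref, np + 1L, np + 1L) == substr(alt, np + 1L, np + 1L)) {
    np <- np + 1L
  }
  r2 <- substring(ref, np + 1L)
  a2 <- substring(alt, np + 1L)
  s <- p$start + np
  ns <- 0L
  while (ns < nchar(r2) && ns < nchar(a2) &&
         substr(r2, nchar(r2) - ns, nchar(r2) - ns) ==
         substr(a2, nchar(a2) - ns, nchar(a2) - ns)) {
    ns <- ns + 1L
  }
  r2 <- substr(r2, 1L, nchar(r2) - ns)
  a2 <- substr(a2, 1L, nchar(a2) - ns)
  e <- p$end - ns

  pos1 <- function(a, b) {
    if (b - a == 1L) as.character(b) else paste0(a + 1L, "_", b)
  }
  edit <-
    if (!nzchar(r2) && !nzchar(a2)) {
      # reference agreement over the original span
      if (p$end - p$start == 1L) paste0(p$end, ref, "=")
      else paste0(pos1(p$start, p$end), "=")
    } else if (nchar(r2) == 1L && nchar(a2) == 1L) {
      paste0(s + 1L, r2, ">", a2)
    } else if (!nzchar(r2)) {
      ins_len <- nchar(a2)
      if (s >= ins_len &&
          get_sequence(store, p$sequence_id, s - ins_len, s) == a2) {
        paste0(pos1(s - ins_len, s), "dup")
      } else if (s >= 1L) {
        paste0(s, "_", s + 1L, "ins", a2)
      } else {
        stop("insertion before the first residue cannot be expressed in ",
             "HGVS", call. = FALSE)
      }
    } else if (!nzchar(a2)) {
      paste0(pos1(s, e), "del")
    } else {
      paste0(pos1(s, e), "delins", a2)
    }
  paste0(p$alias, ":", coordinate_type, ".", edit)
}
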