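# Fully justified allele normalization (the Variant Overprecision
# Correction Algorithm).  An ambiguous indel in a repetitive region is not
# pinned to an arbitrary position; instead the allele is rewritten to cover
# the entire region over which equivalent placements exist.

#' Trim common flanking sequence from an allele pair
#'
#' Removes the common suffix first, then the common prefix, so the
#' returned pair shares no first or last character.  The caller
#' compensates by decrementing `end` by `suffix_len` and incrementing
#' `start` by `prefix_len`.
#'
#' @param ref Reference allele sequence (the residues at the location).
#' @param alt Alternate allele sequence (the asserted state).
#' @return List with `ref`, `alt`, `suffix_len`, `prefix_len`.
#' @examples
#' trim_common_flanks("TCA", "GCA")  # ref "T", alt "G", suffix_len 2
#' @export
trim_common_flanks <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  s <- 0L
  while (s < nr && s < na &&
         substr(ref, nr - s, nr - s) == substr(alt, na - s, na - s)) {
    s <- s + 1L
  }
  ref <- substr(ref, 1L, nr - s)
  alt <- substr(alt, 1L, na - s)
  nr <- nr - s
  na <- na - s
  p <- 0L
  while (p < nr && p < na &&
         substr(ref, p + 1L, p + 1L) == substr(alt, p + 1L, p + 1L)) {
    p <- p + 1L
  }
  list(ref = substring(ref, p + 1L), alt = substring(alt, p + 1L),
       suffix_len = s, prefix_len = p)
}

#' Determine the bounds of ambiguity of an indel by rolling
#'
#' Given the full reference context, the inter-residue span of a trimmed
#' indel, and its single non-empty allele sequence, finds how far the
#' edit can roll.  Left roll: while the *last* base of a working copy of
#' the allele sequence equals the base preceding the left bound, the
#' bound moves left and the copy is circularly permuted (last character
#' to the front).  Right roll: symmetric, comparing the *first* base of
#' a fresh working copy against the base following the right bound
#' (which starts at `end` — equal to `start` for insertions).  Rolling
#' halts at the sequence boundaries; the caller's allele sequence is
#' never altered.
#'
#' @param context Full reference sequence (character scalar).
#' @param start Inter-residue start of the trimmed edit.
#' @param allele_seq Non-empty allele sequence (the inserted sequence,
#'   or the deleted reference sequence).
#' @param end Inter-residue end of the trimmed edit; defaults to `start`
#'   (the insertion case).
#' @return List with `left_roll_bound` and `right_roll_bound`.
#' @examples
#' roll_bounds("TTACACACAGG", 9, "CA")  # left 2, right 9
#' @export
roll_bounds <- function(context, start, allele_seq, end = start) {
  stopifnot(nzchar(allele_seq))
  n <- nchar(context)
  m <- nchar(allele_seq)
  start <- .as_int(start, "start")
  end <- .as_int(end, "end")

  left <- start
  work <- allele_seq
  while (left > 0L &&
         substr(work, m, m) == substr(context, left, left)) {
    left <- left - 1L
    work <- paste0(substr(work, m, m), substr(work, 1L, m - 1L))
  }

  right <- end
  work <- allele_seq
  while (right < n &&
         substr(work, 1L, 1L) == substr(context, right + 1L, right + 1L)) {
    right <- right + 1L
    work <- paste0(substr(work, 2L, m), substr(work, 1L, 1L))
  }

  list(left_roll_bound = left, right_roll_bound = right)
}

#' Normalize an allele to its fully justified form
#'
#' Applies the allele normalization procedure: (0) read the reference
#' allele sequence at the location; (1) trim common flanks; (2) classify —
#' both empty means a reference allele, returned unmodified; both
#' non-empty means a substitution, returned with trimmed coordinates and
#' state; exactly one empty means an indel; (3) roll to find the bounds
#' of ambiguity; (4) construct a new allele spanning the whole ambiguity
#' region, with the flanking context prepended and appended to the
#' original (unpermuted) alternate sequence.  The result is idempotent
#' under re-normalization and applying it reproduces exactly the edited
#' sequence of the input allele.
#'
#' Normalization only applies to alleles with a `SequenceLocation` with
#' definite (`Number`) endpoints and a `LiteralSequenceExpression` state;
#' anything else is returned unchanged, marked with a `"vrs_not_normalized"`
#' attribute naming the reason (this is a signal, not an error — an
#' unresolvable location, by contrast, is an error).
#'
#' @param allele An `Allele`.
#' @param store A [vrs_sequence_store()] resolving the allele's sequence.
#' @return The normalized `Allele`.
#' @examples
#' store <- vrs_sequence_store(c(rep1 = "TTACACACAGG"))
#' al <- vrs_allele(vrs_sequence_location("local:rep1", c(9, 9)), "CA")
#' vrs_normalize(al, store)  # interval (2, 9), state "ACACACACA"
#' @export
vrs_normalize <- function(allele, store) {
  stopifnot(inherits(allele, "vrs_object"), identical(allele$type, "Allele"))
  skip <- function(reason) {
    attr(allele, "vrs_not_normalized") <- reason
    allele
  }
  loc <- allele$location
  if (!is.list(loc) || !identical(loc$type, "SequenceLocation")) {
    return(skip("location is not a SequenceLocation"))
  }
  iv <- loc$interval
  if (!identical(iv$start$type, "Number") ||
      !identical(iv$end$type, "Number")) {
    return(skip("interval endpoints are not definite Numbers"))
  }
  if (!identical(allele$state$type, "LiteralSequenceExpression")) {
    return(skip("state is not a LiteralSequenceExpression"))
  }

  start <- iv$start$value
  end <- iv$end$value
  context_len <- get_metadata(store, loc$sequence_id)$length
  if (end > context_len) {
    stop("allele interval (", start, ", ", end, ") exceeds sequence length ",
         context_len, call. = FALSE)
  }
  ref <- get_sequence(store, loc$sequence_id, start, end)
  alt <- allele$state$sequence

  tr <- trim_common_flanks(ref, alt)
  end <- end - tr$suffix_len
  start <- start + tr$prefix_len

  if (!nzchar(tr$ref) && !nzchar(tr$alt)) {
    return(allele)  # reference allele: returned unmodified
  }

  rebuild <- function(new_start, new_end, new_alt) {
    vrs_allele(
      vrs_sequence_location(loc$sequence_id,
                            vrs_sequence_interval(new_start, new_end)),
      vrs_literal_sequence_expression(new_alt))
  }

  if (nzchar(tr$ref) && nzchar(tr$alt)) {
    return(rebuild(start, end, tr$alt))  # substitution
  }

  # indel: exactly one of the trimmed sequences is non-empty
  rolled <- roll_bounds(
    context = get_sequence(store, loc$sequence_id),
    start = start,
    allele_seq = if (nzchar(tr$alt)) tr$alt else tr$ref,
    end = end)
  lb <- rolled$left_roll_bound
  rb <- rolled$right_roll_bound
  new_alt <- paste0(get_sequence(store, loc$sequence_id, lb, start),
                    tr$alt,
                    get_sequence(store, loc$sequence_id, end, rb))
  rebuild(lb, rb, new_alt)
}
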