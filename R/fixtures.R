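# Deterministic fixture generation: repeat-rich toy sequences and allele
# cases whose expected normalized forms are computed by a brute-force
# apply-and-compare oracle.  The oracle deliberately shares no rolling code
# with vrs_normalize(), so agreement between the two is evidence rather
# than tautology.

.NUC <- c("A", "C", "G", "T")

.rand_seq <- function(n) {
  if (n == 0L) return("")
  paste(sample(.NUC, n, replace = TRUE), collapse = "")
}

#' Generate a repeat-rich toy sequence
#'
#' Builds `flank + motif x copies + flank` with seeded random flanks
#' chosen so they do not extend the repeat run: the flank base adjacent
#' to the core never continues the motif period, so the core is a
#' maximal run.  Identical arguments always give identical output.
#'
#' @param motif Non-empty repeat unit over `ACGT`.
#' @param copies Number of tandem copies (`>= 0`).
#' @param flank_len Length of each random flank (`>= 0`).
#' @param seed Integer seed; generation uses an isolated RNG state.
#' @return A character scalar of length `2 * flank_len + copies *
#'   nchar(motif)`.
#' @examples
#' make_repeat_sequence("CA", 3, 2, seed = 7)
#' @export
make_repeat_sequence <- function(motif, copies, flank_len, seed) {
  motif <- toupper(motif)
  if (!nzchar(motif)) stop("motif must be non-empty", call. = FALSE)
  stopifnot(copies >= 0L, flank_len >= 0L)
  withr::with_seed(seed, {
    core <- strrep(motif, copies)
    left <- .rand_seq(flank_len)
    right <- .rand_seq(flank_len)
    if (copies > 0L && flank_len > 0L) {
      m <- nchar(motif)
      last <- substr(motif, m, m)
      first <- substr(motif, 1L, 1L)
      # adjacent flank bases must break the period
      if (substr(left, flank_len, flank_len) == last) {
        substr(left, flank_len, flank_len) <- sample(setdiff(.NUC, last), 1L)
      }
      if (substr(right, 1L, 1L) == first) {
        substr(right, 1L, 1L) <- sample(setdiff(.NUC, first), 1L)
      }
    }
    paste0(left, core, right)
  })
}

#' Brute-force ambiguity region of an edit (normalization oracle)
#'
#' Computes, without any rolling, the fully justified form of an allele
#' by enumeration: the edit is applied to the full sequence; the edit is
#' reduced to a minimal indel or substitution by flank trimming; and for
#' indels every placement of an equal-length edit that reproduces the
#' identical edited sequence is enumerated.  The expected normalized
#' interval is the union span of all equivalent placements and the
#' expected state is read off the edited sequence.
#'
#' @param context Full reference sequence.
#' @param start,end Inter-residue interval of the input allele.
#' @param alt Alternate (state) sequence of the input allele.
#' @return List with `start`, `end`, `state`, `edited`, and `kind`
#'   (`"reference"`, `"substitution"`, `"insertion"`, `"deletion"`).
#' @export
oracle_normalize <- function(context, start, end, alt) {
  n <- nchar(context)
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(start >= 0L, start <= end, end <= n)
  edited <- paste0(substr(context, 1L, start), alt,
                   substring(context, end + 1L))

  ref <- substr(context, start + 1L, end)
  # independent minimal reduction (suffix then prefix)
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    end <- end - 1L
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    start <- start + 1L
    ref <- substring(ref, 2L)
    alt <- substring(alt, 2L)
  }

  if (!nzchar(ref) && !nzchar(alt)) {
    return(list(start = start, end = end, state = "",
                edited = edited, kind = "reference"))
  }
  if (nzchar(ref) && nzchar(alt)) {
    return(list(start = start, end = end, state = alt,
                edited = edited, kind = "substitution"))
  }

  if (nzchar(alt)) {
    # insertion of L characters: placement p is equivalent iff prefix and
    # suffix of the edited sequence agree with the context around p
    L <- nchar(alt)
    ps <- Filter(function(p) {
      substr(edited, 1L, p) == substr(context, 1L, p) &&
        substring(edited, p + L + 1L) == substring(context, p + 1L)
    }, 0:n)
    lo <- min(unlist(ps))
    hi <- max(unlist(ps))
    kind <- "insertion"
  } else {
    # deletion of L characters starting at p
    L <- nchar(ref)
    ps <- Filter(function(p) {
      substr(edited, 1L, p) == substr(context, 1L, p) &&
        substring(edited, p + 1L) == substring(context, p + L + 1L)
    }, 0:(n - L))
    lo <- min(unlist(ps))
    hi <- max(unlist(ps)) + L
    kind <- "deletion"
  }
  state_len <- (hi - lo) + nchar(alt) - nchar(ref)
  list(start = lo, end = hi,
       state = substr(edited, lo + 1L, lo + state_len),
       edited = edited, kind = kind)
}

#' Generate allele normalization fixture cases
#'
#' Produces `n` deterministic cases over repeat-rich sequences (motifs
#' 1-5 bp, 1-8 copies, flanks up to 20 bp, indels up to 10 bp), cycling
#' through substitution, insertion, deletion, reference, homopolymer and
#' microsatellite tags so every tag is represented.  Each case carries
#' the input allele and the expected fully justified interval and state,
#' computed at generation time by [oracle_normalize()] — never by the
#' normalization module itself.
#'
#' @param n Number of cases (`>= 1`).
#' @param seed Integer seed; each case derives its own sub-seed.
#' @return A list of cases, each with `name`, `sequence`, `allele_in`,
#'   `expected_interval`, `expected_state`, `tags`.
#' @export
make_indel_cases <- function(n, seed) {
  stopifnot(n >= 1L)
  tags <- c("substitution", "insertion", "deletion", "reference",
            "homopolymer", "microsatellite")
  lapply(seq_len(n), function(i) {
    tag <- tags[((i - 1L) %% length(tags)) + 1L]
    withr::with_seed(.sub_seed(seed, i), .make_case(i, tag, seed))
  })
}

# derive a per-case 32-bit seed from an arbitrary integer master seed
.sub_seed <- function(seed, i, salt = 0) {
  as.integer((as.numeric(seed) * 1009 + i + salt * 7919) %% 2147483629)
}

.make_case <- function(i, tag, seed) {
  motif_len <- switch(tag,
    homopolymer = 1L,
    microsatellite = sample(2:5, 1L),
    sample(1:5, 1L))
  motif <- .rand_seq(motif_len)
  copies <- sample(1:8, 1L)
  flank <- sample(0:20, 1L)
  sequence <- make_repeat_sequence(motif, copies, flank,
                                   seed = .sub_seed(seed, i, salt = 1))
  n <- nchar(sequence)
  core_start <- flank                      # inter-residue start of the run
  core_end <- flank + copies * motif_len

  edit <- switch(tag,
    substitution = {
      pos <- sample(0:(n - 1L), 1L)
      refc <- substr(sequence, pos + 1L, pos + 1L)
      list(start = pos, end = pos + 1L,
           alt = sample(setdiff(.NUC, refc), 1L))
    },
    reference = {
      s <- sample(0:(n - 1L), 1L)
      e <- min(n, s + sample(1:5, 1L))
      list(start = s, end = e, alt = substr(sequence, s + 1L, e))
    },
    insertion = ,
    homopolymer = ,
    microsatellite = {
      if (stats::runif(1) < 0.5) {
        # insert whole motif copies somewhere in or at the edge of the run
        k <- sample(1:min(3L, max(1L, 10L %/% motif_len)), 1L)
        pos <- sample(core_start:core_end, 1L)
        list(start = pos, end = pos, alt = strrep(motif, k))
      } else {
        # delete a motif-aligned slice of the run (fall back to an
        # arbitrary insertion when the run is too short)
        max_del <- min(core_end - core_start, 10L)
        if (max_del >= motif_len && stats::runif(1) < 0.5) {
          k <- sample(seq_len(max_del %/% motif_len), 1L)
          s <- core_start + (sample(seq_len(copies - k + 1L), 1L) - 1L) *
            motif_len
          list(start = s, end = s + k * motif_len, alt = "")
        } else {
          pos <- sample(0:n, 1L)
          list(start = pos, end = pos, alt = .rand_seq(sample(1:10, 1L)))
        }
      }
    },
    deletion = {
      len <- sample(1:min(10L, n), 1L)
      s <- sample(0:(n - len), 1L)
      list(start = s, end = s + len, alt = "")
    })

  exp <- oracle_normalize(sequence, edit$start, edit$end, edit$alt)
  sq <- paste0("ga4gh:SQ.", sha512t24u(sequence))
  allele <- vrs_allele(
    vrs_sequence_location(sq, c(edit$start, edit$end)), edit$alt)
  if (exp$kind == "reference") {
    # reference-matched alleles are expected back unmodified
    exp$start <- edit$start
    exp$end <- edit$end
    exp$state <- edit$alt
  }
  list(name = paste0("case", i),
       sequence = sequence,
       allele_in = allele,
       expected_interval = c(exp$start, exp$end),
       expected_state = exp$state,
       tags = unique(c(tag, exp$kind)))
}

#' Write a fixture corpus to disk
#'
#' Emits a conformance corpus other implementations can consume: a
#' multi-record FASTA of the case sequences and a JSON Lines file with
#' one case per line (input allele document, expected normalized
#' interval and state, tags).
#'
#' @param cases Output of [make_indel_cases()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the two files written.
#' @export
write_fixture_corpus <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "fixtures.fasta")
  jsonl <- file.path(dir, "fixtures.jsonl")
  fa <- unlist(lapply(cases, function(cs) {
    c(paste0(">", cs$name), cs$sequence)
  }))
  writeLines(fa, fasta)
  lines <- vapply(cases, function(cs) {
    as.character(jsonlite::toJSON(list(
      name = cs$name,
      allele_in = .untypify(cs$allele_in),
      expected_interval = cs$expected_interval,
      expected_state = cs$expected_state,
      tags = cs$tags), auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, jsonl)
  invisible(c(fasta = fasta, jsonl = jsonl))
}
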