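# The computed-identifier algorithm: normalize, serialize, digest
# (SHA-512 truncated to 24 bytes, base64url), prefix.  Plus the birthday-
# bound collision analysis behind the 24-byte choice.

#' Truncated SHA-512 digest (sha512t24u)
#'
#' SHA-512 of the input, truncated to its first 24 bytes and encoded with
#' the base64url alphabet.  24 bytes encode to exactly 32 characters with
#' no padding (24 is divisible by 3); this is enforced, not assumed.
#'
#' @param blob A raw vector, or a character scalar taken as UTF-8 bytes.
#' @return A 32-character digest string over `A-Z a-z 0-9 - _`.
#' @examples
#' sha512t24u("ACGT")  # "aKF498dAxcJAqme6QYQ7EZ07-fiw8Kw2"
#' @export
sha512t24u <- function(blob) {
  if (is.character(blob)) {
    stopifnot(length(blob) == 1L)
    blob <- charToRaw(enc2utf8(blob))
  }
  stopifnot(is.raw(blob))
  h <- unclass(openssl::sha512(blob))[1:24]
  dg <- chartr("+/", "-_", jsonlite::base64_enc(h))
  if (nchar(dg) != 32L || grepl("=", dg, fixed = TRUE)) {
    stop("internal error: truncated digest must be 32 unpadded characters",
         call. = FALSE)
  }
  dg
}

#' Bare digest of an identifiable object
#'
#' The 32-character sha512t24u digest of the object's canonical digest
#' serialization, without namespace or type prefix.
#'
#' @param obj An identifiable `vrs_object` or a sequence string.
#' @return A 32-character digest string.
#' @export
ga4gh_digest <- function(obj) {
  sha512t24u(digest_serialize(obj))
}

#' Compute a globally consistent identifier for a VRS object
#'
#' Runs the four-operation identifier algorithm: (1) normalize, using the
#' type's normalization rules where they exist (currently literal-state
#' alleles, when a sequence store is supplied); (2) digest-serialize to
#' canonical bytes; (3) hash with SHA-512 truncated to 24 bytes,
#' base64url-encoded; (4) prepend the class prefix and `ga4gh` namespace.
#' Equal objects always receive equal identifiers, and an allele built
#' through any alias of a sequence identifies identically because aliases
#' are resolved to the one `ga4gh:SQ` digest before serialization.
#'
#' A character scalar is treated as a raw sequence and identified as
#' `ga4gh:SQ.<digest of its bytes>` (no JSON wrapper).
#'
#' @param obj An identifiable `vrs_object`, or a sequence string.
#' @param store Optional [vrs_sequence_store()]; required to resolve
#'   non-`ga4gh` `sequence_id`s and to normalize alleles.
#' @param normalize Normalize before identification (strongly
#'   recommended)?  Types without normalization rules are identified
#'   as-is either way.
#' @return The identifier CURIE, e.g. `"ga4gh:VA.<32-char digest>"`.
#' @examples
#' store <- vrs_sequence_store(c(tiny1 = "CCTAC"))
#' al <- vrs_allele(vrs_sequence_location("local:tiny1", c(1, 2)), "T")
#' ga4gh_identify(al, store)
#' @export
ga4gh_identify <- function(obj, store = NULL, normalize = TRUE) {
  if (.is_scalar_chr(obj)) {
    return(paste0("ga4gh:SQ.", sha512t24u(digest_serialize(obj))))
  }
  if (!is.list(obj) || !.is_scalar_chr(obj[["type"]])) {
    stop("not a typed VRS object", call. = FALSE)
  }
  if (!is_identifiable(obj$type)) {
    stop(obj$type, " is not identifiable", call. = FALSE)
  }
  if (!is.null(store)) {
    obj <- .resolve_sequence_ids(obj, store)
    if (normalize && obj$type == "Allele") {
      obj <- vrs_normalize(obj, store)
    }
  }
  prefix <- .vrs_type_info(obj$type)$prefix
  paste0("ga4gh:", prefix, ".", ga4gh_digest(obj))
}

# Rewrite every sequence_id in the object to its ga4gh:SQ alias.
.resolve_sequence_ids <- function(obj, store) {
  if (!is.list(obj)) return(obj)
  if (!is.null(obj[["sequence_id"]]) &&
      !startsWith(obj[["sequence_id"]], "ga4gh:")) {
    sq <- translate_sequence_identifier(store, obj[["sequence_id"]], "ga4gh")
    if (length(sq) == 0L) {
      stop("no ga4gh alias known for ", obj[["sequence_id"]], call. = FALSE)
    }
    obj[["sequence_id"]] <- sq[[1]]
  }
  cls <- class(obj)
  out <- lapply(obj, function(v) {
    if (is.list(v)) .resolve_sequence_ids(v, store) else v
  })
  class(out) <- cls
  out
}

#' Birthday-bound collision analysis for truncated digests
#'
#' For a corpus of `m` messages hashed to `b`-bit digests, the collision
#' probability is approximately `P = m^2 / 2^(b + 1)` (clipped to
#' `[0, 1]`); inverting gives the digest length needed for a target
#' probability, `b = log2(m^2 / P) - 1`.  Message length is irrelevant.
#' With the 24-byte (192-bit) digest used here, a corpus of 1e18 objects
#' has a collision probability below 1e-21.
#'
#' @param m Number of messages in the corpus (`>= 0`; `>= 1` for
#'   `min_digest_bits()`).
#' @param b Digest length in bits.
#' @param P Target collision probability in `(0, 1]`.
#' @return `collision_probability()`: a probability; `min_digest_bits()`:
#'   a (possibly fractional) number of bits.
#' @examples
#' collision_probability(1e18, 192)   # ~7.97e-23
#' min_digest_bits(1e18, 1e-21)       # ~188.4, so 24 bytes suffice
#' @export
collision_probability <- function(m, b) {
  stopifnot(m >= 0, b > 0)
  min(1, m^2 / 2^(b + 1))
}

#' @rdname collision_probability
#' @export
min_digest_bits <- function(m, P) {
  stopifnot(m >= 1)
  if (P <= 0 || P > 1) stop("P must be in (0, 1]", call. = FALSE)
  2 * log2(m) - log2(P) - 1
}
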