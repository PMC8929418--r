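# Shared fixtures.  Digests marked "frozen" were computed with an
# independent SHA-512/base64url implementation outside this package.

SQ_EMPTY <- "z4PhNX7vuL3xVChQ1m2AB9Yg5AULVxXc"   # frozen: sha512t24u("")
SQ_ACGT  <- "aKF498dAxcJAqme6QYQ7EZ07-fiw8Kw2"   # frozen: sha512t24u("ACGT")
SQ_CCTAC <- "hB3nKSRQEGv2Nevr0iAvsnFn62K9W8r5"   # frozen: sha512t24u("CCTAC")
# frozen: digest of the SequenceLocation {CCTAC, (1,2)} and of the C>T Allele
VSL_CCTAC_1_2 <- "hEfiKs6JZ5_CQX9uLA5KaDZhOU2rYybh"
VA_CCTAC_C2T  <- "_tuB2s92J_hj4nXsuk7enw3gKsJzCN7Y"

tiny_store <- function() {
  vrs_sequence_store(c(tiny1 = "CCTAC", rep1 = "TTACACACAGG"))
}

tiny_allele <- function(start = 1, end = 2, state = "T",
                        sequence_id = "local:tiny1") {
  vrs_allele(vrs_sequence_location(sequence_id, c(start, end)), state)
}

# document for the C>T allele with keys in an arbitrary order
shuffled_doc <- function(doc, seed) {
  withr::with_seed(seed, {
    shuffle <- function(x) {
      if (!is.list(x)) return(x)
      nms <- names(x)
      if (!is.null(nms)) x <- x[sample(nms)]
      lapply(x, shuffle)
    }
    shuffle(x = doc)
  })
}

allele_doc <- function(start = 1L, end = 2L, state = "T",
                       sequence_id = paste0("ga4gh:SQ.", SQ_CCTAC)) {
  list(type = "Allele",
       location = list(type = "SequenceLocation",
                       sequence_id = sequence_id,
                       interval = list(type = "SequenceInterval",
                                       start = list(type = "Number",
                                                    value = start),
                                       end = list(type = "Number",
                                                  value = end))),
       state = list(type = "LiteralSequenceExpression", sequence = state))
}

write_tiny_fasta <- function(records = c(tiny1 = "CCTAC"),
                             path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(records), function(nm) {
    c(paste0(">", nm), records[[nm]])
  })), path)
  path
}

# apply an allele's edit to its full sequence (used to check edit
# preservation without going through the package's normalization)
apply_allele <- function(context, allele) {
  iv <- allele$location$interval
  paste0(substr(context, 1, iv$start$value),
         allele$state$sequence,
         substring(context, iv$end$value + 1))
}
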