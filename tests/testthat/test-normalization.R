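test_that("flank trimming removes the common suffix before the prefix", {
  expect_equal(trim_common_flanks("TCA", "GCA"),
               list(ref = "T", alt = "G", suffix_len = 2L, prefix_len = 0L))
  # identical strings vanish entirely into the suffix pass
  expect_equal(trim_common_flanks("A", "A"),
               list(ref = "", alt = "", suffix_len = 1L, prefix_len = 0L))
  expect_equal(trim_common_flanks("", "G"),
               list(ref = "", alt = "G", suffix_len = 0L, prefix_len = 0L))
  expect_equal(trim_common_flanks("ACGT", "AGT"),
               list(ref = "C", alt = "", suffix_len = 2L, prefix_len = 1L))
})

test_that("rolling finds the bounds of ambiguity", {
  expect_equal(roll_bounds("TTACACACAGG", 9, "CA"),
               list(left_roll_bound = 2L, right_roll_bound = 9L))
  # homopolymer rolls to both sequence boundaries
  expect_equal(roll_bounds("AAAA", 4, "A"),
               list(left_roll_bound = 0L, right_roll_bound = 4L))
  # no neighboring match: no roll
  expect_equal(roll_bounds("GATTACA", 3, "C"),
               list(left_roll_bound = 3L, right_roll_bound = 3L))
})

test_that("reference alleles are returned unmodified", {
  store <- tiny_store()
  ref <- tiny_allele(1, 2, "C")   # matches the reference base
  out <- vrs_normalize(ref, store)
  expect_true(vrs_equal(out, ref))
  # even in a repetitive region, an asserted reference span is kept
  rep_ref <- vrs_allele(vrs_sequence_location("local:rep1", c(3, 5)), "CA")
  expect_true(vrs_equal(vrs_normalize(rep_ref, store), rep_ref))
})

test_that("substitutions keep their coordinates", {
  store <- tiny_store()
  out <- vrs_normalize(tiny_allele(1, 2, "T"), store)
  expect_identical(out$location$interval$start$value, 1L)
  expect_identical(out$location$interval$end$value, 2L)
  expect_identical(out$state$sequence, "T")
  # flanks shared with the reference are trimmed off a substitution
  wide <- tiny_allele(0, 4, "CGTA")   # ref CCTA -> only position 1 changes
  out <- vrs_normalize(wide, store)
  expect_identical(out$location$interval$start$value, 1L)
  expect_identical(out$location$interval$end$value, 2L)
  expect_identical(out$state$sequence, "G")
})

test_that("a repeat insertion is fully justified over the ambiguity region", {
  store <- tiny_store()
  ins <- vrs_allele(vrs_sequence_location("local:rep1", c(9, 9)), "CA")
  out <- vrs_normalize(ins, store)
  expect_identical(out$location$interval$start$value, 2L)
  expect_identical(out$location$interval$end$value, 9L)
  expect_identical(out$state$sequence, "ACACACACA")
  # the same edit expressed at the other end of the run converges
  ins5 <- vrs_allele(vrs_sequence_location("local:rep1", c(2, 2)), "AC")
  expect_true(vrs_equal(vrs_normalize(ins5, store), out))
})

test_that("unsupported alleles pass through with a not-normalized signal", {
  store <- tiny_store()
  ranged <- vrs_allele(
    vrs_sequence_location("local:tiny1",
                          vrs_sequence_interval(vrs_indefinite_range(1, "<="),
                                                vrs_number(3))),
    "T")
  out <- vrs_normalize(ranged, store)
  expect_match(attr(out, "vrs_not_normalized"), "definite")

  rse <- vrs_allele(
    vrs_sequence_location("local:rep1", c(2, 9)),
    vrs_repeated_sequence_expression(
      vrs_literal_sequence_expression("CA"), 4))
  expect_match(attr(vrs_normalize(rse, store), "vrs_not_normalized"),
               "Literal")

  chrom <- vrs_allele(
    vrs_chromosome_location("taxonomy:9606", "11",
                            vrs_cytoband_interval("q22.2", "q22.3")),
    "T")
  expect_match(attr(vrs_normalize(chrom, store), "vrs_not_normalized"),
               "SequenceLocation")

  # unresolvable locations are a hard error, not a signal
  missing <- vrs_allele(vrs_sequence_location("local:absent", c(0, 1)), "T")
  expect_error(vrs_normalize(missing, store), "unknown")
  beyond <- tiny_allele(3, 9, "T")
  expect_error(vrs_normalize(beyond, store), "exceeds")
})

test_that("normalization agrees with the brute-force oracle and preserves edits", {
  cases <- make_indel_cases(120, seed = 42)
  for (cs in cases) {
    store <- vrs_sequence_store(stats::setNames(cs$sequence, cs$name))
    out <- vrs_normalize(cs$allele_in, store)
    iv <- out$location$interval
    expect_identical(c(iv$start$value, iv$end$value),
                     as.integer(cs$expected_interval))
    expect_identical(out$state$sequence, cs$expected_state)
    # edit preservation: the normalized allele reproduces the edited
    # sequence of the input allele
    expect_identical(apply_allele(cs$sequence, out),
                     apply_allele(cs$sequence, cs$allele_in))
    # idempotence
    expect_true(vrs_equal(vrs_normalize(out, store), out))
  }
})
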