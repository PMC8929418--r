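test_that("SPDI expressions parse to alleles on inter-residue coordinates", {
  store <- tiny_store()
  al <- parse_spdi("local:tiny1:1:1:T", store)
  expect_identical(al$location$interval$start$value, 1L)
  expect_identical(al$location$interval$end$value, 2L)
  expect_identical(al$state$sequence, "T")
  expect_match(al$location$sequence_id, "^ga4gh:SQ\\.")

  ins <- parse_spdi("local:tiny1:3:0:G", store)
  expect_identical(ins$location$interval$start$value, 3L)
  expect_identical(ins$location$interval$end$value, 3L)

  # sequence-form deletion is validated against the store
  expect_true(vrs_equal(parse_spdi("local:tiny1:1:C:T", store), al))
  expect_error(parse_spdi("local:tiny1:1:A:T", store), "does not match")
  expect_error(parse_spdi("local:tiny1:1:1", store), "malformed")
  expect_error(parse_spdi("local:absent:1:1:T", store), "unknown")
})

test_that("SPDI formatting inverts parsing", {
  store <- tiny_store()
  al <- parse_spdi("local:tiny1:1:1:T", store)
  expect_identical(format_spdi(al, store), "local:tiny1:1:1:T")
  refm <- tiny_allele(1, 2, "C")
  expect_identical(format_spdi(refm, store), "local:tiny1:1:1:C")
  norm <- vrs_normalize(
    vrs_allele(vrs_sequence_location("local:rep1", c(9, 9)), "CA"), store)
  expect_identical(format_spdi(norm, store), "local:rep1:2:7:ACACACACA")
  expect_error(format_spdi(al, store, namespace = "ensembl"), "no alias")
})

test_that("HGVS residue coordinates convert to inter-residue intervals", {
  store <- tiny_store()
  al <- parse_hgvs("local:tiny1:g.2C>T", store)
  expect_identical(al$location$interval$start$value, 1L)
  expect_identical(al$location$interval$end$value, 2L)
  expect_identical(al$state$sequence, "T")

  del <- parse_hgvs("local:tiny1:g.3_4del", store)
  expect_identical(del$location$interval$start$value, 2L)
  expect_identical(del$location$interval$end$value, 4L)
  expect_identical(del$state$sequence, "")

  ins <- parse_hgvs("local:tiny1:g.3_4insGG", store)
  expect_identical(ins$location$interval$start$value, 3L)
  expect_identical(ins$location$interval$end$value, 3L)
  expect_identical(ins$state$sequence, "GG")

  di <- parse_hgvs("local:tiny1:g.2_3delinsAA", store)
  expect_identical(di$location$interval$start$value, 1L)
  expect_identical(di$state$sequence, "AA")

  # asserted reference residues are checked against the store
  expect_true(vrs_equal(
    parse_hgvs("local:tiny1:g.2C>G", store),
    vrs_allele(vrs_sequence_location(paste0("ga4gh:SQ.", SQ_CCTAC),
                                     c(1, 2)), "G")))
  expect_error(parse_hgvs("local:tiny1:g.2A>G", store), "asserted reference")
  expect_error(parse_hgvs("local:tiny1:g.3_4delTT", store),
               "asserted reference")
  expect_error(parse_hgvs("local:tiny1:g.99C>T", store), "out of bounds")
  expect_error(parse_hgvs("local:tiny1:g.3_5insGG", store), "adjacent")
  expect_error(parse_hgvs("local:tiny1:c.76A>T", store), "cannot parse")
  expect_error(parse_hgvs("NC_000001.10:g.(?_15764950)_(15765020_?)dup",
                          store),
               "uncertain")
})

test_that("duplications become molecular insertions after the span", {
  store <- tiny_store()
  dup <- parse_hgvs("local:rep1:g.8_9dup", store)
  expect_identical(dup$location$interval$start$value, 9L)
  expect_identical(dup$location$interval$end$value, 9L)
  expect_identical(dup$state$sequence, "CA")
  expect_identical(dup$type, "Allele")  # never a CopyNumber
  single <- parse_hgvs("local:tiny1:g.2dup", store)
  expect_identical(single$state$sequence, "C")
  expect_identical(single$location$interval$start$value, 2L)
})

test_that("HGVS formatting right-shifts to the 3'-most representation", {
  store <- tiny_store()
  expect_identical(format_hgvs(tiny_allele(1, 2, "T"), store),
                   "local:tiny1:g.2C>T")
  # fully justified repeat insertion renders as the 3'-most dup
  norm <- vrs_normalize(
    vrs_allele(vrs_sequence_location("local:rep1", c(2, 2)), "AC"), store)
  expect_identical(format_hgvs(norm, store), "local:rep1:g.8_9dup")
  # fully justified deletion renders as the 3'-most del
  ndel <- vrs_normalize(
    vrs_allele(vrs_sequence_location("local:rep1", c(2, 4)), ""), store)
  expect_identical(format_hgvs(ndel, store), "local:rep1:g.8_9del")
  # reference agreement form
  expect_identical(format_hgvs(tiny_allele(1, 2, "C"), store),
                   "local:tiny1:g.2C=")
  # non-repeat insertion renders as ins
  al <- parse_hgvs("local:tiny1:g.3_4insGG", store)
  expect_identical(format_hgvs(al, store), "local:tiny1:g.3_4insGG")
})

test_that("substitution positions survive a parse/format round trip", {
  store <- tiny_store()
  for (pos in 1:5) {
    ref <- get_sequence(store, "local:tiny1", pos - 1, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    expr <- paste0("local:tiny1:g.", pos, ref, ">", alt)
    expect_identical(format_hgvs(parse_hgvs(expr, store), store), expr)
  }
})

test_that("translator round trips preserve computed identifiers", {
  cases <- make_indel_cases(60, seed = 7)
  for (cs in cases) {
    store <- vrs_sequence_store(stats::setNames(cs$sequence, cs$name))
    a <- vrs_normalize(cs$allele_in, store)
    id_a <- ga4gh_identify(a, store)
    # SPDI round trip is the identity on normalized alleles
    spdi <- format_spdi(a, store)
    expect_true(vrs_equal(parse_spdi(spdi, store), a))
    expect_identical(ga4gh_identify(parse_spdi(spdi, store), store), id_a)
    # HGVS round trip converges to the same identifier
    hgvs <- tryCatch(format_hgvs(a, store), error = function(e) e)
    if (inherits(hgvs, "error")) {
      # only insertions butting the 5' sequence start are inexpressible
      expect_match(conditionMessage(hgvs), "first residue")
      next
    }
    expect_identical(ga4gh_identify(parse_hgvs(hgvs, store), store), id_a)
  }
})

test_that("HGVS and SPDI renderings of one variant converge", {
  store <- tiny_store()
  via_hgvs <- parse_hgvs("local:tiny1:g.2C>T", store)
  via_spdi <- parse_spdi("local:tiny1:1:1:T", store)
  expect_identical(ga4gh_identify(via_hgvs, store),
                   ga4gh_identify(via_spdi, store))
  dup_h <- parse_hgvs("local:rep1:g.8_9dup", store)
  dup_s <- parse_spdi("local:rep1:2:7:ACACACACA", store)
  expect_identical(ga4gh_identify(dup_h, store),
                   ga4gh_identify(dup_s, store))
})
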