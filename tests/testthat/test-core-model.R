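test_that("well-formed documents validate cleanly and parse to typed objects", {
  doc <- allele_doc()
  expect_equal(nrow(vrs_validate(doc)), 0)
  obj <- vrs_parse(doc)
  expect_s3_class(obj, "vrs_object")
  expect_identical(obj$type, "Allele")
  expect_identical(obj$location$interval$start$value, 1L)
})

test_that("violations are reported with their kind", {
  doc <- allele_doc()
  doc$location <- NULL
  rep <- vrs_validate(doc)
  expect_equal(nrow(rep), 1)
  expect_identical(rep$code, "missing_field")
  expect_match(rep$message, "location")

  bad_iv <- list(type = "SequenceInterval",
                 start = list(type = "Number", value = 5L),
                 end = list(type = "Number", value = 2L))
  rep <- vrs_validate(bad_iv)
  expect_identical(rep$code, "invariant")
  expect_match(rep$message, "start must be <= end")

  # a document with no discriminator is malformed, not field-invalid
  expect_identical(vrs_validate(list(foo = 1))$code, "malformed")
  expect_identical(vrs_validate(list(type = "Nonsense"))$code, "unknown_type")

  doc <- allele_doc()
  doc$label <- "BRAF V600E"   # extraneous labels are rejected
  expect_identical(vrs_validate(doc)$code, "extra_field")
})

test_that("string primitives are pattern-checked", {
  expect_error(vrs_sequence_location("no-colon-here ", c(0, 1)), "invalid")
  expect_error(vrs_literal_sequence_expression("ACGT7"), "invalid")
  expect_error(
    vrs_chromosome_location("taxonomy:9606", "11",
                            vrs_cytoband_interval("x22", "q23")),
    "invalid")
  loc <- vrs_chromosome_location("taxonomy:9606", "11",
                                 vrs_cytoband_interval("pter", "q22.3"))
  expect_identical(loc$chr, "11")
  expect_error(
    vrs_chromosome_location("taxonomy:9606", "chr11",
                            vrs_cytoband_interval("p11", "q11")),
    "chr")
})

test_that("identifiability follows the class hierarchy", {
  expect_true(is_identifiable("Allele"))
  expect_true(is_identifiable("ChromosomeLocation"))
  expect_true(is_identifiable("SequenceLocation"))
  expect_true(is_identifiable("Haplotype"))
  expect_true(is_identifiable("Text"))
  expect_true(is_identifiable("VariationSet"))
  expect_true(is_identifiable("CopyNumber"))
  expect_false(is_identifiable("SequenceInterval"))
  expect_false(is_identifiable("LiteralSequenceExpression"))
  expect_false(is_identifiable("Number"))
  expect_false(is_identifiable("Gene"))
  expect_error(is_identifiable("Genotype"), "unknown")
})

test_that("value equality ignores the optional _id and field order", {
  a <- tiny_allele()
  b <- vrs_allele(vrs_sequence_location("local:tiny1", c(1, 2)), "T",
                  id = "mydb:variant42")
  expect_true(vrs_equal(a, b))
  expect_false(vrs_equal(a, tiny_allele(state = "G")))
  shuffled <- vrs_parse(shuffled_doc(allele_doc(), seed = 5))
  plain <- vrs_parse(allele_doc())
  expect_true(vrs_equal(shuffled, plain))
})

test_that("valid objects survive a JSON round trip", {
  objs <- list(
    tiny_allele(),
    vrs_text("del Phe508", id = "mydb:1"),
    vrs_haplotype(list(tiny_allele(), tiny_allele(state = "G"))),
    vrs_copy_number(vrs_gene(gene_id = "hgnc:1097"),
                    vrs_indefinite_range(3, ">=")),
    vrs_derived_sequence_expression(
      vrs_sequence_location("local:tiny1", c(0, 5)), TRUE),
    vrs_repeated_sequence_expression(
      vrs_literal_sequence_expression("CAG"), vrs_definite_range(36, 40)))
  for (obj in objs) {
    back <- vrs_from_json(vrs_to_json(obj))
    expect_equal(nrow(vrs_validate(back)), 0)
    expect_true(vrs_equal(obj, back))
  }
})

test_that("range and count invariants are enforced", {
  expect_error(vrs_definite_range(5, 2), "min")
  expect_error(vrs_indefinite_range(1, "=="), "invalid")
  expect_error(vrs_sequence_interval(-1, 2), "start must be >= 0")
  expect_error(
    vrs_repeated_sequence_expression(
      vrs_literal_sequence_expression("CA"), -2),
    "count")
  expect_error(vrs_text(""), "definition")
  expect_error(vrs_haplotype(list()), "members")
})

test_that("haplotype and set members are de-duplicated by value", {
  a1 <- tiny_allele()
  a2 <- vrs_allele(vrs_sequence_location("local:tiny1", c(1, 2)), "T",
                   id = "mydb:other")  # same value, different _id
  expect_error(vrs_haplotype(list(a1, a2)), "duplicate")
  expect_error(vrs_variation_set(list(a1, tiny_allele(state = "G"), a1)),
               "duplicate")
  # an inline member duplicates its own CURIE reference
  sq_allele <- vrs_allele(
    vrs_sequence_location(paste0("ga4gh:SQ.", SQ_CCTAC), c(1, 2)), "T")
  curie <- ga4gh_identify(sq_allele)
  expect_error(vrs_haplotype(list(sq_allele, curie)), "duplicate")
  hap <- vrs_haplotype(list(sq_allele, tiny_allele(state = "G")))
  expect_length(hap$members, 2)
})

test_that("sequence characters are uppercase-folded on ingestion", {
  expect_identical(vrs_literal_sequence_expression("acgt")$sequence, "ACGT")
})
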