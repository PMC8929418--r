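Package: vrsr
Title: Value-Object Representation and Federated Identification of Sequence Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Immutable value-object types for the GA4GH Variation
    Representation Specification (VRS): alleles, haplotypes, copy number
    and their supporting locations, intervals and sequence expressions,
    all on strict inter-residue coordinates.  Provides fully justified
    allele normalization (the Variant Overprecision Correction
    Algorithm), canonical digest serialization, and globally consistent
    computed identifiers built from truncated SHA-512 digests
    (sha512t24u).  Includes a FASTA-backed sequence store implementing
    the DataProxy contract, translation to and from HGVS and SPDI
    variant notation, a deterministic fixture generator with an
    independent brute-force normalization oracle, machine-readable
    schema emission, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    openssl,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
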