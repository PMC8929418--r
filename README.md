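# vrsr

An R implementation of the GA4GH Variation Representation Specification
(VRS): immutable value-object types for molecular and systemic sequence
variation, fully justified allele normalization, canonical digest
serialization, and globally consistent computed identifiers, with
translation to and from the HGVS and SPDI variant nomenclatures.

## The problem

Exchanging variant data between databases, clinical labs and pipelines
founders on two ambiguities. First, the *same* variant has many names:
an insertion in a microsatellite can be written at any position within
the repeat, on a RefSeq or Ensembl accession, in HGVS or SPDI or VCF
conventions. Second, registry identifiers (rsIDs, ClinVar accessions)
are assigned, not computed, so two systems cannot agree on an identifier
without prior negotiation.

VRS resolves both by modeling variation as **value objects** — minimal,
immutable objects defined entirely by their content — and deriving
identifiers from that content:

1. **Inter-residue coordinates.** Positions count the spaces *between*
   residues, so an interval `(a, b)` spans `b − a` residues and `(a, a)`
   is an insertion point. One location convention serves substitutions,
   deletions and insertions alike.
2. **Fully justified normalization** (the Variant Overprecision
   Correction Algorithm, VOCA). An ambiguous indel is *rolled* left and
   right through its repeat context; the normalized allele covers the
   entire region of ambiguity `[left_roll_bound, right_roll_bound)`
   instead of an arbitrary left- or right-aligned point.
3. **Computed identifiers.** An identifiable object is serialized to a
   canonical JSON byte string (nested identifiable objects replaced by
   their digests, keys in code-point order, no insignificant
   whitespace), hashed with SHA-512 truncated to 24 bytes, base64url
   encoded (`sha512t24u`, 32 characters), and prefixed:
   `ga4gh:VA.<digest>`. For a corpus of *m* objects and a *b*-bit
   digest, the collision probability is `P ≈ m² / 2^(b+1)`; at
   `b = 192` and `m = 10¹⁸`, `P < 10⁻²¹`.

Equivalent descriptions — any alias of the sequence, any placement of
the indel, HGVS or SPDI spelling — converge to the same identifier with
no registry in the loop.

## Worked example

```r
library(vrsr)

# a sequence store: FASTA-backed in practice (vrs_read_fasta), in-memory here
store <- vrs_sequence_store(c(tiny1 = "CCTAC", rep1 = "TTACACACAGG"))

# a C>T substitution at residue 2 of CCTAC (inter-residue interval (1, 2))
al <- vrs_allele(vrs_sequence_location("local:tiny1", c(1, 2)), "T")
ga4gh_identify(al, store)
#> [1] "ga4gh:VA._tuB2s92J_hj4nXsuk7enw3gKsJzCN7Y"

# a CA duplication inside the (CA)n microsatellite of rep1, parsed from HGVS
ins <- parse_hgvs("local:rep1:g.8_9dup", store)
norm <- vrs_normalize(ins, store)
norm$location$interval$start$value   #> 2
norm$location$interval$end$value     #> 9
norm$state$sequence                  #> "ACACACACA"
```

The normalized allele replaces the whole ambiguous repeat region
`(2, 9)` (`ACACACA`) with `ACACACACA` — one more `CA` unit — rather than
pinning the insertion to one of its eight equivalent positions. All
spellings of this event identify identically:

```r
format_spdi(norm, store)        #> "local:rep1:2:7:ACACACACA"
format_hgvs(norm, store)        #> "local:rep1:g.8_9dup"  (3'-shifted, per HGVS)
ga4gh_identify(norm, store)     #> "ga4gh:VA.03salJbPVbBSzTHI26nHXehF7L1KGpIE"

collision_probability(1e18, 192)
#> [1] 7.96546e-23
```

A command-line front end covers the same operations over FASTA and JSON
Lines streams:

```sh
inst/cli/vrs-tool translate --from hgvs --to spdi --fasta genome.fa < variants.txt
inst/cli/vrs-tool identify --fasta genome.fa < alleles.jsonl
```

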