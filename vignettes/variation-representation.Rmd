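---
title: "Value-object variation representation: model, normalization, identifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value-object variation representation: model, normalization, identifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrsr)
```

## The information model

`vrsr` models sequence variation as **value objects**: immutable objects
whose identity is exactly their content. An `Allele` is a location plus
an asserted state; it carries no accession, no gene symbol, no label —
anything extraneous to the variation itself is rejected at validation.
The released classes fall into four groups:

* **Variation** — `Allele`, `Haplotype`, `Text`, `VariationSet`,
  `CopyNumber`. `Allele` and `Haplotype` describe *molecular* variation
  (the state of one contiguous molecule); `CopyNumber` describes
  *systemic* variation (an aggregate quantity over a genome or cell).
  The distinction is deliberate: a tandem duplication and a copy-number
  gain are different claims, and conflating them is a known source of
  misinterpretation in clinical reporting.
* **Location** — `SequenceLocation` (an interval on an identified
  sequence) and `ChromosomeLocation` (a cytoband interval).
* **SequenceExpression** — literal, derived-from-location, and repeated
  subsequence forms.
* **General purpose** — `Number`, `DefiniteRange`, `IndefiniteRange`,
  the two interval types, `Gene`.

Only Variation, Location, and raw sequences are *identifiable*; an
interval or a sequence expression has no meaning in isolation and never
receives an identifier. R's copy-on-modify semantics give the
immutability contract for free: every transformation in the package
returns a new object.

All classes validate against a single internal registry, which is also
the source for `emit_schema()`; there is no second, hand-maintained
schema to drift out of step. The schema language does not express
every invariant (member de-duplication, interval ordering when
endpoints are ranges), so `vrs_validate()` remains the authoritative
check; `schema_validate()` is an independent interpreter used to verify
agreement on structural violations.

### Coordinates

All coordinates are **inter-residue**: they count the spaces between
residues, so interval `(a, b)` spans `b − a` residues, `(a, a)` is an
insertion point, and no knowledge of the edit type is needed to
interpret a location. The package exposes *no* residue-numbered entry
point anywhere — conversion happens only at the HGVS boundary, where
residue `n` maps to `(n − 1, n)`. This prevents the classic
off-by-one family of errors that arises when 0-based, 1-based and
inter-residue conventions mix inside one code base.

### Validation patterns

The model requires regex validation for CURIEs and cytoband
designators but fixes no particular patterns; the ones here are package
choices: a CURIE is `^[A-Za-z0-9._~-]+:\S+$` (non-empty namespace
without a colon, non-empty reference), a sequence is `^[A-Z*]*$`
(the union of IUPAC nucleic and amino alphabets, including ambiguity
codes and the stop `*`), and a cytoband is
`^(pter|qter|[pq][1-9][0-9]*(\.[0-9]+)*)$`. Sequences are folded to
uppercase on ingestion because digests are byte-sensitive: a mixed-case
`acgt`/`ACGT` pair would otherwise silently split one variant into two
identifiers. The same reasoning applies to the open question of
whether sequence digests are computed over case-folded bytes — this
package folds first, and states so here because it affects identifier
equality with implementations that do not.

## Allele normalization (VOCA)

An indel inside a repeat can be written at any equivalent position.
Left- and right-aligning conventions (VCF, HGVS) pick an arbitrary
endpoint; this package instead *fully justifies*: the normalized allele
covers the whole region of ambiguity. The procedure, for alleles with
a definite `SequenceLocation` and a literal state:

0. Read the reference allele sequence at the location; let `start`,
   `end` be the location's endpoints.
1. Trim the common **suffix first**, then the common prefix, adjusting
   `end` and `start`. Suffix-first order matters: for `TCA → GCA` it
   yields `T → G`, not a different residue assignment.
2. If both trimmed sequences are empty the input is a reference
   allele and is returned **unmodified** — asserting a span of
   reference sequence is a meaningful statement of state, even inside
   a repeat, and must not be rewritten. If both are non-empty the
   allele is a substitution; return it with trimmed coordinates.
3. Otherwise exactly one sequence is non-empty (an insertion or
   deletion). Roll a *working copy* of it: leftwards while its **last**
   base equals the base preceding the left bound (circularly permuting
   last-to-front each step), rightwards while its **first** base equals
   the base following the right bound (first-to-back).
4. Return a new allele on `[left_roll_bound, right_roll_bound)` whose
   state is the left context + the **original** alternate sequence +
   the right context.

Three readings of the written procedure are ambiguous, and each is
resolved here by an apply-and-compare criterion — the normalized allele
must reproduce exactly the edited sequence of the input, and its
interval must equal the span of all equivalent placements found by
brute-force enumeration:

* The right roll starts at `end`, not `start`. The two coincide for
  insertions; for deletions, starting at `start` double-counts the
  deleted span and fails edit preservation.
* Step 4 uses the original (unpermuted) alternate sequence; the
  circular permutations of step 3 exist only to detect rolling and are
  discarded. Feeding a permuted copy into step 4 breaks edit
  preservation for repeat insertions.
* "Terminal base" means the last character for the left roll and the
  first for the right roll; only that reading satisfies the oracle.

Other numerical choices: rolling halts at coordinates 0 and the
sequence length (no circular-genome wrap — the model targets linear
assemblies); base comparison is exact byte equality, so IUPAC ambiguity
codes never match other codes (an `N` does not roll through an `A`
run), keeping normalization deterministic and digest-stable.
Normalization reads only the located span plus the rolled context, so
it works against streaming or sliced sequence backends.

Alleles the rules do not cover — ranged endpoints, repeated or derived
sequence expressions, cytoband locations — pass through unchanged with
a `vrs_not_normalized` attribute naming the reason; an unresolvable
sequence or an out-of-range interval is a hard error instead, on the
view that a location pointing outside its sequence is caller error, not
an alternative representation.

Normalization is applied by default when computing identifiers but can
be disabled per call (`normalize = FALSE`): an allele may be read
either as a minimal description of change (normalize it) or as an
assertion of literal state (leave it alone), and forcing normalization
would make the second view inexpressible.

## Digest serialization and computed identifiers

Identifiers are derived, not assigned. The serialization that feeds
the hash is distinct from display JSON: nested identifiable objects are
replaced by their bare 32-character digests, `sequence_id` CURIEs are
reduced to their digest segment, member arrays are sorted by code
point, underscore-prefixed (`_id`) and null fields are dropped, and the
result is rendered as canonical JSON — UTF-8, keys in code-point order,
no insignificant whitespace, two-character escapes where RFC 8259
defines them. Every numeric field in the released classes is an
integer and serializes in minimal decimal form, which sidesteps the
canonical-float problem entirely. Array sorting applies only to arrays
of digests/ids (haplotype and set members); no other arrays exist in
the released classes.

The digest is SHA-512 truncated to its first 24 bytes, base64url
encoded: 32 characters, never padded (24 is divisible by 3; the code
enforces rather than assumes this). The identifier is
`ga4gh:<prefix>.<digest>` with a fixed class-prefix table (`VA`
alleles, `VSL` sequence locations, `SQ` raw sequences, ...). Raw
sequences digest their residue bytes directly, with no JSON wrapper, so
a sequence's identifier is a function of nothing but its residues.

Because object references must be in the `ga4gh` namespace before
digesting, `ga4gh_identify()` resolves accessions through the sequence
store first; this is precisely what makes identification
synonym-invariant — `refseq:...`, `ensembl:...` and `local:...`
aliases of one sequence collapse to one `SQ` digest before the allele
is hashed. `species_id` and `gene_id` are concept references, not
object references, and keep their CURIE form in the blob.

The 24-byte length is justified by the birthday bound
`P ≈ m²/2^(b+1)`: for 10¹⁸ messages, 192 bits give
`P ≈ 8 × 10⁻²³ < 10⁻²¹`, and inverting (`b = log2(m²/P) − 1`) shows
~188.4 bits suffice, so 24 bytes leave headroom.

## Translators

SPDI positions are inter-residue already, so translation is direct;
the deletion field may be a length or an asserted sequence, the latter
checked against the store. HGVS support is the linear-coordinate
subset (`g.`, `m.`, `n.`): substitution, identity, del, ins, delins,
dup. Transcript `c.` (UTR/intron offsets) and protein `p.` coordinates
are out of scope, as are uncertain breakpoints (`(?_123)`), which are
rejected with a specific error rather than approximated. A `dup` is
translated as a molecular insertion of the duplicated span immediately
after that span, never as a `CopyNumber` — duplication syntax asserts a
tandem event on a molecule, and a systemic copy-number claim must be
made explicitly. On output, `format_hgvs()` re-derives the 3'-most
minimal form from the fully justified allele (trim prefix first, then
suffix; emit `dup` when the insertion equals the span preceding it),
since HGVS mandates 3'-shifting while the stored form is fully
justified. One corner is inexpressible: an insertion whose rightmost
equivalent placement is before residue 1 has no linear HGVS form and
raises an error.

## The fixture generator and its oracle

`make_repeat_sequence()` builds `flank + motif×copies + flank` with
seeded flanks whose bases adjacent to the core never continue the motif
period, so the repeat run is maximal by construction.
`make_indel_cases()` cycles through substitution, insertion, deletion,
reference, homopolymer and microsatellite cases over motifs of 1–5 bp,
1–8 copies, flanks up to 20 bp and indels up to 10 bp — the regime
where placement ambiguity actually arises in short-read variant
calling (homopolymer slippage, microsatellite indels).

Expected outcomes are computed by `oracle_normalize()`, a brute-force
enumerator that shares no code with the rolling implementation: it
applies the edit, reduces it to a minimal indel, then tests every
placement of an equal-length edit for reproducing the identical edited
sequence; the expected interval is the union span of all equivalent
placements. Agreement between two independent routes is the core
evidence that the rolling reading above is correct.

What the generator does *not* emulate: ambiguity codes (rolling
semantics for them are undefined, so fixtures are ACGT-only), nested
or interleaved repeats with multiple periods, chromosome-scale
sequences, and real accession namespaces. Passing the suite therefore
demonstrates correctness of the algorithms on the ambiguity structure
the model addresses, not performance or curation behavior on real
genomes. Test and acceptance runs use 1,000 oracle cases plus
100-case serialization/translator sweeps, sizes chosen to exercise
every tag combination many times while keeping a full run in tens of
seconds.

## Known limitations

* Normalization rules for `RepeatedSequenceExpression` alleles are
  specified outside the released model and are not implemented; such
  alleles identify as-is.
* The sequence store is in-memory and FASTA-backed; there is no
  refget/REST or SeqRepo backend, though the DataProxy surface
  (`get_sequence`, `get_metadata`, `translate_sequence_identifier`)
  is the contract one would implement for them.
* No VCF translation, no ISCN parsing, no protein-level support, and
  none of the planned classes (Genotype, fusions, structural
  variation).
* Identifier equality with other implementations depends on their
  treatment of sequence case folding (see above).
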