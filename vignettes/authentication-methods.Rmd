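---
title: "Multi-locus DNA barcode authentication: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-locus DNA barcode authentication: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbarcode)
```

## The problem

Commercial herbal material sold as *Hypericum perforatum* (St John's Wort)
is routinely adulterated with congeners — most problematically its sister
species *H. maculatum*, which grows alongside it and differs at only a
handful of nucleotide positions in the standard barcode regions. A
pharmacopoeia-grade DNA test therefore cannot rest on overall sequence
similarity: close relatives of the target can be *more* similar to a test
sample than distant conspecific accessions are. The workable alternative is
a diagnostic key: a small number of *essential bases* that are fixed in the
target and absent from a defined adulterant panel, read in the context of
an overall identity requirement, and corroborated by cheap secondary
characters from other loci.

`herbarcode` implements that workflow end to end:

1. **Curation** — screen public accessions for a restricted panel of
   species, reject unsupported singleton outliers, and summarise
   within-species variation as IUPAC consensus *subtypes*; locate columns
   that discriminate the target from every panel member and variability
   hotspots suitable for mini-barcode design.
2. **Reference matching** — a case-encoded reference barcode (lowercase =
   essential base) applied with an inclusive 95% overall identity
   threshold; essential-base failure vetoes a pass regardless of identity.
3. **Chloroplast haplotyping** — an rbcL key of seven mapped SNPs giving
   core types 1 / 2 / intermediate 1-2 plus two target-species marker SNPs
   (labels `1`, `1(p)`, `1p`, `2`, `1-2`).
4. **RNA structure characters** — the psbA 3' UTR stem-loop, whose
   diagnostic deletion truncates the hairpin stem (LONG vs SHORT classes),
   and compensatory base changes (CBCs) between ITS2 secondary structures.
5. **Verdict** — a deterministic rule cascade combining the three
   characters into codes M / m / P / p / U (confirmed/possible adulterant,
   confirmed/possible target, undetermined).

## The decision cascade

ITS is primary: a reference-barcode pass is a confirmed target (`P`); a
match to the adulterant reference is a confirmed adulterant (`M`) when the
long-stem psbA character corroborates it and the rbcL haplotype is not the
anomalous intermediate (`1-2`), otherwise a possible adulterant (`m`). A
sequenced ITS that meets no reference is undetermined (`U`) no matter what
the plastid characters say — in the test collection several such samples
still showed the target-typical short stem, and the cascade deliberately
refuses to promote them. When ITS failed to sequence, the stem class
decides: short stem → possible target (`p`); long stem confirms a nominal
adulterant as `m` but leaves a nominal target `U`. That asymmetry is
reconstructed from the observed outcomes of the 38-sample test collection,
not from a stated rule, and `decide_identity()`'s documentation flags it
as such. The rbcL haplotype never decides anything on its own: in the test
collection the two supposedly target-specific marker SNPs turned up in the
majority of adulterant samples, so the key's role is confined to the
M-to-m downgrade and to audit output.

`verdict_rules()` prints the active cascade; the row-level regression
against the transcribed 38-sample table (and its printed tallies) is part
of the test suite.

## The haplotype key

The packaged key (`rbcl_key()`) maps positions 66, 180, 263, 300, 372,
378, 492 over an all-consensus background `C,C,A,A,A,A,A`. Core type 1 is
keyed on 300=G & 372=C. The published panel rows show 180=T co-occurring
with the type-1 pair in most — but not all — type-1 species (one species
carries the pair with 180 at consensus), so 180 is mapped and reported but
not required. Core type 2 is 378=G & 492=T, both required: a reference
sample carrying the full type-1 pattern plus a lone 378=G is printed as
type 1, which the key reproduces. The intermediate `1-2` is the
all-consensus pattern at the five core sites. Types are evaluated in
priority order (1 before 2), which also fixes the call for the
hypothetical vector carrying both complete patterns. State vectors
matching no pattern are `novel` — deliberately not forced into the nearest
type, since haplotypes unseen in the panel are exactly what a quality test
must not silently absorb. Missing data at any core site degrades the call
to `insufficient data`.

## Reference-barcode semantics

A reference barcode is one or more case-encoded IUPAC segments. Matching
aligns each segment independently (semi-global: the pattern is consumed in
full, the test sequence's ends are free; IUPAC-compatibility scoring +1/-1
with linear gap -2; ties resolved leftmost/high-road so results are
platform-stable). An essential position fails iff the aligned test base is
a gap or incompatible with the — possibly ambiguous — essential code.
Segment identity is compatible columns over pattern length; segments
combine by length-weighted mean by default, with a per-segment-minimum
mode (`combine = "min"`) because the published standard does not state
whether its 95% applies across or within segments. The threshold is
inclusive (a 19-of-20-column match passes at 0.95): "a 95% match" is read
as "at least". Both strands are tried and the better orientation is
logged. Gaps at non-essential positions count as mismatches for identity.

## RNA structure characters

Hairpin folding is base-pair maximisation (Nussinov-style) over canonical
pairs including the GU wobble, with a minimum apex loop of 3 — matching
the three-base AAA/UUU loops of the published structures — and a
deterministic traceback (pair whenever optimal, 3'-most partner, which
stacks helices). Thermodynamic folding is intentionally out of scope: the
character of interest is the *stem length* of an isolated hairpin between
two conserved anchors, for which maximum pairing is adequate and exactly
testable against an exhaustive-enumeration oracle (equality is asserted
for hundreds of random sequences up to 14 nt). Externally computed
dot-brackets can be supplied via `structured_sequence()` for parity.

`extract_stem_loop()` requires each anchor motif to occur exactly once,
folds the region between them, and classifies SHORT iff the terminal helix
has at most `short_max_bp = 8` pairs. No numeric boundary is published;
the packaged archetypes fold to 6 bp (deletion-truncated) and 12 bp
(extended), so 8 separates them with a two-pair margin on either side; the
threshold is configurable. Alignment to the packaged archetypes is
reported as cross-check evidence but never decides the class.

CBC counting follows the standard definition: over aligned position pairs
base-paired in both structures, both partners differing is a CBC, exactly
one a hemi-CBC. The published per-species CBC table derives from an
external structure database and is not reproducible from the paper-level
inputs; the package instead asserts the counting invariants
(symmetry, self-zero, `cbc + hemi <= shared pairs`) on random structure
pairs and reproduces the qualitative clade gradient — 0 CBCs within the
target's clade, rising with clade distance — on a synthetic fixture panel
(`cbc_demo_panel()`) that plants exactly the published counts.

The 12-letter sequence+structure alphabet maps each (base, pairing state)
combination to one letter (unpaired bases keep A/C/G/U; opening-strand
bases map to D/E/F/I, closing-strand to K/L/M/P). It is internally
consistent and invertible, and is documented in-repo rather than claimed
identical to any external tool's code.

## The synthetic generator

`generate_panel()` emulates the statistical structure the methods assume:
a shared ancestral sequence, two species-specific SNPs per species at
disjoint columns, three target and two adulterant subtypes differing at
seven planted columns, two accessions per (species x subtype), and
substitution-only noise kept off the planted columns so that planted truth
stays exact. Defaults (20 species, 300 columns, zero noise) mirror the
case-study panel scale; at zero noise, parameter recovery — discriminating
sites, subtype count and consensuses, haplotype labels, stem classes — is
asserted at 100%. `generate_test_collection()` mirrors the test-collection
design (22 nominal target, 16 nominal adulterant samples, ~30% ITS
dropout emulating the observed sequencing success) and can emit ITS, rbcL
and psbA sequences consistent with the planted characters. Indels occur
only in the psbA flanks, where the emulated region is notorious for them;
homopolymer-length jitter there never changes the stem class, and a
property test asserts it.

What the generator does *not* emulate: phylogenetic covariance between
species (each species is an independent mutation of the ancestor),
hybridisation and chloroplast capture, length variation inside barcode
regions, and sequencing-quality artefacts. Passing the recovery tests
therefore demonstrates the machinery is correct under its own model, not
that real panels are this clean — the transcribed 38-sample table, with
its anomalous haplotypes and failed sequences, is the realistic fixture.

The 38-sample character table ships checked in (with an md5 guard) rather
than generated, because it is the regression surface; the clustering
default `link_identity = 0.985` sits between the within-subtype identity
(>= 0.993 at the default noise) and the between-subtype identity
(~0.977 at 7 planted differences over 300 columns).

## Numerical and interface conventions

* All coordinates are 1-based inclusive, everywhere, and every report
  header says so.
* Pairwise identity = compatible columns / aligned columns excluding
  gap–gap pairs, on a global alignment scored match +1, mismatch 0,
  gap -1. The source methodology names the 95% criterion but not the
  identity definition; this is the conventional choice and is documented
  on `pairwise_identity()`.
* The outlier filter discards only *unsupported singletons*: records
  linked to no other record at the threshold, and only when a mutually
  supported cluster exists. Two distant records with no core are both
  kept — there is no basis to call either the outlier. The filter is
  idempotent.
* Consensus building: a column emits a plain base when its frequency
  reaches `1 - ambiguity_floor`; otherwise the minimal IUPAC code over
  bases at or above the floor. Majority-gap columns are dropped with a
  logged coordinate map.
* Subtype labels are deterministic (clusters ordered by size, then
  consensus string) and invariant to input row order.
* The character-table dialect adds an `its_closest` column so that a
  failed ITS can distinguish "matched the adulterant reference" from
  "matched nothing" — the published table overloads a single "No" token
  for both. A lowercase stem token `s` is normalised to SHORT.

## Problem sizes

The shipped tests fold ~600 random sequences of <= 14 nt against the
enumeration oracle, sweep all 16,384 seven-position state vectors against
a brute-force haplotype oracle, run 1,000 random structure pairs through
the CBC invariants, and generate panels of 10-20 species at 240-300
columns; the whole suite runs in under two minutes on one core. These
sizes were chosen as the smallest that exercise every planted structure;
all generators scale by configuration.

## Known limitations

* Base-pair maximisation can overcall stems in sequences whose true
  structure is thermodynamically dominated; the anchors confine folding to
  a short region where this is immaterial, but the stem-loop class of an
  arbitrary full-length spacer should not be read off `fold_hairpin()`.
* Semi-global alignment placement among exactly co-optimal alignments is
  deterministic but arbitrary at the leftmost-choice level; states
  extracted within a few bases of a truncation boundary may be reported
  as gaps rather than bases (both degrade a haplotype call to
  `insufficient data`, so calls stay conservative).
* The verdict engine is single-specimen: it does not model mixtures or
  quantify contamination.
* The packaged reference barcode and psbA archetypes are synthetic stand-ins
  with the documented structural properties; they are fixtures for the
  machinery, not published reference data.
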