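---
title: "Canonical reaction identifiers: the model behind rxnid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical reaction identifiers: the model behind rxnid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two laboratories running the same transformation will almost never describe
it identically: component order, drawing orientation, whether the solvent is
listed as a reagent, the direction the arrow points.  A reaction identifier
useful for indexing and deduplication must erase exactly those arbitrary
choices while keeping the chemical essence: which species go in, which come
out, and which are present throughout.  `rxnid` implements the RInChI
formalism for this: a layered canonical string over the per-molecule standard
InChI, plus three hashed keys of decreasing information content for database
work.

The package draws a sharp line between molecule-level and reaction-level
work.  Everything about a single structure — canonicalization, InChI,
AuxInfo, InChIKey — is delegated to the standard InChI engine bundled with
Open Babel (`obabel`); `rxnid` contributes the reaction-level model:
normalization, layer assignment, serialization, parsing, hashing, file
conversion, and reaction algebra.

## The six-layer string

A reaction is reduced to three component groups (two molecule groups and the
agents — species present at both ends, such as catalysts and solvents) plus
a direction flag and counts of "no-structure" materials (enzymes,
heterogeneous metals, anything without an InChI).  Serialization rules:

* Within a group, prefix-stripped InChI bodies are sorted byte-wise and
  joined with `!`.  Byte-wise (C-locale radix) order is deliberate:
  "alphabetical" must mean the same thing on every platform.
* Of the two molecule groups, whichever serializes lexicographically smaller
  becomes layer two — roles are recorded separately, in layer five, as
  `d+` / `d-` / `d=` (equilibrium) or nothing (unspecified).  The flag says
  which layer holds the starting materials, so swapping reactants and
  products flips only this flag.
* Layer six (`/u a-b-c`) counts no-structure components per layer, with
  trailing zero sections dropped and the whole layer omitted when all three
  counts are zero.  The parser additionally accepts zero-padded dialects
  such as `/u1-0-0` and re-emits them canonically.
* Separators with nothing to separate are omitted; the empty reaction is
  exactly `RInChI=1.00.1S`.  When later molecule layers are non-empty,
  internal `<>` separators are kept (`/<>X` for an empty layer two); trailing
  empty `<>` are dropped even when a direction or `/u` layer follows.  This
  matches the behaviour of Open Babel's independent RInChI writer, against
  which the serializer is cross-checked in the test suite.

Before serialization a record is normalized: duplicates within a group
collapse (keyed on the full InChI string, so different drawings of one
molecule are one component), and any InChI on both sides moves to the
agents.  No-structure components have no identity, so they are never merged
and never move; each is counted where it was declared.  Normalization can be
disabled (`normalize_record(x, enabled = FALSE)`) for byte-compatibility
experiments with software that skips the duplicate check.

## The hashed keys

The Long key simply lists each component's InChIKey (layers separated by
`--`), supporting per-molecule text search.  The Short and Web keys hash
layer content with a fixed primitive, `hash_letters()`:

* SHA-256 of the payload, rendered as uppercase letters with the InChIKey
  base-26 encoding: consecutive little-endian 14-bit windows of the digest
  become letter triplets, with a 9-bit doublet after the fourth triplet
  (mirroring the 65-bit block structure of the InChIKey itself), truncated
  to 4, 10, 12 or 17 letters.  The triplet code maps 0..16383 onto the
  alphabetically ordered three-letter strings minus the 676 beginning with
  "E" and the 516 from "TAA" through "TTV"; the doublet code uses the first
  512 two-letter strings.
* Payloads are the per-component *major* InChI parts (formula, `/c`, `/h`,
  `/q`) or *minor* parts (stereo and isotope sublayers), joined with `!` in
  RInChI component order, empty pieces dropped.  The proton sublayer `/p` is
  excluded from both and accumulated as a signed count, encoded by its own
  letter (`N` = 0, `M` = −1, `O` = +1, saturating at the alphabet ends with
  a warning).  An empty payload yields the canonical blanks `UHFF` /
  `UHFFFADPSC`.

Assigning `/q` to the major part mirrors the InChIKey's own first/second
block split; the calibration suite pins the whole construction — encoding,
windowing, payload joining — against the published blank strings and the
published full Web key of the worked example, so any deviation in these
choices is caught immediately.

The Short key is fixed-format (55 letters + 8 hyphens): header `SA`,
direction group (`EUHFF` etc.), three 10-letter major hashes for layers
two/three/four, three 5-letter groups (protonation letter + 4-letter minor
hash), and three letters counting no-structure components (`Z` = zero,
`A` = 1, ..., saturating at `Y` = 25 so the zero letter is never colonized).
The Web key pools all structured bodies across layers, deduplicates and
sorts them, and hashes majors (17 letters) and minors (12 letters, after the
total protonation letter) — by construction it cannot see which layer a
molecule sat in, which is exactly what makes it useful for comparing
databases with different role conventions.

The no-structure letters and the protonation letters saturate rather than
wrap; a reaction with 30 unidentified components is already beyond what the
format can distinguish, and a warning is raised.

## Files

RXN and RD files (MDL V2000) are parsed with the package's own light-weight
reader — the format is line-oriented and the reaction-level structure
($RXN/$MOL/$RFMT/$DTYPE/$DATUM blocks) is the package's direct concern.
Molfile *content* is never interpreted beyond the counts line; blocks go to
the engine verbatim.  Conventions:

* RXN cannot express equilibria, unknown direction, or agents.  Readers
  default to forward (overridable), and `write_rxn()` appends agents behind
  a `$RXNID-AGENTS` sentinel that `read_rxn()` recognizes — a documented
  dialect; foreign readers ignore the trailing section.
* In RD files, datum molfiles whose field name contains `CATALYST` or
  `SOLVENT` (case-insensitive), and molfiles outside RXN sections, become
  agents.  Which field names the reference software scans is not public;
  this substring rule is the package's documented choice.
* Only variation 1 of an RD record is used.  Its steps (successive `$RXN`
  blocks; a `VARIATION` datum before a block reassigns it) are merged with
  the same set algebra as `add_rinchis()`, so a species produced by one step
  and consumed by the next vanishes from the merged record.
* `write_rxn()` requires the RAuxInfo: component molfiles are rebuilt from
  their InChIs by the engine and the original coordinates are restored from
  the aligned AuxInfo (`/N` numbering + `/rC` coordinates).  Chiral
  components keep the engine's freshly generated 2D layout instead, because
  re-positioning atoms under fixed wedge flags would corrupt the stereo
  parity; identity of the round-tripped RInChI takes precedence over layout.
  Without RAuxInfo the rebuild is refused rather than inventing coordinates.

The RAuxInfo itself mirrors RInChI layers one to four with the same
separators, listing each structured component's AuxInfo body (prefix
`AuxInfo=1/` stripped, mirroring the InChI prefix rule; the parser tolerates
unstripped dialects) in exactly the RInChI component order.  No-structure
components carry no AuxInfo and are not listed.

## Reaction algebra

`add_rinchis()` composes reaction steps into one overall reaction on InChI
*sets* — stoichiometry-free, consistent with the no-duplicate rule.
Intermediates (produced by one step, consumed by a later one) cancel and are
dropped; an enolate formed and then alkylated never appears in the sum.
Agents are treated as present on both sides of their step, which makes the
operation well-behaved across serialization boundaries: an agent that a
later step genuinely consumes correctly re-emerges as a net reactant, and
ordinary agents come out as agents again.

A limitation worth stating plainly: without stoichiometry, a chain that
consumes one species in several different steps (produce once, consume
twice) has no well-defined set sum, and grouping then matters.  For
flow-consistent chains — each species produced by at most one step and
consumed by at most one later step, the shape of real multistep sequences —
addition is associative, and the test suite verifies this on randomized
cascade chains against an independently coded set-flow oracle.  Equilibrium
steps are rejected rather than guessed; backward steps are re-oriented
automatically.

`compare_keys()` encodes the deduplication semantics: equal Web keys with
differing Short keys flag "same chemistry, different role assignment" — the
typical water-as-reagent-or-solvent disagreement between databases.

## The fixture generator

`make_fixture()` emulates the input side of a reaction-registration
pipeline: small organic molecules (linear alkanes, alcohols, diols, amines,
thiols, carboxylic acids, carboxylate anions, chiral secondary alcohols;
chain lengths 1–12 by default) drawn as V2000 molfiles on a zigzag grid,
assembled into RXN/RD files.  Anions exercise the `/p` accounting, chiral
entries the minor-layer hashing, zero-atom blocks the no-structure path.
Every library entry has a distinct InChI and the same seed yields
byte-identical files; the global RNG state is left untouched.

What it deliberately does not emulate: stoichiometric coefficients, salts
and multi-fragment components, isotopic labelling, tautomer-prone
structures, V3000 tables, and the messiness of real patent-extracted files
(mis-numbered counts lines, nonstandard data fields).  Green tests therefore
demonstrate the serialization, hashing and algebra contracts, not robustness
against every wild file in circulation.

## Numerical and scale choices

There is no floating-point numerics here; determinism questions are about
string order (byte-wise everywhere), hashing (SHA-256, fully specified
above) and RNG (only in `make_fixture()`, local and seed-driven).  The test
suite checks the format-length invariants over 1000 generated reactions and
the behavioural properties over dozens of randomized cases each — sizes
chosen so the whole suite runs in well under a minute on one core while
covering every branch of the layer/omission logic.  Engine results are
cached per molfile text, so repeated fixture molecules cost one `obabel`
call.

## Known limitations

* Non-standard (non-`1S`) InChIs are rejected by design.
* V3000 connection tables are not read.
* The engine is pinned per session (`inchi_engine_version()`); identifiers
  generated by different InChI versions should not be mixed in one database
  without checking.
* The Long-RInChIKey layout between header and layers follows the package's
  documented convention (single hyphen after the header, `--` between
  layers); no-structure components are not represented in it.
* Reconstructed molfiles place implicit hydrogens implicitly; explicit-H
  layouts in the original file are not restored atom-for-atom.
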