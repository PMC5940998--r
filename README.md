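# rxnid

Canonical identifiers for chemical reactions: the RInChI layered string, its
RAuxInfo companion, and the three hashed RInChIKeys, computed from MDL
RXN/RD files or from per-component molfiles.

## The problem

Reaction databases need a label that two people drawing the same reaction
will produce independently.  Molecule-level canonicalization is solved by
the standard InChI; `rxnid` builds the reaction-level identifier on top of
it:

```
RInChI=1.00.1S/<group A>!<...><><group B>!<...><><agents>/d<+|-|=>/u<a>-<b>-<c>
```

* layers two and three hold the two molecule groups as `!`-separated,
  byte-wise sorted, prefix-stripped InChIs — the *smaller serialized group
  always comes first*, so drawing order and direction never change the
  molecule layers;
* layer four holds agents (catalysts, solvents: present at both ends);
* layer five records which layer held the starting materials (`d+`, `d-`,
  `d=` for equilibria, absent when unknown);
* layer six counts components with no InChI-representable structure.

Three hashed keys serve database work: the **Long** key (per-component
InChIKeys, searchable by molecule), the **Short** key (fixed 63 characters:
SHA-256 hashes of the concatenated major and minor InChI layers per group,
rendered in the InChIKey base-26 letter code, plus protonation and
no-structure letters), and the **Web** key (47 characters, role-insensitive:
all components pooled and sorted before hashing, so "water as reagent" and
"water as solvent" collide on purpose).

Per-molecule InChI/AuxInfo/InChIKey generation is delegated to the standard
InChI engine bundled with Open Babel (`obabel` must be on the `PATH`).

## Worked example

The hydrolysis of ethyl acetate (ethyl acetate + water ⇌ acetic acid +
ethanol, sulfuric acid catalyst), drawn from five bundled molfiles:

```r
library(rxnid)

rec <- read_rxn(system.file("extdata", "ethyl-acetate-hydrolysis.rxn",
                            package = "rxnid"))
rec$direction <- "equilibrium"

rinchi(rec)
#> RInChI=1.00.1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)!C2H6O/c1-2-3/h3H,2H2,1H3<>C4H8O2/c1-3-6-4(2)5/h3H2,1-2H3!H2O/h1H2<>H2O4S/c1-5(2,3)4/h(H2,1,2,3,4)/d=

rinchi_keys(rec)
#> Long-RInChIKey=SA-EUHFF-QTBSBXVTEAMEQO-UHFFFAOYSA-N-LFQSCWFLJHTTHZ-UHFFFAOYSA-N--XEKOWRVHYACXOJ-UHFFFAOYSA-N-XLYOFNOQVPJJNP-UHFFFAOYSA-N--QAOWNCQODCNURD-UHFFFAOYSA-N
#> Short-RInChIKey=SA-EUHFF-JJFIATRHOH-UDXZTNISGZ-QAOWNCQODC-NUHFF-NUHFF-NUHFF-ZZZ
#> Web-RInChIKey=SMUHAWIQPXIVCEVKG-NUHFFFADPSCTJSA
```

Reading the output: acetic acid and ethanol sort before ethyl acetate and
water, so the *products* of the drawing are layer two and the `d=` flag
marks the equilibrium.  In the Short key, `EUHFF` encodes that equilibrium,
`JJFIATRHOH` is the 10-letter hash of the layer-two major InChI layers, the
`NUHFF` groups say "zero protonation, no stereochemistry" per layer, and
`ZZZ` means no no-structure components anywhere.  The Web key would stay
identical if water were re-filed as a solvent.

Other entry points: `rauxinfo()` (layered AuxInfo for layout recovery),
`write_rxn()` (RInChI + RAuxInfo back to an RXN file), `read_rdfile()`
(RD records, variations, multistep merging), `add_rinchis()` (multistep
composition with intermediate cancellation), `compare_keys()` (database
deduplication semantics), `make_fixture()` (deterministic toy RXN/RD
files), and `rinchi_table()` for batch processing into a tibble.  A thin
command-line front end lives in `exec/rxnid`.

See the vignette (`vignettes/reaction-identifiers.Rmd`) for the model,
serialization and hashing conventions, and known limitations.

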