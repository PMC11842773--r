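# qudtmapper

Metadata for environmental and ecological datasets records measurement
units as free text, and the same unit arrives in many disguises: `gm/m2`,
`g/m2`, `gm-2`, `g/m^2`, `g.m-2` and `gramPerMeterSquared` are all the
same mass-per-area unit. `qudtmapper` links such *ad hoc* raw unit strings
to units in the [QUDT](https://qudt.org) ontology so that they become
machine-interpretable: each matched string gains a stable code
(`GM-PER-M2`), a URI, a label, a dimension vector and SI conversion
parameters.

The core method is two ordered passes of literal string substitutions:

1. **pseudounit phase** — normalize the raw string to a lowercase,
   symbol-free grouping key: `g/m^2` → `grampermetersquared`;
2. **QUDT phase** — rewrite the pseudounit into a dash-delimited QUDT
   code candidate: `grampermetersquared` → `-GM--PER--M2-` →
   (finalized) `GM-PER-M2`, then match it, case-sensitively, against the
   vocabulary. Dashes mark converted segments, so partially rewritten
   strings are unambiguous; finalization trims and collapses dashes and
   keeps only the first `PER` token (`GM-PER-M2-PER-DAY` → `GM-PER-M2-DAY`).

On top of the rewriter the package builds the reusable artifacts: an
enriched lookup table keyed by raw unit, pseudounit, QUDT code or UCUM
alias; value conversion between units with exactly equal dimension
vectors, `y = (m_from·x + b_from − b_to)/m_to`; corpus match statistics; a
synthetic corpus generator with ground truth; an annotator that inserts
RDF-triple-style `annotation` elements into EML 2.2 documents; and a
lookup service plus command-line interface.

## Worked example

```r
library(qudtmapper)
vocab <- qudt_fixture_vocabulary()          # 53-unit QUDT v2.1.25 subset
table <- build_lookup_table(NULL, vocab)    # vocabulary-only lookup table

to_pseudounit(c("g/m^2", "grams per square meter"))
#> [1] "grampermetersquared" "grampermetersquared"

rewrite_to_candidate("grampermetersquaredperday")$trace
#>   order                    before                   after
#> 1    25 grampermetersquaredperday       gramper-M2-perday
#> 2   170         gramper-M2-perday     gramper-M2-per-DAY-
#> 3   220       gramper-M2-per-DAY-     -GM-per-M2-per-DAY-
#> 4   565       -GM-per-M2-per-DAY- -GM--PER--M2--PER--DAY-

finalize_candidate("-GM--PER--M2--PER--DAY-")
#> [1] "GM-PER-M2-DAY"

resolve("gramPerMeterSquared", table, vocab)
#> <'gramPerMeterSquared' -> GM-PER-M2 [rewritten]>
resolve("kPa", table, vocab)
#> <'kPa' -> KiloPA [ucum]>
resolve("martha stewart", table, vocab)
#> <no match for 'martha stewart' (candidate: marthastewart)>

convert_value(0, vocab_unit(vocab, "DEG_C"), vocab_unit(vocab, "K"))
#> [1] 273.15
convert_value(1, vocab_unit(vocab, "GM-PER-M2"),
              vocab_unit(vocab, "KiloGM-PER-HA"))
#> [1] 10
```

The trace shows the stepwise conversion: each fired rule's order and the
string state before and after, ending at the marked candidate whose
finalized form is a real QUDT code. Conversion works only between units
whose eight-dimension vectors are exactly equal — converting `mg/L` to
`mmol/L` errors, because that needs the substance's molar mass, which is
a property of the measurement, not the unit.

Annotating an EML 2.2 document:

```r
f <- system.file("extdata", "synthetic-eml-sample.xml", package = "qudtmapper")
res <- annotate_document(f, table, vocab)
res$report[, c("attribute_id", "raw_unit", "qudt_code")]
#>   attribute_id           raw_unit      qudt_code
#> 1    att.depth              meter              M
#> 2      att.po4 micromolesPerLiter MicroMOL-PER-L
```

Each matched attribute receives an `annotation` element pairing the "has
unit" predicate with the unit's QUDT URI
(`http://qudt.org/vocab/unit/MicroMOL-PER-L` for the phosphate column);
running the annotator again adds nothing.

A command-line wrapper ships in `inst/scripts/qudtmapper`
(subcommands `normalize`, `map`, `build-table`, `resolve`, `convert`,
`annotate`, `stats`, `simulate`, `serve`).

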