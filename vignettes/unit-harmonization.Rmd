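---
title: "Harmonizing ad hoc unit strings against the QUDT ontology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing ad hoc unit strings against the QUDT ontology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qudtmapper)
```

## The problem

Dataset metadata records measurement units as free text. The same physical
unit — grams of dry mass per square metre, say — appears as `g/m2`, `gm-2`,
`g m-2`, `g.m-2`, `gramPerMeterSquared` or `grams per square meter`
depending on who typed it and which convention their repository favoured.
Human readers cope; software does not. Linking each of these surface forms
to a single unit concept in an ontology makes datasets comparable by unit,
and brings along everything the ontology knows about the unit: a stable
URI, a label, a dimension vector and the multiplier (and, for affine units
such as Celsius, offset) needed to convert to coherent SI.

`qudtmapper` implements that linkage as a pipeline of **ordered literal
string substitutions** targeting QUDT unit codes, plus the artifacts built
on top of it: an enriched lookup table, value conversion, corpus
statistics, a lookup service, and an annotator that writes RDF-triple-style
`annotation` elements into EML 2.2 metadata.

## The two-phase rewrite model

**Phase 1 — pseudounits.** `to_pseudounit()` collapses a raw string to a
canonical lowercase form containing only `[a-z0-9]`: Unicode symbol
mapping (micro sign and Greek mu coincide, superscript digits become plain
digits, the degree sign becomes `deg`), trim, lowercase, then the
pseudo-phase rules applied in order, then deletion of remaining whitespace
and symbols. The pseudounit is the grouping key: all the gram-per-square-
metre variants above become `grampermetersquared`.

Rules are literal substrings, not patterns; order is the only control
mechanism. One deliberate mechanical choice: rules are applied to the
string padded with a single space on each side, so a rule's pattern may
include spaces to anchor on word boundaries. That is what lets the rule
`" m "` → `" meter "` expand a lone `m` without touching the `m` inside
`gram`, while remaining a plain substring replacement.

```{r}
to_pseudounit(c("g/m^2", "grams per square meter", "µmol/L", "°C"))
```

**Phase 2 — QUDT candidates.** `rewrite_to_candidate()` applies the
qudt-phase rules, whose replacements are dash-delimited, QUDT-cased tokens
(`-CentiM-`, `-DEG_C-`). Because pseudounits cannot contain dashes and the
replacement tokens contain no lowercase fragments that later rules match,
converted segments are visibly inert: at every step it is clear which part
of the string still awaits conversion.

```{r}
rewrite_to_candidate("grampermetersquaredperday")$trace
```

`finalize_candidate()` then strips leading/trailing dashes, collapses dash
runs, and keeps only the first `PER` token (later `PER`s reduce to plain
dashes), yielding `GM-PER-M2-DAY` — which is looked up, case-sensitively,
among the vocabulary's codes. An unmatched candidate is a value, not an
error: unmatched distinct units are collected, ordered by use count, as
the list of candidates missing from the ontology.

**Why order matters.** Within the qudt phase, longer fragments are ordered
before the shorter fragments they contain. The canonical trap is
`grampercentimetersquared`: if `percent` fired before `centimetersquared`,
the candidate would be mangled; the shipped ordering rewrites the
centimetre fragment first, and a test permutes the rules to confirm the
outcome genuinely depends on order.

**Rule sets are data.** The shipped sets (94 pseudo rules, 112 qudt rules)
were authored to cover the surface grammar of the bundled vocabulary,
including three deliberate misspellings (`cenimeter`, `celcius`,
`cubitmeter`). Larger curated lists — for instance ones derived from a
full production corpus — drop in via `load_rules()`; nothing downstream
assumes a particular rule count.

## Vocabulary, dimension vectors and conversion

The vocabulary input is a flat snapshot table (one row per unit) rather
than an RDF graph, so the core library needs no network access or RDF
stack; `scripts/import-qudt-ttl.R` converts an official QUDT Turtle
release into this form offline. The bundled snapshot contains 53 units
transcribed from QUDT v2.1.25, spanning mass, length, area, volume, time,
temperature, amount of substance, pressure, energy, velocity,
concentration and dimensionless ratios.

A dimension vector is the unit's exponent over the eight basis dimensions
(amount of substance, electric current, length, luminous intensity, mass,
thermodynamic temperature, time, dimensionless), written
`A0E0L-2I0M1H0T0D0` for mass per area. Exponents parse to exactly
representable values (integers and `dot5` halves), so vector equality —
the gate for conversion — is exact, never a floating-point tolerance.

Conversion uses the published multiplier/offset pair:
$y = (m_{from}\,x + b_{from} - b_{to}) / m_{to}$. Units with equal
dimension vectors convert; anything else errors. That guard is semantic,
not defensive: milligrams per litre and millimoles per litre share a
syntax but converting between them needs the substance's molar mass, a
property of the measurement, not the unit. Units loaded without a
published vector or multiplier refuse to convert rather than guess.

## The lookup table

`build_lookup_table()` assembles the reusable artifact from four row
sources: mapped distinct raw units (with use counts), every vocabulary
unit keyed by its own code, every successfully mapped pseudounit, and
every UCUM alias longer than two characters. Two-character aliases are
excluded by design: at that length collisions between unit systems (and
between case conventions) make the alias ambiguous as a bare key.
`resolve()` walks raw key → QUDT code → UCUM alias → pseudounit key → full
rewrite, case-sensitively at the raw layer (folding `MG` into `mg` would
be wrong — those are different units in case-sensitive coding systems);
case-insensitivity enters only through the pseudounit route.

## The synthetic corpus generator

Real unit corpora cannot be bundled, so `generate_synthetic_corpus()`
emulates their structure from three published regularities: a heavily
skewed use-count distribution (most distinct units used once or twice, a
handful tens of thousands of times), multiple surface variants per
underlying unit, and a junk fraction of strings that are not units at all
(missing-value codes, site names, stray labels).

Concretely: true units are drawn from the vocabulary and rendered through
an explicit, versioned `variant_grammar()` (symbolic, exponent-style,
spelled-out, camelCase, and a fixed misspelling list); use counts follow a
power law `top_uses · rank^(-s)` with default exponent `s = 1.5` and
`top_uses = 20000`, values chosen so the generated histogram reproduces
the qualitative shape of real corpora (top-10 forms carry well over half
of all instances); junk strings come from a fixed lexicon of realistic
non-units, enter as singletons (the long tail is where misplaced metadata
accumulates), and are verified non-resolvable at generation time; and
heavily used forms are split across all three organizations while rare
forms belong to one, mirroring observed organization overlap. Defaults are
200 distinct forms and 10% junk. Generation is a pure function of the
seed.

Because every grammar form is rule-covered and junk is non-resolvable by
construction, the generator carries a ground-truth map, and recovery tests
can demand *zero* wrong-code matches rather than merely a high match rate.
What passing those tests shows is that the pipeline is exact on the
conventions the grammar encodes and that the distinct-versus-instance
skew effect falls out of the frequency structure. What it cannot show is
coverage of conventions outside the grammar — real corpora contain far
more orthographic chaos than any fixed grammar, which is why the matched
fraction of *distinct* units in production use stays low even when the
matched fraction of *instances* is high.

## EML annotation

`annotate_document()` resolves each attribute-level `standardUnit` or
`customUnit` declaration and appends, inside the attribute, an
`annotation` element pairing a property URI with the unit's QUDT URI, both
labelled. The default predicate is QUDT's "has unit"
(`http://qudt.org/schema/qudt/hasUnit`); this is a package decision —
repositories that prefer another predicate can override it. Annotation is
idempotent (an identical existing triple is never duplicated), never
touches the source document, optionally bumps the trailing revision
integer of the `packageId`, and optionally assigns deterministic,
position-derived `id`s to attributes lacking one (EML requires an id on
elements that carry annotations; without `add_ids` such attributes are
skipped and reported). Only EML 2.2+ documents are accepted — annotation
entered the schema at 2.2, and silently upgrading older documents would
misrepresent their provenance.

Validation uses a hand-authored subset schema
(`eml-2.2-subset-synthetic.xsd`, explicitly labelled synthetic) covering
the element structure the annotator reads and writes, including element
order inside `attribute` and the required `label` attributes and absolute
URIs in annotations. It is not the official multi-file EML schema;
documents exercising EML features outside this subset should be validated
against the official release separately.

## Service and CLI

`handle_lookup()` is the stateless request handler: `rawunit` in, one of
`json`/`xml`/`html` out, all three renderings carrying the same fields,
with an EML-ready annotation fragment included for matches and client
errors for empty queries or unknown return types. `serve_units()` wraps it
in a minimal blocking HTTP listener over a base-R server socket, intended
for local use. `units_cli()` (wrapped by `inst/scripts/qudtmapper`)
exposes `normalize`, `map`, `build-table`, `resolve`, `convert`,
`annotate`, `stats`, `simulate` and `serve`, with all randomness governed
by `--seed`.

## Numerical and design choices

- **Exactness over tolerance.** Dimension-vector equality is exact;
  conversion round-trip tests use a 1e-9 relative tolerance purely for
  floating-point arithmetic, not for semantics.
- **Tie-breaking.** When two rules could fire at the same position, the
  earlier rule wins over the whole string — rule order is the single
  source of control, with no length- or position-based arbitration.
- **Degenerate inputs.** Any input has a pseudounit; the empty pseudounit
  means "nothing unit-like survived" and is never a table key. Empty
  corpora, header-only vocabularies and unit-free EML documents are all
  valid inputs with empty outputs.
- **Determinism.** Table builds are pure functions of (corpus, vocabulary,
  rules) — serialized output is byte-identical across runs; generated ids
  and synthetic corpora are pure functions of position and seed.
- **Problem sizes.** The test suite and the acceptance script run the
  synthetic study at 200 distinct forms (≈50,000 instances), 1,000 random
  strings for finalization properties, and exhaustive pairwise conversion
  over the 53-unit vocabulary — sizes at which the whole suite completes
  in well under a minute while still exercising every code path.

## Known limitations

- The bundled vocabulary is a 53-unit subset; production use requires
  importing a full QUDT release through the Turtle importer.
- The shipped rule sets cover the bundled grammar, not the full diversity
  of a production corpus; matching quality on real metadata is a property
  of the rule data, which this package treats as replaceable input.
- One known QUDT-internal naming inconsistency (a mass-per-area unit coded
  with a `MicroG` acceleration prefix) is loaded as published, not
  corrected: the vocabulary module never edits the ontology.
- Substance-dependent conversions (molar ↔ mass) are out of scope by
  design; so are annotations describing what was measured or its context,
  which belong to measurement ontologies rather than unit vocabularies.
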