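---
title: "Managing taxonomic name-strings: parsing, repair, matching and confidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing taxonomic name-strings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnkit)
```

## The problem

A *name-string* is the literal sequence of characters used as a label for
a taxon in a data source. Only a fraction of the name-strings in real
sources are clean code-compliant scientific names: the rest carry
authorship in every imaginable style, chresonyms (name + a *user* of the
name rather than its author), annotations (`cf.`, `aff.`, `nr`, `non`,
`sensu`), strain and accession tails, concatenations with interpolated
separators, 10-character truncations, lost leading characters, common
names, acronyms, and hybrid formulas. Interconnecting data across sources
by name therefore needs a toolchain: parse, canonicalize, repair, classify,
match, score, and identify. This vignette describes the models and the
decisions behind each stage; every number shown is computed by the code.

## Parsing model

`gn_parse()` is *total*: it returns for every input, degrading to
`quality = "unparseable"` rather than failing. Interpretation is
positional — one latinized token is a uninomial, two are genus + specific
epithet, three or more add infraspecific parts:

```{r}
gn_parse(c("Bison", "Bison bison", "Bison bison athabascae"))[,
  c("uninomial", "genus", "specific_epithet", "quality")]
```

Rank markers come from an editable vocabulary
(`inst/extdata/vocabulary.yaml`) seeded with the infrasubspecific markers
seen in real aggregated sources (`ssp.`, `var.`, `f.`, `morph.`,
`f.sp.`, `convar.`, `sect.`, Greek letters, ...). The lists are
deliberately open-ended; unknown markers fall to the unparsed `tail` and
the parse is marked `with_tail` instead of guessing. Three recovery
conventions are built in because they are frequent and safe:

* a lower-case head token is retried capitalized and flagged
  (`case_repaired`) — all-lower-case binomials are otherwise
  systematically missed;
* a bracketed genus (`[Bacillus] sp.`) — the prokaryote convention for
  uncertain placement — recovers the genus and records the brackets as a
  nomenclatural-status annotation;
* bracketed years (`(Kollar, [1844])`) parse as years with a flag.

Authorship parsing accepts all-caps house styles (`POWELL & BIRT 2001`)
but rejects an "author" that is an all-caps token with no year
(`CCUG 53888`, `JCM 13257`) — those are collection codes and belong in
the tail. Years must lie in [1700, 2100], which is also what makes
five-digit accession numbers fail the year test. An `ex` between author
names records the preceding names as ex-authors (botanical convention).
The annotation token `null` is recorded verbatim with the negation kind;
its meaning in sources is unspecified, so recording beats interpreting.

Hybrid notation is handled before tokenization: the multiplication sign
in its common encodings (`×`, Cyrillic `х`/`Х`, standalone Latin
`x`/`X`) splits a formula into components; a leading sign marks a named
natural hybrid with a single component.

## Canonical forms

The *complete* canonical retains every latinized element (subgenus, rank
markers); the *standard* canonical retains only what the codes require,
and is what matching uses. For a bare subgeneric combination the
standard form is the subgenus:

```{r}
gn_canonical(c("Aaleniella (Danocythere)",
               "Carex scirpoidea Michx. ssp. convoluta (Kük.) Dunlop"))
```

Design choices here: hyphens are *kept* in standard canonicals (they are
code-legal) but erased in `match_key()`, so `roseo-caerulea` and
`roseocaerulea` share one key; hybrid signs are excluded from both forms
(hybridity survives as a flag) because sign encoding is chaotic and
matching must be sign-agnostic; diacritics are transliterated in the key
only; `Candidatus` is kept in the complete form and dropped from the
standard form. Canonicalization is idempotent, and unparseable input is
an error — no canonical exists — rather than an empty string.

## Pre-processing dirty sources

Uncurated repositories concatenate genus and species with interpolated
characters and truncate to 10 characters. `gn_preprocess()` applies an
ordered, per-source-editable rule list; each firing rule logs its id and
flags:

```{r}
r <- gn_preprocess(c("Triticum_aestivum", "Danio0reri", "corbulasulcata"))
cbind(r[, c("original", "repaired", "unresolvable")],
      flags = vapply(r$flags, paste, "", collapse = ","))
```

Two honesty rules matter. Truncated strings (`Danio reri`) are *not*
dictionary-expanded — without the source's own translation table,
expansion is guessing; the truncation suspect is flagged and recovery is
left to fuzzy matching, which can prove its work. And a single
all-lower-case token with no separator (`corbulasulcata`), or a doubled
separator (`Pan__Herm` — genus *Pan* or an abbreviation?), is marked
`unresolvable` rather than split arbitrarily. `X` acts as a separator
only between a capitalized and a lower-case token so hybrid formulas are
never destroyed.

## Classification

`gn_classify()` assigns exactly one major class per string, with a
diagnostic subclass under `not_useful`. Overlapping cues are resolved by
a fixed priority: numbered → virus → hybrid → symbiont → negated → clade
→ common name → not-useful. Virus must outrank clade because virus
strings routinely embed host binomials
(`Yersinia pestis bacteriophage phiA1122`); symbiont strings likewise
name the *host*, which is exactly the wrong thing to match. `cf.`,
`aff.` and `nr` negate the species but usually leave a usable genus, so
such strings demote to `clade_genus` when the genus parses; bare
`non`/`nec`/`not` negate outright:

```{r}
gn_classify(c("RTBV", "Gambierodiscus aff toxicus",
              "Zootermopsis hindgut protist",
              "environmental samples"))[, 1:3]
```

The classifier is vocabulary-driven and every decision cites either a
vocabulary hit or a structural reason. A golden corpus of roughly ninety
published example strings with their expected classes ships in
`inst/extdata/golden_classification.tsv` and is enforced by the test
suite. Known boundary cases, deliberately not forced: bare vernacular
words without a vocabulary hit (`baboon`) are indistinguishable from
bare epithets (`caudata`) without a lexicon and land in `not_useful`;
strings like `Labiotermes nr labralis` classify as `clade_genus` here
(the genus is usable) even though a stricter reading files them under
negated; common-name detection is a capitalization/function-word/
vocabulary heuristic, not a multilingual lexicon — with some 7,000
living languages that is out of scope.

## Fuzzy matching

`dl_distance()` implements the restricted Damerau-Levenshtein (optimal
string alignment) distance: insertions, deletions, substitutions and
*adjacent transpositions*, with no substring edited twice — the variant
used in scientific-name spell-checking. Because of the restriction the
triangle inequality is not claimed. The implementation is checked
against an independent brute-force recursive oracle on hundreds of
random pairs in the test suite.

Nomenclatural heuristics are implemented as a pre-normalization rather
than modified edit costs: before comparison, keys are folded for
interchangeable latinizations (*i/y*, *ae/e*, *oe/e*) and gender
terminations (*-us/-um/-a*). Folding may reduce a distance but a raw
difference always costs at least one edit, so *taeniata* still sits at
distance 1 from *taeniatus*, not 0. Candidate search is banded by key
length; a first-letter mismatch is allowed whenever the tolerance admits
an edit, which is what lets `chneumon dorsalis` (lost leading character)
find *Ichneumon dorsalis*. All targets tying at the minimal distance are
returned — multi-target matches are information, not noise:

```{r}
fuzzy_candidates("mumia",
  c("cumia", "mimia", "mucia", "mukia", "numia", "rumia"),
  match_params(1))
```

## Cross-mapping tiers

`gn_crossmap()` tries, per source record: exact full string; canonical
exact via match key; canonical fuzzy at distance 1, then 2 up to the
tolerance (capped at 6 — the largest distance at which a correct match
has been observed); partial canonical (infraspecific epithets stripped);
partial canonical fuzzy; genus part; none. The first tier with a hit
wins and names the category. Two orderings were genuinely open: that
genus-part comes last is fixed by how the method is described; placing
canonical fuzzy *before* partial canonical is this package's choice —
full-name evidence, even inexact, beats deliberate truncation. Matches
at distance 2 or more are kept rather than dropped (audit trails beat
data loss); the scoring below flags them for human review
automatically. Raising the tolerance never removes a match or changes
the category of a record matched at an earlier tier, and this
monotonicity is property-tested.

## Confidence scoring

Match features map to points, and points to confidence through a base-3
logistic, `1 / (1 + 3^(-p))` — neutral 0.5 at zero points, saturating in
both directions:

```{r}
data.frame(
  feature = c("uninomial exact", "binomial canonical",
              "binomial + authorship agrees",
              "binomial + authorship conflicts",
              "binomial at edit distance 2"),
  points = c(1, 4, 6.3, 1, 0),
  confidence = round(gn_sigmoid(c(1, 4, 6.3, 1, 0)), 3)
)
```

The weights are *calibrated against the published outputs* of the
scoring approach, not transcribed from its prose: the prose point
arithmetic ("add one", "add 3", "a further point", "subtract 2") is not
mutually consistent with its own printed confidences under any single
logistic, so the printed confidences (0.75 / 0.988 / 0.999 / 0.75) are
treated as authoritative. A base-3 logistic reproduces 1 → 0.75 and
4 → 0.988 exactly; the authorship bonus is then +2.3 (0.999 at three
decimals) and the conflict penalty −3 (back to 0.75). The fuzzy penalty
of −2 per edit puts an ED-2 binomial match exactly on the 0.5 boundary,
matching the observation that such matches are wrong about 40% of the
time and need a human check; the multi-target penalty of −1 drops a
two-way ED-1 binomial tie to 0.75. All weights live in
`score_weights()` and can be re-tuned per application. The human-check
rule is exactly `confidence <= 0.5` — an ED-2 match whose authorship
also agrees scores above the line and is deliberately not force-flagged.

## Identifiers

`gn_uuid()` mints UUID v5 (SHA-1) identifiers in the namespace derived
at run time from the DNS namespace and `"globalnames.org"`. The *raw*
string is hashed — no trimming, case folding or canonicalization —
because the identifier's job is to distinguish, not reconcile: a
Cyrillic `а` lookalike must get a different identifier from its Latin
twin, which is how such encoding problems become discoverable at all.
Canonical-form identifiers are available behind an explicit flag.

## The synthetic-corruption generator

`gn_simulate()` draws one corruption operator per clean name from a
probability mix and records the operator and seed, so every dirty string
carries its ground truth. The operators mirror the observed pathology
classes: separator concatenation (`_`, `0`, `X`), 10-character
truncation, lost leading characters, stripped genera, authorship noise,
chresonym swaps, seeded misspellings of verified edit distance, case
damage, and strain/acronym tails. The default clean pool is a bundled
list of ~200 valid binomials spanning the tree of life. The default mix
leans toward concatenation and single misspellings because those
dominate real uncurated sources.

What the generator does *not* emulate: multilingual common names, virus
nomenclature, encoding damage, and correlated errors (a source that
truncates usually truncates everything). Passing the recovery tests
therefore shows the pipeline handles each pathology class in isolation
at realistic rates — it does not certify performance on any particular
real repository. The enforced recovery properties are: pre-processing
plus canonical matching recovers 100% of concatenation/case-only
corruption, and fuzzy matching at tolerance 1 recovers 100% of
single-edit misspellings of names whose nearest other clean name is at
least 3 edits away (closer neighbours genuinely are ambiguous at
distance 1, as the *Mumia* example above shows).

## Numerical and degenerate-input choices

* Parsing never raises; canonicalizing unparseable input raises by
  default and returns `NA` behind `on_unparseable = "na"`.
* Empty target checklists cross-map to all-`none`; duplicate source ids
  are an error, not a warning.
* Distances are exact integers from a full dynamic programme; the
  length-band prefilter is an optimization only and cannot drop a
  within-tolerance candidate.
* Fuzzy ties are all returned and sorted (distance, then key) for
  deterministic output; re-runs on identical input are byte-identical.
* Problem sizes in the shipped tests (≈200-name pools, 500 oracle
  pairs) keep the whole suite comfortably under a few minutes on one
  CPU while exercising every tier; they are fixture scale, chosen to
  make properties checkable exactly (100% recovery), not estimates of
  corpus-scale rates.

## Known limitations

* No nomenclatural-code validity checking and no author disambiguation
  against registries; authorship comparison is surname-prefix overlap.
* No gender-agreement rewriting of epithets; the termination fold in
  matching is a coarse stand-in.
* No per-dataset translation tables for truncated names.
* No taxonomic-concept (`sensu`) management, no reconciliation groups
  across more than two sources, no phonetic pre-bucketing.
* The common-name/bare-epithet boundary is undecidable without a
  lexicon; such strings are flagged, not resolved.
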