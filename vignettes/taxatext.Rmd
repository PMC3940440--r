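---
title: "Methods: dictionary annotation and association-network extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dictionary annotation and association-network extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxatext)
library(dplyr)
```

## The problem

Biodiversity aggregators attach narrative *text objects* to taxon pages:
paragraphs about habitat, trophic strategy, associations, reproduction and
so on, each labeled with a topical *subchapter*, a language and a curator
trust flag. Almost all the ecological knowledge in these pages is locked
in prose. `taxatext` implements two workflows that pull structure out of
that prose, entirely offline:

1. **URI annotation.** A dictionary maps lowercase *stem keys* to concept
   URIs — e.g. `predat → …/Predation` — and a text object is tagged with
   every URI whose key occurs as a substring of its lowercased body. The
   stem strategy (one truncated key instead of entries for "predator",
   "predation", "predatory") keeps the dictionary small at the cost of a
   known, measurable false-positive profile.
2. **Association-network extraction.** For each taxon page, text under
   the four ecology subchapters (Associations, Trophic Strategy, General
   Ecology, Habitat) is scanned for scientific names; names are
   reconciled against an authority table (synonym → accepted name and
   identifier), mentions of the page's own subject are dropped, and each
   surviving mention becomes a directed edge *subject taxon → mentioned
   taxon*, exportable as TSV, SIF or GraphML for graph tools.

Both workflows come with the evaluation machinery used to judge them —
confusion counts against gold standards, per-unit and micro-averaged
precision/recall/F1, Fleiss' kappa for annotator agreement, relative
improvement over a baseline, and error-category summaries — plus a
synthetic-corpus generator so every stage can be tested end to end
without network access.

## The annotator

`annotate_text()` lowercases the body once, then scans dictionary keys in
file order. Each key that occurs yields exactly one hit at its *first*
occurrence; the scan then moves to the next key. Per-key occurrence
counting is deliberately out of scope: the unit of interest is "this
concept applies to this object", not term frequency. Two tallies are
reported, raw hits and unique URIs, because several stems may map to one
concept.

Substring matching deliberately crosses word boundaries — that is what
makes stems work — so the five documented error modes are *accepted
behavior* of the annotator, measured by the evaluation module rather than
prevented: negation ("does not migrate" still matches `migrat`), terms
describing a related taxon, word-part collisions (`forest` inside "kelp
forest"), generalities, and homonyms. `validate_dictionary()` flags the
structural risks a dictionary author controls: keys that are substrings
of other keys, keys shorter than four characters, and shared URIs.

At `"taxon"` scope, `annotate_corpus()` unions unique URIs over a page's
objects, keeping the earliest hit as provenance. This trades specificity
for dictionary economy: a single general stem can tag a taxon even when
no individual paragraph would warrant it.

## The name finder and resolver

`find_names()` is a deliberately simple, rule-based recognizer. Its
grammar: a *binomial* is a capitalized latinate token followed by a
lowercase latinate token (letters only, length ≥ 2, one optional hyphen,
covering genera like *Pseudo-nitzschia*); an *abbreviated binomial*
("C. pipiens") expands to the nearest preceding genus with a matching
initial, where only genus tokens known to the names table may anchor the
expansion — otherwise capitalized English words would hijack it; genus
*uninomials* and irregular names (viruses such as "Tobacco mosaic virus")
are found only by exact table listing, because free grammar rules are
routinely confounded by such nomenclature. Overlaps resolve
longest-match-first and reported mentions never overlap.

The default mode is `"strict"`: only candidates verified against the
table are returned. This choice follows the practical asymmetry of
curation — a false edge in a published network costs far more than a
missed one — and makes results deterministic. `"heuristic"` mode adds
unverified binomial-shaped candidates (with a blacklist suppressing
sentence-initial collisions like "This species") and is guaranteed to
return a superset of strict results. Common names are not matched unless
explicitly enabled with table-listed common names; scientific-name
finders do not see them, a recall gap worth quantifying but not silently
papering over.

`resolve_names()` is an exact, case-insensitive, whitespace-normalized
lookup: a current name maps to itself, a synonym maps in one hop to its
accepted record and inherits that record's taxon id, anything else comes
back unmatched. No fuzzy matching — resolution stays auditable. Unmatched
mentions are excluded from networks by default (retainable by canonical
string), and resolution is idempotent on accepted names.

## Network assembly

Per page: filter to the ecology subchapters → find names → resolve →
drop self references (`self_filter = TRUE` by default; synonym mentions
of the subject are also self references because they resolve to the same
id) → optionally drop *higher-taxon* edges — an edge to a taxon that is
an ancestor, via the table's `parent_id` chain, of another resolved
mention on the same page. The higher-taxon filter is **off** by default:
it is offered because ancestor inclusion is the dominant false-positive
mode of this extraction style, but applying it needs rank/parent data and
changes the plain "mentioned on the page" semantics, so it is an explicit
opt-in. Edge multiplicity collapses to one edge with a supporting-object
count; edges are directed (page subject → mentioned taxon), with an
undirected collapse available at export.

## Evaluation conventions

* Precision `tp/(tp+fp)`, recall `tp/(tp+fn)`; any 0/0 ratio is 0 by
  convention, so species with no scoreable output get all-zero or blank
  rows rather than NaN.
* F1 is the harmonic mean of *unrounded* precision and recall, and 0 when
  both are 0.
* `metrics_report()` prints 3-decimal metrics rounded half away from zero
  (`round_half_up()`; base R's half-to-even would disagree with published
  tables), keeps unrounded values in an attribute, and computes its TOTAL
  row from summed counts (micro-averaging), never by averaging per-unit
  metrics. Internal comparisons use unrounded values.
* URI comparison is set arithmetic over unique URIs per object, with
  `tn = 0`: there is no natural candidate universe for concepts.
* Association comparison *requires* an explicit candidate-pair universe
  for `tn`, because no definition of "a pair the workflow considered and
  rejected" is canonical. The packaged default,
  `association_universe()`, takes every (subject, resolved-mention) pair
  the finder produces anywhere on a page — any subchapter — as the widest
  set of pairs the pipeline could have asserted. This is an interpretive
  choice and is therefore an argument, not a constant.
* `fleiss_kappa()` implements the standard chance-corrected agreement for
  a fixed rater count and errors out (rather than returning a value) when
  every rating falls in one category, where kappa is undefined.

## The synthetic generator

`generate_corpus()` builds corpora from sentence templates — not a
language model — so the gold record is exact, auditable and reproducible
bit-for-bit under a fixed seed (`withr::with_seed`; the session RNG is
untouched). Its defaults are the study conditions the package targets:

| parameter | default | rationale |
|---|---|---|
| `n_taxa` | 21 | test-species count of the motivating evaluation |
| `objects_per_taxon` | 2–45 | per-species object counts averaging in the twenties |
| `terms_per_object` | 2 (Poisson) | observed ≈ 2.1 URIs per object |
| `ecology_fraction` | 0.4 | share of objects under ecology subchapters; not reported anywhere, chosen once as a plausible mid value |
| `association_density` | 2 (Poisson) | per-object association count; no distribution is published, so this free choice is exposed in config |
| `synonym_rate` | 0.06 | observed old-name share (36/583 ≈ 6%) |
| `trap_rates` | 0.01–0.04 | per-object rates whose relative sizes follow the observed error taxonomy (related-taxa largest, negation smallest) |
| `self_reference_rate`, `higher_taxon_rate` | 0.05 | the two documented association error modes |

Every pool species carries one older synonym in a different genus, so the
planted synonym-use rate is exactly `synonym_rate` in expectation.
Negation traps use the fixed frame "does not engage in …"; word-part
traps embed the surface in a larger phrase ("kelp forest"-style). Traps
are recorded in the gold annotation file with their `error_category`, so
expected false positives are known per category and a miniature error
taxonomy can be reconstructed from any run. After assembly the generator
re-scans every body and aborts if the scan disagrees with the planted
record — gold consistency is enforced by construction, not trusted.

What the generator does **not** emulate: real provider mix, real species
biology, long documents (real objects run to thousands of words; template
objects are a few sentences), free-form prose variation, OCR noise, and
non-English text. Passing tests on synthetic corpora therefore
demonstrate the *mechanical correctness* of matching, resolution,
filtering and scoring — not the linguistic coverage of the grammar or the
ecological adequacy of a particular dictionary on real text.

## Numerical and degenerate-input choices

Markup cleaning parses with an HTML parser (entities decoded, tags
padded so adjacent blocks do not fuse words), falls back to a regex strip
on pathological input, NFC-normalizes and squishes whitespace; it is
idempotent. Empty corpora, empty dictionaries (with a warning), objects
with zero hits, and empty networks are all valid values, not errors.
Integrity violations — duplicate ids, synonyms pointing nowhere,
uppercase dictionary keys, malformed URIs — fail fast at load with the
offending record named.

## Problem sizes in the test suite

The suite exercises the annotator-versus-oracle equivalence on a
generated corpus of ≥ 1,000 objects, trap-rate recovery on ≥ 500 objects
(three-sigma binomial bands), and the synonym-share measurement on
several hundred resolved mentions; smaller seeded corpora cover the
remaining properties. These sizes were chosen to make the binomial
tolerances meaningful while keeping a full run comfortably under a
minute.

## Known limitations

The finder's grammar is a contract validated against this package's own
gold fixtures, not a re-implementation of any external name-finding
service; strict mode's recall is bounded by the supplied names table.
Error categories are gold-fixture labels — the package measures planted
error modes but does not classify novel errors automatically. Dictionary
quality dominates annotation quality, and no automatic dictionary
construction is attempted.
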