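---
title: "Methods: fuzzy matching and scoring of plant scientific names"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy matching and scoring of plant scientific names}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxresolve)
```

## The problem

Lists of plant names assembled from herbarium labels, ecological
inventories, trait tables and phylogeny tip labels are riddled with
misspellings, outdated synonyms, annotation noise ("cf.", "aff.",
"Indet."), morphospecies placeholders ("Fabaceae sp. 21"), all-caps
entries and embedded accession codes. Left uncorrected, these inflate
species counts and break joins between datasets. `taxresolve` standardizes
such lists against one or more reference taxonomies held in a local store:
it cleans each string, atomizes it into name components, fuzzy-matches the
components against the reference, scores and ranks the candidates, flags
ambiguous situations, and converts synonyms to their accepted names.

## Pipeline

Each submitted name passes independently through four stages.

**Pre-processing** (`preprocess()`). Underscores become spaces (phylogeny
tip labels), a pre-pended family is split off (standard `-aceae`/`-idae`
endings plus the conserved names without them: Gramineae, Compositae,
...), annotation vocabulary and morphospecies/accession codes are removed
and recorded, and all-caps input is case-adjusted (first letter upper, the
rest lower) because parsing is case sensitive. The cleaned string is then
looked up verbatim in the store: a complete match is assigned an overall
match score (OMS) of 1.0 and skips fuzzy matching. When a family
accompanied the name, exact homonym hits are first filtered to that
family.

**Parsing** (`parse_name()`). A rule-ordered tokenizer assigns components
by botanical casing conventions: the leading capitalized token is the
genus, lower-case tokens are epithets, recognized rank indicators
(`var.`, `subsp.`/`ssp.`, `fo.`/`f.`, `subvar.`) are standardized, a
parenthesized author is the basionym author and trailing name-cased text
the combining author. Hybrid markers flag the name and only the leading
parent is atomized. `parse_quality` records the tolerance used: `strict`,
`relaxed` (diacritics, doubled parentheses, bracketed years), `salvage`
(leftover text set aside in `unmatched_text`) or `failed`. The deepest
populated component determines the submitted rank, which later drives
partial-match flagging.

**Fuzzy matching** (`hierarchical_search()`). Matching is genus-first in
the Taxamatch style: candidate genera are selected before any epithet is
compared, species are evaluated only inside qualifying genera, and
infraspecific taxa only under qualifying species, which keeps the search
linear in practice. Two similarity channels are used per component:

* *Orthographic*: a modified Damerau–Levenshtein distance (`mdld()`) with
  unit insertions, deletions, substitutions and adjacent transpositions,
  extended with transpositions of adjacent blocks of up to `max_block = 4`
  characters at the cost of the longer block. Transposed syllables
  (`vecusilosus` → `vesiculosus`) therefore cost 2 rather than the 4
  substitutions a plain alignment would charge. The block cap keeps
  long-range rearrangements expensive; 4 covers transposed syllables.
* *Phonetic*: components are reduced to keys (`phonetic_key()`) by
  lower-casing, diacritic folding, an ordered substitution table (ae/oe →
  e, ph → f, th → t, non-initial ch → c, y → i, k → c, sz → s, initial
  Mc → Mac, X → Z, ps/pt/ts simplifications) and collapse of doubled
  letters; epithets are first stemmed (`stem_epithet()`) so the gender
  endings -is, -us, -ys, -es, -um, -as, -os all become -a. Phonetic
  matching is exact equality of precomputed keys, which costs one lookup
  at query time.

Authorship is compared separately (`author_similarity()`) with a relaxed
n-gram measure: known abbreviations are expanded from a built-in sample
dictionary (~70 entries; the full standard abbreviation list is beyond
scope and the dictionary is file-extensible), and a 2/3-bigram + 1/3
trigram Dice similarity is computed twice — on the original strings and on
diacritic-folded ASCII — and averaged. The averaging deliberately scores
diacritic variants as similar but not identical. When either side lacks an
author, no author comparison is made at all; we do not score an absent
author as zero because that would systematically punish reference sources
that omit authorship.

**Post-processing** (`score_candidate()`, candidate tests, ranking,
warnings, synonym conversion), described next.

## Scoring model

Each compared component receives a partial match score

$$PMS = 1 - 2\,ED/MaxED,$$

where $MaxED$ is the longer of the two strings, so $PMS \in [-1, 1]$. A
penalty of 0.3 is subtracted when the submitted rank indicator is present
but wrong (`fo.` against a stored `var.` gives an exact epithet a PMS of
0.7). Query components with no counterpart in a shallower reference record
(the unmatched epithet of a genus-level partial match) score $-1$: this is
the unique choice under which a perfect genus-only partial match to a
binomial lands exactly at the scale midpoint (OMS 0.50), which is where
the ranking logic expects it.

The scientific-name match score $SNMS$ is the sum of the $k$ component
scores, and is rescaled to $[0,1]$ with a sign-preserving arctangent
transformation:

$$SNMS_{tr} = \frac{\operatorname{atan}\!\big((s\,SNMS/k)^{2t+1}\big)}
  {2\,\operatorname{atan}\!\big(s^{2t+1}\big)} + \frac12 .$$

For every $s > 0$, $t \ge 0$ this maps $-k \mapsto 0$, $0 \mapsto 0.5$ and
$k \mapsto 1$ and is strictly increasing. With the defaults $s = 2$,
$t = 1$ the curve has five regions — certainty at both extremes, a flat
center of uncertainty, and two steep discrimination bands between them —
so small evidence moves the score most when one is neither sure of a match
nor sure of a mismatch. As $s \to 0$ with $t = 0$ it degrades gracefully
to a linear rescaling. Among the algebraically plausible placements of the
exponent this is the one that reproduces both anchor behaviours we require
of it (the 0.50 midpoint for a perfect genus partial and a
cross-genus species match near 0.96 for a one-edit genus with exact
epithet), so it is the form implemented; `s` and `t` remain configurable.

The overall match score blends in the author score when a comparison was
possible,

$$OMS = 0.8\,SNMS_{tr} + 0.2\,AMS - p \quad\text{or}\quad
  OMS = SNMS_{tr} - p,$$

with $p = 0.1$ when the submission contained text matched to nothing, and
is clamped to $[0,1]$. Verbatim exact hits bypass all of this at 1.0.

## Candidate tests

A candidate must pass the **maximum-ED test** — total edit distance at
most 2 per name part (rank indicators are not parts), i.e. 4 for a
binomial, 6 for a trinomial — and then either the **phonetic test** (all
components key-equal) or the **match threshold test**. The threshold test
is per component: $ED/MSL$ at most 0.5 for components shorter than 6
characters and 0.3334 otherwise (the laxer short-string bound compensates
the bias against matching short strings), with the first character
required to match for $2 \le ED < 4$ and the first three for $ED = 4$.
The published form of this conjunction is unsatisfiable for $ED \le 1$
(there is no branch for it), so distances of 0 and 1 pass unconditionally
— any other reading would reject near-exact matches. Distances above 4
fail the threshold test outright, leaving phonetic equality as the only
rescue.

The genus pre-filter of the hierarchical search keeps every genus that is
key-equal, within an edit distance of 2, *or* passes the threshold test.
The last clause matters: a genus at distance 3 with nine or more letters
passes the printed ratio test and can head a legitimate candidate, so a
budget-only pre-filter would make the staged search disagree with a
whole-database scan. With it, the staged search provably returns exactly
the brute-force candidate set, and the test suite asserts that equality on
dozens of random fixtures.

## Ranking, warnings, synonym conversion

Two rankings are always computed and stored. The *unconstrained* ranking
sorts by descending SNMS, then OMS, then taxonomic status (accepted >
synonym — with illegitimate and invalid treated as synonyms — >
no opinion), with an alphabetical final tie-break; a tie on all keys
between the two leaders flags `ambiguous_match`. The
*taxonomy-constrained* ranking sorts component-by-component from the top
(family if submitted, then genus, species, infraspecifics), so a perfect
genus outranks a good species match in a different genus. Four warnings
can be attached: `partial_match`, `ambiguous_match`,
`better_spelling_match_in_different_higher_taxon` (constrained best, when
the unconstrained best scores higher elsewhere) and
`better_higher_taxonomic_match_available` (unconstrained best, when the
constrained winner differs). An optional source constraint stably
partitions either ranking by source priority; with one source it is a
no-op. Finally, matched synonyms carry their accepted name: chains are
collapsed at load time, so conversion is a single hop, and a cycle is a
load-time validation error.

## The reference store

`load_exchange_file()` reads a Darwin-Core-style TSV (columns `taxonID`,
`scientificName`, `scientificNameAuthorship`, `taxonRank`,
`parentNameUsageID`, `acceptedNameUsageID`, `taxonomicStatus`, `family`)
into an in-memory store; the relational database of a server deployment
is deliberately not replicated, so tests run anywhere with zero
installation. Loading validates ranks, statuses, duplicate ids and
dangling links, takes family membership from the file's `family` column,
builds a nested-set (preorder interval) index over the parent pointers so
descendant queries are two comparisons per record, and precomputes the
phonetic keys and stems the matcher uses — the store always answers
phonetic questions exactly as the query-time functions would. Multiple
sources can be loaded side by side; their synonymy assertions are kept
separate, never merged, and source priority defaults to load order.
`exact_lookup()` matches the canonical form and compares authors only
when the query supplies one, since reference sources disagree on
authorship formatting.

## The synthetic-data generator

`generate_taxonomy()` builds pseudo-Latin taxonomies (CV-syllable words
with stemmable endings; families end in `-aceae`) with configurable
synonym fraction, infraspecific fraction and planted cross-family homonym
pairs, and `corrupt_name()` derives ground-truthed queries by sampled
corruption operations: character edits that keep the first letter intact,
gender ending swaps (phonetically equal, nonzero edit distance), rank
indicator swaps, all-caps, family prefixes, annotations and morphospecies
codes. Defaults (3 families / 10 genera / 50 species, 20% synonymy, 10%
infraspecifics) emulate a small checklist-sized source with realistic
synonymy. Generated names are drawn pairwise at least 5 edits apart with
distinct phonetic keys (homonym copies excepted) so that a query corrupted
by at most 2 edits per component has a unique intended target; realized
edit distances are recomputed and stored with each query. Generation is
deterministic per seed, and real genus names are avoided so no fixture can
accidentally collide with meaning.

What the generator does *not* emulate: realistic name-frequency
distributions, OCR frame shifts, vernacular names, hybrid formulas and
the orthographic clustering of real Latin epithets (real floras contain
near-miss epithet pairs like *gracilis*/*gracilior* that the separation
rule excludes). Passing the recovery tests therefore demonstrates that
the engine implements its tests and rankings correctly, not that real
herbarium data will resolve at the same rate.

## Numerical and design choices

* Block-transposition cost is the length of the longer swapped block;
  blocks are capped at 4 characters.
* The OMS is clamped at 0 after penalties; negative confidence is not
  meaningful to report.
* Exact score ties are compared at a tolerance of $10^{-9}$ when flagging
  ambiguity.
* Degenerate queries (nothing left after cleaning) resolve to the family
  when a family prefix was present, and to no-match otherwise; a
  family-rank fallback for deeper queries is attempted only when a family
  accompanied the name and nothing at genus rank or deeper survived.
* When no reference family passes the component tests, a submitted family
  prefix is demoted to unmatched text (0.1 penalty) rather than forcing a
  non-match.
* Multi-hop synonym chains are collapsed at load; `no opinion` records
  resolve to themselves.
* Test problem sizes: the search-equivalence property runs 50 random
  fixtures of 20–120 species (up to ~170 records each with genera,
  families, synonyms and infraspecifics), the recovery property 100
  corrupted queries against a 63-record store, and the nested-set
  property 100 random taxonomies; the edit-distance oracle is exhaustive
  over all 3-letter-alphabet string pairs up to length 3 and sampled
  (3000 seeded pairs) up to length 6.

## Limitations

Homonyms within one family are distinguishable only by authorship, which
ranks but never excludes candidates here. Hybrid formulas are flagged and
reduced to their leading parent. Taxon-concept differences — the same
name meaning different circumscriptions in different sources — are
invisible to string matching by construction; keeping each source's
assertions separate and reporting the source of every match is the
package's only defense.
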