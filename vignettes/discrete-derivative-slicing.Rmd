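---
title: "Slicing literature co-occurrence networks with set-valued discrete derivatives"
author: "ddslice authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slicing literature co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddslice)
```

# The model

A literature corpus is a collection of citation records, each carrying a
*set* of controlled descriptor terms (MeSH headings or database
keywords).  The package's unit of analysis is the unordered pair of
distinct descriptors indexed on the same citation.  A record with `k`
distinct descriptors emits exactly `choose(k, 2)` pairs; the *frequency*
of a pair is the number of records emitting it.  Two modelling
assumptions follow from the set semantics:

* a pair counts at most once per record, regardless of how often either
  term might appear in other fields;
* records with fewer than two descriptors are legitimate corpus members
  that emit no pairs — dropping them would distort corpus statistics such
  as term-occurrence ranks.

On a pair table with maximum frequency `k` the calculus is purely
set-theoretic.  The slice at threshold `i` collects the pairs with
frequency at least `i`; the level distribution `ld_i` is the difference
of adjacent slices, i.e. the pairs at frequency exactly `i`; the discrete
derivative differences adjacent *levels*, `ld'_i = ld_i - ld_{i+1}`, and
higher orders iterate this.  All differences are set differences: the
operands are families of pairs, not counts, and the constancy result
below is a statement about sets.

## Why the derivative is constant

Pairs at distinct frequencies are disjoint by construction, so
`ld_i ∩ ld_{i+1} = ∅` and therefore `ld_i - ld_{i+1} = ld_i`: the
derivative of any order equals the level distribution on the levels where
it is defined.  `verifyConstantDerivative()` turns this from a
paper-and-pencil argument into an executable check that is run inside
`runPipeline()` on every analysis; a failure would indicate a corrupted
frequency table (or a bug) and aborts the run.

```{r theorem}
tb <- countFrequencies(generateCorpus(generatorConfig(
  nRecords = 120, vocabSize = 60, seed = 7))$corpus)
verifyConstantDerivative(tb, maxOrder = 4)
```

## Defined versus empty levels

Differencing drops the top level at each step ("the derivative of the
last point is meaningless"), so the order-`m` series exists on levels
`1..k-m` only.  A level inside that range can still be *empty* — corpora
routinely show blank frequencies — and the package distinguishes the two
cases: empty levels are present as zero-row pair frames, levels beyond
`k-m` are absent, and `seriesLevel()` raises an error for them rather
than returning an empty set.

## A note on the pair-construction pseudocode

The classical double-loop formulation of pair construction (`j` running
over the full `1..k` for every `i`) literally emits self-pairs and both
orientations of every pair, while its printed worked output contains only
the `choose(k, 2)` unordered `i < j` pairs.  The worked output is
authoritative: `enumeratePairs()` implements the unordered semantics, and
the literal loop survives only behind `literal = TRUE` so the discrepancy
stays documented and testable.

# Tunable parameters

| parameter | where | default | rationale |
|---|---|---|---|
| `majorTopicOnly` | `readMedlineXML()` | `FALSE` | mirrors the retrieval-side "major topic only" restriction when the XML was not already filtered; a heading survives if its descriptor or any qualifier is flagged |
| `includeQualifiers` | `readMedlineXML()` | `FALSE` | qualifier texts ("physiopathology") as standalone terms; reproduces mixed hand-curated lists, off by default to stay faithful to the MeSH schema |
| `policy` | `intersectTables()` | `"min"` | a pair reaches slice level `f` of the intersection iff it reaches `f` in both corpora; `sum`/`left`/`right` provided for sensitivity analysis |
| `mode` | `filterByLexicon()` | `"both"` | both endpoints in the lexicon gives term–term networks; `"either"` keeps term–concept links |
| `minRim` | `findWheels()` | 5 | wheels are defined pictorially in practice; 5 is the smallest rim worth reporting, and the motif is a star — rim–rim edges are not required |
| `maxOrder` | `verifyConstantDerivative()` | 4 | orders beyond the first are redundant by the constancy result; 4 covers the orders one would plausibly inspect |
| `vocabularySkew` | `generatorConfig()` | 1.5 | power-law rank exponent; see below |

Ordering everywhere is bytewise (C-locale radix): canonical pair order,
row order of persisted tables, vertex and edge order of graphs.  This
makes every artefact bit-exact across runs and locales; the cost — a
non-linguistic sort of non-ASCII terms — is irrelevant for determinism
purposes.  Term normalization trims and collapses internal whitespace but
preserves case, because controlled vocabularies distinguish terms by
case more than a lowercasing merge would tolerate; *matching* (lexicons,
cross-query seeds) is case-insensitive, which is the forgiving direction
for user-supplied lists.

# The synthetic-data generator

No deposited corpus accompanies this method, and the original snapshots
of the motivating analysis (PubMed/SinoMed, 2010) cannot be re-created.
The generator therefore states a world in which every operation is
testable offline:

* `nRecords` background records draw between 2 and 8 descriptors
  (inclusive range, uniform) from a vocabulary of `vocabSize` terms under
  a power-law rank distribution with exponent 1.5.  The skew reproduces
  the qualitative signature of real keyword corpora: a heavy head of
  ubiquitous terms, pair frequencies spanning a wide range, and slice
  occupancy thinning as the threshold rises.
* *Planted pairs* are inserted into exactly their target number of
  records.  Host records are disjoint across plants, so plants that share
  endpoints (e.g. a planted triangle of herb pairs) cannot inflate one
  another.  Background draws that would accidentally push a planted pair
  past its target are redrawn (bounded retries, then an error) — the
  background of a host record can be redrawn without touching the plant,
  because plant insertions and background draws are tracked separately.
  Ground truth is therefore exact, which planted-recovery tests require.
* *Planted stars* occupy dedicated records containing only the center and
  one rim term.  This is a deliberate deviation from insertion-style
  planting: inserting a hub into populous background records would let
  the hub accumulate high-frequency edges to common background terms, and
  the star's realized structure would no longer be the configured one.
  Dedicated records guarantee exact center–rim frequencies and no
  spurious hub edges.
* Determinism: all randomness flows from the single `seed` through a
  private RNG stream; the caller's `.Random.seed` is saved and restored,
  and identical configurations produce byte-identical corpora.

What the generator does **not** emulate: real MeSH semantics, topical
correlation between terms, per-year drift, or the marginal distribution
of descriptors-per-citation in any specific database.  A green test
therefore establishes that the *operations* are correct on corpora with
realistic frequency spread and planted ground truth — not that any
biological conclusion drawn from a real corpus is valid.

# Design choices where the method leaves room

* **Intersection frequencies.**  How the combined frequency of a shared
  pair should be computed is genuinely open (minimum, sum, or a recount
  over a merged record set).  The default is `min`, the only choice under
  which "pair present at slice `f` of the intersection" means "present at
  slice `f` in both corpora" — which is how intersected networks are read
  in practice (a pair absent from a joint frequency-19 network even
  though both terms occur in both corpora).  The alternatives remain one
  keyword away for sensitivity analysis.
* **Ranking granularity.**  `rankItems()` counts *records* containing a
  term, not keyword-field occurrences; record-level counts are invariant
  to indexing duplication and bounded by the corpus size, which makes the
  ranking comparable across corpora.
* **Lexicon matching.**  Exact-term, case-insensitive.  Substring
  matching on short herb names ("Salvia" inside "Salvia miltiorrhiza
  extract") would be a different, curator-controlled feature; silent
  substring hits are the wrong default.
* **Wheel formalization.**  A wheel is a hub with its neighbours as rim
  (a star).  Rim–rim edges are permitted but not required, and no attempt
  is made to classify rim nodes into "specific" versus "abstract"
  concepts — that is a manual judgement with no stated rule.
* **Qualifier terms.**  Whether qualifier texts were counted corpus-wide
  as descriptors in the motivating analysis is unknowable from the
  record; both behaviours are supported and the schema-faithful one is
  the default.

# Degenerate inputs and numerical corner cases

* Empty corpus → empty table; empty table → `maxFrequency` 0, no levels,
  vacuous verification pass.
* A table whose maximum frequency is 1 has no level to differentiate:
  order 1 is an empty series with a warning, not an error.
* `levelDistribution()` computes each level twice (slice difference and
  direct lookup) and errors on disagreement; the redundancy is cheap and
  guards the central identity of the package.
* Duplicate record ids, malformed XML, wrong column counts, unknown
  centers and infeasible plants all fail fast with the offending
  identifier, line or pair named in the error.

# Limitations

* Raw co-occurrence counts only — no tf-idf, PMI or other weighting; the
  calculus is defined on counts and deliberately stays there.
* No numeric-valued derivatives: assigning numbers to descriptors in a
  continuous space would give the derivative a numeric meaning, but that
  is speculation beyond the set-valued method implemented here.
* No live database querying; corpora enter as MEDLINE-dialect XML or
  two-column record tables.
* Graph export carries no layout coordinates; arranging wheels for
  viewing is Cytoscape's job.
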