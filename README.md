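# ddslice

Frequency slicing and set-valued discrete derivatives for literature
co-occurrence networks.

## The problem

Biomedical citation databases attach a set of controlled descriptor terms
(MeSH headings in PubMed, keyword fields elsewhere) to every record.  When
two descriptors are indexed on the same citation they *co-occur*, and the
number of citations in which a pair co-occurs is its frequency.  Mining the
pair-frequency table of a large disease corpus — or of the intersection of
two disease corpora — surfaces shared biology: the high-frequency pairs
organise into wheel-shaped (star) subnetworks around hubs such as
"Inflammation" or "Apoptosis".  `ddslice` is for researchers who want to
run that workflow offline and reproducibly: parse corpora, count pairs,
slice, differentiate, intersect, filter against a curated term list (e.g.
Chinese herbs used for two diseases), and export the resulting networks to
Cytoscape.

## The calculus

Let `frequency(e)` be the number of records containing the pair `e`, and
`k = max frequency`.  For `i = 1..k`:

- **slice**: `slice_i = { e : frequency(e) >= i }`.  Slices are nested,
  `slice_{i+1} ⊆ slice_i`, and `slice_1` is the whole table.
- **level distribution**: `ld_i = slice_i − slice_{i+1}` — the pairs at
  frequency exactly `i`.  Levels are pairwise disjoint and partition the
  table.
- **discrete derivative**: `ld′_i = ld_i − ld_{i+1}` (set difference),
  and higher orders `ld^(m) = (ld^(m−1))′`.  Each differencing step drops
  the top level, so order `m` lives on levels `1..k−m`.

Because pairs at distinct frequencies are disjoint sets,
`ld_i − ld_{i+1} = ld_i`: **discrete derivatives of every order are
constant**, equal to the level distributions on their surviving range.
`verifyConstantDerivative()` checks this executable identity on any table.

## Worked example

The canonical check is a single citation (PMID 20464912) carrying eight
headings; its pair enumeration must be exactly the 28 = C(8,2) unordered
pairs:

```r
library(ddslice)
fx <- table3Fixture()
countFrequencies(fx)
#> FrequencyTable 'worked_example': 28 pair(s), max frequency 1
#>                        a                           b frequency
#>  Evidence-Based Medicine                      Humans         1
#>  Evidence-Based Medicine Muscle Stretching Exercises         1
#>  ...
```

A synthetic corpus with a planted star shows the motif workflow end to
end.  The generator plants a hub ("Inflammation") linked to 6 rim terms,
each edge in exactly 19 records, on top of 150 background records drawn
from a heavy-tailed vocabulary:

```r
gen <- generateCorpus(generatorConfig(nRecords = 150, vocabSize = 60,
  plantedStars = data.frame(center = "Inflammation", rimSize = 6,
                            frequency = 19),
  seed = 42, label = "demo"))
tbl <- countFrequencies(gen$corpus)
tbl
#> FrequencyTable 'demo': 197 pair(s), max frequency 22

verifyConstantDerivative(tbl, 4)
#> Constant-derivative verification up to order 4: PASS (57/57 checks)

findWheels(toGraph(sliceAt(tbl, 19)), minRim = 5)
#> DataFrame with 1 row and 3 columns
#>         center      size                       rim
#> 1 Inflammation         6 Inflammation rim01,...
```

Slicing the table at frequency 19 isolates the planted wheel: one hub with
its 6 rim terms, recovered exactly.  `crossQuery(tbl, "Inflammation",
minFreq = 19)` returns exactly those 6 star edges — the seed-term
verification step.  `exportGraph(..., "sif", path)` or `"graphml"` hands
any of these networks to Cytoscape.

Two-corpus analysis: `intersectTables(tabA, tabB, policy = "min")` keeps
the pairs present in both corpora (a pair reaches slice level `f` of the
intersection iff it reaches `f` in both), `filterByLexicon()` restricts to
a curated term table, and `rankItems()` ranks lexicon terms by record
occurrence.  `runPipeline(runConfig(...))` wires the whole workflow and
emits a JSON run report.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch: it generates two seeded corpora sharing a planted pair plus a
planted star, executes the full pipeline (counting, min-policy
intersection, slicing, constant-derivative verification up to order 4,
lexicon filtering, cross-query, exports) and writes its result JSON.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The script exits non-zero if any stage fails or the derivative-constancy
verification does not pass.
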