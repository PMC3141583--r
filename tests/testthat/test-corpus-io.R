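test_that("MEDLINE XML parsing harvests descriptors per citation", {
  f <- write_medline_fixture(withr::local_tempfile(fileext = ".xml"))
  co <- readMedlineXML(f)
  expect_s4_class(co, "Corpus")
  expect_equal(recordIds(co), c("100", "101", "102"))
  expect_setequal(co[["100"]],
    c("Arthritis, Rheumatoid", "Humans", "Inflammation"))
  expect_equal(co[["101"]], "Apoptosis")
  # citations with no surviving headings are retained, emitting no pairs
  expect_length(co[["102"]], 0)
  expect_equal(nrow(enumeratePairs(co)[["102"]]), 0)
})

test_that("major-topic restriction and qualifier harvesting", {
  f <- write_medline_fixture(withr::local_tempfile(fileext = ".xml"))
  major <- readMedlineXML(f, majorTopicOnly = TRUE)
  # descriptor flagged Y, or any qualifier flagged Y, survives
  expect_setequal(major[["100"]],
    c("Arthritis, Rheumatoid", "Inflammation"))
  expect_length(major[["101"]], 0)
  quals <- readMedlineXML(f, includeQualifiers = TRUE)
  expect_setequal(quals[["100"]],
    c("Arthritis, Rheumatoid", "drug therapy", "Humans", "Inflammation",
      "immunology"))
  majorQ <- readMedlineXML(f, majorTopicOnly = TRUE,
    includeQualifiers = TRUE)
  expect_setequal(majorQ[["100"]],
    c("Arthritis, Rheumatoid", "Inflammation", "immunology"))
})

test_that("XML error paths: malformed input and duplicate PMIDs", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<PubmedArticleSet><oops>", bad)
  expect_error(readMedlineXML(bad), "malformed XML")
  dup <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<PubmedArticleSet>",
    "<PubmedArticle><MedlineCitation><PMID>7</PMID></MedlineCitation></PubmedArticle>",
    "<PubmedArticle><MedlineCitation><PMID>7</PMID></MedlineCitation></PubmedArticle>",
    "</PubmedArticleSet>"), dup)
  expect_error(readMedlineXML(dup), "duplicate PMID.*7")
})

test_that("empty citation set parses to an empty corpus", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<PubmedArticleSet/>", f)
  expect_equal(length(readMedlineXML(f)), 0)
})

test_that("MEDLINE write -> read round-trips a synthetic corpus", {
  gen <- generateCorpus(generatorConfig(nRecords = 3, vocabSize = 15,
    seed = 11, label = "rt"))
  f <- withr::local_tempfile(fileext = ".xml")
  writeMedlineXML(gen$corpus, f)
  back <- readMedlineXML(f, label = "rt")
  expect_equal(recordIds(back), recordIds(gen$corpus))
  for (id in recordIds(back))
    expect_equal(back[[id]], gen$corpus[[id]])
  expect_equal(corpusLabel(back), corpusLabel(gen$corpus))
})

test_that("record tables group lines by id and deduplicate", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("20464912\tphysiopathology",
    "20464912\trehabilitation", "20464912\tEvidence-Based Medicine",
    "20464912\tHumans", "20464912\tMuscle Stretching Exercises",
    "20464912\tPhysical Fitness", "20464912\tResistance Training",
    "20464912\tTreatment Outcome"), f)
  co <- readRecordTable(f)
  expect_equal(length(co), 1)
  expect_length(co[["20464912"]], 8)

  writeLines(c("1\tAngelica", "1\tAngelica"), f)
  dedup <- readRecordTable(f)
  expect_equal(dedup[["1"]], "Angelica")
})

test_that("record-table errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\tA", "2\tB\tC"), f)
  expect_error(readRecordTable(f), "line 2")
  writeLines(c("record_id\tdescriptor", "1\tA"), f)
  expect_equal(length(readRecordTable(f, header = TRUE)), 1)
})

test_that("record-table write -> read is the identity on corpora", {
  gen <- generateCorpus(generatorConfig(nRecords = 50, vocabSize = 25,
    seed = 4, label = "rt50"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRecordTable(gen$corpus, f)
  back <- readRecordTable(f, label = "rt50")
  expect_equal(recordIds(back), recordIds(gen$corpus))
  expect_identical(as.list(descriptors(back)),
    as.list(descriptors(gen$corpus)))
  # descriptor assignments on disk match the in-memory total
  expect_equal(length(readLines(f)), sum(lengths(descriptors(gen$corpus))))
})

test_that("lexicons normalize, deduplicate and warn when empty", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Angelica", "Salvia", "Safflower", "Astragalus"), f)
  expect_equal(length(readLexicon(f)), 4)
  writeLines(c("Angelica", "# a comment", "", "  angelica  "), f)
  lex <- readLexicon(f)
  expect_equal(length(lex), 1)
  expect_equal(lexiconTerms(lex), "Angelica")
  writeLines(character(0), f)
  expect_warning(empty <- readLexicon(f), "no terms")
  expect_equal(length(empty), 0)
})

test_that("a 539-line synthetic lexicon reports size 539", {
  f <- withr::local_tempfile(fileext = ".txt")
  terms <- sprintf("Herb %03d", seq_len(539))
  writeLines(terms, f)
  # independent oracle: distinct line count straight off the file
  expect_equal(length(unique(readLines(f))), 539)
  expect_equal(length(readLexicon(f)), 539)
})

test_that("corpus construction enforces its invariants", {
  expect_error(Corpus(c("1", "1"), list("A", "B")), "duplicate")
  co <- Corpus("1", list(c("  A  B ", "A B", "C")))
  # whitespace normalization collapses the first two into one descriptor
  expect_equal(co[["1"]], c("A B", "C"))
})
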