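test_that("table intersection keeps shared pairs under each policy", {
  l <- FrequencyTable(data.frame(a = c("A", "C"), b = c("B", "D"),
    frequency = c(7L, 3L)), label = "CHD")
  r <- FrequencyTable(data.frame(a = c("A", "E"), b = c("B", "F"),
    frequency = c(19L, 2L)), label = "RA")
  m <- intersectTables(l, r)                       # default min
  expect_equal(tableLabel(m), "CHD_RA")
  expect_equal(pairFrequencies(m)$frequency, 7L)
  expect_equal(pairFrequencies(intersectTables(l, r, "sum"))$frequency, 26L)
  expect_equal(pairFrequencies(intersectTables(l, r, "left"))$frequency, 7L)
  expect_equal(pairFrequencies(intersectTables(l, r, "right"))$frequency,
    19L)
})

test_that("intersection edge cases: disjoint, self, commutativity, size", {
  l <- countFrequencies(generateCorpus(sweep_config(6))$corpus)
  r <- countFrequencies(generateCorpus(sweep_config(46))$corpus)
  d1 <- FrequencyTable(data.frame(a = "X", b = "Y", frequency = 1L), "l")
  d2 <- FrequencyTable(data.frame(a = "P", b = "Q", frequency = 1L), "r")
  expect_equal(nPairs(intersectTables(d1, d2)), 0)
  self <- intersectTables(l, l)
  expect_identical(pairFrequencies(self), pairFrequencies(l)) # idempotent
  for (pol in c("min", "sum")) {
    ab <- intersectTables(l, r, pol)
    ba <- intersectTables(r, l, pol)
    expect_same_pairs(pairFrequencies(ab), pairFrequencies(ba),
      with_freq = TRUE)
  }
  expect_true(nPairs(intersectTables(l, r)) <= min(nPairs(l), nPairs(r)))
})

test_that("lexicon filtering keeps herb pairs in both/either modes", {
  herbs <- c("Angelica", "Salvia", "Safflower", "Astragalus")
  lex <- HerbLexicon(herbs)
  herbPairs <- enumeratePairs(herbs)
  herbPairs$frequency <- 4L
  mixed <- rbind(herbPairs,
    data.frame(a = "Angelica", b = "Inflammation", frequency = 9L),
    data.frame(a = "Apoptosis", b = "Humans", frequency = 2L))
  tb <- FrequencyTable(mixed, label = "sino")
  both <- filterByLexicon(tb, lex, "both")
  expect_same_pairs(pairSet(both), herbPairs[, c("a", "b")])
  either <- filterByLexicon(tb, lex, "either")
  expect_equal(nPairs(either), nrow(herbPairs) + 1)
  # both-mode result is a subset of either-mode
  kb <- paste(pairSet(both)$a, pairSet(both)$b)
  ke <- paste(pairSet(either)$a, pairSet(either)$b)
  expect_true(all(kb %in% ke))
  # matching is case-insensitive but exact-term: Angelica touches its
  # three herb partners plus Inflammation
  expect_equal(nPairs(filterByLexicon(tb, HerbLexicon("ANGELICA"),
    "either")), 4)
  expect_equal(nPairs(filterByLexicon(tb, HerbLexicon("Angeli"),
    "either")), 0)
  expect_warning(none <- filterByLexicon(tb, HerbLexicon()), "empty")
  expect_equal(nPairs(none), 0)
})

test_that("planted herb pairs are recovered exactly from a noisy corpus", {
  herbs <- sprintf("Herb%02d", 1:3)
  planted <- data.frame(
    a = c("Herb01", "Herb01", "Herb02"),
    b = c("Herb02", "Herb03", "Herb03"),
    frequency = c(6L, 5L, 4L))
  gen <- generateCorpus(generatorConfig(nRecords = 120, vocabSize = 60,
    plantedPairs = planted, seed = 17, label = "sino"))
  tb <- countFrequencies(gen$corpus)
  got <- filterByLexicon(tb, HerbLexicon(herbs), "both")
  expect_same_pairs(pairFrequencies(got), planted, with_freq = TRUE)
})

test_that("item ranking counts records and breaks ties stably", {
  co <- Corpus(sprintf("r%02d", 1:17), c(
    rep(list(c("Angelica", "Fever")), 10),
    rep(list(c("Salvia", "angelica")), 7)))
  lex <- HerbLexicon(c("Angelica", "Salvia", "Safflower", "Astragalus"))
  rk <- rankItems(co, lex, topN = 4)
  # case-insensitive: 'angelica' records also count toward Angelica
  expect_equal(as.character(rk$term), c("Angelica", "Salvia"))
  expect_equal(as.integer(rk$count), c(17L, 7L))
  expect_true(all(rk$count <= length(co)))
  expect_equal(nrow(rankItems(Corpus(), lex, 4)), 0)
  # planted ground-truth counts recovered, ties lexicographic
  co2 <- Corpus(sprintf("s%02d", 1:6), c(
    rep(list("Safflower"), 3), rep(list("Astragalus"), 3)))
  rk2 <- rankItems(co2, lex, topN = 2)
  expect_equal(as.character(rk2$term), c("Astragalus", "Safflower"))
})

test_that("cross-query recovers a planted star's incident pairs", {
  gen <- generateCorpus(generatorConfig(nRecords = 150, vocabSize = 40,
    plantedStars = data.frame(center = "Inflammation", rimSize = 6L,
      frequency = 19L), seed = 23))
  tb <- countFrequencies(gen$corpus)
  got <- crossQuery(tb, "Inflammation", minFreq = 19)
  want <- data.frame(a = "Inflammation",
    b = gen$plantedStars[[1]]$rim, frequency = 19L)
  expect_same_pairs(pairFrequencies(got), want, with_freq = TRUE)
  # no-op filter: every term as seed at minimum frequency 1
  allTerms <- unique(c(pairFrequencies(tb)$a, pairFrequencies(tb)$b))
  expect_identical(pairFrequencies(crossQuery(tb, allTerms, 1)),
    pairFrequencies(tb))
  expect_equal(nPairs(crossQuery(tb, "NotATerm", 1)), 0)
  expect_error(crossQuery(tb, character(0)), "non-empty")
})
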