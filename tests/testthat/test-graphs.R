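test_that("the worked-example pair set builds the complete graph K8", {
  tb <- countFrequencies(table3Fixture())
  g <- toGraph(tb)
  expect_equal(nodeCount(g), 8)
  expect_equal(edgeCount(g), 28)
  deg <- igraph::degree(asIgraph(g))
  expect_true(all(deg == 7))                       # complete graph
  expect_equal(sum(deg), 2 * edgeCount(g))
})

test_that("graph construction: counts, empty input, endpoint-union oracle", {
  expect_equal(nodeCount(toGraph(FrequencyTable())), 0)
  expect_equal(edgeCount(toGraph(FrequencyTable())), 0)
  sl <- sliceAt(countFrequencies(
    generateCorpus(sweep_config(14))$corpus), 2)
  g <- toGraph(sl)
  expect_equal(edgeCount(g), nPairs(sl))
  # oracle: node count is the size of the endpoint union, by plain scan
  u <- character(0)
  for (r in seq_len(nrow(pairSet(sl))))
    u <- unique(c(u, pairSet(sl)$a[r], pairSet(sl)$b[r]))
  expect_equal(nodeCount(g), length(u))
  expect_setequal(graphNodes(g), u)
})

test_that("wheel detection finds hubs by degree", {
  star <- data.frame(a = "Hub", b = sprintf("N%d", 1:8), frequency = 3L)
  w <- findWheels(toGraph(star), minRim = 5)
  expect_equal(nrow(w), 1)
  expect_equal(w$center, "Hub")
  expect_equal(w$size, 8L)
  expect_setequal(w$rim[[1]], sprintf("N%d", 1:8))
  path4 <- data.frame(a = c("P1", "P2", "P3"), b = c("P2", "P3", "P4"),
    frequency = 1L)
  expect_equal(nrow(findWheels(toGraph(path4), minRim = 5)), 0)
  # beyond the maximum degree nothing qualifies
  g <- toGraph(star)
  expect_equal(nrow(findWheels(g,
    minRim = max(igraph::degree(asIgraph(g))) + 1L)), 0)
})

test_that("two stars sharing rim nodes report both centers", {
  g <- toGraph(two_star_frame())
  w <- findWheels(g, minRim = 5)
  expect_setequal(w$center, c("HubA", "HubB"))
  expect_equal(w$size[w$center == "HubA"], 8L)     # 5 shared + 3 own
  expect_equal(w$size[w$center == "HubB"], 7L)     # 5 shared + 2 own
  # degree-table oracle
  deg <- table(c(two_star_frame()$a, two_star_frame()$b))
  expect_setequal(w$center, names(deg)[deg >= 5])
  # shared rim nodes sit on both rims (wheel-wheel case)
  expect_true(all(sprintf("S%02d", 1:5) %in% w$rim[[1]]))
  expect_true(all(sprintf("S%02d", 1:5) %in% w$rim[[2]]))
})

test_that("hub intersection returns the analytically forced subgraph", {
  g <- toGraph(two_star_frame(shared = 5))
  sub <- hubIntersection(g, "HubA", "HubB")
  expect_equal(nodeCount(sub), 7)                  # 2 centers + 5 shared
  expect_equal(edgeCount(sub), 10)                 # each shared node x 2
  ed <- graphEdges(sub)
  expect_true(all(ed$a %in% c("HubA", "HubB") | ed$b %in% c("HubA", "HubB")))
  # the center-center edge joins iff present in the input
  ge <- graphEdges(hubIntersection(toGraph(
    two_star_frame(with_hub_edge = TRUE)), "HubA", "HubB"))
  expect_equal(nrow(ge), 11)
  expect_true(any(ge$a == "HubA" & ge$b == "HubB"))
})

test_that("hub intersection: disjoint neighbourhoods and errors", {
  df <- data.frame(a = c("X", "Y"), b = c("X1", "Y1"), frequency = 1L)
  sub <- hubIntersection(toGraph(df), "X", "Y")
  expect_setequal(graphNodes(sub), c("X", "Y"))
  expect_equal(edgeCount(sub), 0)
  expect_error(hubIntersection(toGraph(df), "X", "Nope"), "Nope")
})

test_that("hub intersection matches the common-neighbour oracle", {
  tb <- countFrequencies(generateCorpus(sweep_config(5))$corpus)
  g <- toGraph(sliceAt(tb, 2))
  nodes <- graphNodes(g)
  deg <- igraph::degree(asIgraph(g))
  hubs <- names(sort(deg, decreasing = TRUE))[1:2]
  sub <- hubIntersection(g, hubs[1], hubs[2])
  common <- oracle_common_neighbors(graphEdges(g), hubs[1], hubs[2])
  expect_setequal(graphNodes(sub), c(hubs, common))
  # subgraph property: every edge of the result is an input edge
  kin <- paste(graphEdges(g)$a, graphEdges(g)$b)
  kout <- paste(graphEdges(sub)$a, graphEdges(sub)$b)
  expect_true(all(kout %in% kin))
})

test_that("graph export: SIF rows, GraphML attributes, TSV round-trip", {
  tb <- countFrequencies(table3Fixture())
  g <- toGraph(tb)
  dir <- withr::local_tempdir()
  sif <- file.path(dir, "k8.sif")
  exportGraph(g, "sif", sif)
  rows <- readLines(sif)
  expect_length(rows, 28)
  expect_true(all(grepl("\tcooc\t", rows, fixed = TRUE)))
  # edge TSV reimports to an identical graph
  etsv <- file.path(dir, "k8_edges.tsv")
  exportGraph(g, "edge_tsv", etsv)
  back <- toGraph(readFrequencyTable(etsv))
  expect_equal(graphEdges(back), graphEdges(g))
  expect_identical(graphNodes(back), graphNodes(g))
  # GraphML carries the frequency edge attribute
  gml <- file.path(dir, "k8.graphml")
  exportGraph(g, "graphml", gml)
  re <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(re), 28)
  expect_true("frequency" %in% igraph::edge_attr_names(re))
  # empty graph exports are empty/header-only per format
  e <- toGraph(FrequencyTable())
  empty_sif <- file.path(dir, "empty.sif")
  exportGraph(e, "sif", empty_sif)
  expect_length(readLines(empty_sif), 0)
  empty_tsv <- file.path(dir, "empty.tsv")
  exportGraph(e, "edge_tsv", empty_tsv)
  expect_length(readLines(empty_tsv), 1)           # header only
  expect_error(exportGraph(g, "dot", file.path(dir, "x")), "arg")
})
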