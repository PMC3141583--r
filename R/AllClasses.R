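#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges CharacterList
NULL

#' Corpus of descriptor records
#'
#' A `Corpus` holds an ordered collection of citation records, each carrying
#' a record identifier (a PMID or a local id) and a set of descriptor terms
#' (MeSH headings or database keywords).  Descriptor sets are deduplicated
#' and whitespace-normalized on construction; record ids must be unique.
#' Records with zero or one descriptor are retained: they simply emit no
#' co-occurrence pairs.
#'
#' @slot records A [IRanges::CharacterList] named by record id; each element
#'   is the record's descriptor set, sorted bytewise.
#' @slot label Character scalar naming the corpus source (e.g. `"CHD"`,
#'   `"RA"`, `"CHD_RA"`).
#'
#' @seealso [Corpus()] for the constructor, [readMedlineXML()],
#'   [readRecordTable()] for parsers, [countFrequencies()].
#' @exportClass Corpus
setClass("Corpus",
    representation(records = "CharacterList", label = "character"),
    prototype(records = IRanges::CharacterList(), label = "corpus"))

setValidity("Corpus", function(object) {
    msgs <- character(0)
    ids <- names(object@records)
    if (length(object@records) > 0L) {
        if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
            msgs <- c(msgs, "every record must have a non-empty id")
        else if (anyDuplicated(ids))
            msgs <- c(msgs, paste0("duplicate record id(s): ",
                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    d <- unlist(object@records, use.names = FALSE)
    if (length(d) && any(!nzchar(d)))
        msgs <- c(msgs, "descriptors must be non-empty strings")
    dup <- vapply(object@records, anyDuplicated, integer(1))
    if (any(dup > 0L))
        msgs <- c(msgs, "descriptor sets must not contain duplicates")
    if (length(object@label) != 1L || is.na(object@label))
        msgs <- c(msgs, "label must be a single string")
    if (length(msgs)) msgs else TRUE
})

#' Lexicon of filter terms
#'
#' An ordered set of normalized terms used to filter pair tables and rank
#' term occurrences, emulating a curated table such as a list of Chinese
#' herbs.  Matching against a lexicon is case-insensitive; the stored terms
#' keep their original case.
#'
#' @slot terms Character vector of distinct, normalized, non-empty terms,
#'   sorted bytewise.
#'
#' @seealso [HerbLexicon()], [readLexicon()], [filterByLexicon()],
#'   [rankItems()].
#' @exportClass HerbLexicon
setClass("HerbLexicon", representation(terms = "character"),
    prototype(terms = character(0)))

setValidity("HerbLexicon", function(object) {
    msgs <- character(0)
    if (length(object@terms) && any(!nzchar(object@terms)))
        msgs <- c(msgs, "lexicon terms must be non-empty")
    if (anyDuplicated(tolower(object@terms)))
        msgs <- c(msgs, "lexicon terms must be distinct (case-insensitive)")
    if (length(msgs)) msgs else TRUE
})

#' Descriptor-pair frequency table
#'
#' Maps each canonical unordered descriptor pair to the number of records in
#' which the two descriptors co-occur.  Pairs are stored with endpoints in
#' bytewise-lexicographic order (`a < b`) and rows sorted by descending
#' frequency, then lexicographically, so that persistence is bit-exact
#' across runs.
#'
#' @slot pairs A data.frame with character columns `a`, `b` and integer
#'   column `frequency` (all >= 1); one row per distinct pair.
#' @slot label Character scalar naming the source corpus.
#'
#' @seealso [countFrequencies()], [sliceAt()], [levelDistribution()],
#'   [intersectTables()], [writeFrequencyTable()].
#' @exportClass FrequencyTable
setClass("FrequencyTable",
    representation(pairs = "data.frame", label = "character"))

.emptyPairFrame <- function(frequency = TRUE) {
    df <- data.frame(a = character(0), b = character(0),
        stringsAsFactors = FALSE)
    if (frequency) df$frequency <- integer(0)
    df
}

.validPairFrame <- function(df, needFreq = TRUE) {
    msgs <- character(0)
    need <- c("a", "b", if (needFreq) "frequency")
    if (!all(need %in% names(df)))
        return(paste0("pair frame needs columns: ", paste(need, collapse = ", ")))
    if (nrow(df)) {
        lt <- .strLt(df$a, df$b)
        if (!all(lt))
            msgs <- c(msgs, "pairs must be canonical (a < b, bytewise) and a != b")
        if (needFreq && (any(df$frequency < 1L) ||
                any(df$frequency != as.integer(df$frequency))))
            msgs <- c(msgs, "frequencies must be positive integers")
        if (anyDuplicated(paste(df$a, df$b, sep = "\x1f")))
            msgs <- c(msgs, "pairs must be distinct")
    }
    msgs
}

setValidity("FrequencyTable", function(object) {
    msgs <- .validPairFrame(object@pairs, needFreq = TRUE)
    if (length(object@label) != 1L)
        msgs <- c(msgs, "label must be a single string")
    if (length(msgs)) msgs else TRUE
})

#' Frequency slice of a pair table
#'
#' The set of descriptor pairs whose corpus frequency is greater than or
#' equal to a threshold `i`.  Slices are nested: the slice at `i + 1` is a
#' subset of the slice at `i`, and the slice at 1 is the whole table.
#'
#' @slot threshold Integer scalar >= 1.
#' @slot pairs Canonical pair frame (`a`, `b`, `frequency`) of the retained
#'   pairs, with their original frequencies.
#'
#' @seealso [sliceAt()], [levelDistribution()].
#' @exportClass Slice
setClass("Slice",
    representation(threshold = "integer", pairs = "data.frame"))

setValidity("Slice", function(object) {
    msgs <- .validPairFrame(object@pairs, needFreq = TRUE)
    if (length(object@threshold) != 1L || object@threshold < 1L)
        msgs <- c(msgs, "threshold must be a single integer >= 1")
    else if (nrow(object@pairs) && any(object@pairs$frequency < object@threshold))
        msgs <- c(msgs, "all pair frequencies must be >= threshold")
    if (length(msgs)) msgs else TRUE
})

#' Level distribution of a pair table
#'
#' The set of descriptor pairs at an exact frequency `i`: the difference of
#' the adjacent slices at `i` and `i + 1`.  Level distributions at distinct
#' levels are disjoint and jointly partition the pair table.
#'
#' @slot level Integer scalar >= 1.
#' @slot pairs Canonical pair frame (`a`, `b`) of the pairs at this level.
#'
#' @seealso [levelDistribution()], [derivativeSeries()].
#' @exportClass LevelDistribution
setClass("LevelDistribution",
    representation(level = "integer", pairs = "data.frame"))

setValidity("LevelDistribution", function(object) {
    msgs <- .validPairFrame(object@pairs, needFreq = FALSE)
    if (length(object@level) != 1L || object@level < 1L)
        msgs <- c(msgs, "level must be a single integer >= 1")
    if (length(msgs)) msgs else TRUE
})

#' Family of per-level pair sets at a derivative order
#'
#' For a table with maximum frequency `k`, the order-0 series holds the
#' level distributions at levels `1..k`; each differencing step (set
#' difference of adjacent levels) drops the top level, so the order-`m`
#' series is defined on levels `1..k-m`.  Levels above that bound are
#' absent (undefined), which is distinct from a level that is present but
#' empty.
#'
#' @slot order Integer scalar >= 0, the derivative order.
#' @slot levels Named list of canonical pair frames (`a`, `b`); names are
#'   the level indices `"1".."k-order"` in order.
#' @slot label Character scalar carried over from the source table.
#'
#' @seealso [derivativeSeries()], [verifyConstantDerivative()].
#' @exportClass DerivativeSeries
setClass("DerivativeSeries",
    representation(order = "integer", levels = "list", label = "character"))

setValidity("DerivativeSeries", function(object) {
    msgs <- character(0)
    if (length(object@order) != 1L || object@order < 0L)
        msgs <- c(msgs, "order must be a single integer >= 0")
    n <- length(object@levels)
    if (n && !identical(names(object@levels), as.character(seq_len(n))))
        msgs <- c(msgs, "levels must be named 1..n consecutively")
    bad <- unlist(lapply(object@levels, .validPairFrame, needFreq = FALSE))
    msgs <- c(msgs, bad)
    if (length(msgs)) msgs else TRUE
})

#' Report of the constant-derivative verification
#'
#' Records, for every (order, level) combination checked, whether the
#' order-`m` derivative at that level is set-identical to the first
#' derivative at the same level, together with the overall verdict.  This is
#' the executable form of the observation that distinct-frequency level
#' distributions are disjoint, so differencing them changes nothing.
#'
#' @slot checks A data.frame with integer columns `order`, `level` and
#'   logical column `identical`.
#' @slot pass Logical scalar: `TRUE` iff every check passed.
#' @slot maxOrder Integer scalar, the highest order checked.
#'
#' @seealso [verifyConstantDerivative()].
#' @exportClass DerivativeVerification
setClass("DerivativeVerification",
    representation(checks = "data.frame", pass = "logical",
        maxOrder = "integer"))

#' Undirected descriptor co-occurrence graph
#'
#' Nodes are descriptor terms; edges are canonical descriptor pairs carrying
#' a `frequency` attribute.  The graph is simple (no self-loops, no
#' multi-edges) and is stored with vertices and edges in deterministic
#' bytewise order so exports are bit-exact across runs.
#'
#' @slot graph An [igraph::igraph] undirected graph with vertex attribute
#'   `name` and numeric edge attribute `frequency`.
#'
#' @seealso [toGraph()], [findWheels()], [hubIntersection()],
#'   [exportGraph()].
#' @exportClass CoocGraph
setClass("CoocGraph", representation(graph = "ANY"))

setValidity("CoocGraph", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g))
        return("graph slot must be an igraph object")
    msgs <- character(0)
    if (igraph::is_directed(g))
        msgs <- c(msgs, "graph must be undirected")
    if (igraph::ecount(g) > 0L) {
        if (any(igraph::which_loop(g)))
            msgs <- c(msgs, "graph must not contain self-loops")
        if (!"frequency" %in% igraph::edge_attr_names(g))
            msgs <- c(msgs, "edges must carry a frequency attribute")
    }
    if (length(msgs)) msgs else TRUE
})

#' Configuration of the synthetic corpus generator
#'
#' Describes a world the generator can realize deterministically from its
#' seed: background records drawing descriptor sets from a heavy-tailed
#' (power-law rank) vocabulary, plus planted pairs with exact target
#' frequencies and planted stars (one center linked to each rim term at a
#' fixed per-edge frequency).
#'
#' @slot nRecords Integer >= 0: number of records in the corpus.
#' @slot vocabSize Integer >= 1: background vocabulary size.
#' @slot descriptorsPerRecord Integer vector of length 2, the inclusive
#'   range of background descriptor-set sizes.
#' @slot vocabularySkew Positive double: exponent of the power-law rank
#'   distribution over the vocabulary (larger = heavier head).
#' @slot plantedPairs data.frame (`a`, `b`, `frequency`): pairs inserted
#'   into exactly `frequency` records each.
#' @slot plantedStars data.frame (`center`, `rimSize`, `frequency`).
#' @slot seed Integer seed driving all randomness.
#' @slot label Character scalar for the generated corpus.
#'
#' @seealso [generatorConfig()], [generateCorpus()].
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
    representation(nRecords = "integer", vocabSize = "integer",
        descriptorsPerRecord = "integer", vocabularySkew = "numeric",
        plantedPairs = "data.frame", plantedStars = "data.frame",
        seed = "integer", label = "character"))

setValidity("GeneratorConfig", function(object) {
    msgs <- character(0)
    if (object@nRecords < 0L)
        msgs <- c(msgs, "nRecords must be >= 0")
    if (object@vocabSize < 1L)
        msgs <- c(msgs, "vocabSize must be >= 1")
    r <- object@descriptorsPerRecord
    if (length(r) != 2L || r[1] < 1L || r[2] < r[1])
        msgs <- c(msgs, "descriptorsPerRecord must be an increasing range with min >= 1")
    if (object@vocabularySkew <= 0)
        msgs <- c(msgs, "vocabularySkew must be positive")
    pp <- object@plantedPairs
    if (nrow(pp)) {
        if (any(pp$frequency < 1L))
            msgs <- c(msgs, "planted pair frequencies must be >= 1")
        if (any(pp$frequency > object@nRecords))
            msgs <- c(msgs, "infeasible plant: planted pair frequency exceeds nRecords")
        if (any(pp$a == pp$b))
            msgs <- c(msgs, "planted pairs must have distinct endpoints")
    }
    ps <- object@plantedStars
    if (nrow(ps)) {
        if (any(ps$rimSize < 1L) || any(ps$frequency < 1L))
            msgs <- c(msgs, "star rimSize and frequency must be >= 1")
        if (sum(ps$rimSize * ps$frequency) > object@nRecords)
            msgs <- c(msgs,
                "infeasible plant: star edge records exceed nRecords")
    }
    if (length(msgs)) msgs else TRUE
})
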