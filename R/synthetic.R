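#' Configure the synthetic corpus generator
#'
#' Describes a corpus world that [generateCorpus()] realizes
#' deterministically: `nRecords` citation records whose background
#' descriptor sets are drawn from a `vocabSize`-term vocabulary under a
#' power-law rank distribution (probability of rank `r` proportional to
#' `r^-vocabularySkew`), so that pair frequencies span a broad, thinning
#' range the way real keyword corpora do.  On top of the background,
#' specific pairs can be planted at exact target frequencies, and stars
#' (one center linked to each of `rimSize` rim terms at a fixed per-edge
#' frequency) can be planted for motif-recovery tests.
#'
#' @param nRecords Number of records, >= 0.
#' @param vocabSize Background vocabulary size, >= 1.
#' @param descriptorsPerRecord Length-2 integer range of background
#'   descriptor-set sizes per record (inclusive).
#' @param vocabularySkew Power-law exponent, > 0.  1.5 gives the
#'   heavy-tailed head typical of controlled-vocabulary usage.
#' @param plantedPairs data.frame with columns `a`, `b`, `frequency`, or
#'   NULL.  Each pair is inserted into exactly `frequency` records; the
#'   target must not exceed `nRecords`.
#' @param plantedStars data.frame with columns `center`, `rimSize`,
#'   `frequency`, or NULL.  Each star edge occupies `frequency` dedicated
#'   records containing only the center and one rim term, so the star's
#'   realized structure is exact.
#' @param seed Integer seed; all randomness flows from it.
#' @param label Label for the generated corpus.
#' @return A [GeneratorConfig-class].
#' @seealso [generateCorpus()]
#' @export
generatorConfig <- function(nRecords = 100L, vocabSize = 50L,
                            descriptorsPerRecord = c(2L, 8L),
                            vocabularySkew = 1.5,
                            plantedPairs = NULL, plantedStars = NULL,
                            seed = 0L, label = "synthetic") {
    if (is.null(plantedPairs))
        plantedPairs <- data.frame(a = character(0), b = character(0),
            frequency = integer(0), stringsAsFactors = FALSE)
    if (is.null(plantedStars))
        plantedStars <- data.frame(center = character(0),
            rimSize = integer(0), frequency = integer(0),
            stringsAsFactors = FALSE)
    plantedPairs$frequency <- as.integer(plantedPairs$frequency)
    plantedStars$rimSize <- as.integer(plantedStars$rimSize)
    plantedStars$frequency <- as.integer(plantedStars$frequency)
    new("GeneratorConfig",
        nRecords = .assertCount(nRecords, "nRecords", min = 0L),
        vocabSize = .assertCount(vocabSize, "vocabSize", min = 1L),
        descriptorsPerRecord = as.integer(descriptorsPerRecord),
        vocabularySkew = as.numeric(vocabularySkew),
        plantedPairs = plantedPairs, plantedStars = plantedStars,
        seed = as.integer(seed), label = label)
}

# one background descriptor set: size from the configured range, terms
# sampled without replacement under the power-law rank weights
.drawRecord <- function(vocab, weights, sizeRange) {
    sizes <- sizeRange[1L]:sizeRange[2L]
    k <- if (length(sizes) == 1L) sizes else sample(sizes, 1L)
    k <- min(k, length(vocab))
    .radixSort(sample(vocab, k, replace = FALSE, prob = weights))
}

#' Generate a synthetic corpus with known ground truth
#'
#' Realizes a [generatorConfig()] world.  Background records draw their
#' descriptor sets from the skewed vocabulary; each planted pair has both
#' endpoints inserted into exactly its target number of records (chosen
#' without replacement); each planted star edge gets dedicated records
#' containing only the center and one rim term.  Background draws that
#' would accidentally raise a planted pair above its target are redrawn
#' (bounded retries, then an error), so the returned ground truth is exact.
#'
#' The same configuration (including seed) always produces a
#' byte-identical corpus; the caller's RNG stream is left untouched.
#'
#' @param config A [GeneratorConfig-class].
#' @return A list with elements:
#'   \describe{
#'     \item{`corpus`}{the generated [Corpus-class];}
#'     \item{`plantedPairs`}{data.frame `a`, `b`, `frequency` (canonical
#'       order, exact realized = target frequencies);}
#'     \item{`plantedStars`}{list, one entry per star, with `center`,
#'       `rim` (character vector) and `frequency`;}
#'     \item{`seed`}{the seed used.}
#'   }
#' @examples
#' gen <- generateCorpus(generatorConfig(nRecords = 20, vocabSize = 10,
#'                                       seed = 1))
#' length(gen$corpus)
#' @export
generateCorpus <- function(config) {
    stopifnot(is(config, "GeneratorConfig"))
    validObject(config)
    .withSeed(config@seed, .generateCorpusImpl(config))
}

.generateCorpusImpl <- function(config) {
    n <- config@nRecords
    pp <- config@plantedPairs
    ps <- config@plantedStars
    if (nrow(pp)) {
        cp <- .canonicalizePairs(.normalizeTerm(pp$a), .normalizeTerm(pp$b))
        pp <- data.frame(a = cp$a, b = cp$b, frequency = pp$frequency,
            stringsAsFactors = FALSE)
    }
    if (n == 0L)
        return(list(corpus = Corpus(label = config@label),
            plantedPairs = .sortPairFrame(pp), plantedStars = list(),
            seed = config@seed))

    vocab <- sprintf("T%04d", seq_len(config@vocabSize))
    weights <- seq_len(config@vocabSize)^(-config@vocabularySkew)
    weights <- weights / sum(weights)

    # star edges claim dedicated records first
    starRecords <- list()   # record index -> c(center, rim term)
    stars <- list()
    free <- seq_len(n)
    if (nrow(ps)) {
        for (s in seq_len(nrow(ps))) {
            center <- .normalizeTerm(ps$center[s])
            rim <- sprintf("%s rim%02d", center, seq_len(ps$rimSize[s]))
            for (r in rim) {
                take <- free[seq_len(ps$frequency[s])]
                free <- free[-seq_len(ps$frequency[s])]
                for (idx in take)
                    starRecords[[as.character(idx)]] <- c(center, r)
            }
            stars[[length(stars) + 1L]] <-
                list(center = center, rim = rim,
                    frequency = ps$frequency[s])
        }
    }

    # background draw per record; plant insertions tracked separately so a
    # colliding background can be redrawn without disturbing any plant
    background <- vector("list", n)
    plantTerms <- vector("list", n)
    for (i in free)
        background[[i]] <- .drawRecord(vocab, weights,
            config@descriptorsPerRecord)

    # each plant gets its own disjoint host records, so plants sharing an
    # endpoint (e.g. a planted triangle) cannot inflate one another
    plantHosts <- vector("list", nrow(pp))
    if (nrow(pp)) {
        avail <- free
        for (p in seq_len(nrow(pp))) {
            f <- pp$frequency[p]
            if (f > length(avail))
                stop("infeasible plant: not enough free records for pair ",
                    pp$a[p], " / ", pp$b[p], call. = FALSE)
            hosts <- if (length(avail) == 1L) avail
                else sample(avail, f, replace = FALSE)
            avail <- setdiff(avail, hosts)
            plantHosts[[p]] <- hosts
            for (idx in hosts)
                plantTerms[[idx]] <- unique(c(plantTerms[[idx]],
                    pp$a[p], pp$b[p]))
        }
    }

    compose <- function(i) {
        key <- as.character(i)
        if (!is.null(starRecords[[key]])) starRecords[[key]]
        else unique(c(plantTerms[[i]], background[[i]]))
    }

    # redraw backgrounds that accidentally realize a planted pair beyond
    # its target (possible when planted terms also live in the vocabulary)
    if (nrow(pp)) {
        for (attempt in seq_len(100L)) {
            colliders <- integer(0)
            for (p in seq_len(nrow(pp))) {
                hit <- Filter(function(i) {
                    d <- compose(i)
                    pp$a[p] %in% d && pp$b[p] %in% d
                }, free)
                colliders <- union(colliders,
                    setdiff(hit, plantHosts[[p]]))
            }
            if (!length(colliders)) break
            if (attempt == 100L)
                stop("could not realize planted pair frequencies exactly ",
                    "after 100 redraws; loosen the configuration",
                    call. = FALSE)
            for (idx in colliders)
                background[[idx]] <- .drawRecord(vocab, weights,
                    config@descriptorsPerRecord)
        }
        for (p in seq_len(nrow(pp))) {
            realized <- sum(vapply(seq_len(n), function(i) {
                d <- compose(i)
                pp$a[p] %in% d && pp$b[p] %in% d
            }, logical(1)))
            if (realized != pp$frequency[p])
                stop("planted pair ", pp$a[p], " / ", pp$b[p],
                    " realized at ", realized, ", target ", pp$frequency[p],
                    call. = FALSE)
        }
    }

    ids <- sprintf("R%06d", seq_len(n))
    list(corpus = Corpus(ids, lapply(seq_len(n), compose),
            label = config@label),
        plantedPairs = .sortPairFrame(pp), plantedStars = stars,
        seed = config@seed)
}

#' Worked-example corpus: one citation with eight MeSH headings
#'
#' The single printed record used throughout the worked example: PMID
#' 20464912 with its eight headings (a mixed descriptor/qualifier list as
#' exported from a hand-curated record table).  Its pair enumeration is the
#' canonical check for the pair-construction semantics: exactly
#' `choose(8, 2) = 28` unordered pairs.
#'
#' @return A [Corpus-class] with one record.
#' @examples
#' nrow(enumeratePairs(table3Fixture()[["20464912"]]))
#' @export
table3Fixture <- function() {
    Corpus("20464912", list(c(
        "physiopathology", "rehabilitation", "Evidence-Based Medicine",
        "Humans", "Muscle Stretching Exercises", "Physical Fitness",
        "Resistance Training", "Treatment Outcome")),
        label = "worked_example")
}
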