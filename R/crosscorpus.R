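#' Intersect the pair tables of two corpora
#'
#' Keeps the pairs present in both tables — the construction of a shared
#' co-occurrence table for two disease corpora (e.g. the CHD and RA tables
#' reduced to their common pairs).  The combined frequency of a retained
#' pair is set by `policy`:
#' \describe{
#'   \item{`min`}{the smaller of the two frequencies (default).  A pair then
#'     reaches slice level `f` of the intersection iff it reaches level `f`
#'     in both corpora.}
#'   \item{`sum`}{the sum of the two frequencies.}
#'   \item{`left`, `right`}{the frequency from one side only.}
#' }
#'
#' @param left,right [FrequencyTable-class] objects.
#' @param policy Combine policy; see above.
#' @return A [FrequencyTable-class] labelled
#'   `"<left label>_<right label>"`.
#' @examples
#' l <- FrequencyTable(data.frame(a = "A", b = "B", frequency = 7L), "L")
#' r <- FrequencyTable(data.frame(a = "A", b = "B", frequency = 19L), "R")
#' pairFrequencies(intersectTables(l, r))
#' @export
intersectTables <- function(left, right,
                            policy = c("min", "sum", "left", "right")) {
    stopifnot(is(left, "FrequencyTable"), is(right, "FrequencyTable"))
    policy <- match.arg(policy)
    label <- paste(left@label, right@label, sep = "_")
    lk <- .pairKey(left@pairs$a, left@pairs$b)
    rk <- .pairKey(right@pairs$a, right@pairs$b)
    common <- intersect(lk, rk)
    if (!length(common)) return(FrequencyTable(label = label))
    li <- match(common, lk)
    ri <- match(common, rk)
    freq <- switch(policy,
        min = pmin(left@pairs$frequency[li], right@pairs$frequency[ri]),
        sum = left@pairs$frequency[li] + right@pairs$frequency[ri],
        left = left@pairs$frequency[li],
        right = right@pairs$frequency[ri])
    FrequencyTable(data.frame(a = left@pairs$a[li], b = left@pairs$b[li],
        frequency = freq, stringsAsFactors = FALSE), label = label)
}

#' Filter a pair table by a term lexicon
#'
#' Emulates filtering a keyword pair table through a curated term list
#' (e.g. a table of Chinese herbs).  Matching is case-insensitive and
#' exact-term — substring matching on herb names would produce uncontrolled
#' false positives.
#'
#' @param table A [FrequencyTable-class].
#' @param lexicon A [HerbLexicon-class].
#' @param mode `"both"` keeps pairs whose two endpoints are lexicon terms
#'   (term-term networks); `"either"` keeps pairs with at least one lexicon
#'   endpoint (term-concept links).
#' @return A filtered [FrequencyTable-class].  An empty lexicon yields an
#'   empty table with a warning.
#' @export
filterByLexicon <- function(table, lexicon, mode = c("both", "either")) {
    stopifnot(is(table, "FrequencyTable"), is(lexicon, "HerbLexicon"))
    mode <- match.arg(mode)
    if (length(lexicon) == 0L) {
        warning("empty lexicon: filter result is empty", call. = FALSE)
        return(FrequencyTable(label = table@label))
    }
    terms <- tolower(lexiconTerms(lexicon))
    inA <- tolower(table@pairs$a) %in% terms
    inB <- tolower(table@pairs$b) %in% terms
    keep <- if (mode == "both") inA & inB else inA | inB
    FrequencyTable(table@pairs[keep, , drop = FALSE], label = table@label)
}

#' Rank lexicon terms by record occurrence
#'
#' Counts, for each lexicon term, the number of corpus records whose
#' descriptor set contains the term (case-insensitive), and returns the
#' terms in descending count order — the step that surfaces the most-used
#' herbs in a treatment-literature corpus.  Terms occurring in no record
#' are omitted; ties break bytewise-lexicographically.
#'
#' @param corpus A [Corpus-class].
#' @param lexicon A [HerbLexicon-class].
#' @param topN Truncate the ranking to its first `topN` entries.
#' @return A [S4Vectors::DataFrame] with columns `term` and `count`.
#' @export
rankItems <- function(corpus, lexicon, topN = 4L) {
    stopifnot(is(corpus, "Corpus"), is(lexicon, "HerbLexicon"))
    topN <- .assertCount(topN, "topN", min = 1L)
    terms <- lexiconTerms(lexicon)
    low <- tolower(terms)
    descs <- as.list(descriptors(corpus))
    counts <- vapply(low, function(t)
        sum(vapply(descs, function(d) t %in% tolower(d), logical(1))),
        integer(1))
    keep <- counts >= 1L
    terms <- terms[keep]; counts <- counts[keep]
    o <- .radixOrder(-counts, terms)
    n <- min(topN, length(terms))
    S4Vectors::DataFrame(term = terms[o][seq_len(n)],
        count = unname(counts[o][seq_len(n)]))
}

#' Cross-query a pair table with seed terms
#'
#' Keeps the pairs that touch at least one seed term and reach a minimum
#' frequency — the verification step that, starting from a handful of herb
#' names, pulls out their co-occurrence neighbourhoods (e.g. a four-herb
#' network at co-occurrence frequency >= 4).
#'
#' @param table A [FrequencyTable-class].
#' @param seedTerms Non-empty character vector of seed terms
#'   (case-insensitive match).
#' @param minFreq Minimum pair frequency, integer >= 1.
#' @return A filtered [FrequencyTable-class].
#' @export
crossQuery <- function(table, seedTerms, minFreq = 1L) {
    stopifnot(is(table, "FrequencyTable"))
    if (!length(seedTerms))
        stop("seedTerms must be non-empty", call. = FALSE)
    minFreq <- .assertCount(minFreq, "minFreq", min = 1L)
    seeds <- tolower(.normalizeTerm(as.character(seedTerms)))
    keep <- (tolower(table@pairs$a) %in% seeds |
             tolower(table@pairs$b) %in% seeds) &
        table@pairs$frequency >= minFreq
    FrequencyTable(table@pairs[keep, , drop = FALSE], label = table@label)
}
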