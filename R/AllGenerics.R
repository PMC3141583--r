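#' @rdname Corpus-class
#' @param x,object An object of the documented class.
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' @rdname Corpus-class
#' @export
setGeneric("descriptors", function(x) standardGeneric("descriptors"))

#' @rdname Corpus-class
#' @export
setGeneric("corpusLabel", function(x) standardGeneric("corpusLabel"))

#' @rdname HerbLexicon-class
#' @export
setGeneric("lexiconTerms", function(x) standardGeneric("lexiconTerms"))

#' @rdname FrequencyTable-class
#' @export
setGeneric("pairFrequencies", function(x) standardGeneric("pairFrequencies"))

#' @rdname FrequencyTable-class
#' @export
setGeneric("tableLabel", function(x) standardGeneric("tableLabel"))

#' Number of distinct pairs in a table, slice, level or series level
#' @param x A pair-carrying object.
#' @return Integer count of distinct pairs.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' Set of pairs carried by an object
#' @param x A pair-carrying object.
#' @return A data.frame with character columns `a`, `b` (canonical order).
#' @export
setGeneric("pairSet", function(x) standardGeneric("pairSet"))

#' @rdname maxFrequency
#' @export
setGeneric("maxFrequency", function(x) standardGeneric("maxFrequency"))

#' @rdname enumeratePairs
#' @export
setGeneric("enumeratePairs",
    function(x, ...) standardGeneric("enumeratePairs"))

#' @rdname toGraph
#' @export
setGeneric("toGraph", function(x, ...) standardGeneric("toGraph"))
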