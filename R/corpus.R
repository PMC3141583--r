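#' Construct a corpus of descriptor records
#'
#' Builds a [Corpus-class] from record ids and descriptor sets.  Descriptors
#' are whitespace-normalized, empty strings dropped, duplicates removed, and
#' each set stored sorted bytewise.
#'
#' @param recordIds Character vector of record identifiers (PMIDs or local
#'   ids); must be distinct.
#' @param descriptors A list (or [IRanges::CharacterList]) parallel to
#'   `recordIds`; each element the record's descriptor terms.
#' @param label Corpus source label, e.g. `"CHD"`.
#' @return A [Corpus-class] object.
#' @examples
#' Corpus("1", list(c("Humans", "Apoptosis")), label = "demo")
#' @export
Corpus <- function(recordIds = character(0), descriptors = list(),
                   label = "corpus") {
    if (length(recordIds) != length(descriptors))
        stop("recordIds and descriptors must have equal length", call. = FALSE)
    .assertScalarString(label, "label")
    descriptors <- lapply(descriptors, function(d) {
        d <- .normalizeTerm(as.character(d))
        .radixSort(unique(d[nzchar(d)]))
    })
    cl <- IRanges::CharacterList(descriptors)
    names(cl) <- as.character(recordIds)
    new("Corpus", records = cl, label = label)
}

#' @rdname Corpus-class
#' @export
setMethod("recordIds", "Corpus", function(x) names(x@records))

#' @rdname Corpus-class
#' @export
setMethod("descriptors", "Corpus", function(x) x@records)

#' @rdname Corpus-class
#' @export
setMethod("corpusLabel", "Corpus", function(x) x@label)

#' @rdname Corpus-class
#' @export
setMethod("length", "Corpus", function(x) length(x@records))

#' @rdname Corpus-class
#' @param i Record index or record id.
#' @export
setMethod("[[", "Corpus", function(x, i) x@records[[i]])

setMethod("show", "Corpus", function(object) {
    nd <- sum(lengths(object@records))
    cat("Corpus '", object@label, "': ", length(object@records),
        " record(s), ", nd, " descriptor assignment(s)\n", sep = "")
    if (length(object@records)) {
        head_ids <- utils::head(names(object@records), 3L)
        for (id in head_ids)
            cat("  ", id, ": {",
                paste(utils::head(object@records[[id]], 4L), collapse = ", "),
                if (length(object@records[[id]]) > 4L) ", ..." else "",
                "}\n", sep = "")
        if (length(object@records) > 3L) cat("  ...\n")
    }
})

#' Construct a term lexicon
#'
#' @param terms Character vector of terms; normalized and deduplicated
#'   case-insensitively (first spelling wins).
#' @return A [HerbLexicon-class] object.
#' @examples
#' HerbLexicon(c("Angelica", "Salvia", "Safflower", "Astragalus"))
#' @export
HerbLexicon <- function(terms = character(0)) {
    terms <- .normalizeTerm(as.character(terms))
    terms <- terms[nzchar(terms)]
    terms <- terms[!duplicated(tolower(terms))]
    new("HerbLexicon", terms = .radixSort(terms))
}

#' @rdname HerbLexicon-class
#' @export
setMethod("lexiconTerms", "HerbLexicon", function(x) x@terms)

#' @rdname HerbLexicon-class
#' @export
setMethod("length", "HerbLexicon", function(x) length(x@terms))

setMethod("show", "HerbLexicon", function(object) {
    cat("HerbLexicon: ", length(object@terms), " term(s)\n", sep = "")
    if (length(object@terms))
        cat("  ", paste(utils::head(object@terms, 6L), collapse = ", "),
            if (length(object@terms) > 6L) ", ..." else "", "\n", sep = "")
})
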