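#' Construct a frequency table from a pair frame
#'
#' Rows are canonicalized (endpoints swapped into bytewise order, self-pairs
#' rejected) and sorted by descending frequency then lexicographically.
#'
#' @param pairs data.frame with columns `a`, `b`, `frequency`.
#' @param label Source label.
#' @return A [FrequencyTable-class].
#' @export
FrequencyTable <- function(pairs = .emptyPairFrame(), label = "table") {
    .assertScalarString(label, "label")
    stopifnot(is.data.frame(pairs),
        all(c("a", "b", "frequency") %in% names(pairs)))
    if (nrow(pairs) && any(pairs$a == pairs$b))
        stop("self-pairs are not allowed", call. = FALSE)
    cp <- .canonicalizePairs(as.character(pairs$a), as.character(pairs$b))
    df <- data.frame(a = cp$a, b = cp$b,
        frequency = as.integer(pairs$frequency), stringsAsFactors = FALSE)
    new("FrequencyTable", pairs = .sortPairFrame(df), label = label)
}

#' @rdname FrequencyTable-class
#' @param x,object A [FrequencyTable-class].
#' @export
setMethod("pairFrequencies", "FrequencyTable", function(x) x@pairs)

#' @rdname FrequencyTable-class
#' @export
setMethod("tableLabel", "FrequencyTable", function(x) x@label)

#' @rdname FrequencyTable-class
#' @export
setMethod("nPairs", "FrequencyTable", function(x) nrow(x@pairs))

#' @rdname FrequencyTable-class
#' @export
setMethod("length", "FrequencyTable", function(x) nrow(x@pairs))

#' @rdname FrequencyTable-class
#' @export
setMethod("pairSet", "FrequencyTable",
    function(x) .sortPairFrame(x@pairs[, c("a", "b")]))

setMethod("show", "FrequencyTable", function(object) {
    cat("FrequencyTable '", object@label, "': ", nrow(object@pairs),
        " pair(s), max frequency ", maxFrequency(object), "\n", sep = "")
    if (nrow(object@pairs))
        print(utils::head(object@pairs, 5L), row.names = FALSE)
})

#' Enumerate co-occurrent descriptor pairs of a record
#'
#' A record carrying `k` distinct descriptors emits exactly
#' `choose(k, 2)` unordered pairs of distinct descriptors — no self-pairs
#' and no ordered duplicates, matching the worked pair listing for an
#' 8-heading citation (28 pairs).  The historical pseudocode for this step
#' loops `j` over the full `1..k` range for every `i`, which would emit
#' self-pairs and both orientations; `literal = TRUE` reproduces that
#' behaviour solely to document the discrepancy with its printed output.
#'
#' @param x A character vector of descriptors, or a [Corpus-class] (one
#'   enumeration per record).
#' @param literal Emit the literal double-loop output (ordered, with
#'   self-pairs) instead of the canonical unordered set.
#' @param ... Passed between methods.
#' @return For a character vector: a canonical pair frame (`a`, `b`) —
#'   or, with `literal = TRUE`, an ordered pair frame including self-pairs.
#'   For a corpus: a named list of pair frames, one per record.
#' @examples
#' enumeratePairs(c("A", "B", "C"))
#' @export
setMethod("enumeratePairs", "character", function(x, literal = FALSE, ...) {
    d <- .radixSort(unique(.normalizeTerm(x)))
    d <- d[nzchar(d)]
    k <- length(d)
    if (literal) {
        idx <- expand.grid(i = seq_len(k), j = seq_len(k))
        return(data.frame(a = d[idx$i], b = d[idx$j],
            stringsAsFactors = FALSE))
    }
    if (k < 2L) return(.emptyPairFrame(frequency = FALSE))
    idx <- utils::combn(k, 2L)
    .sortPairFrame(data.frame(a = d[idx[1L, ]], b = d[idx[2L, ]],
        stringsAsFactors = FALSE))
})

#' @rdname enumeratePairs
#' @export
setMethod("enumeratePairs", "Corpus", function(x, literal = FALSE, ...) {
    out <- lapply(as.list(descriptors(x)), enumeratePairs, literal = literal)
    names(out) <- recordIds(x)
    out
})

#' Count co-occurrence frequencies over a corpus
#'
#' The frequency of a pair is the number of records whose descriptor set
#' contains both endpoints; pairs absent from every record are absent from
#' the table.  Invariant under record order and descriptor order.
#'
#' @param corpus A [Corpus-class].
#' @return A [FrequencyTable-class] labelled like the corpus.
#' @examples
#' co <- Corpus(c("1", "2"), list(c("A", "B"), c("A", "B", "C")))
#' pairFrequencies(countFrequencies(co))
#' @export
countFrequencies <- function(corpus) {
    stopifnot(is(corpus, "Corpus"))
    descs <- as.list(descriptors(corpus))
    parts <- lapply(descs, function(d) {
        k <- length(d)
        if (k < 2L) return(NULL)
        idx <- utils::combn(k, 2L)
        list(a = d[idx[1L, ]], b = d[idx[2L, ]])
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts))
        return(FrequencyTable(label = corpusLabel(corpus)))
    a <- unlist(lapply(parts, `[[`, "a"), use.names = FALSE)
    b <- unlist(lapply(parts, `[[`, "b"), use.names = FALSE)
    dt <- data.table::data.table(a = a, b = b)
    agg <- dt[, list(frequency = .N), by = c("a", "b")]
    FrequencyTable(as.data.frame(agg), label = corpusLabel(corpus))
}

#' Persist a frequency table as TSV
#'
#' Three columns `descriptor_a`, `descriptor_b`, `frequency` with a header
#' line, rows sorted by descending frequency then lexicographically —
#' bit-exact across runs.
#'
#' @param table A [FrequencyTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [readFrequencyTable()]
#' @export
writeFrequencyTable <- function(table, path) {
    stopifnot(is(table, "FrequencyTable"))
    df <- pairFrequencies(table)
    lines <- c("descriptor_a\tdescriptor_b\tfrequency",
        if (nrow(df)) paste(df$a, df$b, df$frequency, sep = "\t"))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Read a frequency table written by [writeFrequencyTable()]
#'
#' @param path Path to the TSV file.
#' @param label Table label; defaults to the file name without extension.
#' @return A [FrequencyTable-class].
#' @export
readFrequencyTable <- function(path,
                               label = sub("\\.[^.]*$", "", basename(path))) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, encoding = "UTF-8")
    if (!length(lines))
        stop("'", path, "' is empty; expected a header line", call. = FALSE)
    lines <- lines[-1L]
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(FrequencyTable(label = label))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 3L)
    if (length(bad))
        stop("line ", bad[1L] + 1L, " of '", path,
            "' does not have 3 columns", call. = FALSE)
    FrequencyTable(data.frame(
        a = vapply(fields, `[`, character(1), 1L),
        b = vapply(fields, `[`, character(1), 2L),
        frequency = as.integer(vapply(fields, `[`, character(1), 3L)),
        stringsAsFactors = FALSE), label = label)
}
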