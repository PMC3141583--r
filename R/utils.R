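.datatable.aware <- TRUE

# Internal string/pair helpers.  All ordering in this package is bytewise
# (C-locale radix order) so results do not depend on the session locale.

.radixSort <- function(x) sort(x, method = "radix")

.radixOrder <- function(...) order(..., method = "radix")

# bytewise a < b for equal-length character vectors; a[i] == b[i] gives FALSE
.strLt <- function(a, b) {
    if (!length(a)) return(logical(0))
    vapply(seq_along(a), function(i) {
        if (a[i] == b[i]) return(FALSE)
        identical(.radixSort(c(a[i], b[i]))[1L], a[i])
    }, logical(1))
}

# trim + collapse internal whitespace runs; case preserved
.normalizeTerm <- function(x) {
    x <- gsub("[[:space:]]+", " ", x)
    sub("^ ", "", sub(" $", "", x))
}

.pairKey <- function(a, b) paste(a, b, sep = "\x1f")

.keyToPairFrame <- function(keys) {
    if (!length(keys))
        return(.emptyPairFrame(frequency = FALSE))
    parts <- strsplit(keys, "\x1f", fixed = TRUE)
    df <- data.frame(a = vapply(parts, `[`, character(1), 1L),
        b = vapply(parts, `[`, character(1), 2L),
        stringsAsFactors = FALSE)
    .sortPairFrame(df)
}

# canonical row order: descending frequency (if present), then a, then b
.sortPairFrame <- function(df) {
    if (!nrow(df)) { rownames(df) <- NULL; return(df) }
    o <- if ("frequency" %in% names(df))
        .radixOrder(-df$frequency, df$a, df$b)
    else .radixOrder(df$a, df$b)
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
    df
}

# swap endpoints where needed so that a < b bytewise; drops self-pairs
.canonicalizePairs <- function(a, b) {
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    swap <- .strLt(b, a)
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    list(a = a, b = b)
}

.assertScalarString <- function(x, what) {
    if (!is.character(x) || length(x) != 1L || is.na(x))
        stop(what, " must be a single string", call. = FALSE)
    x
}

.assertCount <- function(x, what, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
            x < min)
        stop(what, " must be a single integer >= ", min, call. = FALSE)
    as.integer(x)
}

# run expr with a private RNG stream seeded by `seed`; caller's stream intact
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}
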