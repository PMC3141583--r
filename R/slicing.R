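#' Maximum pair frequency of a table
#'
#' The hierarchical parameter `k`: the largest frequency present in a pair
#' table, or 0 for an empty table.  Slices, levels and derivative series
#' are all indexed against it.
#'
#' @param x A [FrequencyTable-class].
#' @return A non-negative integer.
#' @examples
#' tb <- FrequencyTable(data.frame(a = "A", b = "B", frequency = 3))
#' maxFrequency(tb)
#' @rdname maxFrequency
#' @export
setMethod("maxFrequency", "FrequencyTable", function(x) {
    if (!nrow(x@pairs)) 0L else max(x@pairs$frequency)
})

#' Slice a frequency table at a threshold
#'
#' The slice at `i` is the set of pairs with frequency greater than or
#' equal to `i` — the "frequency >= i" panels of a sliced co-occurrence
#' network.  Slices are nested (`sliceAt(x, i + 1)` is a subset of
#' `sliceAt(x, i)`) and the slice at 1 is the whole table.  A slice may be
#' empty: sliced corpora routinely show blank panels at frequencies where
#' no pair lands.
#'
#' @param table A [FrequencyTable-class].
#' @param i Threshold, integer >= 1.
#' @return A [Slice-class].
#' @examples
#' tb <- FrequencyTable(data.frame(a = c("A", "C"), b = c("B", "D"),
#'                                 frequency = c(3L, 1L)))
#' pairSet(sliceAt(tb, 2))
#' @export
sliceAt <- function(table, i) {
    stopifnot(is(table, "FrequencyTable"))
    i <- .assertCount(i, "slice threshold", min = 1L)
    df <- table@pairs[table@pairs$frequency >= i, , drop = FALSE]
    new("Slice", threshold = i, pairs = .sortPairFrame(df))
}

#' @rdname Slice-class
#' @param x,object A [Slice-class].
#' @export
setMethod("pairSet", "Slice",
    function(x) .sortPairFrame(x@pairs[, c("a", "b")]))

#' @rdname Slice-class
#' @export
setMethod("nPairs", "Slice", function(x) nrow(x@pairs))

#' @rdname Slice-class
#' @export
sliceThreshold <- function(x) { stopifnot(is(x, "Slice")); x@threshold }

setMethod("show", "Slice", function(object) {
    cat("Slice at frequency >= ", object@threshold, ": ",
        nrow(object@pairs), " pair(s)\n", sep = "")
})

#' Level distribution: the pairs at an exact frequency
#'
#' The level distribution at `i` is the difference of adjacent slices,
#' `sliceAt(x, i) - sliceAt(x, i + 1)` — equivalently the pairs whose
#' frequency is exactly `i`.  Both routes are computed and must agree; a
#' mismatch would indicate a corrupted table and raises an error.
#'
#' @inheritParams sliceAt
#' @param i Level, integer >= 1.  Levels above [maxFrequency()] are empty.
#' @return A [LevelDistribution-class].
#' @examples
#' tb <- FrequencyTable(data.frame(a = c("A", "C"), b = c("B", "D"),
#'                                 frequency = c(3L, 1L)))
#' pairSet(levelDistribution(tb, 1))
#' @export
levelDistribution <- function(table, i) {
    stopifnot(is(table, "FrequencyTable"))
    i <- .assertCount(i, "level", min = 1L)
    bySlice <- setdiff(.pairKey(sliceAt(table, i)@pairs$a,
                                sliceAt(table, i)@pairs$b),
                       .pairKey(sliceAt(table, i + 1L)@pairs$a,
                                sliceAt(table, i + 1L)@pairs$b))
    direct <- table@pairs[table@pairs$frequency == i, , drop = FALSE]
    if (!setequal(bySlice, .pairKey(direct$a, direct$b)))
        stop("internal inconsistency: slice-difference and direct lookup ",
            "disagree at level ", i, call. = FALSE)
    new("LevelDistribution", level = i,
        pairs = .sortPairFrame(direct[, c("a", "b")]))
}

#' @rdname LevelDistribution-class
#' @param x,object A [LevelDistribution-class].
#' @export
setMethod("pairSet", "LevelDistribution", function(x) x@pairs)

#' @rdname LevelDistribution-class
#' @export
setMethod("nPairs", "LevelDistribution", function(x) nrow(x@pairs))

#' @rdname LevelDistribution-class
#' @export
ldLevel <- function(x) { stopifnot(is(x, "LevelDistribution")); x@level }

setMethod("show", "LevelDistribution", function(object) {
    cat("LevelDistribution at frequency == ", object@level, ": ",
        nrow(object@pairs), " pair(s)\n", sep = "")
})

# difference adjacent key sets `order` times; each step drops the top level
.deriveKeys <- function(levels, order) {
    for (m in seq_len(order)) {
        n <- length(levels)
        levels <- lapply(seq_len(n - 1L), function(i)
            setdiff(levels[[i]], levels[[i + 1L]]))
        names(levels) <- as.character(seq_len(n - 1L))
    }
    levels
}

# level keys 1..k as a named list of pair-key character vectors
.levelKeys <- function(table) {
    k <- maxFrequency(table)
    if (k == 0L) return(stats::setNames(list(), character(0)))
    df <- table@pairs
    keys <- .pairKey(df$a, df$b)
    out <- lapply(seq_len(k), function(i) keys[df$frequency == i])
    names(out) <- as.character(seq_len(k))
    out
}

#' Discrete derivative series of a frequency table
#'
#' The order-0 series is the family of level distributions at levels
#' `1..k` (`k` = [maxFrequency()]).  The order-1 discrete derivative at
#' level `i` is the set difference of adjacent levels,
#' `level(i) - level(i + 1)`; higher orders difference the previous order.
#' Each differencing step drops the top level ("it is meaningless to
#' differentiate the last point"), so order `m` is defined on levels
#' `1..k-m`.  Because pairs at distinct frequencies are disjoint sets, the
#' difference removes nothing: every order equals the level distributions
#' on its surviving range — see [verifyConstantDerivative()].
#'
#' @inheritParams sliceAt
#' @param order Derivative order, integer >= 0.
#' @return A [DerivativeSeries-class].  If `order >= k` the series has no
#'   levels and a warning is issued.
#' @examples
#' tb <- FrequencyTable(data.frame(a = c("A", "C"), b = c("B", "D"),
#'                                 frequency = c(2L, 1L)))
#' seriesLevels(derivativeSeries(tb, 1))
#' @export
derivativeSeries <- function(table, order = 1L) {
    stopifnot(is(table, "FrequencyTable"))
    order <- .assertCount(order, "derivative order", min = 0L)
    k <- maxFrequency(table)
    levels <- .levelKeys(table)
    if (order >= max(k, 1L) && order > 0L) {
        if (order >= k)
            warning("order ", order, " >= max frequency ", k,
                ": empty derivative series", call. = FALSE)
        levels <- stats::setNames(list(), character(0))
    } else if (order > 0L) {
        levels <- .deriveKeys(levels, order)
    }
    new("DerivativeSeries", order = order,
        levels = lapply(levels, .keyToPairFrame), label = table@label)
}

#' @rdname DerivativeSeries-class
#' @param x,object A [DerivativeSeries-class].
#' @export
seriesOrder <- function(x) { stopifnot(is(x, "DerivativeSeries")); x@order }

#' @rdname DerivativeSeries-class
#' @return `seriesLevels()`: named list of canonical pair frames, one per
#'   defined level.
#' @export
seriesLevels <- function(x) { stopifnot(is(x, "DerivativeSeries")); x@levels }

#' @rdname DerivativeSeries-class
#' @param level Level index.
#' @export
seriesLevel <- function(x, level) {
    stopifnot(is(x, "DerivativeSeries"))
    lv <- x@levels[[as.character(level)]]
    if (is.null(lv))
        stop("level ", level, " is not defined for order ", x@order,
            call. = FALSE)
    lv
}

setMethod("show", "DerivativeSeries", function(object) {
    cat("DerivativeSeries '", object@label, "', order ", object@order,
        ": ", length(object@levels), " level(s)\n", sep = "")
    if (length(object@levels)) {
        sizes <- vapply(object@levels, nrow, integer(1))
        cat("  pairs per level: ",
            paste(utils::head(sizes, 10L), collapse = " "),
            if (length(sizes) > 10L) " ..." else "", "\n", sep = "")
    }
})

#' Verify that discrete derivatives are constant across orders
#'
#' For every order `m` in `2..maxOrder` and every level `i` on the shared
#' range `1..k-m`, checks that the order-`m` series is set-identical to the
#' order-1 series at the same level.  This is the executable form of the
#' constancy result: level distributions at distinct frequencies are
#' disjoint, hence `ld_i - ld_{i+1} = ld_i` and differencing any number of
#' times changes nothing.
#'
#' @inheritParams sliceAt
#' @param maxOrder Highest order to verify, integer >= 2.
#' @return A [DerivativeVerification-class]; its `pass` slot is `TRUE` iff
#'   all checks hold (vacuously `TRUE` for an empty table).
#' @examples
#' tb <- FrequencyTable(data.frame(a = c("A", "C", "E"),
#'                                 b = c("B", "D", "F"),
#'                                 frequency = c(3L, 2L, 1L)))
#' verificationPassed(verifyConstantDerivative(tb, 4))
#' @export
verifyConstantDerivative <- function(table, maxOrder = 4L) {
    stopifnot(is(table, "FrequencyTable"))
    maxOrder <- .assertCount(maxOrder, "maxOrder", min = 2L)
    k <- maxFrequency(table)
    lvl <- .levelKeys(table)
    first <- if (k >= 2L) .deriveKeys(lvl, 1L) else list()
    ords <- integer(0); lvls <- integer(0); eqs <- logical(0)
    prev <- first
    for (m in 2:maxOrder) {
        top <- k - m
        if (top < 1L) break
        prev <- .deriveKeys(prev, 1L)     # order m from order m-1
        for (i in seq_len(top)) {
            ords <- c(ords, m); lvls <- c(lvls, i)
            eqs <- c(eqs, setequal(prev[[i]], first[[i]]))
        }
    }
    checks <- data.frame(order = ords, level = lvls, identical = eqs)
    new("DerivativeVerification", checks = checks,
        pass = all(checks$identical), maxOrder = maxOrder)
}

#' @rdname DerivativeVerification-class
#' @param x,object A [DerivativeVerification-class].
#' @export
verificationPassed <- function(x) {
    stopifnot(is(x, "DerivativeVerification")); x@pass
}

#' @rdname DerivativeVerification-class
#' @export
verificationChecks <- function(x) {
    stopifnot(is(x, "DerivativeVerification")); x@checks
}

setMethod("show", "DerivativeVerification", function(object) {
    cat("Constant-derivative verification up to order ", object@maxOrder,
        ": ", if (object@pass) "PASS" else "FAIL",
        " (", sum(object@checks$identical), "/", nrow(object@checks),
        " checks)\n", sep = "")
})

#' Export per-level (or per-slice) pair tables
#'
#' Writes one TSV per frequency under `dir`, named
#' `<label>_freq_<i>.tsv`, mirroring per-frequency table naming such as
#' `CHD_RA_Frqncy_i`.  Levels that are empty produce a header-only file;
#' this keeps the blank-panel phenomenon visible on disk.
#'
#' @inheritParams sliceAt
#' @param dir Output directory (created if needed).
#' @param what `"level"` (frequency == i) or `"slice"` (frequency >= i).
#' @param range Integer vector of frequencies; default `1..k`.
#' @return Character vector of the files written, invisibly.
#' @export
exportLevels <- function(table, dir, what = c("level", "slice"),
                         range = NULL) {
    stopifnot(is(table, "FrequencyTable"))
    what <- match.arg(what)
    k <- maxFrequency(table)
    if (is.null(range)) range <- seq_len(k)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (i in range) {
        sub <- if (what == "slice") sliceAt(table, i)@pairs
            else table@pairs[table@pairs$frequency == i, , drop = FALSE]
        f <- file.path(dir, sprintf("%s_freq_%d.tsv", table@label, i))
        writeFrequencyTable(
            FrequencyTable(.sortPairFrame(sub), label = table@label), f)
        files <- c(files, f)
    }
    invisible(files)
}
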