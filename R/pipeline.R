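#' Configuration of a full mining run
#'
#' A flat key-value description of the three-phase workflow: mine one or
#' two corpora into pair tables, optionally intersect them, run the
#' slicing/derivative calculus with its constancy verification, then
#' optionally filter by a lexicon, rank lexicon terms, and cross-query with
#' seed terms, exporting everything requested.  All randomness (synthetic
#' inputs only) flows from the single `seed`.
#'
#' @param inputA,inputB Paths to corpus files (`inputB` may be `NA` for a
#'   single-corpus run), or `NA` when corpora are passed to [runPipeline()]
#'   directly.
#' @param format Input format: `"table"` (two-column record table) or
#'   `"medline"` (citation XML).
#' @param labelA,labelB Corpus labels.
#' @param majorTopicOnly,includeQualifiers Passed to [readMedlineXML()].
#' @param combinePolicy Passed to [intersectTables()] when two corpora are
#'   given.
#' @param derivativeOrder Highest derivative order to verify (>= 2).
#' @param lexiconPath Optional lexicon file for filtering/ranking.
#' @param filterMode Passed to [filterByLexicon()].
#' @param rankTop Ranking truncation, passed to [rankItems()].
#' @param crossSeeds Optional character vector of seed terms for
#'   [crossQuery()].
#' @param crossMinFreq Minimum frequency for the cross-query.
#' @param exportFormats Subset of `c("sif", "graphml", "edge_tsv")` to
#'   export the final table's graph in.
#' @param exportLevelTables Also write one per-level TSV per frequency.
#' @param outDir Output directory; `NA` disables all file output.
#' @param seed Integer seed.
#' @param logLevel `"INFO"`, `"DEBUG"` or `"QUIET"`.
#' @return A named list of class `RunConfig`.
#' @seealso [runPipeline()]
#' @export
runConfig <- function(inputA = NA_character_, inputB = NA_character_,
                      format = c("table", "medline"),
                      labelA = "A", labelB = "B",
                      majorTopicOnly = FALSE, includeQualifiers = FALSE,
                      combinePolicy = "min", derivativeOrder = 4L,
                      lexiconPath = NA_character_, filterMode = "both",
                      rankTop = 4L, crossSeeds = character(0),
                      crossMinFreq = 1L,
                      exportFormats = character(0),
                      exportLevelTables = FALSE,
                      outDir = NA_character_, seed = 0L,
                      logLevel = c("INFO", "DEBUG", "QUIET")) {
    cfg <- list(inputA = inputA, inputB = inputB,
        format = match.arg(format), labelA = labelA, labelB = labelB,
        majorTopicOnly = majorTopicOnly,
        includeQualifiers = includeQualifiers,
        combinePolicy = combinePolicy,
        derivativeOrder = .assertCount(derivativeOrder, "derivativeOrder",
            min = 2L),
        lexiconPath = lexiconPath, filterMode = filterMode,
        rankTop = rankTop, crossSeeds = crossSeeds,
        crossMinFreq = crossMinFreq, exportFormats = exportFormats,
        exportLevelTables = exportLevelTables,
        outDir = outDir, seed = as.integer(seed),
        logLevel = match.arg(logLevel))
    class(cfg) <- "RunConfig"
    cfg
}

.plog <- function(cfg, level, ...) {
    ranks <- c(QUIET = 0L, INFO = 1L, DEBUG = 2L)
    if (ranks[[level]] <= ranks[[cfg$logLevel]])
        message("[", level, "] ", ...)
}

.loadCorpus <- function(cfg, path, label) {
    if (cfg$format == "medline")
        readMedlineXML(path, majorTopicOnly = cfg$majorTopicOnly,
            includeQualifiers = cfg$includeQualifiers, label = label)
    else readRecordTable(path, label = label)
}

#' Run the full mining workflow
#'
#' Executes ingest, pair enumeration, frequency counting, the optional
#' two-corpus intersection, slicing with level distributions and the
#' constant-derivative verification, optional lexicon filtering / ranking /
#' cross-query, and requested exports.  Returns (and, when `outDir` is set,
#' writes as JSON) a machine-readable run report: per-stage counts, the
#' verification verdict, and a manifest of files written.
#'
#' @param config A [runConfig()] object.
#' @param corpusA,corpusB Optional [Corpus-class] objects, overriding
#'   `config$inputA` / `config$inputB` (useful for in-memory runs).
#' @return The run report, invisibly: a nested list with elements `stages`
#'   (named counts), `verification` (`pass`, `maxOrder`, `checks`),
#'   `ranking`, `manifest` and `seed`.  The verification verdict failing
#'   raises an error after the report is written, so scripted runs exit
#'   non-zero.
#' @export
runPipeline <- function(config = runConfig(), corpusA = NULL,
                        corpusB = NULL) {
    stopifnot(inherits(config, "RunConfig"))
    manifest <- character(0)
    outDir <- config$outDir
    if (!is.na(outDir))
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    if (is.null(corpusA)) {
        if (is.na(config$inputA))
            stop("stage ingest: no corpus A (set inputA or pass corpusA)",
                call. = FALSE)
        corpusA <- .loadCorpus(config, config$inputA, config$labelA)
    }
    if (is.null(corpusB) && !is.na(config$inputB))
        corpusB <- .loadCorpus(config, config$inputB, config$labelB)
    .plog(config, "INFO", "ingest: corpus A '", corpusLabel(corpusA),
        "' with ", length(corpusA), " record(s)",
        if (!is.null(corpusB)) paste0("; corpus B '", corpusLabel(corpusB),
            "' with ", length(corpusB), " record(s)"))

    tabA <- countFrequencies(corpusA)
    tabB <- if (!is.null(corpusB)) countFrequencies(corpusB)
    .plog(config, "INFO", "pairs: ", nPairs(tabA), " distinct pair(s) in A",
        if (!is.null(tabB)) paste0(", ", nPairs(tabB), " in B"))

    main <- if (!is.null(tabB))
        intersectTables(tabA, tabB, policy = config$combinePolicy)
    else tabA
    if (!is.null(tabB))
        .plog(config, "INFO", "intersect (", config$combinePolicy, "): ",
            nPairs(main), " shared pair(s)")

    k <- maxFrequency(main)
    levelSizes <- if (k > 0)
        vapply(seq_len(k), function(i)
            nPairs(levelDistribution(main, i)), integer(1))
    else integer(0)
    .plog(config, "DEBUG", "levels 1..", k, " pair counts: ",
        paste(levelSizes, collapse = " "))
    verif <- if (k >= 1)
        verifyConstantDerivative(main, config$derivativeOrder)
    else new("DerivativeVerification",
        checks = data.frame(order = integer(0), level = integer(0),
            identical = logical(0)),
        pass = TRUE, maxOrder = as.integer(config$derivativeOrder))
    .plog(config, "INFO", "derivative constancy up to order ",
        config$derivativeOrder, ": ",
        if (verificationPassed(verif)) "PASS" else "FAIL")

    filtered <- NULL
    ranking <- NULL
    if (!is.na(config$lexiconPath)) {
        lex <- readLexicon(config$lexiconPath)
        filtered <- filterByLexicon(main, lex, mode = config$filterMode)
        ranking <- rankItems(corpusA, lex, topN = config$rankTop)
        .plog(config, "INFO", "lexicon filter (", config$filterMode, "): ",
            nPairs(filtered), " pair(s) kept of ", nPairs(main))
    }
    crossed <- if (length(config$crossSeeds))
        crossQuery(main, config$crossSeeds, minFreq = config$crossMinFreq)

    if (!is.na(outDir)) {
        f <- file.path(outDir, paste0(tableLabel(main), "_pairs.tsv"))
        writeFrequencyTable(main, f); manifest <- c(manifest, f)
        if (config$exportLevelTables)
            manifest <- c(manifest, exportLevels(main, outDir))
        g <- toGraph(main)
        for (fmt in config$exportFormats) {
            ext <- c(sif = "sif", graphml = "graphml",
                edge_tsv = "edges.tsv")[[fmt]]
            f <- file.path(outDir, paste0(tableLabel(main), ".", ext))
            exportGraph(g, fmt, f); manifest <- c(manifest, f)
        }
        if (!is.null(filtered)) {
            f <- file.path(outDir,
                paste0(tableLabel(main), "_filtered.tsv"))
            writeFrequencyTable(filtered, f); manifest <- c(manifest, f)
        }
        if (!is.null(crossed)) {
            f <- file.path(outDir,
                paste0(tableLabel(main), "_crossquery.tsv"))
            writeFrequencyTable(crossed, f); manifest <- c(manifest, f)
        }
    }

    report <- list(
        stages = list(
            recordsA = length(corpusA),
            recordsB = if (!is.null(corpusB)) length(corpusB),
            pairsA = nPairs(tabA),
            pairsB = if (!is.null(tabB)) nPairs(tabB),
            intersection = if (!is.null(tabB)) nPairs(main),
            mainPairs = nPairs(main),
            maxFrequency = k,
            levelSizes = levelSizes,
            filteredPairs = if (!is.null(filtered)) nPairs(filtered),
            crossQueryPairs = if (!is.null(crossed)) nPairs(crossed)),
        verification = list(pass = verificationPassed(verif),
            maxOrder = config$derivativeOrder,
            checks = nrow(verificationChecks(verif))),
        ranking = if (!is.null(ranking))
            list(term = as.character(ranking$term),
                count = as.integer(ranking$count)),
        manifest = manifest,
        seed = config$seed)
    if (!is.na(outDir)) {
        f <- file.path(outDir, "run_report.json")
        jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
            null = "null")
        report$manifest <- c(manifest, f)
    }
    if (!verificationPassed(verif))
        stop("stage verify: constant-derivative verification failed",
            call. = FALSE)
    invisible(report)
}
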