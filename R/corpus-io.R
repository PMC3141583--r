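#' Read a MEDLINE/PubMed XML citation export
#'
#' Parses the PubMed citation XML dialect (`PubmedArticleSet` containing
#' `PubmedArticle` / `MedlineCitation` elements with a `PMID` and a
#' `MeshHeadingList`) into a [Corpus-class]: one record per citation, its
#' descriptor set taken from the `DescriptorName` elements.
#'
#' MeSH headings mark major topics with `MajorTopicYN="Y"` on the
#' descriptor or on one of its qualifiers.  With `majorTopicOnly = TRUE`
#' a heading survives only if the descriptor or any of its qualifiers is so
#' flagged, mirroring the "Restrict Search to Major Topic headings only"
#' retrieval option.  With `includeQualifiers = TRUE` the qualifier texts
#' (e.g. "physiopathology", "rehabilitation") are additionally harvested as
#' standalone terms, which reproduces the mixed descriptor/qualifier lists
#' seen in hand-curated record tables.
#'
#' Citations with zero surviving headings are retained; they simply emit no
#' co-occurrence pairs downstream.
#'
#' @param path Path to the XML file.
#' @param majorTopicOnly Keep only major-topic headings.
#' @param includeQualifiers Harvest qualifier names as standalone terms.
#' @param label Corpus label; defaults to the file name without extension.
#' @return A [Corpus-class].
#' @seealso [writeMedlineXML()], [readRecordTable()]
#' @export
readMedlineXML <- function(path, majorTopicOnly = FALSE,
                           includeQualifiers = FALSE,
                           label = sub("\\.[^.]*$", "", basename(path))) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    doc <- tryCatch(xml2::read_xml(path),
        error = function(e) stop("malformed XML in '", path, "': ",
            conditionMessage(e), call. = FALSE))
    cits <- xml2::xml_find_all(doc, ".//MedlineCitation")
    ids <- character(length(cits))
    descs <- vector("list", length(cits))
    for (i in seq_along(cits)) {
        cit <- cits[[i]]
        ids[i] <- xml2::xml_text(xml2::xml_find_first(cit, "./PMID"))
        heads <- xml2::xml_find_all(cit, "./MeshHeadingList/MeshHeading")
        terms <- character(0)
        for (h in heads) {
            dn <- xml2::xml_find_first(h, "./DescriptorName")
            qs <- xml2::xml_find_all(h, "./QualifierName")
            dMajor <- identical(xml2::xml_attr(dn, "MajorTopicYN"), "Y")
            qMajor <- xml2::xml_attr(qs, "MajorTopicYN") == "Y"
            if (!majorTopicOnly || dMajor || any(qMajor, na.rm = TRUE))
                terms <- c(terms, xml2::xml_text(dn))
            if (includeQualifiers) {
                keepQ <- if (majorTopicOnly) which(qMajor %in% TRUE)
                    else seq_along(qs)
                if (length(keepQ))
                    terms <- c(terms, xml2::xml_text(qs[keepQ]))
            }
        }
        descs[[i]] <- terms
    }
    if (anyDuplicated(ids))
        stop("duplicate PMID(s) in '", path, "': ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            call. = FALSE)
    Corpus(ids, descs, label = label)
}

#' Write a corpus as minimal MEDLINE-style citation XML
#'
#' Emits the subset of the PubMed citation dialect that [readMedlineXML()]
#' consumes (`PubmedArticleSet`/`PubmedArticle`/`MedlineCitation` with
#' `PMID` and `MeshHeadingList`), so that write followed by read is the
#' identity on records.  All headings are written as plain descriptors with
#' `MajorTopicYN="N"`.
#'
#' @param corpus A [Corpus-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeMedlineXML <- function(corpus, path) {
    stopifnot(is(corpus, "Corpus"))
    root <- xml2::xml_new_root("PubmedArticleSet")
    for (id in recordIds(corpus)) {
        art <- xml2::xml_add_child(root, "PubmedArticle")
        cit <- xml2::xml_add_child(art, "MedlineCitation")
        xml2::xml_add_child(cit, "PMID", id)
        mh <- xml2::xml_add_child(cit, "MeshHeadingList")
        for (term in corpus[[id]]) {
            h <- xml2::xml_add_child(mh, "MeshHeading")
            xml2::xml_add_child(h, "DescriptorName", term,
                MajorTopicYN = "N")
        }
    }
    xml2::write_xml(root, path)
    invisible(path)
}

#' Read a plain two-column record table
#'
#' Each line holds `record_id<delimiter>descriptor` (the plain-text export
#' shape used by databases that cannot emit XML).  Lines are grouped by
#' record id, in order of first appearance; duplicate (id, descriptor)
#' lines collapse to one descriptor.
#'
#' @param path Path to a UTF-8 text file.
#' @param delimiter Field separator, default TAB.
#' @param header Skip one header line.
#' @param label Corpus label; defaults to the file name without extension.
#' @return A [Corpus-class].
#' @seealso [writeRecordTable()]
#' @export
readRecordTable <- function(path, delimiter = "\t", header = FALSE,
                            label = sub("\\.[^.]*$", "", basename(path))) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, encoding = "UTF-8")
    offset <- 0L
    if (header && length(lines)) { lines <- lines[-1L]; offset <- 1L }
    keep <- nzchar(lines)
    fields <- strsplit(lines[keep], delimiter, fixed = TRUE)
    bad <- which(lengths(fields) != 2L)
    if (length(bad)) {
        lineNo <- which(keep)[bad[1L]] + offset
        stop("line ", lineNo, " of '", path, "' has ",
            lengths(fields)[bad[1L]], " column(s), expected 2", call. = FALSE)
    }
    ids <- vapply(fields, `[`, character(1), 1L)
    terms <- vapply(fields, `[`, character(1), 2L)
    uids <- unique(ids)
    descs <- split(terms, factor(ids, levels = uids))
    Corpus(uids, descs, label = label)
}

#' Write a corpus as a plain two-column record table
#'
#' One `record_id<delimiter>descriptor` line per descriptor assignment;
#' records in corpus order, descriptors in their stored (bytewise) order,
#' so output is bit-exact across runs.
#'
#' @inheritParams writeMedlineXML
#' @param delimiter Field separator, default TAB.
#' @param header Write a `record_id<delimiter>descriptor` header line.
#' @return `path`, invisibly.
#' @export
writeRecordTable <- function(corpus, path, delimiter = "\t",
                             header = FALSE) {
    stopifnot(is(corpus, "Corpus"))
    ids <- recordIds(corpus)
    n <- lengths(descriptors(corpus))
    lines <- if (length(ids))
        paste(rep(ids, n), unlist(descriptors(corpus), use.names = FALSE),
            sep = delimiter)
    else character(0)
    if (header)
        lines <- c(paste("record_id", "descriptor", sep = delimiter), lines)
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Read a term lexicon
#'
#' One term per line; blank lines and lines starting with `#` are ignored.
#' Terms are whitespace-normalized and deduplicated case-insensitively.
#'
#' @param path Path to a UTF-8 text file.
#' @return A [HerbLexicon-class].  An empty file yields an empty lexicon
#'   with a warning.
#' @export
readLexicon <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- .normalizeTerm(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    lex <- HerbLexicon(lines)
    if (length(lex) == 0L)
        warning("lexicon '", path, "' contains no terms", call. = FALSE)
    lex
}

#' Write a term lexicon, one term per line
#'
#' @param lexicon A [HerbLexicon-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeLexicon <- function(lexicon, path) {
    stopifnot(is(lexicon, "HerbLexicon"))
    writeLines(lexiconTerms(lexicon), path, useBytes = TRUE)
    invisible(path)
}
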