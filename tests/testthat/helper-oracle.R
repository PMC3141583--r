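# Independent brute-force oracles.  These deliberately avoid the package's
# internal pair machinery: plain nested loops, base-R tallies.

# tally pair -> number of records containing both endpoints
oracle_pair_counts <- function(corpus) {
  tally <- new.env(parent = emptyenv())
  for (id in recordIds(corpus)) {
    d <- sort(unique(corpus[[id]]), method = "radix")
    k <- length(d)
    if (k < 2) next
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        key <- paste(d[i], d[j], sep = "\r")
        cur <- if (is.null(tally[[key]])) 0L else tally[[key]]
        tally[[key]] <- cur + 1L
      }
    }
  }
  keys <- ls(tally)
  if (!length(keys))
    return(data.frame(a = character(0), b = character(0),
      frequency = integer(0)))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  df <- data.frame(
    a = vapply(parts, `[`, character(1), 1),
    b = vapply(parts, `[`, character(1), 2),
    frequency = vapply(keys, function(k) tally[[k]], integer(1)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df[order(-df$frequency, df$a, df$b, method = "radix"), ]
}

# unordered-set comparison of two (a, b[, frequency]) pair frames
pair_frame_key <- function(df, with_freq = FALSE) {
  if (!nrow(df)) return(character(0))
  lo <- pmin_chr(df$a, df$b); hi <- pmax_chr(df$a, df$b)
  if (with_freq) paste(lo, hi, df$frequency, sep = "\r")
  else paste(lo, hi, sep = "\r")
}

pmin_chr <- function(a, b) ifelse(mapply(function(x, y)
  identical(sort(c(x, y), method = "radix")[1], x), a, b), a, b)
pmax_chr <- function(a, b) ifelse(mapply(function(x, y)
  identical(sort(c(x, y), method = "radix")[1], x), a, b), b, a)

expect_same_pairs <- function(got, want, with_freq = FALSE) {
  expect_setequal(pair_frame_key(got, with_freq),
    pair_frame_key(want, with_freq))
  expect_equal(nrow(got), nrow(want))
}

# common neighbours of two nodes by nested scan over an edge frame
oracle_common_neighbors <- function(edges, x, y) {
  nb <- function(v) {
    out <- character(0)
    for (r in seq_len(nrow(edges))) {
      if (edges$a[r] == v) out <- c(out, edges$b[r])
      if (edges$b[r] == v) out <- c(out, edges$a[r])
    }
    unique(out)
  }
  intersect(nb(x), nb(y))
}

# deterministic sweep configurations: seeds 0..99 mapped into the stated
# ranges (50-500 records, vocabulary 20-200)
sweep_config <- function(seed) {
  generatorConfig(
    nRecords = 50L + (seed * 91L) %% 451L,
    vocabSize = 20L + (seed * 37L) %% 181L,
    descriptorsPerRecord = c(2L, 8L),
    vocabularySkew = 1.5,
    seed = seed,
    label = paste0("sweep", seed))
}
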