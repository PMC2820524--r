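#' Read a JASPAR-style 4-row count matrix
#'
#' Accepts the JASPAR text format: an optional `>` header followed by four
#' rows, either bare numbers or `A [ 1 2 3 ]` style.
#'
#' @param path Path to the matrix file.
#' @param ... Passed to [pwm_from_counts()] (pseudocount, background).
#' @return A `pwm` object.
#' @export
read_jaspar <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^>", lines)]
  if (length(lines) < 4L) rlang::abort("expected 4 count rows")
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
    l <- gsub("[\\[\\]]", "", l, perl = TRUE)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (length(unique(lengths(rows))) != 1L) rlang::abort("ragged count rows")
  counts <- do.call(rbind, rows)
  rownames(counts) <- .DNA_BASES
  pwm_from_counts(counts, ...)
}

#' Read a MEME minimal-format motif
#'
#' Parses the first `letter-probability matrix` block of a MEME minimal
#' motif file; probabilities are converted back to counts using the
#' declared `nsites` (default 20 when absent).
#'
#' @param path Path to the MEME minimal file.
#' @param ... Passed to [pwm_from_counts()].
#' @return A `pwm` object.
#' @export
read_meme <- function(path, ...) {
  lines <- readLines(path)
  hdr <- grep("letter-probability matrix", lines)
  if (length(hdr) == 0L) rlang::abort("no letter-probability matrix block found")
  hdr <- hdr[1]
  nsites <- 20
  m <- regmatches(lines[hdr], regexec("nsites=\\s*(\\d+)", lines[hdr]))[[1]]
  if (length(m) == 2L) nsites <- as.numeric(m[2])
  w <- NA_integer_
  m <- regmatches(lines[hdr], regexec("w=\\s*(\\d+)", lines[hdr]))[[1]]
  if (length(m) == 2L) w <- as.integer(m[2])
  body <- lines[(hdr + 1L):length(lines)]
  rows <- list()
  for (l in body) {
    l <- trimws(l)
    if (!grepl("^[0-9.]", l)) break
    rows[[length(rows) + 1L]] <- as.numeric(strsplit(l, "\\s+")[[1]])
    if (!is.na(w) && length(rows) == w) break
  }
  probs <- do.call(rbind, rows) # w x 4, columns A C G T
  counts <- t(probs) * nsites
  rownames(counts) <- .DNA_BASES
  pwm_from_counts(counts, ...)
}

#' Write motif hits as a tab-separated table
#'
#' @param hits A hit tibble from [scan_sequence()].
#' @param path Output path.
#' @param seq_id Sequence identifier for the first column.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path, seq_id = "seq") {
  df <- cbind(seq_id = seq_id, as.data.frame(hits))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
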