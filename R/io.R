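#' Read a multi-record FASTA file into a tibble
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `desc` and `seq` (uppercase DNA).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  tibble(id = id, desc = desc, seq = unname(toupper(as.character(ss))))
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param x A tibble with `id`/`seq` (optionally `desc`) or a named character
#'   vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- .as_named_seqs(x)
  nm <- names(seqs)
  if (is.data.frame(x) && "desc" %in% names(x)) {
    has_desc <- !is.na(x$desc) & nzchar(x$desc)
    nm[has_desc] <- paste(nm[has_desc], x$desc[has_desc])
  }
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read BED (3-6 column) features into a tibble
#'
#' BED files are 0-based half-open; on read, intervals are converted to the
#' package-wide 1-based closed convention.
#'
#' @param path Path to a BED file.
#' @return A tibble with `chrom`, `start`, `end` (1-based closed), and when
#'   present `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(fields))
  get <- function(i) vapply(fields, `[[`, character(1), i)
  out <- tibble(
    chrom = get(1),
    start = as.integer(get(2)) + 1L,
    end = as.integer(get(3))
  )
  if (ncol >= 4L) out$name <- get(4)
  if (ncol >= 5L) out$score <- suppressWarnings(as.numeric(get(5)))
  if (ncol >= 6L) out$strand <- get(6)
  out
}

#' Write intervals as BED6
#'
#' @param x A tibble with `chrom` (or `subject_id`/`seq_id`), `start`, `end`
#'   (1-based closed) and optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  chrom <- .col_or(x, "chrom", .col_or(x, "subject_id", .col_or(x, "seq_id", NULL)))
  name <- .col_or(x, "name", .col_or(x, "region", rep(".", nrow(x))))
  score <- .col_or(x, "score", rep(0, nrow(x)))
  strand <- .col_or(x, "strand", rep(".", nrow(x)))
  start <- .col_or(x, "start", .col_or(x, "s_start", NULL))
  end <- .col_or(x, "end", .col_or(x, "s_end", NULL))
  df <- data.frame(chrom, as.integer(start) - 1L, as.integer(end), name, score, strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write features as GFF3
#'
#' @param x A tibble with columns `seqid`, `type`, `start`, `end`, and
#'   optionally `source`, `score`, `strand`, `attributes`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(x, path) {
  n <- nrow(x)
  df <- data.frame(
    seqid = x$seqid,
    source = .col_or(x, "source", rep("tecoopt", n)),
    type = x$type,
    start = as.integer(x$start),
    end = as.integer(x$end),
    score = .col_or(x, "score", rep(".", n)),
    strand = .col_or(x, "strand", rep(".", n)),
    phase = rep(".", n),
    attributes = .col_or(x, "attributes", rep(".", n))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
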