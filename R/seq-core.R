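#' Reverse complement of a DNA string
#'
#' Base-wise complement, reversed. IUPAC ambiguity codes are complemented to
#' the code of the complementary base set (Y to R, N to N, and so on).
#' Lower-case input is upper-cased; RNA (`U`) is rejected.
#'
#' @param seq A single DNA string over the IUPAC alphabet.
#' @return A DNA string of the same length.
#' @examples
#' reverse_complement("CTGCAACAATGCATT")
#' @export
reverse_complement <- function(seq) {
  seq <- .check_dna(seq)
  if (nchar(seq) == 0L) return("")
  stringi::stri_reverse(chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", seq))
}

#' Extract a subsequence, strand-aware
#'
#' Returns the 1-based closed slice `[start, end]` of a sequence; on the
#' minus strand the reverse complement of that slice is returned.
#'
#' @param seq A DNA string (or a 1-row FASTA tibble / named string).
#' @param start,end 1-based inclusive positions, `1 <= start <= end <= nchar`.
#' @param strand `"+"` or `"-"`.
#' @return A DNA string.
#' @export
extract_subsequence <- function(seq, start, end, strand = "+") {
  seq <- .as_named_seqs(seq, "seq")
  if (length(seq) != 1L) rlang::abort("`seq` must be a single sequence")
  seq <- unname(seq)
  stopifnot(strand %in% c("+", "-"))
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end > nchar(seq) || start > end) {
    rlang::abort(sprintf(
      "interval [%d, %d] out of bounds for sequence of length %d",
      start, end, nchar(seq)
    ))
  }
  out <- substr(seq, start, end)
  if (strand == "-") reverse_complement(out) else out
}

#' Match a DNA string against an IUPAC pattern
#'
#' `TRUE` iff every base of `seq` belongs to the base set of the
#' corresponding IUPAC code in `pattern`. Pattern and sequence must have the
#' same length; this is a positional membership test, not a search.
#'
#' @param pattern IUPAC pattern (e.g. `"YARNG"`, the terminal motif shared by
#'   P-superfamily DNA transposons).
#' @param seq DNA string of the same length.
#' @return A logical scalar.
#' @examples
#' iupac_match("YARNG", "CAATG")
#' @export
iupac_match <- function(pattern, seq) {
  pattern <- .check_dna(pattern, "pattern")
  seq <- .check_dna(seq, "seq")
  if (nchar(pattern) != nchar(seq)) {
    rlang::abort("`pattern` and `seq` must have the same length")
  }
  if (nchar(pattern) == 0L) return(TRUE)
  pc <- .chars(pattern)
  sc <- .chars(seq)
  all(mapply(function(p, s) s %in% .IUPAC_MAP[[p]], pc, sc))
}

#' Convert TSS-relative promoter positions to 1-based sequence indices
#'
#' Promoter papers report binding-site positions relative to the
#' transcription start site (TSS): position -1 is the base immediately
#' upstream of the TSS, +1 is the TSS itself (there is no position 0). For a
#' promoter sequence written 5' to 3' with the TSS at index `tss_index`,
#' this converts between the two conventions.
#'
#' @param pos TSS-relative position(s), negative upstream, positive
#'   downstream (no zero).
#' @param tss_index 1-based index of the TSS base within the sequence.
#' @return Integer vector of 1-based sequence indices.
#' @export
tss_to_index <- function(pos, tss_index) {
  pos <- as.integer(pos)
  if (any(pos == 0L)) rlang::abort("TSS-relative coordinates have no position 0")
  as.integer(ifelse(pos < 0L, tss_index + pos, tss_index + pos - 1L))
}

#' @rdname tss_to_index
#' @param index 1-based sequence indices to convert back.
#' @export
index_to_tss <- function(index, tss_index) {
  index <- as.integer(index)
  as.integer(ifelse(index < tss_index, index - tss_index, index - tss_index + 1L))
}
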