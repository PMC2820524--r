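# De-novo characterization of a candidate class II (cut-and-paste) element:
# terminal inverted repeats, target-site duplication, ORF content, terminal
# motif, majority-rule consensus, and classification.

#' Find terminal inverted repeats (TIRs)
#'
#' Searches for the longest prefix/suffix pair, anchored at the element
#' termini, such that the prefix equals the reverse complement of the suffix
#' with at most `max_mismatch` substitutions. TIRs are the structural
#' hallmark of class II (DNA) transposons.
#'
#' @param element DNA string of the candidate element.
#' @param min_len,max_len Candidate TIR length range in bp.
#' @param max_mismatch Maximum substitutions tolerated between the 5' TIR
#'   and the reverse complement of the 3' TIR.
#' @return A one-row tibble (`length`, `mismatches`, `left_start`,
#'   `left_end`, `right_start`, `right_end`, `tir_seq`) or a zero-row tibble
#'   when no terminal pair qualifies.
#' @export
find_tirs <- function(element, min_len = 10L, max_len = 100L, max_mismatch = 0L) {
  element <- .check_dna(element, "element")
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (min_len > max_len) rlang::abort("`min_len` must be <= `max_len`")
  n <- nchar(element)
  if (n < 2L * min_len) rlang::abort("element shorter than twice `min_len`")
  empty <- tibble(
    length = integer(), mismatches = integer(),
    left_start = integer(), left_end = integer(),
    right_start = integer(), right_end = integer(), tir_seq = character()
  )
  for (len in seq(min(max_len, n %/% 2L), min_len)) {
    prefix <- substr(element, 1L, len)
    suffix <- substr(element, n - len + 1L, n)
    mm <- sum(.chars(prefix) != .chars(reverse_complement(suffix)))
    if (mm <= max_mismatch) {
      return(tibble(
        length = len, mismatches = mm,
        left_start = 1L, left_end = len,
        right_start = n - len + 1L, right_end = n,
        tir_seq = prefix
      ))
    }
  }
  empty
}

#' Find the target-site duplication (TSD) flanking an element
#'
#' Upon insertion, cut-and-paste transposons duplicate a short host sequence
#' on both flanks. Given the element's interval on its host, this returns
#' the longest exact duplication of length in `[min_len, max_len]`
#' immediately flanking it.
#'
#' @param host Host DNA string (or 1-row FASTA tibble).
#' @param element_start,element_end 1-based closed interval of the element
#'   on the host (TSD copies excluded).
#' @param min_len,max_len TSD length search range in bp.
#' @return A one-row tibble (`seq`, `length`, `left_start`, `left_end`,
#'   `right_start`, `right_end`) or a zero-row tibble when no flanking
#'   duplication qualifies.
#' @export
find_tsd <- function(host, element_start, element_end, min_len = 2L, max_len = 20L) {
  host <- unname(.as_named_seqs(host, "host"))
  stopifnot(length(host) == 1L)
  s <- as.integer(element_start); e <- as.integer(element_end)
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (min_len > max_len) rlang::abort("`min_len` must be <= `max_len`")
  n <- nchar(host)
  if (s - max_len < 1L || e + max_len > n) {
    rlang::abort("element needs at least `max_len` bp of host flank on both sides")
  }
  for (k in seq(max_len, min_len)) {
    left <- substr(host, s - k, s - 1L)
    right <- substr(host, e + 1L, e + k)
    if (left == right) {
      return(tibble(
        seq = left, length = k,
        left_start = s - k, left_end = s - 1L,
        right_start = e + 1L, right_end = e + k
      ))
    }
  }
  tibble(
    seq = character(), length = integer(),
    left_start = integer(), left_end = integer(),
    right_start = integer(), right_end = integer()
  )
}

#' Majority-rule IUPAC consensus of aligned element copies
#'
#' Per alignment column, base frequencies are computed over all rows with
#' gaps counting in the denominator. Columns whose gap fraction reaches
#' `threshold` are dropped. Otherwise the column emits the single base
#' reaching `threshold`, or the minimal IUPAC code covering all bases tied
#' at or above `threshold`, or, when no base reaches it, the IUPAC code of
#' all bases present.
#'
#' @param aligned_copies Character vector (>= 2) of equal-length gapped
#'   sequences, or a FASTA tibble.
#' @param threshold Inclusion threshold in `(0, 1]` (default 0.5, the
#'   conventional 50% majority rule for repeat consensus building).
#' @return An object of class `consensus_model` with elements `consensus`
#'   (IUPAC string), `threshold`, `n_copies`, `alignment_length`,
#'   `kept_columns`.
#' @export
build_consensus <- function(aligned_copies, threshold = 0.5) {
  seqs <- .as_named_seqs_gapped(aligned_copies)
  if (length(seqs) < 2L) rlang::abort("need at least two aligned copies")
  if (length(unique(nchar(seqs))) != 1L) {
    rlang::abort("aligned copies must all have the same (gapped) length")
  }
  stopifnot(threshold > 0, threshold <= 1)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- nrow(mat)
  cols <- character(0)
  kept <- integer(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    gap_frac <- sum(col == "-") / n
    if (gap_frac >= threshold) next
    bases <- col[col != "-"]
    freq <- table(bases) / n
    at_thr <- names(freq)[freq >= threshold]
    code <- if (length(at_thr) >= 1L) .iupac_code_for(at_thr) else .iupac_code_for(names(freq))
    cols <- c(cols, code)
    kept <- c(kept, j)
  }
  structure(
    list(
      consensus = .collapse(cols), threshold = threshold,
      n_copies = n, alignment_length = ncol(mat), kept_columns = kept
    ),
    class = "consensus_model"
  )
}

.as_named_seqs_gapped <- function(x) {
  if (is.data.frame(x)) x <- setNames(as.character(x$seq), as.character(x$id))
  if (is.null(names(x))) names(x) <- paste0("copy", seq_along(x))
  vapply(x, .check_dna, character(1), allow_gap = TRUE)
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf(
    "<consensus_model> %d copies, %d/%d columns kept, threshold %.2f\n%s\n",
    x$n_copies, length(x$kept_columns), x$alignment_length, x$threshold, x$consensus
  ))
  invisible(x)
}

#' Longest open reading frame over all six frames
#'
#' Length, in codons (start codon included, stop excluded), of the longest
#' ATG-to-stop ORF over the three frames of both strands. Used to test
#' whether a candidate element encodes a transposase.
#'
#' @param seq DNA string.
#' @return Integer codon count (0 when no complete ORF exists).
#' @export
longest_orf <- function(seq) {
  seq <- .check_dna(seq)
  if (nchar(seq) < 6L) return(0L)
  best <- 0L
  for (s in c(seq, reverse_complement(seq))) {
    for (f in 0:2) {
      len <- nchar(s) - f
      len <- len - len %% 3L
      if (len < 6L) next
      sub <- substr(s, f + 1L, f + len)
      aa <- as.character(suppressWarnings(
        Biostrings::translate(Biostrings::DNAString(sub),
                              if.fuzzy.codon = "X", no.init.codon = TRUE)
      ))
      m <- gregexpr("M[^*]*\\*", aa)[[1]]
      if (m[1] != -1L) best <- max(best, max(attr(m, "match.length")) - 1L)
    }
  }
  as.integer(best)
}

#' Classify a candidate element from its recorded features
#'
#' Decision table: TIR and TSD present with no ORF of at least
#' `orf_min_codons` codons -> `nonautonomous_class_II`; TIR and TSD with a
#' long ORF -> `class_II_autonomous`; no TIR but a poly-A tract (>= 8 A) at
#' the 3' end (or >= 8 T at the 5' end) -> `class_I_like`
#' (retroelement-like); otherwise `unclassified`.
#'
#' @param has_tir,has_tsd Logical: were TIRs / a TSD detected?
#' @param longest_orf_codons Longest ORF in codons (see [longest_orf()]).
#' @param element Optional element sequence, used only for the poly-A check
#'   when `has_tir` is `FALSE`.
#' @param orf_min_codons ORF length (codons) separating "no open reading
#'   frame" from a putative transposase.
#' @return One of `"nonautonomous_class_II"`, `"class_II_autonomous"`,
#'   `"class_I_like"`, `"unclassified"`.
#' @export
classify_element <- function(has_tir, has_tsd, longest_orf_codons,
                             element = NULL, orf_min_codons = 100L) {
  if (has_tir && has_tsd) {
    return(if (longest_orf_codons >= orf_min_codons) "class_II_autonomous"
           else "nonautonomous_class_II")
  }
  if (!has_tir && !is.null(element)) {
    element <- .check_dna(element, "element")
    if (grepl("A{8,}$", element) || grepl("^T{8,}", element)) {
      return("class_I_like")
    }
  }
  "unclassified"
}

#' Annotate a candidate transposable element
#'
#' Composes [find_tirs()], [find_tsd()], [longest_orf()], the terminal-motif
#' test (IUPAC `YARNG`, the P-superfamily terminal consensus, against the
#' first five bases) and [classify_element()] into one annotation object.
#'
#' @param element Element DNA string.
#' @param host Optional host sequence carrying the element (needed for TSD
#'   detection).
#' @param element_start,element_end Element interval on `host` (1-based
#'   closed), required when `host` is given.
#' @param tir_min_len,tir_max_len,tir_max_mismatch TIR search parameters.
#' @param tsd_min_len,tsd_max_len TSD search range.
#' @param orf_min_codons See [classify_element()].
#' @return An object of class `te_annotation`; see [tidy.te_annotation()].
#' @export
annotate_element <- function(element, host = NULL,
                             element_start = NULL, element_end = NULL,
                             tir_min_len = 10L, tir_max_len = 100L,
                             tir_max_mismatch = 0L,
                             tsd_min_len = 2L, tsd_max_len = 20L,
                             orf_min_codons = 100L) {
  element <- .check_dna(element, "element")
  tir <- find_tirs(element, tir_min_len, tir_max_len, tir_max_mismatch)
  tsd <- if (!is.null(host)) {
    find_tsd(host, element_start, element_end, tsd_min_len, tsd_max_len)
  } else {
    tibble(
      seq = character(), length = integer(),
      left_start = integer(), left_end = integer(),
      right_start = integer(), right_end = integer()
    )
  }
  orf <- longest_orf(element)
  motif <- nchar(element) >= 5L && iupac_match("YARNG", substr(element, 1, 5))
  cls <- classify_element(
    has_tir = nrow(tir) > 0L, has_tsd = nrow(tsd) > 0L,
    longest_orf_codons = orf, element = element, orf_min_codons = orf_min_codons
  )
  structure(
    list(
      element_length = nchar(element), tir = tir, tsd = tsd,
      longest_orf_codons = orf, terminal_motif_match = motif,
      classification = cls
    ),
    class = "te_annotation"
  )
}

#' @export
print.te_annotation <- function(x, ...) {
  cat(sprintf("<te_annotation> %d bp element: %s\n", x$element_length, x$classification))
  if (nrow(x$tir)) cat(sprintf("  TIR: %d bp (%d mismatches) %s\n",
                               x$tir$length, x$tir$mismatches, x$tir$tir_seq))
  if (nrow(x$tsd)) cat(sprintf("  TSD: %d bp %s\n", x$tsd$length, x$tsd$seq))
  cat(sprintf("  longest ORF: %d codons; terminal motif (YARNG): %s\n",
              x$longest_orf_codons, x$terminal_motif_match))
  invisible(x)
}

#' Tidy a TE annotation into a one-row tibble
#'
#' @param x A `te_annotation` object.
#' @param ... Unused.
#' @return A one-row tibble of the recorded features.
#' @export
#' @exportS3Method generics::tidy
tidy.te_annotation <- function(x, ...) {
  tibble(
    element_length = x$element_length,
    tir_length = if (nrow(x$tir)) x$tir$length else NA_integer_,
    tir_mismatches = if (nrow(x$tir)) x$tir$mismatches else NA_integer_,
    tsd_length = if (nrow(x$tsd)) x$tsd$length else NA_integer_,
    tsd_seq = if (nrow(x$tsd)) x$tsd$seq else NA_character_,
    longest_orf_codons = x$longest_orf_codons,
    terminal_motif_match = x$terminal_motif_match,
    classification = x$classification
  )
}

#' Reconstruct an element split by a nested insertion
#'
#' When a younger element inserts into an older one, the older element
#' survives as two flanking fragments. Joining the two outer fragments
#' (optionally excising the inner element's own TSD copy) reconstructs the
#' pre-insertion element.
#'
#' @param host Host DNA string carrying both fragments.
#' @param part1_start,part1_end,part2_start,part2_end 1-based closed
#'   intervals of the two outer fragments; the nested insertion lies between
#'   them. Intervals must not overlap.
#' @return A list with `seq` (the reconstructed element) and `length`.
#' @export
reconstruct_split_element <- function(host, part1_start, part1_end,
                                      part2_start, part2_end) {
  host <- unname(.as_named_seqs(host, "host"))
  p <- as.integer(c(part1_start, part1_end, part2_start, part2_end))
  if (p[1] > p[2] || p[3] > p[4]) rlang::abort("malformed part intervals")
  if (p[3] <= p[2]) {
    if (p[3] == p[2] + 1L) {
      # contiguous parts: degenerate (inner insertion of length 0)
    } else {
      rlang::abort("part intervals overlap")
    }
  }
  seq <- paste0(
    extract_subsequence(host, p[1], p[2]),
    extract_subsequence(host, p[3], p[4])
  )
  list(seq = seq, length = nchar(seq))
}
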