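# Pairwise comparison of two paralogous promoters: global alignment,
# segmentation of large alignment gaps into indel "regions", and
# classification of each region as an insertion into its carrier versus a
# loss from the other paralog, using genomic copy number as evidence.

#' Global alignment of two promoter sequences
#'
#' Needleman-Wunsch global alignment with affine gaps (defaults +1/-1,
#' gap open -4, extend -0.5), tuned for long noncoding sequences where
#' large indels should stay contiguous.
#'
#' @param a,b DNA strings, 1-row FASTA tibbles, or named strings. Names (or
#'   tibble `id`s) become the sequence labels.
#' @param match,mismatch,gap_open,gap_extend Scoring scheme; penalties are
#'   given as positive numbers.
#' @return An object of class `promoter_alignment`: list with `a_id`,
#'   `b_id`, `a_aln`, `b_aln` (gapped rows), `score`, `a_len`, `b_len`.
#' @export
align_promoters <- function(a, b, match = 1, mismatch = -1,
                            gap_open = 4, gap_extend = 0.5) {
  av <- .as_named_seqs(a, "a"); bv <- .as_named_seqs(b, "b")
  stopifnot(length(av) == 1L, length(bv) == 1L)
  if (nchar(av) == 0L || nchar(bv) == 0L) rlang::abort("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    unname(av), unname(bv), type = "global",
    substitutionMatrix = .submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend
  )
  structure(
    list(
      a_id = names(av), b_id = names(bv),
      a_aln = as.character(Biostrings::pattern(aln)),
      b_aln = as.character(Biostrings::subject(aln)),
      score = Biostrings::score(aln),
      a_len = nchar(unname(av)), b_len = nchar(unname(bv))
    ),
    class = "promoter_alignment"
  )
}

#' @export
print.promoter_alignment <- function(x, ...) {
  cat(sprintf("<promoter_alignment> %s (%d bp) vs %s (%d bp), %d columns, score %.1f\n",
              x$a_id, x$a_len, x$b_id, x$b_len, nchar(x$a_aln), x$score))
  invisible(x)
}

# Gap runs in one alignment row: tibble(start_col, end_col, len).
.gap_runs <- function(row_chars) {
  r <- rle(row_chars == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start_col = starts[keep], end_col = ends[keep], len = r$lengths[keep])
}

# Merge gap runs separated by fewer than join_dist aligned columns.
.merge_runs <- function(runs, join_dist) {
  if (nrow(runs) <= 1L) {
    runs$gap_total <- runs$len
    return(runs)
  }
  group <- cumsum(c(1L, as.integer(
    runs$start_col[-1L] - runs$end_col[-nrow(runs)] - 1L >= join_dist
  )))
  out <- dplyr::group_by(dplyr::mutate(runs, .g = group), .data$.g)
  out <- dplyr::summarise(
    out,
    start_col = min(.data$start_col), end_col = max(.data$end_col),
    gap_total = sum(.data$len), .groups = "drop"
  )
  out[, c("start_col", "end_col", "gap_total")]
}

#' Segment large indel regions from a promoter alignment
#'
#' Maximal gap runs of at least `min_region_len` bp in one alignment row
#' mark extra DNA carried by the *other* sequence. Gap runs in the same row
#' separated by fewer than `join_dist` aligned columns are merged first.
#' Regions are labeled with Roman numerals from the TSS-proximal end
#' outward; promoters are assumed written 5' to 3' with the TSS adjacent to
#' the 3' (right) end, so labeling runs right to left.
#'
#' @param alignment A `promoter_alignment` from [align_promoters()].
#' @param min_region_len Minimum region length in bp (the published
#'   convention ignores indels below a few hundred bp).
#' @param join_dist Maximum aligned-column separation for merging gap runs.
#' @return A tibble with `region` (Roman label), `carrier` (sequence id
#'   holding the extra DNA), `start`, `end` (1-based closed on the
#'   carrier), `length` (bp of carrier-exclusive sequence), `aln_start`,
#'   `aln_end`.
#' @export
segment_length_divergent_regions <- function(alignment, min_region_len = 200L,
                                             join_dist = 50L) {
  stopifnot(inherits(alignment, "promoter_alignment"))
  a_chars <- .chars(alignment$a_aln)
  b_chars <- .chars(alignment$b_aln)
  a_pos <- cumsum(a_chars != "-")
  b_pos <- cumsum(b_chars != "-")
  collect <- function(gap_row_chars, carrier_id, carrier_pos) {
    runs <- .merge_runs(.gap_runs(gap_row_chars), join_dist)
    runs <- runs[runs$gap_total >= min_region_len, , drop = FALSE]
    if (nrow(runs) == 0L) {
      return(tibble(carrier = character(), start = integer(), end = integer(),
                    length = integer(), aln_start = integer(), aln_end = integer()))
    }
    tibble(
      carrier = carrier_id,
      start = carrier_pos[runs$start_col],
      end = carrier_pos[runs$end_col],
      length = as.integer(runs$gap_total),
      aln_start = as.integer(runs$start_col),
      aln_end = as.integer(runs$end_col)
    )
  }
  regions <- dplyr::bind_rows(
    collect(a_chars, alignment$b_id, b_pos), # gaps in a => extra DNA in b
    collect(b_chars, alignment$a_id, a_pos)
  )
  regions <- dplyr::arrange(regions, dplyr::desc(.data$aln_start))
  regions <- dplyr::mutate(regions, region = .roman(dplyr::row_number()),
                           .before = 1L)
  regions
}

#' Classify indel regions as insertions into the carrier vs losses
#'
#' A region present in multiple genomic copies is repetitive sequence that
#' was added to its carrier; a single-copy region (found only at its own
#' locus) was retained on the carrier and lost from the other paralog.
#'
#' @param regions Region tibble from [segment_length_divergent_regions()].
#' @param carriers FASTA tibble or named character vector containing the
#'   carrier promoter sequences (names matching the `carrier` column).
#' @param genome FASTA tibble or named character vector of genome sequences
#'   (should include the promoter locus itself so that a unique region
#'   counts as one copy).
#' @param params A [search_params()] object for the copy search.
#' @param min_copies_for_repeat Copy count at or above which a region is
#'   called repetitive (insertion into carrier).
#' @return `regions` with `copy_count`, `call` (one of
#'   `insertion_into_carrier`, `loss_from_other`, `ambiguous`) and
#'   `evidence` appended.
#' @export
classify_region_origin <- function(regions, carriers, genome,
                                   params = search_params(),
                                   min_copies_for_repeat = 2L) {
  carriers <- .as_named_seqs(carriers, "carriers")
  out <- purrr::map(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    if (!r$carrier %in% names(carriers)) {
      rlang::abort(paste0("carrier sequence '", r$carrier, "' not supplied"))
    }
    region_seq <- substr(carriers[[r$carrier]], r$start, r$end)
    cc <- count_copies(setNames(region_seq, paste0("region_", r$region)),
                       genome, params)
    call <- if (cc$n >= min_copies_for_repeat) "insertion_into_carrier"
    else if (cc$n == 1L) "loss_from_other"
    else "ambiguous"
    tibble(
      copy_count = cc$n, call = call,
      evidence = sprintf(
        "%d genomic copies at >=%.0f%% identity over >=%.0f%% of length (repeat threshold %d)",
        cc$n, 100 * params$min_identity, 100 * params$min_coverage,
        min_copies_for_repeat
      )
    )
  })
  dplyr::bind_cols(regions, dplyr::bind_rows(out))
}

#' Compare two paralogous promoters end to end
#'
#' Convenience wrapper: [align_promoters()], then
#' [segment_length_divergent_regions()], then (when a genome is supplied)
#' [classify_region_origin()].
#'
#' @inheritParams align_promoters
#' @inheritParams segment_length_divergent_regions
#' @inheritParams classify_region_origin
#' @param genome Optional genome for origin classification.
#' @return The region tibble (with origin calls when `genome` is given);
#'   the `promoter_alignment` is attached as attribute `"alignment"`.
#' @export
compare_promoters <- function(a, b, genome = NULL, min_region_len = 200L,
                              join_dist = 50L, params = search_params(),
                              min_copies_for_repeat = 2L) {
  av <- .as_named_seqs(a, "a"); bv <- .as_named_seqs(b, "b")
  aln <- align_promoters(av, bv)
  regions <- segment_length_divergent_regions(aln, min_region_len, join_dist)
  if (!is.null(genome) && nrow(regions) > 0L) {
    regions <- classify_region_origin(regions, c(av, bv), genome, params,
                                      min_copies_for_repeat)
  }
  attr(regions, "alignment") <- aln
  regions
}
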