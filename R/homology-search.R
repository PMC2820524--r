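# BLASTN-like seed-and-extend local homology search, used to count genomic
# copies of a repeat under an identity/coverage filter. Exact word seeding
# and diagonal clustering are done here; the gapped extension within each
# seeded subject window is an optimal local (Smith-Waterman) alignment.

#' Search parameters for the seed-and-extend homology search
#'
#' Defaults follow megablast-style scoring (+1/-2, gap open -5, extend -2)
#' with the 85% identity over 85% of query length filter conventionally used
#' for repeat copy counting.
#'
#' @param word_size Exact seed word length.
#' @param min_identity,min_coverage Hit filter: identity over aligned
#'   columns (gaps count as mismatches) and fraction of the query aligned.
#' @param match,mismatch Per-column alignment scores.
#' @param gap_open,gap_extend Positive penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param x_drop Extension drop-off; here it pads the seeded subject window
#'   within which the optimal local extension is computed.
#' @param strict_gt If `TRUE`, the identity/coverage filter uses strict `>`
#'   instead of the default inclusive `>=`.
#' @return A list of class `search_params`.
#' @export
search_params <- function(word_size = 11L, min_identity = 0.85,
                          min_coverage = 0.85, match = 1, mismatch = -2,
                          gap_open = 5, gap_extend = 2, x_drop = 20,
                          strict_gt = FALSE) {
  stopifnot(word_size >= 4L, min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1, gap_open >= 0, gap_extend >= 0)
  structure(
    list(word_size = as.integer(word_size), min_identity = min_identity,
         min_coverage = min_coverage, match = match, mismatch = mismatch,
         gap_open = gap_open, gap_extend = gap_extend, x_drop = x_drop,
         strict_gt = isTRUE(strict_gt)),
    class = "search_params"
  )
}

.submat <- function(match, mismatch) {
  letters <- c(.DNA_BASES, "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m)[1:4] <- match
  m["N", "N"] <- mismatch
  m
}

.words_index <- function(seq, w) {
  n <- nchar(seq)
  if (n < w) return(list())
  words <- substring(seq, 1:(n - w + 1L), w:n)
  split(seq_len(n - w + 1L), words)
}

.hit_row <- function(aln, nq, strand, win_start, query_id, subject_id) {
  p_aln <- as.character(Biostrings::pattern(aln))
  s_aln <- as.character(Biostrings::subject(aln))
  pc <- .chars(p_aln); sc <- .chars(s_aln)
  cols <- length(pc)
  matches <- sum(pc == sc & pc != "-")
  qs <- Biostrings::start(Biostrings::pattern(aln))
  qe <- Biostrings::end(Biostrings::pattern(aln))
  if (strand == "-") {
    tmp <- qs
    qs <- nq - qe + 1L
    qe <- nq - tmp + 1L
  }
  tibble(
    query_id = query_id, subject_id = subject_id, strand = strand,
    q_start = qs, q_end = qe,
    s_start = win_start - 1L + Biostrings::start(Biostrings::subject(aln)),
    s_end = win_start - 1L + Biostrings::end(Biostrings::subject(aln)),
    length = cols, matches = matches,
    identity = matches / cols,
    coverage = (qe - qs + 1L) / nq,
    score = Biostrings::score(aln),
    q_aln = p_aln, s_aln = s_aln
  )
}

#' Seed-and-extend local search of a query against a subject sequence
#'
#' Exact `word_size` seeds on both strands are clustered by subject
#' position; each seeded region is extended by optimal local alignment of
#' the query against the padded subject window. Hits are reported sorted by
#' score (descending), ties by subject position.
#'
#' @param query,subject DNA strings (or 1-row FASTA tibbles / named
#'   strings). The query must be at least `word_size` long.
#' @param params A [search_params()] object.
#' @param both_strands Search the minus strand too?
#' @return A tibble of hits: `query_id`, `subject_id`, `strand`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `length` (aligned columns), `matches`,
#'   `identity`, `coverage`, `score`, `q_aln`, `s_aln`.
#' @export
seed_and_extend <- function(query, subject, params = search_params(),
                            both_strands = TRUE) {
  q <- .as_named_seqs(query, "query")
  s <- .as_named_seqs(subject, "subject")
  stopifnot(length(q) == 1L, length(s) == 1L)
  query_id <- names(q); subject_id <- names(s)
  q <- unname(q); s <- unname(s)
  w <- params$word_size
  nq <- nchar(q); ns <- nchar(s)
  if (nq < w) rlang::abort("query shorter than `word_size`")
  if (ns == 0L) return(.empty_hits())
  sub_idx <- .words_index(s, w)
  mat <- .submat(params$match, params$mismatch)
  pad <- as.integer(2 * params$x_drop + 2 * w)
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (strand in strands) {
    qs <- if (strand == "+") q else reverse_complement(q)
    qwords <- substring(qs, 1:(nq - w + 1L), w:nq)
    pos_list <- sub_idx[qwords]
    lens <- lengths(pos_list)
    if (sum(lens) == 0L) next
    qpos <- rep(seq_along(qwords), lens)
    spos <- unlist(pos_list, use.names = FALSE)
    # cluster seeds by alignment diagonal (tolerating indel drift), then by
    # subject position, so tandem copies seed separate extensions
    diag <- spos - qpos
    band <- as.integer(2 * params$x_drop + 10)
    ord <- order(diag, spos)
    qpos <- qpos[ord]; spos <- spos[ord]; diag <- diag[ord]
    cluster <- cumsum(c(TRUE, diff(diag) > band | diff(spos) > nq))
    for (cl in split(seq_along(spos), cluster)) {
      wstart <- max(1L, min(spos[cl] - qpos[cl]) + 1L - pad)
      wend <- min(ns, max(spos[cl] + (nq - qpos[cl])) + pad)
      win <- substr(s, wstart, wend)
      aln <- Biostrings::pairwiseAlignment(
        qs, win, type = "local", substitutionMatrix = mat,
        gapOpening = params$gap_open, gapExtension = params$gap_extend
      )
      if (Biostrings::score(aln) <= 0) next
      out[[length(out) + 1L]] <- .hit_row(aln, nq, strand, wstart, query_id, subject_id)
    }
  }
  if (length(out) == 0L) return(.empty_hits())
  hits <- dplyr::bind_rows(out)
  hits <- dplyr::distinct(hits, .data$subject_id, .data$strand,
                          .data$s_start, .data$s_end, .keep_all = TRUE)
  dplyr::arrange(hits, dplyr::desc(.data$score), .data$s_start)
}

.empty_hits <- function() {
  tibble(
    query_id = character(), subject_id = character(), strand = character(),
    q_start = integer(), q_end = integer(), s_start = integer(),
    s_end = integer(), length = integer(), matches = integer(),
    identity = double(), coverage = double(), score = double(),
    q_aln = character(), s_aln = character()
  )
}

#' Count genomic copies of a query element
#'
#' Runs [seed_and_extend()] against every genome sequence, keeps hits
#' passing the identity and coverage filters, collapses overlapping passing
#' hits (on the subject) to the best-scoring one, and counts the survivors.
#' This mirrors the conventional "BLASTN copies at >=85% identity over
#' >=85% of query length" repeat copy-number estimate.
#'
#' @param query Query DNA string (or 1-row FASTA tibble).
#' @param genome FASTA tibble or named character vector of genome sequences.
#' @param params A [search_params()] object.
#' @return An object of class `copy_count`: list with `n` (integer count),
#'   `hits` (the retained non-overlapping passing hits) and `all_hits`
#'   (every passing hit before collapsing).
#' @export
count_copies <- function(query, genome, params = search_params()) {
  genome <- .as_named_seqs(genome, "genome")
  hits <- purrr::map(names(genome), function(sid) {
    seed_and_extend(query, setNames(genome[sid], sid), params)
  })
  hits <- dplyr::bind_rows(hits)
  pass <- if (params$strict_gt) {
    dplyr::filter(hits, .data$identity > params$min_identity,
                  .data$coverage > params$min_coverage)
  } else {
    dplyr::filter(hits, .data$identity >= params$min_identity,
                  .data$coverage >= params$min_coverage)
  }
  pass <- dplyr::arrange(pass, dplyr::desc(.data$score), .data$s_start)
  kept <- pass[0, ]
  for (i in seq_len(nrow(pass))) {
    row <- pass[i, ]
    overlaps <- nrow(kept) > 0L &&
      any(kept$subject_id == row$subject_id &
            kept$s_start <= row$s_end & kept$s_end >= row$s_start)
    if (!overlaps) kept <- dplyr::bind_rows(kept, row)
  }
  kept <- dplyr::arrange(kept, .data$subject_id, .data$s_start)
  structure(list(n = nrow(kept), hits = kept, all_hits = pass),
            class = "copy_count")
}

#' @export
print.copy_count <- function(x, ...) {
  cat(sprintf("<copy_count> %d non-overlapping passing copies (%d passing hits)\n",
              x$n, nrow(x$all_hits)))
  invisible(x)
}

#' @export
#' @exportS3Method generics::tidy
tidy.copy_count <- function(x, ...) x$hits

#' Nearest annotated features flanking each hit
#'
#' For every hit, reports the nearest feature upstream and downstream on the
#' same subject sequence, with distances in bp (0 when overlapping).
#'
#' @param hits A hit tibble (from [seed_and_extend()] or `count_copies()$hits`).
#' @param features A feature tibble with `chrom`, `start`, `end` and
#'   optionally `name` (e.g. from [read_bed()]).
#' @return `hits` with columns `upstream_feature`, `upstream_dist`,
#'   `downstream_feature`, `downstream_dist` appended.
#' @export
flanking_context <- function(hits, features) {
  if (!"name" %in% names(features)) {
    features$name <- paste0("feature", seq_len(nrow(features)))
  }
  ctx <- purrr::map(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    f <- features[features$chrom == h$subject_id, , drop = FALSE]
    if (nrow(f) == 0L) {
      return(tibble(upstream_feature = NA_character_, upstream_dist = NA_real_,
                    downstream_feature = NA_character_, downstream_dist = NA_real_))
    }
    overlap <- f$start <= h$s_end & f$end >= h$s_start
    up <- f[f$end < h$s_start, , drop = FALSE]
    down <- f[f$start > h$s_end, , drop = FALSE]
    if (any(overlap)) {
      ov <- f[overlap, , drop = FALSE][1, ]
      tibble(upstream_feature = ov$name, upstream_dist = 0,
             downstream_feature = ov$name, downstream_dist = 0)
    } else {
      tibble(
        upstream_feature = if (nrow(up)) up$name[which.max(up$end)] else NA_character_,
        upstream_dist = if (nrow(up)) h$s_start - max(up$end) else NA_real_,
        downstream_feature = if (nrow(down)) down$name[which.min(down$start)] else NA_character_,
        downstream_dist = if (nrow(down)) min(down$start) - h$s_end else NA_real_
      )
    }
  })
  dplyr::bind_cols(hits, dplyr::bind_rows(ctx))
}
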