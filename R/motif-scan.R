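# Position-weight-matrix construction, log-odds scanning of both strands,
# and exact score-distribution p-values by dynamic-programming convolution
# over columns. Scores and p-values are reported in natural-log units.

#' Build a position weight matrix from base counts
#'
#' Log-odds are natural-log:
#' `log((counts[b,j] + a[b]) / (colsum[j] + sum(a))) - log(background[b])`,
#' with the per-column pseudocount mass split across bases in proportion to
#' the background.
#'
#' @param counts A 4 x w nonnegative matrix, rows A, C, G, T (rownames
#'   optional but honored when present).
#' @param pseudocount Total pseudocount mass added per column. Default
#'   `max(0.5, 0.01 * column total)`.
#' @param background Base frequencies (A, C, G, T) summing to 1.
#' @return An object of class `pwm`: list with `counts`, `probs`,
#'   `log_odds`, `background`, `width`, `pseudocount`.
#' @export
pwm_from_counts <- function(counts, pseudocount = NULL,
                            background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) rlang::abort("`counts` must have 4 rows (A, C, G, T)")
  if (!is.null(rownames(counts))) {
    if (!setequal(rownames(counts), .DNA_BASES)) {
      rlang::abort("rownames of `counts` must be A, C, G, T")
    }
    counts <- counts[.DNA_BASES, , drop = FALSE]
  } else {
    rownames(counts) <- .DNA_BASES
  }
  if (any(counts < 0)) rlang::abort("`counts` must be nonnegative")
  csum <- colSums(counts)
  if (any(csum == 0)) rlang::abort("every column needs at least one positive count")
  stopifnot(length(background) == 4L, all(background > 0),
            abs(sum(background) - 1) < 1e-8)
  background <- setNames(as.numeric(background), .DNA_BASES)
  a_tot <- if (is.null(pseudocount)) pmax(0.5, 0.01 * csum) else rep(pseudocount, ncol(counts))
  alpha <- outer(background, rep(1, ncol(counts))) * rep(a_tot, each = 4L)
  probs <- sweep(counts + alpha, 2L, csum + a_tot, "/")
  log_odds <- log(probs) - log(background)
  structure(
    list(counts = counts, probs = probs, log_odds = log_odds,
         background = background, width = ncol(counts),
         pseudocount = a_tot),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, consensus %s\n", x$width, pwm_consensus(x)))
  print(round(x$log_odds, 3))
  invisible(x)
}

#' Highest-scoring word of a PWM
#'
#' @param pwm A [pwm_from_counts()] object.
#' @return The maximum-log-odds word (ties broken A < C < G < T).
#' @export
pwm_consensus <- function(pwm) {
  .collapse(.DNA_BASES[apply(pwm$log_odds, 2L, which.max)])
}

#' Maximum attainable PWM score
#' @param pwm A [pwm_from_counts()] object.
#' @return Sum over columns of the per-column maximum log-odds.
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm$log_odds, 2L, max))

# Discretized tail distribution of the background score: integer-grid DP
# convolution over columns. Returns P(S_grid >= k) indexed by k.
.pwm_tail <- function(pwm, grid = 1e-3) {
  S <- round(pwm$log_odds / grid)
  bg <- pwm$background
  lo <- 0; hi <- 0
  dist <- 1
  for (j in seq_len(pwm$width)) {
    smin <- min(S[, j]); smax <- max(S[, j])
    nlo <- lo + smin; nhi <- hi + smax
    new <- numeric(nhi - nlo + 1L)
    for (b in 1:4) {
      off <- S[b, j] - smin
      idx <- seq_along(dist) + (lo + S[b, j]) - nlo
      new[idx] <- new[idx] + bg[b] * dist
    }
    dist <- new; lo <- nlo; hi <- nhi
  }
  tail <- rev(cumsum(rev(dist)))
  list(lo = lo, hi = hi, tail = tail, grid = grid)
}

#' Exact p-value of a PWM score under the background model
#'
#' The tail probability `Pr(S >= score)` for a random background word of the
#' motif width, with the column score distribution convolved exactly on a
#' fixed discretization grid (round-to-nearest; worst-case log-score error
#' `grid * width / 2`).
#'
#' @param pwm A [pwm_from_counts()] object.
#' @param score Log-odds score(s) to evaluate.
#' @param grid Discretization step in natural-log units.
#' @return Numeric vector of tail probabilities in `(0, 1]` (0 above the
#'   maximum attainable score).
#' @export
score_pvalue <- function(pwm, score, grid = 1e-3) {
  tl <- .pwm_tail(pwm, grid)
  idx <- round(score / grid)
  vapply(idx, function(k) {
    if (k <= tl$lo) 1
    else if (k > tl$hi) 0
    else tl$tail[[k - tl$lo + 1L]]
  }, numeric(1))
}

.encode_dna <- function(seq) match(.chars(seq), .DNA_BASES)

.scan_one_strand <- function(code, lo_mat, min_score) {
  w <- ncol(lo_mat)
  n <- length(code)
  if (n < w) return(tibble(start = integer(), score = double()))
  m <- n - w + 1L
  sc <- numeric(m)
  for (j in seq_len(w)) {
    sc <- sc + lo_mat[cbind(code[j:(j + m - 1L)], j)]
  }
  keep <- which(!is.na(sc) & sc >= min_score)
  tibble(start = keep, score = sc[keep])
}

#' Scan a sequence with a PWM
#'
#' Every window scoring at least `min_score` becomes a hit; windows
#' containing bases outside A/C/G/T (e.g. N) are skipped. On the minus
#' strand the reported `site` is the reverse complement of the genomic
#' slice, and coordinates refer to the plus strand.
#'
#' @param seq DNA string (or 1-row FASTA tibble).
#' @param pwm A [pwm_from_counts()] object.
#' @param min_score Score threshold in natural-log log-odds units.
#' @param both_strands Scan the minus strand too?
#' @param grid Discretization grid for the p-value lookup.
#' @return A tibble of class-annotated hits: `start`, `end`, `strand`,
#'   `site`, `score`, `p_value`, `ln_p`, sorted by position.
#' @export
scan_sequence <- function(seq, pwm, min_score, both_strands = TRUE,
                          grid = 1e-3) {
  seqs <- .as_named_seqs(seq, "seq")
  stopifnot(length(seqs) == 1L)
  s <- unname(seqs)
  n <- nchar(s)
  w <- pwm$width
  if (n < w) rlang::abort("sequence shorter than motif width")
  plus <- .scan_one_strand(.encode_dna(s), pwm$log_odds, min_score)
  plus$strand <- rep("+", nrow(plus))
  hits <- plus
  if (both_strands) {
    rc <- reverse_complement(s)
    minus <- .scan_one_strand(.encode_dna(rc), pwm$log_odds, min_score)
    # window at position i of the reverse complement covers plus-strand
    # coordinates [n - i - w + 2, n - i + 1]
    minus$start <- n - minus$start - w + 2L
    minus$strand <- rep("-", nrow(minus))
    hits <- dplyr::bind_rows(plus, minus)
  }
  if (nrow(hits) == 0L) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  site = character(), score = double(), p_value = double(),
                  ln_p = double()))
  }
  hits$end <- hits$start + w - 1L
  hits$site <- mapply(function(st, strand) {
    extract_subsequence(s, st, st + w - 1L, strand)
  }, hits$start, hits$strand)
  tl <- .pwm_tail(pwm, grid)
  hits$p_value <- vapply(round(hits$score / tl$grid), function(k) {
    if (k <= tl$lo) 1 else if (k > tl$hi) 0 else tl$tail[[k - tl$lo + 1L]]
  }, numeric(1))
  hits$ln_p <- log(hits$p_value)
  out <- dplyr::arrange(hits[, c("start", "end", "strand", "site",
                                 "score", "p_value", "ln_p")], .data$start)
  out
}

#' Expected number of PWM hits in a random background sequence
#'
#' `E = (seq_len - w + 1) * Pr(S >= min_score) * (2 if both strands)`.
#' This is the "random prediction" against which observed binding-site
#' counts are compared.
#'
#' @param pwm A [pwm_from_counts()] object.
#' @param min_score Score threshold.
#' @param seq_len Scanned sequence length in bp.
#' @param both_strands Were both strands scanned?
#' @param grid P-value discretization grid.
#' @return Expected hit count (double).
#' @export
expected_hit_count <- function(pwm, min_score, seq_len, both_strands = TRUE,
                               grid = 1e-3) {
  stopifnot(seq_len >= pwm$width)
  p <- score_pvalue(pwm, min_score, grid)
  (seq_len - pwm$width + 1) * p * (if (both_strands) 2 else 1)
}

#' Observed/expected enrichment ratio
#'
#' @param observed Observed hit count.
#' @param expected Expected hit count under the background model.
#' @return `observed / expected`.
#' @examples
#' enrichment_ratio(7, 0.46) # ~15-fold
#' @export
enrichment_ratio <- function(observed, expected) {
  if (expected <= 0) rlang::abort("`expected` must be > 0")
  observed / expected
}
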