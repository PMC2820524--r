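# Kimura-2-parameter divergence: third-codon-position extraction, pairwise
# transition/transversion counting with pairwise deletion, and the K2P
# distance with its analytic (delta-method) standard error.

#' Extract third codon positions from a coding alignment
#'
#' Third codon positions are the conventional near-neutral site class for
#' molecular-clock dating. Columns `offset + 3, offset + 6, ...` (1-based)
#' are extracted in order; a trailing partial codon is dropped with a
#' warning.
#'
#' @param alignment Gapped FASTA tibble or named character vector of
#'   equal-length sequences.
#' @param frame_offset Number of leading columns before the first complete
#'   codon.
#' @return Named character vector: the third-position sub-alignment.
#' @export
third_codon_positions <- function(alignment, frame_offset = 0L) {
  seqs <- .as_named_seqs_gapped(alignment)
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) rlang::abort("alignment is ragged")
  frame_offset <- as.integer(frame_offset)
  usable <- lens - frame_offset
  if (usable %% 3L != 0L) {
    rlang::warn(sprintf("dropping %d trailing columns (partial codon)", usable %% 3L))
  }
  n_codons <- usable %/% 3L
  if (n_codons == 0L) rlang::abort("no complete codon in alignment")
  pos <- frame_offset + 3L * seq_len(n_codons)
  vapply(seqs, function(s) .collapse(.chars(s)[pos]), character(1))
}

#' Count transitions and transversions between two aligned sequences
#'
#' Columns containing a gap or ambiguity code in either sequence are
#' excluded (pairwise deletion). `P` is the transition proportion (A<->G,
#' C<->T), `Q` the transversion proportion, over the `L` retained sites.
#'
#' @param a,b Equal-length (gapped) DNA strings.
#' @return A list of class `pairwise_counts` with `L`, `P`, `Q`.
#' @export
count_substitutions <- function(a, b) {
  a <- .check_dna(a, "a", allow_gap = TRUE)
  b <- .check_dna(b, "b", allow_gap = TRUE)
  if (nchar(a) != nchar(b)) rlang::abort("sequences must have equal length")
  ca <- .chars(a); cb <- .chars(b)
  ok <- ca %in% .DNA_BASES & cb %in% .DNA_BASES
  ca <- ca[ok]; cb <- cb[ok]
  L <- length(ca)
  if (L == 0L) rlang::abort("no comparable sites after pairwise deletion")
  diff <- ca != cb
  purine <- c("A", "G")
  transition <- diff & ((ca %in% purine) == (cb %in% purine))
  structure(
    list(L = L, P = sum(transition) / L, Q = sum(diff & !transition) / L),
    class = "pairwise_counts"
  )
}

#' Kimura-2-parameter distance with analytic standard error
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with the standard
#' delta-method variance
#' `se^2 = (c1^2 P + c3^2 Q - (c1 P + c3 Q)^2) / L`,
#' `c1 = 1/(1-2P-Q)`, `c2 = 1/(1-2Q)`, `c3 = (c1+c2)/2`.
#'
#' @param counts A `pairwise_counts` object (see [count_substitutions()]),
#'   or a list with elements `L`, `P`, `Q`.
#' @return A one-row tibble with `d`, `se`, `L`, `P`, `Q`.
#' @export
k2p_distance <- function(counts) {
  P <- counts$P; Q <- counts$Q; L <- counts$L
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    rlang::abort("substitution saturation: K2P distance undefined (log argument <= 0)")
  }
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  c1 <- 1 / w1
  c2 <- 1 / w2
  c3 <- (c1 + c2) / 2
  v <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / L
  tibble(d = d, se = sqrt(max(v, 0)), L = L, P = P, Q = Q)
}

#' Pairwise K2P distance matrix of an alignment
#'
#' @param alignment Gapped FASTA tibble or named character vector.
#' @return An object of class `k2p_dist`: list with `taxa`, `d` and `se`
#'   (symmetric matrices).
#' @export
k2p_matrix <- function(alignment) {
  seqs <- .as_named_seqs_gapped(alignment)
  n <- length(seqs)
  if (n < 2L) rlang::abort("need at least two sequences")
  taxa <- names(seqs)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  se <- d
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k2p_distance(count_substitutions(seqs[[i]], seqs[[j]]))
      d[i, j] <- d[j, i] <- k$d
      se[i, j] <- se[j, i] <- k$se
    }
  }
  structure(list(taxa = taxa, d = d, se = se), class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat(sprintf("<k2p_dist> %d taxa\n", length(x$taxa)))
  print(round(x$d, 4))
  invisible(x)
}

#' @export
#' @exportS3Method generics::tidy
tidy.k2p_dist <- function(x, ...) {
  pairs <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(
    taxon1 = x$taxa[pairs[, 1]],
    taxon2 = x$taxa[pairs[, 2]],
    d = x$d[pairs],
    se = x$se[pairs]
  )
}
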