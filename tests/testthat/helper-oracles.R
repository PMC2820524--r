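# Independent oracles and fixture builders shared across tests. These stay
# deliberately naive (brute force / direct DP) so they cannot share bugs
# with the implementation paths they check.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

chars1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

revcomp_naive <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(comp[chars1(x)])), collapse = "")
}

# Smith-Waterman local alignment score, affine gaps: a gap of length L
# costs gap_open + L * gap_extend. Dense double loop on purpose.
sw_score_oracle <- function(a, b, match = 1, mismatch = -2,
                            gap_open = 5, gap_extend = 2) {
  av <- chars1(a); bv <- chars1(b)
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                      Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                      Iy[i, j - 1] - gap_extend)
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1]) + s)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Needleman-Wunsch global score with the same affine-gap convention.
nw_score_oracle <- function(a, b, match = 1, mismatch = -1,
                            gap_open = 4, gap_extend = 0.5) {
  av <- chars1(a); bv <- chars1(b)
  n <- length(av); m <- length(bv)
  M <- matrix(-Inf, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -gap_open - gap_extend * (i - 1)
  for (j in 2:(m + 1)) Iy[1, j] <- -gap_open - gap_extend * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                      Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                      Iy[i, j - 1] - gap_extend)
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# All 4^w words of a PWM with exact log-odds scores and background probs.
enumerate_pwm_words <- function(pwm) {
  w <- pwm$width
  grid <- expand.grid(rep(list(1:4), w))
  score <- rowSums(vapply(seq_len(w), function(j) pwm$log_odds[grid[[j]], j],
                          numeric(nrow(grid))))
  prob <- apply(vapply(seq_len(w), function(j) pwm$background[grid[[j]]],
                       numeric(nrow(grid))), 1, prod)
  data.frame(score = score, prob = prob)
}

# Brute-force longest ATG-to-stop ORF (codons, stop excluded) on 6 frames.
longest_orf_oracle <- function(seq) {
  codon_table_stop <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (s in c(seq, revcomp_naive(seq))) {
    v <- chars1(s)
    for (f in 0:2) {
      starts <- seq(f + 1, length(v) - 2, by = 3)
      codons <- vapply(starts, function(i) paste(v[i:(i + 2)], collapse = ""),
                       character(1))
      open <- NA_integer_
      for (k in seq_along(codons)) {
        if (is.na(open) && codons[k] == "ATG") open <- k
        if (!is.na(open) && codons[k] %in% codon_table_stop) {
          best <- max(best, k - open)
          open <- NA_integer_
        }
      }
    }
  }
  best
}

# A five-taxon additive (in fact ultrametric) distance matrix with known
# path lengths, plus a non-ultrametric additive variant.
additive_matrix_5taxa <- function() {
  # unrooted tree: ((A:2,B:3):1,(C:4,(D:2,E:1):2):1)
  pend <- c(A = 2, B = 3, C = 4, D = 2, E = 1)
  d <- matrix(0, 5, 5, dimnames = list(names(pend), names(pend)))
  d["A", "B"] <- 2 + 3
  d["A", "C"] <- 2 + 1 + 1 + 4
  d["A", "D"] <- 2 + 1 + 1 + 2 + 2
  d["A", "E"] <- 2 + 1 + 1 + 2 + 1
  d["B", "C"] <- 3 + 1 + 1 + 4
  d["B", "D"] <- 3 + 1 + 1 + 2 + 2
  d["B", "E"] <- 3 + 1 + 1 + 2 + 1
  d["C", "D"] <- 4 + 2 + 2
  d["C", "E"] <- 4 + 2 + 1
  d["D", "E"] <- 2 + 1
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# Element with clean TIRs whose interior is screened against extending them.
make_tir_element <- function(tir, interior_len) {
  interior <- rnd_dna(interior_len)
  # ensure the bases adjacent to the TIRs cannot extend the inverted repeat
  first_ok <- setdiff(c("A", "C", "G", "T"),
                      revcomp_naive(substr(interior, interior_len, interior_len)))
  substr(interior, 1, 1) <- first_ok[1]
  paste0(tir, interior, revcomp_naive(tir))
}

# Host with one planted element flanked by an exact TSD, screened so the
# duplication cannot extend outward by one base.
make_tsd_host <- function(element, tsd, flank = 120L) {
  left <- rnd_dna(flank)
  right <- rnd_dna(flank)
  if (substr(left, flank, flank) == substr(right, 1, 1)) {
    repl <- setdiff(c("A", "C", "G", "T"), substr(left, flank, flank))[1]
    substr(right, 1, 1) <- repl
  }
  host <- paste0(left, tsd, element, tsd, right)
  list(host = host, start = flank + nchar(tsd) + 1L,
       end = flank + nchar(tsd) + nchar(element))
}
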