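# Seeded generators producing every input the pipeline needs with known
# ground truth: K2P-evolved sequences, genomes with planted element copies
# and TSDs, promoter pairs with planted indel regions, clock-evolved
# third-codon-position alignments over a species tree containing a gene
# duplication and a later element insertion, and planted motif instances.
#
# Every generator draws from its own seed stream derived from (seed,
# operation name), so adding a generator does not perturb existing outputs.

# Expected transition/transversion proportions under K2P at distance d with
# instantaneous ts:tv rate ratio kappa (P/Q -> kappa as d -> 0).
.k2p_pq <- function(d, kappa = 2) {
  stopifnot(d >= 0, kappa > 0)
  bT <- d / (2 * kappa + 2)
  Q <- 0.5 * (1 - exp(-4 * bT))
  P <- 0.25 + 0.25 * exp(-4 * bT) - 0.5 * exp(-2 * (2 * kappa + 1) * bT)
  list(P = P, Q = Q)
}

.TS_PARTNER <- c(A = "G", C = "T", G = "A", T = "C")
.TV_PARTNERS <- list(A = c("C", "T"), C = c("A", "G"),
                     G = c("C", "T"), T = c("A", "G"))

.mutate_k2p <- function(chars, P, Q) {
  n <- length(chars)
  u <- runif(n)
  out <- chars
  ts <- u < P
  tv1 <- u >= P & u < P + Q / 2
  tv2 <- u >= P + Q / 2 & u < P + Q
  out[ts] <- .TS_PARTNER[chars[ts]]
  out[tv1] <- vapply(chars[tv1], function(b) .TV_PARTNERS[[b]][1L], character(1))
  out[tv2] <- vapply(chars[tv2], function(b) .TV_PARTNERS[[b]][2L], character(1))
  out
}

#' Evolve a sequence under the Kimura-2-parameter model
#'
#' Independent per-site substitution with transition/transversion
#' proportions solving the K2P expectations for the target distance at the
#' given instantaneous ts:tv ratio, so that the K2P estimator applied to
#' (input, output) is consistent for `d`.
#'
#' @param seq DNA string over A/C/G/T.
#' @param d Target K2P distance (substitutions/site), `0 <= d <= 1`.
#' @param kappa Instantaneous transition:transversion rate ratio
#'   (expected P/Q at small distances).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return The mutated DNA string.
#' @export
evolve_sequence_k2p <- function(seq, d, kappa = 2, seed = NULL) {
  seq <- .check_dna(seq)
  if (d < 0 || d > 1) rlang::abort("`d` must be in [0, 1] (saturation-safe range)")
  if (d == 0) return(seq)
  pq <- .k2p_pq(d, kappa)
  .with_op_seed(seed, "evolve_sequence_k2p", {
    .collapse(.mutate_k2p(.chars(seq), pq$P, pq$Q))
  })
}

#' Plant diverged element copies (with TSDs) into a backbone genome
#'
#' Inserts `n_copies` independently K2P-evolved copies of an element at
#' uniform non-overlapping positions, each flanked by a fresh random
#' `tsd_len`-bp target-site duplication. The host base left of each
#' insertion point is screened so that the duplication cannot accidentally
#' extend by one base.
#'
#' @param backbone Host DNA string (before insertion).
#' @param element Element DNA string.
#' @param n_copies Number of copies to plant.
#' @param copy_divergence Per-copy K2P distance from the element.
#' @param tsd_len TSD length in bp.
#' @param kappa ts:tv rate ratio for copy evolution.
#' @param seed Integer seed.
#' @return A list with `genome` (single DNA string), and `truth`: a tibble
#'   with per-copy `start`, `end` (element interval, TSD excluded),
#'   `tsd_seq`, `divergence_target` and `divergence_realized` (proportion
#'   of substituted sites).
#' @export
plant_element_copies <- function(backbone, element, n_copies,
                                 copy_divergence = 0, tsd_len = 8L,
                                 kappa = 2, seed = 1L) {
  backbone <- .check_dna(backbone, "backbone")
  element <- .check_dna(element, "element")
  n_copies <- as.integer(n_copies)
  tsd_len <- as.integer(tsd_len)
  if (n_copies == 0L) {
    return(list(genome = backbone, truth = tibble(
      copy = integer(), start = integer(), end = integer(),
      tsd_seq = character(), divergence_target = double(),
      divergence_realized = double()
    )))
  }
  nb <- nchar(backbone)
  unit <- nchar(element) + 2L * tsd_len
  if (nb < n_copies * (unit + 2L) + 2L) {
    rlang::abort("backbone too short for non-overlapping placements")
  }
  .with_op_seed(seed, "plant_element_copies", {
    # insertion points in backbone coordinates, kept >= 2 apart and off the ends
    ok <- FALSE
    for (try in 1:100) {
      pts <- sort(sample(2:(nb - 1L), n_copies))
      if (n_copies == 1L || min(diff(pts)) >= 2L) { ok <- TRUE; break }
    }
    if (!ok) rlang::abort("could not place copies without overlap")
    bchars <- .chars(backbone)
    pieces <- character(0)
    truth <- vector("list", n_copies)
    prev <- 1L
    for (i in seq_len(n_copies)) {
      p <- pts[i]
      # screen flank: base immediately 5' of the left TSD must differ from
      # the base immediately 3' of the right TSD (else the TSD would extend)
      if (bchars[p - 1L] == bchars[p]) {
        bchars[p] <- sample(setdiff(.DNA_BASES, bchars[p - 1L]), 1L)
      }
      tsd <- .random_dna(tsd_len)
      copy <- evolve_sequence_k2p(element, copy_divergence, kappa, seed = NULL)
      realized <- mean(.chars(copy) != .chars(element))
      left_chunk <- .collapse(bchars[prev:(p - 1L)])
      left_len <- nchar(left_chunk)
      copy_len <- nchar(copy)
      pieces <- c(pieces, left_chunk, tsd, copy, tsd)
      truth[[i]] <- tibble(
        copy = i, tsd_seq = tsd,
        divergence_target = copy_divergence, divergence_realized = realized,
        .piece_left = left_len, .piece_copy = copy_len
      )
      prev <- p
    }
    pieces <- c(pieces, .collapse(bchars[prev:nb]))
    genome <- .collapse(pieces)
    truth <- dplyr::bind_rows(truth)
    # reconstruct coordinates from piece lengths
    starts <- integer(n_copies)
    pos <- 0L
    for (i in seq_len(n_copies)) {
      pos <- pos + truth$.piece_left[i] + tsd_len
      starts[i] <- pos + 1L
      pos <- pos + truth$.piece_copy[i] + tsd_len
    }
    truth$start <- starts
    truth$end <- starts + truth$.piece_copy - 1L
    truth <- truth[, c("copy", "start", "end", "tsd_seq",
                       "divergence_target", "divergence_realized")]
    list(genome = genome, truth = truth)
  })
}

#' Generate a paralogous promoter pair with planted indel regions
#'
#' Both promoters share a random backbone; each specified region is a fresh
#' random sequence inserted into its carrier at a distinct backbone
#' position. Regions are labeled with Roman numerals from the TSS-proximal
#' (3') end outward, matching [segment_length_divergent_regions()].
#'
#' @param backbone_len Shared backbone length in bp.
#' @param region_spec Tibble with columns `carrier` (values `"A"` or `"Y"`)
#'   and `length` (bp). Default mirrors a published autosome/Y promoter
#'   pair: four Y-carried regions of 2348, 315, 598 and 496 bp and one
#'   A-carried region of 728 bp.
#' @param seed Integer seed.
#' @param min_separation Minimum backbone separation between insertion
#'   points (keeps recovered regions distinct).
#' @return A list with `seq_a`, `seq_y` (named `A` / `Y`), `region_seqs`
#'   (named by region label) and `truth`: tibble with `region`, `carrier`,
#'   `backbone_pos`, `start`, `end` (on the carrier), `length`.
#' @export
generate_promoter_pair <- function(backbone_len = 5350L,
                                   region_spec = tibble(
                                     carrier = c("Y", "Y", "Y", "Y", "A"),
                                     length = c(2348L, 315L, 598L, 496L, 728L)
                                   ),
                                   seed = 1L, min_separation = 300L) {
  stopifnot(all(region_spec$carrier %in% c("A", "Y")),
            all(region_spec$length > 0))
  .with_op_seed(seed, "generate_promoter_pair", {
    backbone <- .random_dna(backbone_len)
    n <- nrow(region_spec)
    if (n == 0L) {
      return(list(
        seq_a = c(A = backbone), seq_y = c(Y = backbone),
        region_seqs = character(0),
        truth = tibble(region = character(), carrier = character(),
                       backbone_pos = integer(), start = integer(),
                       end = integer(), length = integer())
      ))
    }
    lo <- min_separation
    hi <- backbone_len - min_separation
    stopifnot(hi > lo + n * min_separation)
    repeat {
      pts <- sort(sample(lo:hi, n))
      if (n == 1L || min(diff(pts)) >= min_separation) break
    }
    spec <- region_spec
    spec$backbone_pos <- pts                       # insert after this base
    spec <- spec[order(-spec$backbone_pos), ]      # proximal (3') first
    spec$region <- .roman(seq_len(n))
    spec$seq <- vapply(spec$length, .random_dna, character(1))
    build <- function(carrier_id) {
      s <- backbone
      rows <- spec[spec$carrier == carrier_id, , drop = FALSE]
      rows <- rows[order(-rows$backbone_pos), , drop = FALSE]
      for (i in seq_len(nrow(rows))) {
        p <- rows$backbone_pos[i]
        s <- paste0(substr(s, 1L, p), rows$seq[i],
                    substr(s, p + 1L, nchar(s)))
      }
      s
    }
    seq_a <- build("A"); seq_y <- build("Y")
    # carrier-sequence coordinates: account for same-carrier insertions
    # that lie 5' of each region
    spec$start <- NA_integer_
    for (i in seq_len(n)) {
      shift <- sum(spec$length[spec$carrier == spec$carrier[i] &
                                 spec$backbone_pos < spec$backbone_pos[i]])
      spec$start[i] <- spec$backbone_pos[i] + shift + 1L
    }
    spec$end <- spec$start + spec$length - 1L
    truth <- as_tibble(spec[, c("region", "carrier", "backbone_pos",
                                "start", "end", "length")])
    list(
      seq_a = c(A = seq_a), seq_y = c(Y = seq_y),
      region_seqs = setNames(spec$seq, spec$region),
      truth = truth
    )
  })
}

#' Plant exact motif instances into a sequence
#'
#' Overwrites `n` non-overlapping windows with the site (or its reverse
#' complement on the minus strand) at recorded positions.
#'
#' @param seq Host DNA string.
#' @param site Motif site sequence to plant.
#' @param n Number of instances.
#' @param seed Integer seed.
#' @param both_strands Sample the strand of each instance?
#' @return A list with `seq` (modified string) and `truth`: tibble with
#'   `start`, `end`, `strand`, `site`.
#' @export
plant_motif_instances <- function(seq, site, n, seed = 1L, both_strands = TRUE) {
  seq <- .check_dna(seq)
  site <- .check_dna(site, "site")
  n <- as.integer(n)
  w <- nchar(site)
  if (n == 0L) {
    return(list(seq = seq, truth = tibble(
      start = integer(), end = integer(), strand = character(), site = character()
    )))
  }
  if (w > nchar(seq)) rlang::abort("site longer than sequence")
  .with_op_seed(seed, "plant_motif_instances", {
    ok <- FALSE
    for (try in 1:200) {
      starts <- sort(sample(seq_len(nchar(seq) - w + 1L), n))
      if (n == 1L || min(diff(starts)) >= w) { ok <- TRUE; break }
    }
    if (!ok) rlang::abort("could not place motif instances without overlap")
    strands <- if (both_strands) sample(c("+", "-"), n, replace = TRUE)
    else rep("+", n)
    chars <- .chars(seq)
    for (i in seq_len(n)) {
      ins <- if (strands[i] == "+") site else reverse_complement(site)
      chars[starts[i]:(starts[i] + w - 1L)] <- .chars(ins)
    }
    list(
      seq = .collapse(chars),
      truth = tibble(start = starts, end = starts + w - 1L,
                     strand = strands, site = site)
    )
  })
}

#' Default five-taxon species history for duplication/insertion scenarios
#'
#' A fish-like history: a distant outgroup calibrating the root at 95 MY,
#' an early-diverging congener at 20 MY, and a three-species crown clade
#' (splits at 5 and 4 MY). A gene duplication on the stem of the crown
#' clade creates a Y-linked paralog lineage.
#'
#' @return A named list of node ages (MY).
#' @export
scenario_species_ages <- function() {
  list(root = 95, ingroup_split = 20, crown = 5, crown2 = 4)
}

#' Simulate a gene-duplication + element-insertion scenario
#'
#' Evolves codon-structured sequences (first and second codon positions
#' frozen, third positions neutral) along a gene tree at a strict clock:
#' the species history of [scenario_species_ages()] plus a paralog lineage
#' branching at `duplication_age` from the stem of the crown clade. An
#' element consensus is instantiated on the paralog lineage at
#' `insertion_age` and evolves at `rate` thereafter, so its expected
#' divergence from the consensus is `insertion_age * rate`.
#'
#' Tips: `outgroup`, `congener`, `sp1_a`, `sp2_a`, `sp3_a` (autosomal
#' paralogs) and `sp1_y` (the duplicated, element-carrying paralog).
#'
#' @param seed Integer seed.
#' @param n_codons Number of codons in the coding alignment.
#' @param rate Substitution rate at third positions, substitutions/site/MY.
#' @param duplication_age,insertion_age Ages in MY (insertion on the
#'   paralog lineage, so `insertion_age <= duplication_age` is required).
#' @param element_len,tir_len,tsd_len Element geometry; the consensus is
#'   built as TIR + random interior + reverse-complemented TIR.
#' @param kappa ts:tv rate ratio.
#' @param ages Node ages of the species history (see
#'   [scenario_species_ages()]).
#' @return A list with `alignment` (named character vector, codon
#'   structured), `element_consensus`, `element_copy` (the promoter copy,
#'   evolved for `insertion_age` MY), `tir_seq`, and `truth` (configured
#'   ages, rate, true element divergence `d_elem_true`).
#' @export
simulate_duplication_scenario <- function(seed = 1L, n_codons = 1000L,
                                          rate = 0.004,
                                          duplication_age = 10,
                                          insertion_age = 8,
                                          element_len = 1316L,
                                          tir_len = 27L, tsd_len = 8L,
                                          kappa = 2,
                                          ages = scenario_species_ages()) {
  stopifnot(rate > 0, duplication_age > 0)
  if (insertion_age > duplication_age) {
    rlang::abort("`insertion_age` must not exceed `duplication_age` (the paralog lineage begins at the duplication)")
  }
  stopifnot(duplication_age < ages$ingroup_split, ages$crown < duplication_age)
  .with_op_seed(seed, "simulate_duplication_scenario", {
    third_root <- .random_dna(n_codons)
    evolve_my <- function(s, dt) evolve_sequence_k2p(s, dt * rate, kappa, seed = NULL)
    # gene tree (ages in MY):
    # root 95: outgroup | ingroup
    # ingroup_split 20: congener | stem
    # duplication 10 (on the stem): crown ancestor (a) | y lineage
    # crown 5: sp1_a | (sp2_a, sp3_a); crown2 4: sp2_a | sp3_a
    n_root <- third_root
    outgroup <- evolve_my(n_root, ages$root)
    ingroup <- evolve_my(n_root, ages$root - ages$ingroup_split)
    congener <- evolve_my(ingroup, ages$ingroup_split)
    stem <- evolve_my(ingroup, ages$ingroup_split - duplication_age)
    y_tip <- evolve_my(stem, duplication_age)
    crown_anc <- evolve_my(stem, duplication_age - ages$crown)
    sp1_a <- evolve_my(crown_anc, ages$crown)
    crown2_anc <- evolve_my(crown_anc, ages$crown - ages$crown2)
    sp2_a <- evolve_my(crown2_anc, ages$crown2)
    sp3_a <- evolve_my(crown2_anc, ages$crown2)
    thirds <- c(outgroup = outgroup, congener = congener,
                sp1_a = sp1_a, sp2_a = sp2_a, sp3_a = sp3_a, sp1_y = y_tip)
    # codon scaffold: frozen first/second positions shared by all tips
    pos12 <- .random_dna(2L * n_codons)
    p1 <- .chars(pos12)[seq(1L, 2L * n_codons, 2L)]
    p2 <- .chars(pos12)[seq(2L, 2L * n_codons, 2L)]
    weave <- function(third) {
      m <- rbind(p1, p2, .chars(third))
      .collapse(as.vector(m))
    }
    alignment <- vapply(thirds, weave, character(1))
    # element: consensus instantiated on the y lineage at insertion_age
    interior <- .random_dna(element_len - 2L * tir_len)
    tir <- .random_dna(tir_len)
    # screen the interior so the inverted repeat cannot extend inward
    last <- substr(interior, nchar(interior), nchar(interior))
    if (substr(interior, 1L, 1L) == reverse_complement(last)) {
      substr(interior, 1L, 1L) <- sample(
        setdiff(.DNA_BASES, reverse_complement(last)), 1L
      )
    }
    consensus <- paste0(tir, interior, reverse_complement(tir))
    element_copy <- evolve_my(consensus, insertion_age)
    list(
      alignment = alignment,
      element_consensus = consensus,
      element_copy = element_copy,
      tir_seq = tir,
      tsd_len = tsd_len,
      truth = list(
        ages = ages, duplication_age = duplication_age,
        insertion_age = insertion_age, rate = rate, kappa = kappa,
        n_codons = n_codons, d_elem_true = insertion_age * rate,
        seed = seed
      )
    )
  })
}
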