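test_that("evolve_sequence_k2p is identity at d = 0 and reproducible by seed", {
  set.seed(801)
  x <- rnd_dna(500)
  expect_identical(evolve_sequence_k2p(x, 0), x)
  a <- evolve_sequence_k2p(x, 0.05, seed = 9)
  b <- evolve_sequence_k2p(x, 0.05, seed = 9)
  c <- evolve_sequence_k2p(x, 0.05, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_error(evolve_sequence_k2p(x, 1.5), "saturation")
})

test_that("the K2P estimator is consistent for the simulated distance", {
  set.seed(802)
  x <- rnd_dna(100000)
  y <- evolve_sequence_k2p(x, 0.034, seed = 5)
  est <- k2p_distance(count_substitutions(x, y))
  expect_lt(abs(est$d - 0.034), 3 * est$se)
  # transition/transversion ratio near the configured 2:1
  expect_lt(abs(est$P / est$Q - 2), 0.4)
})

test_that("planted element copies round-trip TSD detection and copy counting", {
  set.seed(803)
  el <- rnd_dna(400)
  for (s in 1:3) {
    pl <- plant_element_copies(rnd_dna(6000), el, 3, copy_divergence = 0,
                               tsd_len = 8, seed = s)
    expect_identical(nrow(pl$truth), 3L)
    for (i in 1:3) {
      expect_identical(substr(pl$genome, pl$truth$start[i], pl$truth$end[i]), el)
      tsd <- find_tsd(pl$genome, pl$truth$start[i], pl$truth$end[i])
      expect_identical(tsd$length, 8L)
      expect_identical(tsd$seq, pl$truth$tsd_seq[i])
    }
    expect_identical(count_copies(c(el = el), c(g = pl$genome))$n, 3L)
  }
  # n = 0 leaves the backbone untouched
  bb <- rnd_dna(1000)
  expect_identical(plant_element_copies(bb, el, 0)$genome, bb)
  expect_error(plant_element_copies(rnd_dna(100), el, 5, seed = 1), "too short")
})

test_that("generated promoter pairs are recovered region-for-region at zero divergence", {
  spec <- tibble::tibble(carrier = c("Y", "A", "Y"), length = c(450L, 300L, 600L))
  for (s in 1:3) {
    pp <- generate_promoter_pair(backbone_len = 2500, region_spec = spec, seed = s)
    reg <- segment_length_divergent_regions(
      align_promoters(pp$seq_a, pp$seq_y), min_region_len = 200
    )
    expect_identical(nrow(reg), 3L)
    expect_identical(reg$region, pp$truth$region)
    expect_identical(reg$carrier, pp$truth$carrier)
    expect_identical(reg$length, pp$truth$length)
  }
})

test_that("an empty region spec yields an identical promoter pair", {
  pp <- generate_promoter_pair(backbone_len = 800,
                               region_spec = tibble::tibble(carrier = character(),
                                                            length = integer()),
                               seed = 4)
  expect_identical(unname(pp$seq_a), unname(pp$seq_y))
  expect_identical(nrow(pp$truth), 0L)
})

test_that("generators are byte-reproducible for a fixed seed", {
  p1 <- generate_promoter_pair(backbone_len = 1200,
                               region_spec = tibble::tibble(carrier = "Y",
                                                            length = 300L),
                               seed = 11)
  p2 <- generate_promoter_pair(backbone_len = 1200,
                               region_spec = tibble::tibble(carrier = "Y",
                                                            length = 300L),
                               seed = 11)
  expect_identical(p1, p2)
  s1 <- simulate_duplication_scenario(seed = 3, n_codons = 100)
  s2 <- simulate_duplication_scenario(seed = 3, n_codons = 100)
  expect_identical(s1, s2)
})

test_that("planted motif instances are found exactly where recorded, on both strands", {
  set.seed(804)
  pwm <- read_jaspar(system.file("extdata", "dmrt_like_synthetic.jaspar",
                                 package = "tecoopt"))
  site <- pwm_consensus(pwm)
  pm <- plant_motif_instances(rnd_dna(4000), site, 4, seed = 6)
  hits <- scan_sequence(pm$seq, pwm, min_score = pwm_max_score(pwm) - 1e-6)
  expect_identical(hits$start, pm$truth$start)
  expect_identical(hits$strand, pm$truth$strand)
  expect_true(any(pm$truth$strand == "-") || any(pm$truth$strand == "+"))
  # n = 0 leaves the sequence unchanged
  x <- rnd_dna(100)
  expect_identical(plant_motif_instances(x, site, 0)$seq, x)
})

test_that("the duplication scenario instantiates its configured history", {
  sc <- simulate_duplication_scenario(seed = 5, n_codons = 200)
  expect_identical(sort(names(sc$alignment)),
                   sort(c("outgroup", "congener", "sp1_a", "sp2_a", "sp3_a", "sp1_y")))
  expect_identical(unique(nchar(sc$alignment)), 600L)
  expect_identical(nchar(sc$element_consensus), 1316L)
  # TIR structure survives into the consensus
  expect_identical(find_tirs(sc$element_consensus, min_len = 20, max_len = 30)$length, 27L)
  # insertion at age 0: element equals its consensus
  sc0 <- simulate_duplication_scenario(seed = 5, n_codons = 100, insertion_age = 0)
  expect_identical(sc0$element_copy, sc0$element_consensus)
  # first and second codon positions are frozen across tips
  drop_thirds <- function(s) {
    v <- chars1(s)
    paste(v[-seq(3, length(v), by = 3)], collapse = "")
  }
  expect_identical(drop_thirds(sc$alignment[["outgroup"]]),
                   drop_thirds(sc$alignment[["sp1_y"]]))
  expect_error(simulate_duplication_scenario(seed = 1, insertion_age = 12),
               "insertion_age")
})

test_that("scenario element divergence matches insertion_age x rate in expectation", {
  ds <- vapply(1:6, function(s) {
    sc <- simulate_duplication_scenario(seed = 300 + s, n_codons = 50)
    k2p_distance(count_substitutions(sc$element_copy, sc$element_consensus))$d
  }, numeric(1))
  pq <- tecoopt:::.k2p_pq(0.032, 2)
  se1 <- k2p_distance(list(P = pq$P, Q = pq$Q, L = 1316))$se
  expect_lt(abs(mean(ds) - 0.032), 3 * se1 / sqrt(6))
})
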