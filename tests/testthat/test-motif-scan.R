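test_that("pwm_from_counts produces the documented natural-log log-odds", {
  # uniform counts on uniform background: all log-odds zero
  u <- pwm_from_counts(matrix(1, 4, 3))
  expect_equal(max(abs(u$log_odds)), 0, tolerance = 1e-12)
  # one column (A:3, C:1, G:0, T:0) with 0.25 pseudocount per base:
  # p_A = 3.25 / 5, log-odds_A = log(0.65 / 0.25) = log(2.6)
  p <- pwm_from_counts(matrix(c(3, 1, 0, 0), 4, 1), pseudocount = 1)
  expect_equal(unname(p$log_odds["A", 1]), log(2.6), tolerance = 1e-12)
  expect_equal(sum(p$probs[, 1]), 1, tolerance = 1e-12)
  # scaling counts with pseudocount proportional to the column total
  # leaves log-odds unchanged (column totals large enough that the 0.5
  # pseudocount floor does not bind)
  cm <- 50 * matrix(c(8, 3, 1, 0, 5, 5, 1, 1), 4, 2)
  a <- pwm_from_counts(cm, pseudocount = NULL)
  b <- pwm_from_counts(10 * cm, pseudocount = NULL)
  expect_equal(a$log_odds, b$log_odds, tolerance = 1e-12)
  expect_error(pwm_from_counts(matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 4, 2)),
               "positive count")
})

test_that("a width-1 A-favoring PWM hits every A (and every T on the minus strand)", {
  p <- pwm_from_counts(matrix(c(20, 0, 0, 0), 4, 1), pseudocount = 0.1)
  s <- "AATCGA"
  hits <- scan_sequence(s, p, min_score = 1)
  plus <- hits[hits$strand == "+", ]
  minus <- hits[hits$strand == "-", ]
  expect_identical(plus$start, c(1L, 2L, 6L))
  expect_identical(minus$start, c(3L))   # the single T, at position 3
  expect_true(all(hits$site == "A"))
})

test_that("a planted consensus site is the unique hit at the consensus-score threshold", {
  set.seed(501)
  pwm <- read_jaspar(system.file("extdata", "dmrt_like_synthetic.jaspar",
                                 package = "tecoopt"))
  expect_identical(pwm_consensus(pwm), "CTGCAACAATGCATT")
  s <- rnd_dna(2000)
  pm <- plant_motif_instances(s, "CTGCAACAATGCATT", 1, seed = 31, both_strands = FALSE)
  hits <- scan_sequence(pm$seq, pwm, min_score = pwm_max_score(pwm) - 1e-6)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, pm$truth$start)
  expect_identical(hits$site, "CTGCAACAATGCATT")
  expect_equal(hits$ln_p, log(hits$p_value), tolerance = 1e-12)
})

test_that("scanning is strand-symmetric under reverse complement", {
  set.seed(502)
  pwm <- read_jaspar(system.file("extdata", "dmrt_like_synthetic.jaspar",
                                 package = "tecoopt"))
  s <- plant_motif_instances(rnd_dna(1500), "CTGCAACAATGCATT", 2, seed = 7)$seq
  n <- nchar(s)
  fwd <- scan_sequence(s, pwm, min_score = 8)
  rev <- scan_sequence(reverse_complement(s), pwm, min_score = 8)
  # map reverse-scan hits back to forward coordinates
  mapped <- tibble::tibble(
    start = n - rev$end + 1L,
    strand = ifelse(rev$strand == "+", "-", "+"),
    score = rev$score
  )
  mapped <- mapped[order(mapped$start, mapped$strand), ]
  fwd2 <- fwd[order(fwd$start, fwd$strand), c("start", "strand", "score")]
  expect_equal(as.data.frame(mapped), as.data.frame(fwd2), tolerance = 1e-9)
})

test_that("windows containing N are skipped", {
  p <- pwm_from_counts(matrix(c(5, 1, 1, 1), 4, 1), pseudocount = 0.5)
  hits <- scan_sequence("ANA", p, min_score = -10, both_strands = FALSE)
  expect_identical(hits$start, c(1L, 3L))
})

test_that("score_pvalue matches exhaustive enumeration and is a proper tail", {
  set.seed(503)
  for (w in 2:4) {
    cm <- matrix(sample(0:9, 4 * w, replace = TRUE) + 0.5, 4, w)
    pwm <- pwm_from_counts(cm, pseudocount = 1)
    words <- enumerate_pwm_words(pwm)
    qs <- sort(unique(words$score))
    # query midway between adjacent achievable scores: no boundary ambiguity
    mids <- (qs[-1] + qs[-length(qs)]) / 2
    mids <- mids[diff(qs) > 1e-3]
    for (t in c(mids, min(qs) - 1, max(qs) + 1)) {
      expect_equal(score_pvalue(pwm, t, grid = 1e-5),
                   sum(words$prob[words$score >= t]),
                   tolerance = 1e-9)
    }
  }
})

test_that("score_pvalue is monotone non-increasing with correct extremes", {
  set.seed(504)
  cm <- matrix(sample(1:20, 20, replace = TRUE), 4, 5)
  pwm <- pwm_from_counts(cm)
  scores <- seq(sum(apply(pwm$log_odds, 2, min)) - 0.5,
                pwm_max_score(pwm) + 0.5, length.out = 60)
  ps <- score_pvalue(pwm, scores)
  expect_true(all(diff(ps) <= 1e-12))
  expect_identical(ps[1], 1)
  expect_identical(ps[length(ps)], 0)
})

test_that("non-uniform backgrounds weight the score distribution correctly", {
  set.seed(505)
  bg <- c(0.4, 0.1, 0.1, 0.4)
  cm <- matrix(sample(1:9, 12, replace = TRUE), 4, 3)
  pwm <- pwm_from_counts(cm, pseudocount = 1, background = bg)
  words <- enumerate_pwm_words(pwm)
  expect_equal(sum(words$prob), 1, tolerance = 1e-12)
  qs <- sort(unique(words$score))
  mids <- (qs[-1] + qs[-length(qs)]) / 2
  mids <- mids[diff(qs) > 1e-3][1:5]
  for (t in mids) {
    expect_equal(score_pvalue(pwm, t, grid = 1e-5),
                 sum(words$prob[words$score >= t]), tolerance = 1e-9)
  }
})

test_that("expected_hit_count follows E = windows x p x strands and scales linearly", {
  p1 <- pwm_from_counts(matrix(c(2, 1, 1, 1), 4, 3), pseudocount = 1)
  wmin <- sum(apply(p1$log_odds, 2, min))
  # threshold at the minimum: p = 1, single strand
  expect_equal(expected_hit_count(p1, wmin - 1, 100, both_strands = FALSE),
               100 - 3 + 1, tolerance = 1e-12)
  # E = 2300 windows x 1e-4 x 2 strands = 0.46
  pwm <- read_jaspar(system.file("extdata", "dmrt_like_synthetic.jaspar",
                                 package = "tecoopt"))
  t_star <- stats::uniroot(function(s) score_pvalue(pwm, s) - 1e-4,
                           c(0, pwm_max_score(pwm)), tol = 1e-10)$root
  p_at <- score_pvalue(pwm, t_star)
  E <- expected_hit_count(pwm, t_star, 2300 + pwm$width - 1, both_strands = TRUE)
  expect_equal(E, 2300 * p_at * 2, tolerance = 1e-12)
  # linear in sequence length
  E2 <- expected_hit_count(pwm, t_star, 2 * (2300 + pwm$width - 1) - (pwm$width - 1))
  expect_equal(E2, 2 * E, tolerance = 1e-9)
})

test_that("enrichment_ratio reproduces the observed/expected fold change", {
  expect_equal(round(enrichment_ratio(7, 0.46)), 15)
  expect_identical(enrichment_ratio(3, 3), 1)
  expect_identical(enrichment_ratio(0, 0.46), 0)
  expect_error(enrichment_ratio(7, 0), "expected")
})

test_that("MEME minimal motifs parse to the same PWM as their JASPAR counts", {
  tf <- withr::local_tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "MOTIF toy", "letter-probability matrix: alength= 4 w= 2 nsites= 10 E= 0",
    " 0.5 0.2 0.2 0.1", " 0.1 0.1 0.2 0.6"
  ), tf)
  pwm <- read_meme(tf, pseudocount = 1)
  counts <- matrix(c(5, 2, 2, 1, 1, 1, 2, 6), 4, 2)
  ref <- pwm_from_counts(counts, pseudocount = 1)
  expect_equal(pwm$log_odds, ref$log_odds, tolerance = 1e-9)
})
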