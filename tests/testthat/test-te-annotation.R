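REPEAT_TIR <- "CAATGAGTTATATCACTAGAGGAGACA" # 27 bp
REPEAT_TSD <- "GTGTGGCT"                    # 8 bp

test_that("find_tirs recovers the 27-bp terminal inverted repeat of the planted element", {
  set.seed(201)
  el <- make_tir_element(REPEAT_TIR, 500)
  tir <- find_tirs(el, max_mismatch = 0)
  expect_identical(tir$length, 27L)
  expect_identical(tir$mismatches, 0L)
  expect_identical(tir$tir_seq, REPEAT_TIR)
  expect_identical(tir$right_start, nchar(el) - 26L)
})

test_that("find_tirs finds nothing in uniform-random sequence (brute-force confirmed)", {
  set.seed(1)
  x <- rnd_dna(1000)
  expect_identical(nrow(find_tirs(x, min_len = 10, max_mismatch = 0)), 0L)
  # brute-force check over every terminal window length
  any_tir <- any(vapply(10:100, function(len) {
    substr(x, 1, len) == revcomp_naive(substr(x, 1001 - len, 1000))
  }, logical(1)))
  expect_false(any_tir)
})

test_that("find_tirs returns the longest qualifying terminal pair (exhaustive oracle)", {
  el <- paste0("ACGTAC", "AAAA", revcomp_naive("ACGTAC"))
  got <- find_tirs(el, min_len = 4)
  # exhaustive comparison over all prefix/suffix lengths
  lens <- 4:(nchar(el) %/% 2)
  ok <- lens[vapply(lens, function(len) {
    substr(el, 1, len) == revcomp_naive(substr(el, nchar(el) - len + 1, nchar(el)))
  }, logical(1))]
  expect_identical(got$length, max(ok))
  expect_identical(got$length, 6L)
  expect_error(find_tirs(el, min_len = 10, max_len = 5), "min_len")
})

test_that("find_tirs tolerates the allowed number of mismatches", {
  set.seed(202)
  el <- make_tir_element(REPEAT_TIR, 300)
  # break one base of the right TIR
  n <- nchar(el)
  broken <- el
  substr(broken, n - 5, n - 5) <- setdiff(c("A", "C", "G", "T"),
                                          substr(el, n - 5, n - 5))[1]
  expect_identical(nrow(find_tirs(broken, max_mismatch = 0)), 0L)
  expect_identical(find_tirs(broken, max_mismatch = 1)$length, 27L)
})

test_that("find_tsd detects the planted 8-bp duplication and enumerated shorter ones", {
  set.seed(203)
  el <- rnd_dna(400)
  planted <- make_tsd_host(el, REPEAT_TSD)
  tsd <- find_tsd(planted$host, planted$start, planted$end)
  expect_identical(tsd$seq, REPEAT_TSD)
  expect_identical(tsd$length, 8L)
  expect_identical(substr(planted$host, tsd$left_start, tsd$left_end), REPEAT_TSD)

  # flanks sharing exactly ACGT: every k enumerated by hand
  host2 <- paste0(rnd_dna(30), "TTACGT", el, "ACGTGG", rnd_dna(30))
  got <- find_tsd(host2, 37, 36 + nchar(el), min_len = 2, max_len = 6)
  expect_identical(got$length, 4L)
  expect_identical(got$seq, "ACGT")

  # no shared flank at all
  host3 <- paste0(strrep("C", 30), el, strrep("G", 30))
  expect_identical(nrow(find_tsd(host3, 31, 30 + nchar(el))), 0L)

  expect_error(find_tsd(planted$host, 5, planted$end), "flank")
})

test_that("build_consensus applies the 50% majority rule with IUPAC ties and gap drops", {
  cm <- build_consensus(c("A", "A", "C"), 0.5)
  expect_identical(cm$consensus, "A")
  cm2 <- build_consensus(c("ACGT", "ACGT", "ACGT"), 0.5)
  expect_identical(cm2$consensus, "ACGT")
  cm3 <- build_consensus(c("A", "C", "A", "C"), 0.5)
  expect_identical(cm3$consensus, "M")
  # gap fraction >= threshold drops the column
  cm4 <- build_consensus(c("A-T", "A-T", "AGT", "A-T"), 0.5)
  expect_identical(cm4$consensus, "AT")
  expect_identical(cm4$kept_columns, c(1L, 3L))
  # no base reaches threshold: IUPAC code over all bases present
  cm5 <- build_consensus(c("A", "C", "G", "T", "T"), 0.5)
  expect_identical(cm5$consensus, "N")
  expect_error(build_consensus(c("ACG", "AC")), "same")
  expect_error(build_consensus("ACG"), "at least two")
})

test_that("consensus of copies generated at vanishing divergence returns the source", {
  set.seed(204)
  src <- rnd_dna(200)
  copies <- vapply(1:6, function(i) evolve_sequence_k2p(src, 0), character(1))
  expect_identical(build_consensus(copies, 0.5)$consensus, src)
})

test_that("longest_orf matches manual translation and a brute-force 6-frame oracle", {
  expect_identical(longest_orf("ATGAAATAA"), 2L)
  expect_identical(longest_orf("CCCCCC"), 0L)
  expect_identical(longest_orf("ATGAAA"), 0L) # no stop, no complete ORF
  set.seed(2)
  for (i in 1:8) {
    x <- rnd_dna(300)
    expect_identical(longest_orf(x), longest_orf_oracle(x))
  }
})

test_that("classify_element follows the decision table", {
  expect_identical(classify_element(TRUE, TRUE, 40), "nonautonomous_class_II")
  expect_identical(classify_element(TRUE, TRUE, 150), "class_II_autonomous")
  expect_identical(
    classify_element(FALSE, FALSE, 10,
                     element = paste0(rnd_dna(50), strrep("A", 12))),
    "class_I_like"
  )
  expect_identical(classify_element(FALSE, FALSE, 10, element = rnd_dna(50)),
                   "unclassified")
  expect_identical(classify_element(TRUE, FALSE, 10, element = rnd_dna(50)),
                   "unclassified")
})

test_that("annotate_element composes features into a non-autonomous class II call", {
  set.seed(205)
  el <- make_tir_element(REPEAT_TIR, 400)
  planted <- make_tsd_host(el, REPEAT_TSD)
  ann <- annotate_element(el, host = planted$host,
                          element_start = planted$start,
                          element_end = planted$end)
  td <- tidy(ann)
  expect_identical(td$classification, "nonautonomous_class_II")
  expect_identical(td$tir_length, 27L)
  expect_identical(td$tsd_length, 8L)
  expect_true(td$terminal_motif_match) # CAATG matches YARNG
  expect_lt(td$longest_orf_codons, 100L)

  # planting a long ORF flips the call to autonomous
  orf <- paste0("ATG", strrep("GCA", 150), "TAA")
  el2 <- paste0(REPEAT_TIR, orf, rnd_dna(50), revcomp_naive(REPEAT_TIR))
  planted2 <- make_tsd_host(el2, REPEAT_TSD)
  ann2 <- annotate_element(el2, host = planted2$host,
                           element_start = planted2$start,
                           element_end = planted2$end)
  # at least the planted 151 codons (a gap-free shifted frame through the
  # GCA repeat can legitimately be longer)
  expect_gte(ann2$longest_orf_codons, 151L)
  expect_identical(ann2$classification, "class_II_autonomous")
})

test_that("reconstruct_split_element joins fragments of the published lengths", {
  set.seed(206)
  host <- rnd_dna(3000)
  # fragments of 440 and 876 bp flank a nested 1024-bp insertion
  r <- reconstruct_split_element(host, 101, 540, 1565, 2440)
  expect_identical(r$length, 1316L)
  expect_identical(r$seq, paste0(substr(host, 101, 540), substr(host, 1565, 2440)))
  # zero-length inner insertion: concatenation equals the contiguous slice
  r2 <- reconstruct_split_element(host, 101, 540, 541, 900)
  expect_identical(r2$seq, substr(host, 101, 900))
  expect_error(reconstruct_split_element(host, 101, 540, 400, 900), "overlap")
})

test_that("a split element round-trips through reconstruction exactly", {
  set.seed(3)
  el <- make_tir_element(REPEAT_TIR, 600)
  cut <- 440L
  inner <- rnd_dna(1024)
  host <- paste0(rnd_dna(150), substr(el, 1, cut), inner,
                 substr(el, cut + 1, nchar(el)), rnd_dna(150))
  r <- reconstruct_split_element(host, 151, 150 + cut,
                                 150 + cut + 1024 + 1, 150 + 1024 + nchar(el))
  expect_identical(r$seq, el)
})

test_that("planted elements round-trip TIR and TSD detection exactly over seeds", {
  for (s in 1:6) {
    set.seed(300 + s)
    tir_len <- sample(12:30, 1)
    tsd_len <- sample(3:12, 1)
    tir <- rnd_dna(tir_len)
    el <- make_tir_element(tir, 200)
    planted <- make_tsd_host(el, rnd_dna(tsd_len))
    got_tir <- find_tirs(el, min_len = 10, max_len = 40, max_mismatch = 0)
    expect_gte(got_tir$length, tir_len) # interior screening forbids +1 extension
    expect_identical(got_tir$length, tir_len)
    expect_identical(find_tsd(planted$host, planted$start, planted$end)$length,
                     tsd_len)
  }
})
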