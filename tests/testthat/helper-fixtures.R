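# Builds a complete on-disk toy dataset for the end-to-end pipeline: a
# simulated duplication/insertion scenario, a promoter pair whose Y copy
# carries the element (with TSD and a planted binding site), and a genome
# with extra diverged element copies.
build_toy_pipeline <- function(dir, seed = 7) {
  set.seed(seed * 17)
  sc <- simulate_duplication_scenario(seed = seed, n_codons = 600)
  pp <- generate_promoter_pair(
    backbone_len = 2500,
    region_spec = tibble::tibble(carrier = c("Y", "Y", "A"),
                                 length = c(700L, 350L, 450L)),
    seed = seed
  )
  site <- "CTGCAACAATGCATT"
  elp <- plant_motif_instances(sc$element_copy, site, 1, seed = seed,
                               both_strands = FALSE)
  el <- elp$seq
  tsd <- "GTGTGGCT"
  # insert the element near the promoter start: planted indel regions sit at
  # backbone positions >= 300, so the element region cannot merge with them
  insert_at <- 200L
  promY <- unname(pp$seq_y)
  promY <- paste0(substr(promY, 1, insert_at), tsd, el, tsd,
                  substr(promY, insert_at + 1, nchar(promY)))
  el_start <- insert_at + nchar(tsd) + 1L
  el_end <- el_start + nchar(el) - 1L
  pl <- plant_element_copies(rnd_dna(9000), sc$element_consensus, 3,
                             copy_divergence = 0.03, seed = seed + 100)
  write_fasta(tibble::tibble(id = "promA", seq = unname(pp$seq_a)),
              file.path(dir, "promA.fa"))
  write_fasta(tibble::tibble(id = "promY", seq = promY),
              file.path(dir, "promY.fa"))
  write_fasta(tibble::tibble(id = c("chrY", "chrA", "chr1"),
                             seq = c(promY, unname(pp$seq_a), pl$genome)),
              file.path(dir, "genome.fa"))
  write_fasta(tibble::tibble(id = "element", seq = el),
              file.path(dir, "element.fa"))
  write_fasta(tibble::tibble(id = "consensus", seq = sc$element_consensus),
              file.path(dir, "consensus.fa"))
  write_fasta(tibble::tibble(id = names(sc$alignment),
                             seq = unname(sc$alignment)),
              file.path(dir, "coding.fa"))
  file.copy(system.file("extdata", "dmrt_like_synthetic.jaspar",
                        package = "tecoopt"),
            file.path(dir, "pwm.jaspar"))
  pipeline_config(
    promoter_a = file.path(dir, "promA.fa"),
    promoter_y = file.path(dir, "promY.fa"),
    genome = file.path(dir, "genome.fa"),
    pwm = file.path(dir, "pwm.jaspar"),
    coding_alignment = file.path(dir, "coding.fa"),
    element = file.path(dir, "element.fa"),
    element_consensus = file.path(dir, "consensus.fa"),
    element_start = el_start, element_end = el_end,
    outgroup = "outgroup",
    calibration_tips = c("outgroup", "sp1_a"), calibration_age = 95,
    reference_tips = c("sp1_y", "sp1_a"), host_tip = "sp1_y",
    tir_max_mismatch = 3L, min_score = 12, seed = seed
  )
}
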