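# End-to-end orchestration: annotate element -> count genomic copies ->
# scan promoters for binding sites -> compare promoters -> date the
# insertion against the gene duplication. Produces a machine-readable
# report whose summary fields are copied from the stage tables.

#' Assemble a pipeline configuration
#'
#' All inputs are file paths; `validate_config()` is run on construction.
#' A configuration can also be read from a YAML file with
#' [read_pipeline_config()].
#'
#' @param promoter_a,promoter_y FASTA paths of the two paralogous promoters.
#' @param genome FASTA path of the genome to search (should include the
#'   promoter locus).
#' @param pwm Path to a JASPAR-style count matrix.
#' @param coding_alignment Gapped FASTA path of the coding gene alignment
#'   used for dating.
#' @param element FASTA path of the candidate element; the first record is
#'   annotated and dated.
#' @param element_consensus FASTA path of the element family consensus.
#' @param host_promoter Which promoter carries the element: `"Y"` or `"A"`.
#' @param element_start,element_end Element interval on the host promoter
#'   (1-based closed), used for TSD detection; `NULL` skips it.
#' @param outgroup Tip label used to root the gene tree.
#' @param calibration_tips,calibration_age Calibration node (MRCA of the
#'   tips) and its age in MY.
#' @param reference_tips Tips whose MRCA is the reference (duplication)
#'   node for the dating verdict.
#' @param host_tip Tip label of the element-carrying lineage.
#' @param tir_max_mismatch Substitutions tolerated between the element's
#'   two TIR copies during annotation (use a few when annotating a diverged
#'   genomic copy rather than a family consensus).
#' @param min_score PWM scan threshold (natural-log log-odds).
#' @param min_region_len,join_dist Region segmentation parameters.
#' @param search A [search_params()] object.
#' @param z Dating interval half-width in SE units.
#' @param seed Integer seed recorded in the report.
#' @param out_dir Output directory for stage tables and the JSON report
#'   (`NULL`: nothing is written).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(promoter_a, promoter_y, genome, pwm,
                            coding_alignment, element, element_consensus,
                            host_promoter = "Y",
                            element_start = NULL, element_end = NULL,
                            outgroup, calibration_tips, calibration_age,
                            reference_tips, host_tip, tir_max_mismatch = 0L,
                            min_score = 5, min_region_len = 200L,
                            join_dist = 50L, search = search_params(),
                            z = 2, seed = 1L, out_dir = NULL) {
  cfg <- structure(
    list(
      promoter_a = promoter_a, promoter_y = promoter_y, genome = genome,
      pwm = pwm, coding_alignment = coding_alignment, element = element,
      element_consensus = element_consensus, host_promoter = host_promoter,
      element_start = element_start, element_end = element_end,
      outgroup = outgroup, calibration_tips = calibration_tips,
      calibration_age = calibration_age, reference_tips = reference_tips,
      host_tip = host_tip, tir_max_mismatch = as.integer(tir_max_mismatch),
      min_score = min_score,
      min_region_len = min_region_len, join_dist = join_dist,
      search = search, z = z, seed = seed, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg A `pipeline_config`.
#' @return `cfg`, invisibly; aborts naming the offending path or field.
#' @export
validate_config <- function(cfg) {
  paths <- c("promoter_a", "promoter_y", "genome", "pwm",
             "coding_alignment", "element", "element_consensus")
  for (p in paths) {
    if (!is.character(cfg[[p]]) || !file.exists(cfg[[p]])) {
      rlang::abort(paste0("config error: input `", p, "` does not exist: ",
                          cfg[[p]]), class = "tecoopt_config_error")
    }
  }
  if (!cfg$calibration_age > 0) {
    rlang::abort("config error: `calibration_age` must be > 0",
                 class = "tecoopt_config_error")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments
#'   (the `search` key, when present, is a mapping passed to
#'   [search_params()]).
#' @param ... Overrides applied on top of the file values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$search)) vals$search <- do.call(search_params, vals$search)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: element annotation (TIR/TSD/ORF/classification),
#' genomic copy counting, PWM scan of both promoters, promoter comparison
#' with region origin calls, and insertion dating on the calibrated,
#' linearized gene tree. Deterministic given the config.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress stage messages?
#' @return An object of class `analysis_report`; see
#'   [glance.analysis_report()]. When `cfg$out_dir` is set, stage tables
#'   (TSV), a region GFF3 and a JSON report are written there.
#' @export
run_full_analysis <- function(cfg, quiet = FALSE) {
  validate_config(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))

  prom_a <- read_fasta(cfg$promoter_a)[1, ]
  prom_y <- read_fasta(cfg$promoter_y)[1, ]
  genome <- read_fasta(cfg$genome)
  element <- read_fasta(cfg$element)[1, ]
  consensus <- read_fasta(cfg$element_consensus)[1, ]
  pwm <- read_jaspar(cfg$pwm)
  aln_in <- read_fasta(cfg$coding_alignment)

  say("stage 1/5: element annotation")
  host <- if (cfg$host_promoter == "Y") prom_y else prom_a
  ann <- if (!is.null(cfg$element_start)) {
    annotate_element(element$seq, host = host$seq,
                     element_start = cfg$element_start,
                     element_end = cfg$element_end,
                     tir_max_mismatch = cfg$tir_max_mismatch)
  } else {
    annotate_element(element$seq, tir_max_mismatch = cfg$tir_max_mismatch)
  }

  say("stage 2/5: genomic copy counting")
  copies <- count_copies(setNames(element$seq, element$id), genome, cfg$search)

  say("stage 3/5: binding-site scan")
  hits_y <- scan_sequence(setNames(prom_y$seq, prom_y$id), pwm, cfg$min_score)
  hits_a <- scan_sequence(setNames(prom_a$seq, prom_a$id), pwm, cfg$min_score)
  expected <- expected_hit_count(pwm, cfg$min_score, nchar(prom_y$seq))

  say("stage 4/5: promoter comparison")
  regions <- compare_promoters(
    setNames(prom_a$seq, prom_a$id), setNames(prom_y$seq, prom_y$id),
    genome = genome, min_region_len = cfg$min_region_len,
    join_dist = cfg$join_dist, params = cfg$search
  )

  say("stage 5/5: insertion dating")
  thirds <- third_codon_positions(aln_in)
  dm <- k2p_matrix(thirds)
  tree <- nj_tree(dm)
  clock <- linearize_and_calibrate(tree, cfg$outgroup, cfg$calibration_tips,
                                   cfg$calibration_age)
  delem <- k2p_distance(count_substitutions(element$seq, consensus$seq))
  dating <- date_insertion(delem$d, delem$se, clock, cfg$host_tip,
                           cfg$reference_tips, z = cfg$z)

  summary <- tibble(
    element_classification = ann$classification,
    element_copy_count = copies$n,
    n_sites_host_promoter = nrow(hits_y),
    n_sites_other_promoter = nrow(hits_a),
    expected_sites = expected,
    n_regions = nrow(regions),
    insertion_age_point = dating$age_point,
    insertion_age_low = dating$age_low,
    insertion_age_high = dating$age_high,
    reference_age = dating$reference_age,
    verdict = dating$verdict_vs_reference
  )
  report <- structure(
    list(
      schema_version = "1.0", seed = cfg$seed,
      annotation = ann, copies = copies,
      hits_host = hits_y, hits_other = hits_a, expected_sites = expected,
      regions = regions, clock = clock, dating = dating,
      summary = summary,
      config_echo = .config_echo(cfg)
    ),
    class = "analysis_report"
  )
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

.config_echo <- function(cfg) {
  vals <- unclass(cfg)
  vals$search <- unclass(vals$search)
  vals[!vapply(vals, is.null, logical(1))]
}

#' Write an analysis report to disk
#'
#' Stage tables as TSV, regions additionally as GFF3, and the full summary
#' (plus effective configuration, for provenance) as JSON. The JSON is
#' byte-stable for a fixed config.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    as.data.frame(x), file.path(dir, f), sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  wt(tidy(report$annotation), "element_annotation.tsv")
  wt(report$copies$hits, "element_copies.tsv")
  wt(report$hits_host, "sites_host_promoter.tsv")
  wt(report$hits_other, "sites_other_promoter.tsv")
  regions <- report$regions
  wt(regions, "regions.tsv")
  if (nrow(regions) > 0L) {
    write_gff3(tibble(
      seqid = regions$carrier, type = "indel_region",
      start = regions$start, end = regions$end,
      attributes = paste0("ID=region_", regions$region,
                          if ("call" %in% names(regions)) paste0(";call=", regions$call) else "")
    ), file.path(dir, "regions.gff3"))
  }
  wt(tidy(report$clock), "node_ages.tsv")
  wt(glance(report$dating), "insertion_dating.tsv")
  json <- list(
    schema_version = report$schema_version,
    seed = report$seed,
    summary = as.list(report$summary),
    config = report$config_echo
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  s <- x$summary
  cat("<analysis_report>\n")
  cat(sprintf("  element: %s, %d genomic copies\n",
              s$element_classification, s$element_copy_count))
  cat(sprintf("  binding sites: %d on host promoter (%.2f expected), %d on paralog\n",
              s$n_sites_host_promoter, s$expected_sites, s$n_sites_other_promoter))
  cat(sprintf("  indel regions: %d\n", s$n_regions))
  cat(sprintf("  insertion age: %.2f MY [%.2f, %.2f]; vs reference %.2f MY: %s\n",
              s$insertion_age_point, s$insertion_age_low, s$insertion_age_high,
              s$reference_age, s$verdict))
  invisible(x)
}

#' One-row summary of an analysis report
#'
#' @param x An `analysis_report`.
#' @param ... Unused.
#' @return The summary tibble assembled from the stage tables.
#' @export
#' @exportS3Method generics::glance
glance.analysis_report <- function(x, ...) x$summary
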