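#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; see [run_pipeline()] for recognised fields
#' @return configuration list
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' @noRd
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(),          # synthetic_spec() overrides
    filter = list(min_overhang = 20L, min_reads = 2L),
    ir = list(min_intron_reads = 5L, min_breadth = 0.8),
    das = list(p_junction_events = 0.05, p_intron_retention = 0.001,
               unique_min_junction_reads = 5L, unique_min_ir_coverage = 5L,
               unique_min_ir_breadth = 0.8),
    decoy = list(n_junctions = 2000L, flank_len = 90L, read_len = 101L),
    min_mapq = 10L
  )
}

#' Run the splicing-analysis pipeline
#'
#' Orchestrates the stages over a synthetic experiment (or user inputs via
#' the config's `annotation`/`genome`/`alignments` paths): `simulate`, `qc`,
#' `filter` (junction extraction, decoy calibration, confident filter),
#' `classify` (AS events + intron retention + novelty), `diff` (Fisher
#' differential testing and DAS summary), `features` (dinucleotides,
#' offsets, co-occurrence) or `all`. Stage outputs are TSV/JSON files in
#' `outdir`; a manifest records every seed and threshold used, so a rerun
#' with the same config reproduces the outputs exactly.
#'
#' @param config configuration list (see [read_pipeline_config()]) or path
#'   to a YAML file; defaults used for anything unset
#' @param outdir output directory, created if needed
#' @param stages character vector of stages, or `"all"`
#' @return the manifest list, invisibly
#' @export
run_pipeline <- function(config = list(), outdir, stages = "all") {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(default_config(), config)
  if ("all" %in% stages) {
    stages <- c("simulate", "qc", "filter", "classify", "diff", "features")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)

  need <- function(stage, files) {
    miss <- files[!file.exists(p(files))]
    if (length(miss)) {
      stop("stage '", stage, "' needs earlier outputs (",
           paste(miss, collapse = ", "), "); run the producing stage first")
    }
  }

  spec <- do.call(synthetic_spec, utils::modifyList(
    list(seed = cfg$seed), cfg$simulate
  ))
  crit <- do.call(filter_criteria, cfg$filter)
  irc <- do.call(ir_criteria, cfg$ir)
  thr <- do.call(das_thresholds, cfg$das)

  if ("simulate" %in% stages) {
    sim <- simulate_splicing_experiment(spec)
    Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
    write_annotation(sim$annotation, p("annotation.gff3"))
    write_tsv(sim$truth$events, p("truth_events.tsv"))
    write_tsv(sim$truth$junctions, p("truth_junctions.tsv"))
    counts <- simulate_counts(sim, spec)
    write_tsv(counts, p("counts.tsv"))
    for (cond in spec$conditions) {
      a <- simulate_alignments(sim, spec, cond)
      write_sam(a$alignments, p(sprintf("alignments_%s.sam", cond)),
                sim$annotation$chrom_lengths)
      write_tsv(a$spurious, p(sprintf("spurious_%s.tsv", cond)))
    }
  }

  ann <- NULL
  load_inputs <- function() {
    if (is.null(ann)) {
      need("qc/filter/classify", c("annotation.gff3", "genome.fa"))
      ann <<- read_annotation(p("annotation.gff3"))
    }
    ann
  }

  if ("qc" %in% stages) {
    ann <- load_inputs()
    need("qc", "alignments_control.sam")
    qc <- library_qc(p("alignments_control.sam"), ann,
                     min_mapq = cfg$min_mapq, seed = cfg$seed)
    jsonlite::write_json(list(
      feature_fractions = as.list(qc$feature_fractions),
      saturation = qc$saturation,
      n_reads = qc$n_reads
    ), p("qc.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("filter" %in% stages) {
    ann <- load_inputs()
    need("filter", "alignments_control.sam")
    genome <- Biostrings::readDNAStringSet(p("genome.fa"))
    names(genome) <- sub(" .*", "", names(genome))
    j <- extract_junctions(p("alignments_control.sam"), ann,
                           min_mapq = cfg$min_mapq)
    write_tsv(j, p("junctions_all.tsv"))
    jf <- filter_junctions(j, crit)
    write_tsv(jf, p("junctions_confident.tsv"))
    dsp <- do.call(decoy_spec, utils::modifyList(list(seed = cfg$seed),
                                                 cfg$decoy))
    decoys <- build_decoy_junctions(ann, genome, dsp)
    Biostrings::writeXStringSet(decoys, p("decoy_junctions.fa"))
    calib <- calibrate_filter(
      simulate_decoy_support(dsp$n_junctions, seed = cfg$seed),
      simulate_annotated_support(dsp$n_junctions, seed = cfg$seed + 1L),
      crit
    )
    jsonlite::write_json(list(
      criteria = unclass(crit),
      fraction_decoys_removed = calib$fraction_decoys_removed,
      fraction_annotated_retained = calib$fraction_annotated_retained,
      decoy_spec = unclass(dsp)
    ), p("calibration.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("classify" %in% stages) {
    ann <- load_inputs()
    need("classify", c("junctions_confident.tsv", "alignments_control.sam"))
    jf <- utils::read.delim(p("junctions_confident.tsv"),
                            stringsAsFactors = FALSE)
    ev <- classify_events(jf, ann)
    ev <- annotate_novelty(ev, ann)
    cov <- intron_coverage(p("alignments_control.sam"), ann,
                           min_mapq = cfg$min_mapq)
    ir <- call_intron_retention(cov, irc)
    ev <- rbind(ev, annotate_novelty(ir_as_events(ir), ann))
    write_tsv(ev, p("events.tsv"))
    write_tsv(cov, p("intron_coverage.tsv"))
  }

  if ("diff" %in% stages) {
    need("diff", c("counts.tsv", "events.tsv"))
    counts <- utils::read.delim(p("counts.tsv"), stringsAsFactors = FALSE)
    res <- test_events(counts, control = spec$conditions[1], thresholds = thr)
    write_tsv(res, p("das_results.tsv"))
    summ <- das_summary(res)
    jsonlite::write_json(list(
      per_treatment = summ$per_treatment,
      n_das_genes = summ$n_das_genes,
      genes_in_multiple = summ$genes_in_multiple,
      fraction_in_multiple = summ$fraction_in_multiple
    ), p("das_summary.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("features" %in% stages) {
    ann <- load_inputs()
    need("features", c("junctions_confident.tsv", "events.tsv"))
    genome <- Biostrings::readDNAStringSet(p("genome.fa"))
    names(genome) <- sub(" .*", "", names(genome))
    jf <- utils::read.delim(p("junctions_confident.tsv"),
                            stringsAsFactors = FALSE)
    ev <- utils::read.delim(p("events.tsv"), stringsAsFactors = FALSE)
    for (col in c("alt_sites", "inclusion_junctions", "exclusion_junctions")) {
      if (col %in% names(ev)) ev[[col]][is.na(ev[[col]])] <- ""
    }
    dn <- splice_site_dinucleotides(jf, genome)
    write_tsv(dn$per_junction, p("dinucleotides.tsv"))
    off <- alt_ss_offsets(ev)
    write_tsv(off$offsets, p("offsets.tsv"))
    co <- skipping_altss_cooccurrence(ev, ann, seed = cfg$seed)
    jsonlite::write_json(list(
      observed_fraction = co$observed_fraction,
      expected_fraction = co$expected_fraction,
      p_value = co$p_value, n_skipped_exons = co$n_skipped_exons,
      testable = co$testable
    ), p("cooccurrence.json"), auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "splicescope",
    version = as.character(utils::packageVersion("splicescope")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = stages,
    seed = cfg$seed,
    filter_criteria = unclass(crit),
    ir_criteria = unclass(irc),
    das_thresholds = unclass(thr),
    min_mapq = cfg$min_mapq
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
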