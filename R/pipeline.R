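# End-to-end orchestration: simulate -> funnel -> ORA -> consensus -> IC50,
# with a run manifest and per-stage error reporting.

#' Assemble (or read) a pipeline run configuration
#'
#' @param out_dir run directory (required).
#' @param seed master seed; all simulated inputs derive from it.
#' @param simulate generate the synthetic cohort (and a dose-response plate)
#'   under `out_dir/inputs` instead of reading existing files.
#' @param profile [funnel_profile()] used when simulating.
#' @param tumor_vcf,normal_vcf,reference,targets_bed,transcripts_tsv,cds_fasta,db_dir,cgc
#'   input paths when not simulating.
#' @param query_genes optional explicit gene list (path) for the ORA stage;
#'   when absent the funnel's extracted genes are used.
#' @param pathways_gmt,universe ORA database paths.
#' @param predictor_calls TSV of predictor verdicts.
#' @param plate_csv optional dose-response plate.
#' @param gate a [variant_gate()]; `funnel` a [funnel_config()].
#' @return config list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 230L, simulate = TRUE,
                            profile = funnel_profile(),
                            tumor_vcf = NULL, normal_vcf = NULL,
                            reference = NULL, targets_bed = NULL,
                            transcripts_tsv = NULL, cds_fasta = NULL,
                            db_dir = NULL, cgc = NULL, query_genes = NULL,
                            pathways_gmt = NULL, universe = NULL,
                            predictor_calls = NULL, plate_csv = NULL,
                            gate = variant_gate(), funnel = funnel_config()) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a YAML pipeline configuration
#' @param path YAML file with [pipeline_config()] fields.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

validate_config <- function(cfg) {
  if (is.null(cfg$out_dir)) stopf("configuration error: out_dir is required")
  if (!isTRUE(cfg$simulate)) {
    need <- c("tumor_vcf", "normal_vcf", "reference", "targets_bed",
              "transcripts_tsv", "cds_fasta", "db_dir", "cgc")
    for (f in need) {
      if (is.null(cfg[[f]]))
        stopf("configuration error: %s is required when simulate = FALSE", f)
      if (!file.exists(cfg[[f]]))
        stopf("configuration error: %s does not exist: %s", f, cfg[[f]])
    }
  }
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Executes (optionally) cohort simulation, the discovery funnel with QC,
#' pathway over-representation, predictor consensus and, when plate data is
#' present, IC50 fitting; every report is written under `out_dir` both as TSV
#' and (for the funnel) as a human-readable summary, plus a JSON manifest
#' recording seed and configuration. Stage failures propagate with the stage
#' name attached and leave a FAILED marker file.
#'
#' @param config a [pipeline_config()], a YAML path, or a plain list of its
#'   fields.
#' @return list with the funnel report, ORA results, consensus table, IC50
#'   table and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
  else if (inherits(config, "run_config")) config
  else do.call(pipeline_config, config)
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  fail_marker <- file.path(cfg$out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s: %s", name, conditionMessage(e)), fail_marker)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  if (isTRUE(cfg$simulate)) {
    inputs <- file.path(cfg$out_dir, "inputs")
    cohort <- stage("simulate", generate_cohort(cfg$profile, cfg$seed, inputs))
    p <- cohort$paths
    cfg$tumor_vcf <- p$tumor_vcf; cfg$normal_vcf <- p$normal_vcf
    cfg$reference <- p$reference; cfg$targets_bed <- p$targets
    cfg$transcripts_tsv <- p$transcripts; cfg$cds_fasta <- p$cds_fasta
    cfg$db_dir <- p$db_dir; cfg$cgc <- p$cgc
    cfg$query_genes <- cfg$query_genes %||% p$query_genes
    cfg$pathways_gmt <- cfg$pathways_gmt %||% p$pathways
    cfg$universe <- cfg$universe %||% p$universe
    cfg$predictor_calls <- cfg$predictor_calls %||% p$predictor_calls
    if (is.null(cfg$plate_csv)) {
      cfg$plate_csv <- file.path(inputs, "plate.csv")
      stage("simulate", generate_dose_response(seed = cfg$seed + 11L,
                                               path = cfg$plate_csv))
    }
  }

  report <- stage("funnel", run_funnel(
    cfg$tumor_vcf, cfg$normal_vcf, cfg$reference, cfg$targets_bed,
    cfg$transcripts_tsv, cfg$cds_fasta, cfg$db_dir, cfg$cgc,
    config = cfg$funnel, gate = cfg$gate,
    out_dir = file.path(cfg$out_dir, "funnel")))

  ora <- NULL
  if (!is.null(cfg$pathways_gmt) && !is.null(cfg$universe)) {
    query <- if (!is.null(cfg$query_genes)) readLines(cfg$query_genes)
    else report$genes
    ora <- stage("ora", run_ora(query, read_gmt(cfg$pathways_gmt),
                                readLines(cfg$universe)))
    write_tsv_base(ora$results, file.path(cfg$out_dir, "enrichment.tsv"))
  }

  consensus <- NULL
  if (!is.null(cfg$predictor_calls)) {
    calls <- stage("consensus", read_predictor_calls(cfg$predictor_calls))
    consensus <- stage("consensus", consensus_table(calls))
    write_tsv_base(consensus, file.path(cfg$out_dir, "consensus.tsv"))
  }

  ic50 <- NULL
  if (!is.null(cfg$plate_csv) && file.exists(cfg$plate_csv)) {
    ic50 <- stage("fit-ic50", fit_plate(read_plate(cfg$plate_csv)))
    write_tsv_base(ic50, file.path(cfg$out_dir, "ic50.tsv"))
  }

  manifest <- list(seed = cfg$seed, simulate = isTRUE(cfg$simulate),
                   profile = if (isTRUE(cfg$simulate)) unclass(cfg$profile),
                   funnel_counts = as.list(as.data.frame(report)),
                   package_version = as.character(utils::packageVersion("somaticfunnel")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(report = report, ora = ora, consensus = consensus, ic50 = ic50,
       out_dir = cfg$out_dir)
}
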