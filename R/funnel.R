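# The discovery funnel: germline subtraction, ordered database-novelty
# cascade, functional classification, gene extraction and Cancer Gene Census
# comparison, with the count after every stage recorded.

#' Funnel configuration
#'
#' @param novelty_db_order database names applied in order by
#'   [apply_filter_cascade()]; "passing" a database means being absent from it
#'   (novelty-keeping semantics). The dbSNP-like catalogue comes first by
#'   default.
#' @param functional_kinds_kept coding-consequence kinds retained as
#'   functional; synonymous SNVs are excluded.
#' @export
funnel_config <- function(novelty_db_order = c("avsnp150", "COSMIC", "ExAC_ALL",
                                               "GME", "esp", "gnomAD", "clinvar",
                                               "ICGC", "Nci60", "1000g"),
                          functional_kinds_kept = c("nonsynonymous SNV",
                                                    "stopgain", "stoploss",
                                                    "frameshift insertion",
                                                    "frameshift deletion",
                                                    "nonframeshift insertion",
                                                    "nonframeshift deletion")) {
  if ("synonymous SNV" %in% functional_kinds_kept)
    stopf("functional_kinds_kept must exclude synonymous SNV")
  list(novelty_db_order = novelty_db_order,
       functional_kinds_kept = functional_kinds_kept)
}

SNV_KINDS <- c("nonsynonymous SNV", "stopgain", "stoploss")

#' Remove germline variants shared with the matched normal
#'
#' Set-algebraic tumor-minus-normal subtraction by normalized variant key;
#' shared calls are treated as inherited.
#'
#' @param tumor_variants,normal_variants normalized variant tables.
#' @return list with `exclusive` (tumor-only variants), `n_shared`,
#'   `n_exclusive`, `n_tumor_total`, `n_normal_total`.
#' @export
subtract_germline <- function(tumor_variants, normal_variants) {
  ts <- unique(stats::na.omit(tumor_variants$sample_id))
  ns <- unique(stats::na.omit(normal_variants$sample_id))
  if (length(intersect(ts, ns)))
    stopf("tumor and normal share sample_id '%s'; inputs swapped?",
          intersect(ts, ns)[1])
  tk <- variant_key(tumor_variants)
  nk <- variant_key(normal_variants)
  shared <- tk %in% nk
  list(exclusive = tumor_variants[!shared, , drop = FALSE],
       n_tumor_total = nrow(tumor_variants),
       n_normal_total = nrow(normal_variants),
       n_shared = sum(shared),
       n_exclusive = sum(!shared))
}

#' Ordered database-novelty filter cascade
#'
#' Sequentially removes variants whose key appears in each database, in the
#' configured order; survivors of the full cascade are the putatively novel
#' set. Intermediate counts depend on the order, the final set does not.
#'
#' @param variants normalized variant table (tumor-exclusive set).
#' @param databases named list of variant-key vectors; must cover the
#'   configured order.
#' @param config a [funnel_config()].
#' @return list with `novel` (surviving variants) and `survivors`, a named
#'   integer vector of counts after each database.
#' @export
apply_filter_cascade <- function(variants, databases, config = funnel_config()) {
  order <- config$novelty_db_order
  miss <- setdiff(order, names(databases))
  if (length(miss))
    stopf("missing database table(s): %s", paste(miss, collapse = ", "))
  keys <- variant_key(variants)
  keep <- rep(TRUE, length(keys))
  survivors <- stats::setNames(integer(length(order)), order)
  for (db in order) {
    keep <- keep & !(keys %in% databases[[db]])
    survivors[db] <- sum(keep)
  }
  list(novel = variants[keep, , drop = FALSE], survivors = survivors)
}

#' Keep exonic variants and drop synonymous SNVs
#'
#' Annotates regions and coding consequences, retains exonic variants, removes
#' synonymous SNVs, and splits the retained functional set into SNVs
#' (nonsynonymous, stopgain, stoploss) versus others (indels).
#'
#' @param novel_variants normalized variant table (post-cascade).
#' @param tx_db transcript models.
#' @param config a [funnel_config()].
#' @return list with `functional` (annotated variant table), `annotated` (all
#'   input variants annotated) and counts `n_exonic`, `n_synonymous`,
#'   `n_functional`, `n_snv`, `n_other`.
#' @export
classify_and_filter_functional <- function(novel_variants, tx_db,
                                           config = funnel_config()) {
  ann <- annotate_variants(novel_variants, tx_db)
  exonic <- ann[ann$region == "exonic", , drop = FALSE]
  syn <- exonic$kind == "synonymous SNV"
  functional <- exonic[!syn & exonic$kind %in% config$functional_kinds_kept, ,
                       drop = FALSE]
  list(functional = functional, annotated = ann,
       n_exonic = nrow(exonic),
       n_synonymous = sum(syn),
       n_functional = nrow(functional),
       n_snv = sum(functional$kind %in% SNV_KINDS),
       n_other = sum(!functional$kind %in% SNV_KINDS))
}

#' Extract the unique gene symbols hit by functional variants
#'
#' @param functional_variants annotated variant table (output of
#'   [classify_and_filter_functional()]); multi-gene variants contribute all
#'   symbols.
#' @return character vector of unique, uppercase gene symbols.
#' @export
extract_genes <- function(functional_variants) {
  if (nrow(functional_variants) == 0) return(character(0))
  g <- functional_variants$genes
  if (is.null(g) || any(is.na(g)) || any(!nzchar(g)))
    stopf("unannotated variant present; run classify_and_filter_functional() first")
  unique(toupper(unlist(strsplit(g, ",", fixed = TRUE), use.names = FALSE)))
}

#' Read a Cancer Gene Census style table
#' @param path TSV with columns gene_symbol and tier (1 or 2).
#' @return data.frame with uppercase unique symbols.
#' @export
read_cgc <- function(path) {
  cgc <- read_tsv_base(path)
  cgc$gene_symbol <- toupper(cgc$gene_symbol)
  if (anyDuplicated(cgc$gene_symbol)) stopf("duplicate CGC gene symbols")
  if (!all(cgc$tier %in% c(1L, 2L))) stopf("CGC tier must be 1 or 2")
  cgc
}

#' Compare a gene set against a Cancer Gene Census table
#'
#' @param genes character vector of gene symbols.
#' @param cgc data.frame with gene_symbol and tier (see [read_cgc()]).
#' @return list with `common` (intersected symbols), `n_common`, `n_tier1`,
#'   `n_tier2` and `tier1_pct` (percent of common genes in Tier 1, one
#'   decimal; NA when there is no overlap).
#' @export
cgc_compare <- function(genes, cgc) {
  if (is.null(cgc) || nrow(cgc) == 0) stopf("empty CGC table")
  genes <- unique(toupper(genes))
  common <- intersect(genes, cgc$gene_symbol)
  tiers <- cgc$tier[match(common, cgc$gene_symbol)]
  n1 <- sum(tiers == 1L)
  list(common = common, n_common = length(common),
       n_tier1 = n1, n_tier2 = sum(tiers == 2L),
       tier1_pct = if (length(common)) round(100 * n1 / length(common), 1) else NA_real_)
}

#' Read novelty databases from a directory
#'
#' Each `<name>.tsv` holds columns chrom, pos, ref, alt; the file name (sans
#' extension) is the database name.
#'
#' @param dir directory of database tables.
#' @return named list of variant-key character vectors.
#' @export
read_database_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(files)) stopf("no database tables found in %s", dir)
  out <- lapply(files, function(f) {
    d <- read_tsv_base(f)
    paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  })
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}

as_reference <- function(x) if (is.character(x) && length(x) == 1 && file.exists(x))
  read_reference_fasta(x) else x

as_targets <- function(x) if (is.character(x) && length(x) == 1) read_bed(x) else x

as_databases <- function(x) if (is.character(x) && length(x) == 1) read_database_dir(x) else x

as_cgc <- function(x) if (is.character(x) && length(x) == 1) read_cgc(x) else x

as_tx <- function(x, cds_fasta = NULL) {
  if (is.character(x) && length(x) == 1) read_transcripts(x, cds_fasta) else x
}

#' Run the full discovery funnel
#'
#' Chains quality control, germline subtraction, the database-novelty cascade,
#' functional classification and the Cancer Gene Census comparison, recording
#' the count after every stage. Inputs may be file paths (VCF / FASTA / BED /
#' TSV) or the in-memory objects the readers produce.
#'
#' @param tumor_vcf,normal_vcf VCF paths or variant tables (raw; they are
#'   decomposed, gated and normalized here).
#' @param reference FASTA path or named chromosome sequences.
#' @param targets BED path or 1-based interval data.frame.
#' @param transcripts transcript TSV path or data.frame with `cds_seq`.
#' @param cds_fasta CDS FASTA path (when `transcripts` is a path).
#' @param databases database directory or named list of key vectors.
#' @param cgc CGC TSV path or data.frame.
#' @param config a [funnel_config()].
#' @param gate a [variant_gate()].
#' @param out_dir optional directory for TSV/VCF stage outputs.
#' @return object of class `funnel_report`; the annotated novel functional
#'   variants are in `$functional`.
#' @export
run_funnel <- function(tumor_vcf, normal_vcf, reference, targets, transcripts,
                       cds_fasta = NULL, databases, cgc,
                       config = funnel_config(), gate = variant_gate(),
                       out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("funnel stage '%s' failed: %s", name, conditionMessage(e)))
  }
  reference <- as_reference(reference)
  targets <- as_targets(targets)
  tx <- as_tx(transcripts, cds_fasta)
  databases <- as_databases(databases)
  cgc <- as_cgc(cgc)

  tumor <- stage("load-tumor", {
    if (is.character(tumor_vcf)) load_variants(tumor_vcf, "TUMOR", reference, gate)
    else left_normalize(apply_gate(split_multiallelic(tumor_vcf), gate), reference)
  })
  normal <- stage("load-normal", {
    if (is.character(normal_vcf)) load_variants(normal_vcf, "NORMAL", reference, gate)
    else left_normalize(apply_gate(split_multiallelic(normal_vcf), gate), reference)
  })
  qc_tumor <- stage("qc", compute_qc(tumor, databases[["avsnp150"]] %||% character(0)))
  n_off <- stage("qc", off_target_count(tumor, targets))
  sub <- stage("subtract-germline", subtract_germline(tumor, normal))
  casc <- stage("novelty-cascade", apply_filter_cascade(sub$exclusive, databases, config))
  fun <- stage("functional-filter",
               classify_and_filter_functional(casc$novel, tx, config))
  genes <- stage("extract-genes", extract_genes(fun$functional))
  cgc_cmp <- stage("cgc-compare", cgc_compare(genes, cgc))

  rep <- structure(list(
    n_tumor_total = sub$n_tumor_total,
    n_normal_total = sub$n_normal_total,
    n_shared = sub$n_shared,
    n_exclusive = sub$n_exclusive,
    survivors = casc$survivors,
    n_after_first_db = unname(casc$survivors[1]),
    n_novel = unname(casc$survivors[length(casc$survivors)]),
    n_exonic = fun$n_exonic,
    n_synonymous = fun$n_synonymous,
    n_functional = fun$n_functional,
    n_snv = fun$n_snv,
    n_other = fun$n_other,
    n_genes = length(genes),
    n_cgc_common = cgc_cmp$n_common,
    n_cgc_tier1 = cgc_cmp$n_tier1,
    cgc_tier1_pct = cgc_cmp$tier1_pct,
    n_off_target = n_off,
    qc = qc_tumor,
    genes = genes,
    cgc_common = cgc_cmp$common,
    functional = fun$functional
  ), class = "funnel_report")
  validate_funnel_report(rep)
  if (!is.null(out_dir)) write_funnel_outputs(rep, out_dir)
  rep
}

validate_funnel_report <- function(x) {
  stopifnot(x$n_exclusive == x$n_tumor_total - x$n_shared,
            x$n_functional == x$n_exonic - x$n_synonymous,
            x$n_snv + x$n_other == x$n_functional,
            x$n_cgc_tier1 <= x$n_cgc_common,
            x$n_cgc_common <= x$n_genes,
            all(diff(x$survivors) <= 0))
  invisible(x)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Somatic novel-variant discovery funnel\n")
  cat(sprintf("  tumor variants                %7d\n", x$n_tumor_total))
  cat(sprintf("  normal variants               %7d\n", x$n_normal_total))
  cat(sprintf("  shared (germline, removed)    %7d\n", x$n_shared))
  cat(sprintf("  tumor-exclusive               %7d\n", x$n_exclusive))
  for (db in names(x$survivors))
    cat(sprintf("   after %-22s %7d\n", db, x$survivors[db]))
  cat(sprintf("  novel                         %7d\n", x$n_novel))
  cat(sprintf("  exonic                        %7d\n", x$n_exonic))
  cat(sprintf("  functional (non-synonymous)   %7d  (%d SNV + %d other)\n",
              x$n_functional, x$n_snv, x$n_other))
  cat(sprintf("  unique genes                  %7d\n", x$n_genes))
  cat(sprintf("  CGC overlap                   %7d  (%d Tier 1, %s%%)\n",
              x$n_cgc_common, x$n_cgc_tier1,
              ifelse(is.na(x$cgc_tier1_pct), "NA", x$cgc_tier1_pct)))
  cat(sprintf("  off-target                    %7d\n", x$n_off_target))
  invisible(x)
}

#' Funnel report counts as a one-row data.frame
#' @param x a `funnel_report`.
#' @export
as.data.frame.funnel_report <- function(x, ...) {
  df <- data.frame(n_tumor_total = x$n_tumor_total,
                   n_normal_total = x$n_normal_total,
                   n_shared = x$n_shared, n_exclusive = x$n_exclusive,
                   n_after_first_db = x$n_after_first_db, n_novel = x$n_novel,
                   n_exonic = x$n_exonic, n_synonymous = x$n_synonymous,
                   n_functional = x$n_functional, n_snv = x$n_snv,
                   n_other = x$n_other, n_genes = x$n_genes,
                   n_cgc_common = x$n_cgc_common, n_cgc_tier1 = x$n_cgc_tier1,
                   cgc_tier1_pct = x$cgc_tier1_pct,
                   n_off_target = x$n_off_target)
  for (db in names(x$survivors)) df[[paste0("after_", db)]] <- x$survivors[[db]]
  df
}

write_funnel_outputs <- function(rep, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_base(as.data.frame(rep), file.path(out_dir, "funnel_report.tsv"))
  write_tsv_base(as.data.frame(rep$qc), file.path(out_dir, "qc_report.tsv"))
  fun <- rep$functional
  write_tsv_base(fun, file.path(out_dir, "novel_functional.tsv"))
  write_vcf(fun, file.path(out_dir, "novel_functional.vcf"))
  writeLines(utils::capture.output(print(rep)),
             file.path(out_dir, "funnel_summary.txt"))
  writeLines(sort(rep$genes), file.path(out_dir, "novel_genes.txt"))
  invisible(out_dir)
}
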