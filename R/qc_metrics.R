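# Exome QC metrics: off-target counts, Ti/Tv ratio, dbSNP concordance and
# variant-type proportions.

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

variant_type <- function(ref, alt) {
  rn <- nchar(ref); an <- nchar(alt)
  ifelse(rn == 1L & an == 1L, "SNV",
         ifelse(an > rn, "insertion",
                ifelse(rn > an, "deletion", "MNV")))
}

#' Count variants falling outside the target regions
#'
#' A variant is on-target when its first REF base lies inside some interval.
#'
#' @param variants normalized variant table.
#' @param targets data.frame of 1-based inclusive intervals ([read_bed()]).
#' @return integer count of off-target variants.
#' @export
off_target_count <- function(variants, targets) {
  if (nrow(variants) == 0) return(0L)
  if (is.null(targets) || nrow(targets) == 0) {
    warnf("empty target set: all %d variants counted off-target", nrow(variants))
    return(nrow(variants))
  }
  on <- logical(nrow(variants))
  for (ch in unique(variants$chrom)) {
    i <- which(variants$chrom == ch)
    t <- targets[targets$chrom == ch, , drop = FALSE]
    if (nrow(t) == 0) next
    q <- IRanges::IRanges(start = variants$pos[i], width = 1L)
    s <- IRanges::IRanges(start = t$start, end = t$end)
    on[i] <- IRanges::countOverlaps(q, s) > 0L
  }
  sum(!on)
}

#' Compute exome QC metrics
#'
#' Ti/Tv is computed over SNVs only (transitions A<->G and C<->T; the eight
#' other substitutions are transversions); indels and MNVs never contribute.
#' dbSNP concordance is the percentage of all variants whose normalized key is
#' present in `dbsnp_keys`.
#'
#' @param variants normalized variant table.
#' @param dbsnp_keys character vector of known-polymorphism variant keys.
#' @return object of class `qc_report` with fields n_variants, titv (NA when
#'   no transversions), dbsnp_concordance (percent, NA when empty input) and
#'   type_counts.
#' @export
compute_qc <- function(variants, dbsnp_keys = character(0)) {
  n <- nrow(variants)
  types <- if (n) variant_type(variants$ref, variants$alt) else character(0)
  type_counts <- c(SNV = sum(types == "SNV"),
                   insertion = sum(types == "insertion"),
                   deletion = sum(types == "deletion"),
                   MNV = sum(types == "MNV"))
  snv <- types == "SNV"
  sub <- paste0(variants$ref[snv], ">", variants$alt[snv])
  ti <- sum(sub %in% TRANSITIONS)
  tv <- sum(!(sub %in% TRANSITIONS))
  titv <- if (tv > 0) ti / tv else NA_real_
  conc <- if (n > 0) {
    100 * sum(variant_key(variants) %in% dbsnp_keys) / n
  } else NA_real_
  structure(list(n_variants = n, titv = titv, n_transitions = ti,
                 n_transversions = tv, dbsnp_concordance = conc,
                 type_counts = type_counts),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Exome QC report\n")
  cat(sprintf("  variants:          %d\n", x$n_variants))
  cat(sprintf("  Ti/Tv:             %s  (%d Ti / %d Tv)\n",
              if (is.na(x$titv)) "undefined" else format(round(x$titv, 3)),
              x$n_transitions, x$n_transversions))
  cat(sprintf("  dbSNP concordance: %s\n",
              if (is.na(x$dbsnp_concordance)) "undefined"
              else paste0(format(round(x$dbsnp_concordance, 1)), "%")))
  cat("  type counts:      ",
      paste(names(x$type_counts), x$type_counts, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Flatten a QC report for TSV output
#' @param x a `qc_report`.
#' @return one-row data.frame.
#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(n_variants = x$n_variants, titv = x$titv,
             dbsnp_concordance = x$dbsnp_concordance,
             n_snv = unname(x$type_counts["SNV"]),
             n_insertion = unname(x$type_counts["insertion"]),
             n_deletion = unname(x$type_counts["deletion"]),
             n_mnv = unname(x$type_counts["MNV"]))
}
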