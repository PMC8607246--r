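# Variant container, VCF/BED I/O, multi-allelic decomposition and indel
# left-normalization. A variant set is a plain data.frame with one alternate
# allele per row; all downstream set operations use the normalized key
# chrom:pos:ref:alt.

#' Construct a variant table
#'
#' One row per single-alternate-allele variant, VCF-style 1-based coordinates.
#'
#' @param chrom chromosome names (compared verbatim).
#' @param pos 1-based position of the first REF base.
#' @param ref,alt uppercase allele strings; `ref != alt`, one ALT per row.
#' @param qual call quality (may be `NA`).
#' @param total_depth,variant_depth read depths at the site / supporting ALT.
#' @param call_p caller p-value in `[0, 1]` (may be `NA`).
#' @param sample_id source sample label.
#' @return data.frame of class `variant_tbl`.
#' @export
variant_tbl <- function(chrom, pos, ref, alt, qual = NA_real_,
                        total_depth = NA_integer_, variant_depth = NA_integer_,
                        call_p = NA_real_, sample_id = NA_character_) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  if (n == 0) {
    qual <- numeric(0); total_depth <- integer(0); variant_depth <- integer(0)
    call_p <- numeric(0); sample_id <- character(0)
  }
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   pos = rep_len(as.integer(pos), n),
                   ref = rep_len(toupper(as.character(ref)), n),
                   alt = rep_len(toupper(as.character(alt)), n),
                   qual = rep_len(as.numeric(qual), n),
                   total_depth = rep_len(as.integer(total_depth), n),
                   variant_depth = rep_len(as.integer(variant_depth), n),
                   call_p = rep_len(as.numeric(call_p), n),
                   sample_id = rep_len(as.character(sample_id), n),
                   stringsAsFactors = FALSE)
  validate_variants(df)
  class(df) <- c("variant_tbl", "data.frame")
  df
}

validate_variants <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$pos)) || any(df$pos < 1L))
    stopf("variant positions must be integers >= 1")
  if (any(!nzchar(df$ref)) || any(!nzchar(df$alt)))
    stopf("REF and ALT alleles must be nonempty")
  if (any(df$ref == df$alt))
    stopf("REF must differ from ALT")
  if (any(grepl(",", df$alt, fixed = TRUE)))
    stopf("exactly one ALT allele per variant; split multi-allelic records first")
  bad_p <- !is.na(df$call_p) & (df$call_p < 0 | df$call_p > 1)
  if (any(bad_p)) stopf("call_p must lie in [0, 1]")
  invisible(df)
}

# Symbolic ALTs (<DEL>, breakends) and alleles containing N are carried through
# un-normalized and flagged rather than dropped.
is_symbolic_allele <- function(ref, alt) {
  grepl("[][<>]", alt) | grepl("N", ref, fixed = TRUE) | grepl("N", alt, fixed = TRUE)
}

#' Load-time quality gate on caller statistics
#'
#' Default thresholds: total depth > 50, variant-supporting depth > 15 and
#' caller p-value < 0.01. Records missing a gated field pass with a warning.
#'
#' @param total_depth,variant_depth,call_p thresholds.
#' @param enabled set `FALSE` to bypass the gate.
#' @export
variant_gate <- function(total_depth = 50, variant_depth = 15, call_p = 0.01,
                         enabled = TRUE) {
  list(total_depth = total_depth, variant_depth = variant_depth,
       call_p = call_p, enabled = enabled)
}

#' Apply the quality gate to a variant table
#' @param variants a variant table.
#' @param gate a [variant_gate()].
#' @return the surviving rows.
#' @export
apply_gate <- function(variants, gate = variant_gate()) {
  if (!isTRUE(gate$enabled) || nrow(variants) == 0) return(variants)
  miss <- is.na(variants$total_depth) | is.na(variants$variant_depth) |
    is.na(variants$call_p)
  if (any(miss))
    warnf("%d record(s) missing gated fields pass the quality gate unfiltered", sum(miss))
  keep <- miss |
    (variants$total_depth > gate$total_depth &
       variants$variant_depth > gate$variant_depth &
       variants$call_p < gate$call_p)
  variants[keep, , drop = FALSE]
}

info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  out <- rep(NA_character_, length(info))
  hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
  out[hit] <- sub(paste0("^;?", key, "="), "", m)
  out
}

#' Read a VCF file into raw records
#'
#' One record per data line; multi-allelic ALT fields are kept comma-joined
#' (see [split_multiallelic()]). Depth and p-value statistics are taken from
#' the INFO keys `DP`, `VD` and `PV` when present. Gzip is transparent.
#'
#' @param path VCF v4.x file.
#' @param sample_id label attached to every record.
#' @return data.frame of raw records with columns chrom, pos, ref, alt, qual,
#'   total_depth, variant_depth, call_p, sample_id.
#' @export
read_vcf <- function(path, sample_id = NA_character_) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) stopf("empty VCF: %s", path)
  if (!startsWith(first, "#"))
    stopf("VCF format error: %s has no header line beginning '#CHROM'", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) {
    return(variant_tbl(character(), integer(), character(), character()))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stopf("VCF record error: non-integer POS at data line %d of %s", bad, path)
  }
  info <- fix[, "INFO"]
  df <- data.frame(chrom = fix[, "CHROM"], pos = pos,
                   ref = toupper(fix[, "REF"]), alt = toupper(fix[, "ALT"]),
                   qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
                   total_depth = suppressWarnings(as.integer(info_field(info, "DP"))),
                   variant_depth = suppressWarnings(as.integer(info_field(info, "VD"))),
                   call_p = suppressWarnings(as.numeric(info_field(info, "PV"))),
                   sample_id = sample_id, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (any(!nzchar(df$alt) | is.na(df$alt))) stopf("VCF record with empty ALT in %s", path)
  df
}

#' Write a variant table as a sites-only VCF
#'
#' Depth statistics are emitted as INFO keys `DP`, `VD`, `PV`. A `.gz`
#' extension triggers gzip compression.
#'
#' @param variants variant table (or raw records; ALT may be comma-joined).
#' @param path output path.
#' @export
write_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           "##INFO=<ID=VD,Number=1,Type=Integer,Description=\"Variant-supporting read depth\">",
           "##INFO=<ID=PV,Number=1,Type=Float,Description=\"Caller p-value\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", sep = "\t"))
  info <- paste0(
    ifelse(is.na(variants$total_depth), "", paste0("DP=", variants$total_depth, ";")),
    ifelse(is.na(variants$variant_depth), "", paste0("VD=", variants$variant_depth, ";")),
    ifelse(is.na(variants$call_p), "", paste0("PV=", format(variants$call_p, scientific = FALSE, trim = TRUE), ";")))
  info <- sub(";$", "", info)
  info[!nzchar(info)] <- "."
  qual <- ifelse(is.na(variants$qual), ".", as.character(variants$qual))
  lines <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                 qual, "PASS", info, sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(hdr, lines), con)
  invisible(path)
}

#' Decompose multi-allelic records into single-alternate variants
#'
#' Splits each record carrying a comma-separated ALT into one variant per
#' alternate allele, order preserved, shared fields copied.
#'
#' @param records output of [read_vcf()].
#' @return variant table, one ALT per row.
#' @export
split_multiallelic <- function(records) {
  if (nrow(records) == 0)
    return(variant_tbl(character(), integer(), character(), character()))
  alts <- strsplit(records$alt, ",", fixed = TRUE)
  if (any(lengths(alts) == 0)) stopf("record with empty ALT list")
  idx <- rep(seq_len(nrow(records)), lengths(alts))
  out <- records[idx, , drop = FALSE]
  out$alt <- unlist(alts, use.names = FALSE)
  rownames(out) <- NULL
  validate_variants(out)
  class(out) <- c("variant_tbl", "data.frame")
  out
}

normalize_one <- function(pos, ref, alt, chromseq) {
  if (substr(chromseq, pos, pos + nchar(ref) - 1L) != ref)
    stopf("REF '%s' at pos %d disagrees with the reference sequence", ref, pos)
  repeat {
    rn <- nchar(ref); an <- nchar(alt)
    if (rn >= 1L && an >= 1L && !(rn == 1L && an == 1L) &&
        substr(ref, rn, rn) == substr(alt, an, an)) {
      ref <- substr(ref, 1L, rn - 1L)
      alt <- substr(alt, 1L, an - 1L)
      if (!nzchar(ref) || !nzchar(alt)) {
        if (pos == 1L)
          stopf("left-normalization hit the chromosome boundary at pos 1")
        pos <- pos - 1L
        b <- substr(chromseq, pos, pos)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      }
    } else break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Left-normalize variants against a reference
#'
#' Produces the unique left-aligned, parsimonious representation of each
#' variant: shared trailing bases are truncated (extending one reference base
#' to the left whenever an allele would empty), then shared leading bases are
#' trimmed while both alleles keep length >= 2. SNVs are fixed points and the
#' operation is idempotent. Symbolic alleles and alleles containing N are
#' passed through untouched with `normalized = FALSE`.
#'
#' @param variants variant table.
#' @param reference named character vector of chromosome sequences
#'   (see [read_reference_fasta()]).
#' @return the variant table, normalized, with a logical `normalized` column.
#' @export
left_normalize <- function(variants, reference) {
  n <- nrow(variants)
  if (n == 0) { variants$normalized <- logical(0); return(variants) }
  miss <- setdiff(unique(variants$chrom), names(reference))
  if (length(miss))
    stopf("chromosome(s) absent from reference: %s", paste(miss, collapse = ", "))
  sym <- is_symbolic_allele(variants$ref, variants$alt)
  snv <- !sym & nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  # fast path: verify SNV reference bases in bulk
  if (any(snv)) {
    for (ch in unique(variants$chrom[snv])) {
      i <- which(snv & variants$chrom == ch)
      got <- substring(reference[[ch]], variants$pos[i], variants$pos[i])
      if (any(got != variants$ref[i]))
        stopf("REF disagrees with reference at %s:%d", ch,
              variants$pos[i][got != variants$ref[i]][1])
    }
  }
  todo <- which(!sym & !snv)
  for (i in todo) {
    r <- normalize_one(variants$pos[i], variants$ref[i], variants$alt[i],
                       reference[[variants$chrom[i]]])
    variants$pos[i] <- r$pos
    variants$ref[i] <- r$ref
    variants$alt[i] <- r$alt
  }
  variants$normalized <- !sym
  variants
}

#' Canonical variant identity key
#'
#' `chrom:pos:ref:alt` of the left-normalized representation. Two records
#' denoting the same allele compare equal after [left_normalize()]; sample
#' and genotype fields are ignored. Detectably un-normalized input (a shared
#' trailing base with an allele longer than one base) is an error.
#'
#' @param variants variant table (normalized).
#' @return character vector of keys.
#' @export
variant_key <- function(variants) {
  if (nrow(variants) == 0) return(character(0))
  sym <- is_symbolic_allele(variants$ref, variants$alt)
  multi <- !sym & (nchar(variants$ref) > 1L | nchar(variants$alt) > 1L)
  bad <- multi & last_char(variants$ref) == last_char(variants$alt)
  if (any(bad))
    stopf("un-normalized variant (shared trailing base) at %s:%d; run left_normalize() first",
          variants$chrom[bad][1], variants$pos[bad][1])
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Read BED target regions
#'
#' 0-based half-open intervals on disk are converted to the package's internal
#' 1-based inclusive convention.
#'
#' @param path 3+ column BED file (optionally gzipped).
#' @return data.frame with columns chrom, start, end (1-based inclusive).
#' @export
read_bed <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  df <- utils::read.table(con, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stopf("BED interval with start >= end")
  out
}

#' Write target regions as BED (converting back to 0-based half-open)
#' @param targets data.frame with 1-based inclusive chrom/start/end.
#' @param path output path.
#' @export
write_bed <- function(targets, path) {
  writeLines(paste(targets$chrom, targets$start - 1L, targets$end, sep = "\t"), path)
  invisible(path)
}

#' Read, decompose, normalize and gate a VCF in one step
#'
#' @inheritParams read_vcf
#' @param reference named chromosome sequences for [left_normalize()].
#' @param gate a [variant_gate()]; the default applies the depth/p-value
#'   thresholds at load time.
#' @return normalized, gated variant table.
#' @export
load_variants <- function(path, sample_id, reference, gate = variant_gate()) {
  v <- split_multiallelic(read_vcf(path, sample_id))
  v <- apply_gate(v, gate)
  left_normalize(v, reference)
}
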