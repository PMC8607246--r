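# Transcript-model based annotation: genomic region classification and coding
# consequences (c. / p. strings) computed from first principles against
# spliced CDS sequences.

REGION_RANK <- c(exonic = 5, splicing = 5, UTR5 = 4, UTR3 = 4, intronic = 3,
                 upstream = 2, downstream = 2, intergenic = 1)
# within equal rank, the earlier label wins the report
REGION_ORDER <- names(REGION_RANK)

SPLICE_WINDOW <- 2L   # bp into the intron counted as splice-site
FLANK_WINDOW <- 1000L # upstream/downstream window around transcript ends

#' Read transcript models
#'
#' Models are stored as a TSV (one row per transcript: transcript_id,
#' gene_symbol, chrom, strand, comma-separated exon_starts/exon_ends in
#' genomic order, genomic cds_start/cds_end) plus a FASTA of spliced coding
#' sequences (5'->3' in mRNA orientation) keyed by transcript_id.
#'
#' @param tsv_path transcript table.
#' @param cds_fasta_path CDS FASTA.
#' @return data.frame of transcript models with a `cds_seq` column.
#' @export
read_transcripts <- function(tsv_path, cds_fasta_path) {
  tx <- read_tsv_base(tsv_path)
  tx$chrom <- as.character(tx$chrom)
  tx$transcript_id <- as.character(tx$transcript_id)
  tx$gene_symbol <- as.character(tx$gene_symbol)
  cds <- read_reference_fasta(cds_fasta_path)
  miss <- setdiff(tx$transcript_id, names(cds))
  if (length(miss)) stopf("CDS FASTA missing transcript(s): %s", miss[1])
  tx$cds_seq <- unname(cds[tx$transcript_id])
  validate_transcripts(tx)
  tx
}

validate_transcripts <- function(tx) {
  if (any(nchar(tx$cds_seq) %% 3L != 0L))
    stopf("CDS length not divisible by 3 for %s",
          tx$transcript_id[nchar(tx$cds_seq) %% 3L != 0L][1])
  invisible(tx)
}

#' Write transcript models (TSV + CDS FASTA)
#' @param tx transcript data.frame with `cds_seq`.
#' @param tsv_path,cds_fasta_path output paths.
#' @export
write_transcripts <- function(tx, tsv_path, cds_fasta_path) {
  cds <- tx$cds_seq
  names(cds) <- tx$transcript_id
  write_reference_fasta(cds, cds_fasta_path)
  write_tsv_base(tx[, setdiff(names(tx), "cds_seq")], tsv_path)
  invisible(tsv_path)
}

parse_int_list <- function(x) lapply(strsplit(as.character(x), ",", fixed = TRUE), as.integer)

#' Index transcript models for annotation
#'
#' @param tx transcript data.frame (see [read_transcripts()]).
#' @return object of class `tx_db` used by [classify_region()] and friends.
#' @export
prepare_tx_db <- function(tx) {
  if (inherits(tx, "tx_db")) return(tx)
  starts <- parse_int_list(tx$exon_starts)
  ends <- parse_int_list(tx$exon_ends)
  models <- lapply(seq_len(nrow(tx)), function(i) {
    list(transcript_id = as.character(tx$transcript_id[i]),
         gene_symbol = as.character(tx$gene_symbol[i]),
         chrom = as.character(tx$chrom[i]), strand = tx$strand[i],
         exon_starts = starts[[i]], exon_ends = ends[[i]],
         cds_start = tx$cds_start[i], cds_end = tx$cds_end[i],
         tx_start = min(starts[[i]]), tx_end = max(ends[[i]]),
         cds_seq = tx$cds_seq[i])
  })
  structure(list(models = models,
                 chrom = vapply(models, `[[`, "", "chrom"),
                 span_start = vapply(models, `[[`, 0L, "tx_start"),
                 span_end = vapply(models, `[[`, 0L, "tx_end")),
            class = "tx_db")
}

# per-transcript region class for a single position; NA when out of reach
tx_region_class <- function(pos, m) {
  if (pos >= m$tx_start && pos <= m$tx_end) {
    in_exon <- any(pos >= m$exon_starts & pos <= m$exon_ends)
    if (in_exon) {
      if (pos >= m$cds_start && pos <= m$cds_end) return("exonic")
      if (pos < m$cds_start) return(if (m$strand == "+") "UTR5" else "UTR3")
      return(if (m$strand == "+") "UTR3" else "UTR5")
    }
    k <- length(m$exon_starts)
    for (i in seq_len(k - 1L)) {
      is <- m$exon_ends[i] + 1L
      ie <- m$exon_starts[i + 1L] - 1L
      if (pos >= is && pos <= ie) {
        if (pos - is < SPLICE_WINDOW || ie - pos < SPLICE_WINDOW) return("splicing")
        return("intronic")
      }
    }
    return("intronic")
  }
  five_prime_side <- if (m$strand == "+") pos < m$tx_start else pos > m$tx_end
  dist <- if (pos < m$tx_start) m$tx_start - pos else pos - m$tx_end
  if (dist <= FLANK_WINDOW) return(if (five_prime_side) "upstream" else "downstream")
  NA_character_
}

#' Classify variants by genomic region against transcript models
#'
#' Per-transcript classes are resolved by precedence
#' exonic = splicing > UTR5 = UTR3 > intronic > upstream = downstream >
#' intergenic; splice sites are the first two intronic bases at each
#' exon/intron boundary, and the upstream/downstream windows extend 1 kb from
#' the transcript ends. Classification uses the position of the first REF base.
#'
#' @param variants normalized variant table.
#' @param tx_db transcript models ([prepare_tx_db()] or raw data.frame).
#' @return data.frame with columns region, genes (comma-joined symbols of all
#'   transcripts yielding the winning class) and transcript_ids.
#' @export
classify_region <- function(variants, tx_db) {
  db <- prepare_tx_db(tx_db)
  n <- nrow(variants)
  region <- character(n); genes <- character(n); tids <- character(n)
  for (i in seq_len(n)) {
    pos <- variants$pos[i]
    cand <- which(db$chrom == variants$chrom[i] &
                    db$span_start - FLANK_WINDOW <= pos &
                    db$span_end + FLANK_WINDOW >= pos)
    cls <- vapply(db$models[cand], function(m) tx_region_class(pos, m), character(1))
    keep <- !is.na(cls)
    cls <- cls[keep]; cand <- cand[keep]
    if (length(cls) == 0) {
      region[i] <- "intergenic"; genes[i] <- ""; tids[i] <- ""
      next
    }
    # REGION_ORDER is rank-sorted, so the first label present has maximal rank
    win <- REGION_ORDER[REGION_ORDER %in% cls][1]
    sel <- cand[cls == win]
    region[i] <- win
    genes[i] <- paste(unique(vapply(db$models[sel], `[[`, "", "gene_symbol")),
                      collapse = ",")
    tids[i] <- paste(vapply(db$models[sel], `[[`, "", "transcript_id"),
                     collapse = ",")
  }
  data.frame(region = region, genes = genes, transcript_ids = tids,
             stringsAsFactors = FALSE)
}

# genomic positions of the spliced CDS, ordered 5'->3' in mRNA orientation
cds_genomic_positions <- function(m) {
  pos <- unlist(Map(seq.int, m$exon_starts, m$exon_ends), use.names = FALSE)
  pos <- pos[pos >= m$cds_start & pos <= m$cds_end]
  if (m$strand == "-") rev(pos) else pos
}

#' Coding consequence of a variant within one transcript
#'
#' Maps the genomic change onto the spliced CDS (reverse-complementing alleles
#' for minus-strand models), translates the affected codon with the standard
#' genetic code (stop rendered as `X`), and assigns one of: synonymous SNV,
#' nonsynonymous SNV, stopgain, stoploss, frameshift/nonframeshift insertion
#' or deletion. The cDNA string uses the `c.<ref><pos><alt>` dialect.
#'
#' @param variant one-row variant table (normalized; first REF base in CDS).
#' @param tx one transcript model (row of the transcript table, or an entry of
#'   a `tx_db`).
#' @return list with kind, cdna_change, protein_change, exon_number,
#'   transcript_id, gene_symbol.
#' @export
coding_consequence <- function(variant, tx) {
  m <- if (is.list(tx) && !is.data.frame(tx) && !is.null(tx$exon_starts) &&
           is.integer(tx$exon_starts)) tx else prepare_tx_db(tx)$models[[1]]
  pos <- variant$pos[1]; ref <- variant$ref[1]; alt <- variant$alt[1]
  cdspos <- cds_genomic_positions(m)
  i <- match(pos, cdspos)
  if (is.na(i))
    stopf("variant %s:%d falls outside the CDS of %s", variant$chrom[1], pos,
          m$transcript_id)
  exon_idx <- which(pos >= m$exon_starts & pos <= m$exon_ends)
  exon_number <- if (m$strand == "+") exon_idx else length(m$exon_starts) - exon_idx + 1L
  rn <- nchar(ref); an <- nchar(alt)
  if (rn == 1L && an == 1L) {
    ref_c <- if (m$strand == "+") ref else comp_base(ref)
    alt_c <- if (m$strand == "+") alt else comp_base(alt)
    got <- substr(m$cds_seq, i, i)
    if (got != ref_c)
      stopf("REF base %s disagrees with CDS base %s of %s at cds position %d",
            ref_c, got, m$transcript_id, i)
    ci <- ceiling(i / 3)
    codon <- substr(m$cds_seq, 3L * ci - 2L, 3L * ci)
    off <- i - 3L * (ci - 1L)
    mut <- codon
    substr(mut, off, off) <- alt_c
    ref_aa <- translate_codon(codon)
    alt_aa <- translate_codon(mut)
    kind <- if (ref_aa == alt_aa) "synonymous SNV"
    else if (alt_aa == "X" && ref_aa != "X") "stopgain"
    else if (ref_aa == "X" && alt_aa != "X") "stoploss"
    else "nonsynonymous SNV"
    return(list(kind = kind,
                cdna_change = sprintf("c.%s%d%s", ref_c, i, alt_c),
                protein_change = sprintf("p.%s%d%s", ref_aa, ci, alt_aa),
                exon_number = exon_number, transcript_id = m$transcript_id,
                gene_symbol = m$gene_symbol))
  }
  # anchored indel: first base shared, remainder inserted or deleted
  len <- abs(an - rn)
  frameshift <- (len %% 3L) != 0L
  if (an > rn) {
    kind <- if (frameshift) "frameshift insertion" else "nonframeshift insertion"
    ins <- substr(alt, rn + 1L, an)
    if (m$strand == "-") ins <- revcomp(ins)
    cdna <- sprintf("c.%d_%dins%s", i, i + 1L, ins)
  } else {
    kind <- if (frameshift) "frameshift deletion" else "nonframeshift deletion"
    cdna <- sprintf("c.%d_%ddel", i + 1L, i + len)
  }
  ci <- ceiling((i + 1L) / 3)
  prot <- if (frameshift) sprintf("p.%s%dfs", translate_codon(
    substr(m$cds_seq, 3L * ci - 2L, 3L * ci)), ci)
  else sprintf("p.%s%d%s", translate_codon(substr(m$cds_seq, 3L * ci - 2L, 3L * ci)),
               ci, if (an > rn) "ins" else "del")
  list(kind = kind, cdna_change = cdna, protein_change = prot,
       exon_number = exon_number, transcript_id = m$transcript_id,
       gene_symbol = m$gene_symbol)
}

#' Annotate variants with region, consequences and database memberships
#'
#' The most severe region class across overlapping transcripts is reported
#' (exonic variants list only the consequences of transcripts whose CDS they
#' hit), and one logical membership flag is attached per database.
#'
#' @param variants normalized variant table.
#' @param tx_db transcript models.
#' @param databases named list of variant-key character vectors.
#' @return data.frame: the variants plus region, genes, kind, cdna_change,
#'   protein_change, transcript_id, exon_number and one `in_<db>` column per
#'   database.
#' @export
annotate_variants <- function(variants, tx_db, databases = list()) {
  db <- prepare_tx_db(tx_db)
  cls <- classify_region(variants, db)
  out <- cbind(variants, cls, stringsAsFactors = FALSE)
  out$kind <- NA_character_
  out$cdna_change <- NA_character_
  out$protein_change <- NA_character_
  out$transcript_id <- NA_character_
  out$exon_number <- NA_integer_
  ids <- vapply(db$models, `[[`, "", "transcript_id")
  ex <- which(out$region == "exonic")
  for (i in ex) {
    tid <- strsplit(out$transcript_ids[i], ",", fixed = TRUE)[[1]][1]
    m <- db$models[[match(tid, ids)]]
    cc <- coding_consequence(variants[i, , drop = FALSE], m)
    out$kind[i] <- cc$kind
    out$cdna_change[i] <- cc$cdna_change
    out$protein_change[i] <- cc$protein_change
    out$transcript_id[i] <- cc$transcript_id
    out$exon_number[i] <- cc$exon_number
  }
  if (length(databases)) {
    keys <- variant_key(variants)
    for (nm in names(databases)) {
      out[[paste0("in_", nm)]] <- keys %in% databases[[nm]]
    }
  }
  out
}
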