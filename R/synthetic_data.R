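# Seeded generators for every input the pipeline consumes. The cohort
# generator plants variant categories so that running the full funnel
# reproduces a prescribed stage-by-stage count profile exactly, for any seed.

#' Stage-by-stage funnel count profile
#'
#' Defaults realize the study conditions of a tumor/normal exome pair:
#' 32,917 tumor and 30,939 normal calls sharing 16,700 germline variants; of
#' the 16,217 tumor-exclusive calls 15,119 sit in the dbSNP-like catalogue and
#' 115 in the other nine databases, leaving 983 novel; 582 of those are exonic
#' (91 synonymous, 325 functional SNVs, 166 indels) across 423 unique genes
#' (68 multi-hit extras), 21 of which overlap a 723-gene Cancer Gene Census
#' mock (19 Tier 1).
#'
#' @param n_tumor_total,n_normal_total total calls per sample.
#' @param n_shared germline calls present in both.
#' @param n_in_avsnp150 tumor-exclusive calls in the dbSNP-like catalogue.
#' @param n_in_other_dbs tumor-exclusive calls in the other nine databases.
#' @param n_novel calls in no database.
#' @param n_exonic,n_synonymous,n_functional_snv,n_functional_other exonic
#'   composition (synonymous + functional SNV + other = exonic).
#' @param n_genes unique genes hit by functional calls.
#' @param multi_hit_extra functional calls beyond one per gene.
#' @param n_cgc_common,n_cgc_tier1,cgc_total Cancer Gene Census overlap design.
#' @return validated list of class `funnel_profile`.
#' @export
funnel_profile <- function(n_tumor_total = 32917L, n_normal_total = 30939L,
                           n_shared = 16700L, n_in_avsnp150 = 15119L,
                           n_in_other_dbs = 115L, n_novel = 983L,
                           n_exonic = 582L, n_synonymous = 91L,
                           n_functional_snv = 325L, n_functional_other = 166L,
                           n_genes = 423L, multi_hit_extra = 68L,
                           n_cgc_common = 21L, n_cgc_tier1 = 19L,
                           cgc_total = 723L) {
  p <- lapply(as.list(environment()), as.integer)
  class(p) <- "funnel_profile"
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  chk <- function(ok, what) if (!ok) stopf("invalid funnel profile: %s", what)
  chk(p$n_shared <= min(p$n_tumor_total, p$n_normal_total),
      "n_shared must not exceed either sample total")
  chk(p$n_tumor_total - p$n_shared ==
        p$n_in_avsnp150 + p$n_in_other_dbs + p$n_novel,
      "tumor-exclusive count must equal avsnp150 + other-db + novel members")
  chk(p$n_exonic <= p$n_novel, "n_exonic must not exceed n_novel")
  chk(p$n_synonymous + p$n_functional_snv + p$n_functional_other == p$n_exonic,
      "synonymous + functional SNV + functional other must equal n_exonic")
  chk(p$n_functional_snv + p$n_functional_other ==
        p$n_genes + p$multi_hit_extra,
      "functional variants must equal n_genes + multi_hit_extra")
  chk(p$n_cgc_tier1 <= p$n_cgc_common, "n_cgc_tier1 must not exceed n_cgc_common")
  chk(p$n_cgc_common <= min(p$n_genes, p$cgc_total),
      "n_cgc_common must not exceed min(n_genes, cgc_total)")
  chk(p$n_genes >= 1 && p$n_functional_snv >= 1, "at least one functional SNV gene")
  invisible(p)
}

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

UTR_LEN <- 60L
INTRON_LEN <- 150L
GENE_GAP <- 3200L
TARGET_PAD <- 1500L

# gene symbol, transcript id, strand, per-exon CDS widths (mRNA order) and
# forced codons for the worked-example genes
showcase_specs <- function() {
  list(
    list(gene = "CSF2RB", tx = "NM_000395", strand = "+",
         cds_widths = c(120L, 120L, 120L, 120L, 120L, 300L),
         forced = c("230" = "AGC")),
    list(gene = "KCNQ3", tx = "NM_001204824", strand = "+",
         cds_widths = c(120L, 120L, 120L), forced = c("98" = "CAA")),
    list(gene = "NRCAM", tx = "NM_001037132", strand = "-",
         cds_widths = c(120L, 120L, 120L), forced = c("2" = "CAG")),
    list(gene = "SCN11A", tx = "NM_014139", strand = "+",
         cds_widths = c(600L, 600L, 600L, 600L, 858L), forced = c("1085" = "AAG"))
  )
}

#' Generate a synthetic reference chromosome with transcript models
#'
#' Lays out non-overlapping multi-exon genes along one chromosome, each with a
#' valid ATG...stop CDS (no internal stops), 60 bp UTRs and 150 bp introns;
#' roughly a quarter of the bulk genes are on the minus strand. The first four
#' genes reproduce worked-example transcripts (a CSF2RB-like NM_000395 whose
#' codon 230 is AGC spanning CDS positions 688-690, plus KCNQ3-, NRCAM- and
#' SCN11A-like models with their known codons). Homopolymer runs are written
#' into the downstream target padding of every gene to exercise indel
#' left-normalization.
#'
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @param n_genes number of genes (>= 4 enables the showcase transcripts).
#' @param chrom chromosome name.
#' @return list with `reference` (named chromosome string), `transcripts`
#'   (data.frame incl. `cds_seq`), `targets` (1-based intervals), `hp_runs`
#'   (homopolymer run table) and `chrom`.
#' @export
generate_reference_and_transcripts <- function(seed = 230L, n_genes = 428L,
                                               chrom = "22") {
  set.seed(seed)
  show <- if (n_genes >= 4L) showcase_specs() else list()
  n_bulk <- n_genes - length(show)
  specs <- c(show, lapply(seq_len(n_bulk), function(i) {
    list(gene = sprintf("GENE%04d", i), tx = sprintf("NM_9%06d", i),
         strand = sample(c("+", "-"), 1, prob = c(0.75, 0.25)),
         cds_widths = c(120L, 120L, 120L), forced = character(0))
  }))

  cursor <- 2001L
  rows <- vector("list", length(specs))
  run_rows <- vector("list", length(specs))
  genome_edits <- vector("list", length(specs))
  for (gi in seq_along(specs)) {
    s <- specs[[gi]]
    cw <- s$cds_widths
    k <- length(cw)
    w_m <- cw
    w_m[1] <- w_m[1] + UTR_LEN
    w_m[k] <- w_m[k] + UTR_LEN
    w_g <- if (s$strand == "+") w_m else rev(w_m)
    es <- integer(k); ee <- integer(k)
    pos <- cursor
    for (i in seq_len(k)) {
      es[i] <- pos
      ee[i] <- pos + w_g[i] - 1L
      pos <- ee[i] + INTRON_LEN + 1L
    }
    tx_start <- es[1]; tx_end <- ee[k]
    n_cod <- sum(cw) %/% 3L
    codons <- c("ATG", sample(SENSE_CODONS, n_cod - 2L, replace = TRUE), "TAA")
    if (length(s$forced)) codons[as.integer(names(s$forced))] <- unname(s$forced)
    cds <- paste(codons, collapse = "")
    mrna <- c(sample(BASES, UTR_LEN, replace = TRUE),
              strsplit(cds, "", fixed = TRUE)[[1]],
              sample(BASES, UTR_LEN, replace = TRUE))
    rows[[gi]] <- data.frame(
      transcript_id = s$tx, gene_symbol = s$gene, chrom = chrom,
      strand = s$strand,
      exon_starts = paste(es, collapse = ","),
      exon_ends = paste(ee, collapse = ","),
      cds_start = tx_start + UTR_LEN, cds_end = tx_end - UTR_LEN,
      cds_seq = cds, stringsAsFactors = FALSE)
    genome_edits[[gi]] <- list(
      positions = unlist(Map(seq.int, es, ee), use.names = FALSE),
      bases = if (s$strand == "+") mrna else comp_base(rev(mrna)))
    # two homopolymer runs in the downstream target pad (beyond the 1 kb
    # flank windows so they never change a region class)
    r1 <- tx_end + sample(1050:1180, 1)
    r2 <- tx_end + sample(1250:1380, 1)
    b <- sample(BASES, 2)
    run_rows[[gi]] <- data.frame(start = c(r1, r2), base = b, len = 8L,
                                 stringsAsFactors = FALSE)
    cursor <- tx_end + GENE_GAP
  }
  tx <- do.call(rbind, rows)
  runs <- do.call(rbind, run_rows)

  genome_len <- cursor + 2000L
  genome <- sample(BASES, genome_len, replace = TRUE)
  for (e in genome_edits) genome[e$positions] <- e$bases
  for (i in seq_len(nrow(runs))) {
    r <- runs$start[i]; b <- runs$base[i]
    genome[r:(r + 7L)] <- b
    x <- sample(setdiff(BASES, b), 1)
    genome[r - 1L] <- x
    genome[r + 8L] <- x
  }
  starts <- parse_int_list(tx$exon_starts)
  ends <- parse_int_list(tx$exon_ends)
  targets <- data.frame(
    chrom = chrom,
    start = pmax(vapply(starts, min, 0L) - TARGET_PAD, 1L),
    end = vapply(ends, max, 0L) + TARGET_PAD, stringsAsFactors = FALSE)
  reference <- stats::setNames(paste(genome, collapse = ""), chrom)
  list(reference = reference, transcripts = tx, targets = targets,
       hp_runs = runs, chrom = chrom)
}

# ---- planting helpers ------------------------------------------------------

new_plant_state <- function(genome_len) {
  env <- new.env(parent = emptyenv())
  env$used <- logical(genome_len)
  env
}

res_free <- function(st, a, b) !any(st$used[max(1L, a):b])
res_take <- function(st, a, b) st$used[max(1L, a):b] <- TRUE

strand_allele <- function(x, strand) if (strand == "+") x else comp_base(x)

plant_specific_snv <- function(m, cdspos, cds_i, alt_c, st) {
  pos <- cdspos[cds_i]
  ref_c <- substr(m$cds_seq, cds_i, cds_i)
  if (!res_free(st, pos, pos)) stopf("showcase position already occupied")
  res_take(st, pos, pos)
  list(pos = pos, ref = strand_allele(ref_c, m$strand),
       alt = strand_allele(alt_c, m$strand))
}

plant_coding_snv <- function(m, cdspos, want_syn, st) {
  n_cod <- nchar(m$cds_seq) %/% 3L
  for (c_i in sample(2:(n_cod - 1L))) {
    codon <- substr(m$cds_seq, 3L * c_i - 2L, 3L * c_i)
    aa <- translate_codon(codon)
    for (j in sample(1:3)) {
      i <- 3L * (c_i - 1L) + j
      pos <- cdspos[i]
      if (!res_free(st, pos, pos)) next
      ref_c <- substr(codon, j, j)
      for (alt_c in sample(setdiff(BASES, ref_c))) {
        mut <- codon
        substr(mut, j, j) <- alt_c
        syn <- translate_codon(mut) == aa
        if (syn == want_syn) {
          res_take(st, pos, pos)
          return(list(pos = pos, ref = strand_allele(ref_c, m$strand),
                      alt = strand_allele(alt_c, m$strand)))
        }
      }
    }
  }
  stopf("no %s site available in %s",
        if (want_syn) "synonymous" else "nonsynonymous", m$transcript_id)
}

cds_segments <- function(m) {
  s <- pmax(m$exon_starts, m$cds_start)
  e <- pmin(m$exon_ends, m$cds_end)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

plant_coding_indel <- function(m, type, genestring, st) {
  seg <- cds_segments(m)
  d <- if (type %in% c("fs_del", "fs_ins")) 1L else 3L
  for (attempt in 1:80) {
    si <- sample(nrow(seg), 1)
    lo <- seg$start[si] + 6L
    hi <- seg$end[si] - (d + 8L)
    if (hi <= lo) next
    p <- sample(lo:hi, 1)
    if (!res_free(st, p - 8L, p + d + 8L)) next
    anchor <- substr(genestring, p, p)
    if (type %in% c("fs_del", "nf_del")) {
      ref <- substr(genestring, p, p + d)
      alt <- anchor
    } else {
      ref <- anchor
      alt <- paste0(anchor, paste(sample(BASES, d, replace = TRUE), collapse = ""))
    }
    nv <- normalize_one(p, ref, alt, genestring)
    # keep the normalized anchor inside this CDS segment
    if (nv$pos < seg$start[si] || nv$pos > seg$end[si]) next
    res_take(st, nv$pos - 2L, p + d + 4L)
    return(list(pos_raw = p, ref_raw = ref, alt_raw = alt,
                pos = nv$pos, ref = nv$ref, alt = nv$alt))
  }
  stopf("could not place a coding indel in %s", m$transcript_id)
}

plant_nonexonic <- function(m, class, genestring, st) {
  k <- length(m$exon_starts)
  for (attempt in 1:80) {
    pos <- switch(class,
      intronic = {
        i <- sample(k - 1L, 1)
        sample((m$exon_ends[i] + 4L):(m$exon_starts[i + 1L] - 4L), 1)
      },
      splicing = {
        i <- sample(k - 1L, 1)
        m$exon_ends[i] + sample(1:2, 1)
      },
      UTR5 = {
        left <- (m$strand == "+")
        if (left) sample(m$exon_starts[1]:(m$cds_start - 1L), 1)
        else sample((m$cds_end + 1L):m$exon_ends[k], 1)
      },
      UTR3 = {
        left <- (m$strand == "-")
        if (left) sample(m$exon_starts[1]:(m$cds_start - 1L), 1)
        else sample((m$cds_end + 1L):m$exon_ends[k], 1)
      },
      upstream = {
        if (m$strand == "+") m$tx_start - sample(100:950, 1)
        else m$tx_end + sample(100:950, 1)
      },
      downstream = {
        if (m$strand == "+") m$tx_end + sample(100:950, 1)
        else m$tx_start - sample(100:950, 1)
      },
      stopf("unknown region class %s", class))
    if (!res_free(st, pos, pos)) next
    ref <- substr(genestring, pos, pos)
    alt <- sample(setdiff(BASES, ref), 1)
    res_take(st, pos, pos)
    return(list(pos = pos, ref = ref, alt = alt))
  }
  stopf("could not place a %s variant near %s", class, m$transcript_id)
}

rand_alt <- function(ref) {
  idx <- match(ref, BASES)
  shift <- sample(3L, length(ref), replace = TRUE)
  BASES[((idx - 1L + shift) %% 4L) + 1L]
}

# transition-biased alternate alleles: 73% transitions gives the bulk call set
# a coding-exome-like Ti/Tv of ~2.7
TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
ti_biased_alt <- function(ref, p_transition = 0.73) {
  n <- length(ref)
  alt <- unname(TRANSITION_PARTNER[ref])
  tv <- stats::runif(n) >= p_transition
  if (any(tv)) {
    pick2 <- function(r) sample(setdiff(BASES, c(r, TRANSITION_PARTNER[[r]])), 1)
    alt[tv] <- vapply(ref[tv], pick2, "", USE.NAMES = FALSE)
  }
  alt
}

with_metrics <- function(chrom, pos, ref, alt, sample_id) {
  n <- length(pos)
  td <- 51L + stats::rpois(n, 100)
  vd <- 16L + as.integer(floor((td - 16L) * stats::runif(n, 0.2, 0.8)))
  variant_tbl(chrom = chrom, pos = pos, ref = ref, alt = alt,
              qual = round(stats::runif(n, 60, 999), 1),
              total_depth = td, variant_depth = vd,
              call_p = round(stats::runif(n, 1e-6, 0.009), 6),
              sample_id = sample_id)
}

key_of <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

NOVELTY_DB_NAMES <- c("COSMIC", "ExAC_ALL", "GME", "esp", "gnomAD", "clinvar",
                      "ICGC", "Nci60", "1000g")

#' Generate the novelty database key tables for a cohort
#'
#' avsnp150 holds exactly the planted dbSNP-like members (plus the shared
#' germline keys and seed-dependent decoys absent from the cohort); the nine
#' other catalogues partition the planted other-database members round-robin,
#' each with its own decoys. Decoys never collide with cohort keys.
#'
#' @param cohort a (possibly partial) cohort object carrying `truth` key sets,
#'   `chrom` and `decoy_pool` (free in-target positions with their reference
#'   base).
#' @param profile the cohort's [funnel_profile()] (unused sizes are taken from
#'   the truth sets).
#' @param seed RNG seed for the decoy draw.
#' @return named list of variant-key vectors (avsnp150 + nine others).
#' @export
generate_databases <- function(cohort, profile, seed = 230L) {
  set.seed(seed)
  pool <- cohort$decoy_pool
  n_avsnp_decoy <- min(1500L, nrow(pool) %/% 3L)
  n_other_decoy <- min(100L, nrow(pool) %/% 30L)
  take <- sample(nrow(pool), n_avsnp_decoy + 9L * n_other_decoy)
  dk <- key_of(cohort$chrom, pool$pos[take], pool$ref[take], rand_alt(pool$ref[take]))
  dbs <- vector("list", 10L)
  names(dbs) <- c("avsnp150", NOVELTY_DB_NAMES)
  dbs[["avsnp150"]] <- c(cohort$truth$keys_avsnp, cohort$truth$keys_shared,
                         dk[seq_len(n_avsnp_decoy)])
  other <- cohort$truth$keys_otherdb
  rest <- dk[-seq_len(n_avsnp_decoy)]
  for (i in seq_along(NOVELTY_DB_NAMES)) {
    members <- if (length(other)) other[seq_along(other) %% 9L == (i %% 9L)] else character(0)
    dec <- if (n_other_decoy) rest[((i - 1L) * n_other_decoy + 1L):(i * n_other_decoy)] else character(0)
    dbs[[NOVELTY_DB_NAMES[i]]] <- c(members, dec)
  }
  dbs
}

#' Generate a complete synthetic tumor/normal cohort
#'
#' Plants variants so that the full pipeline reproduces every count of the
#' profile exactly: shared germline variants in both samples (a fraction of
#' them homopolymer indels written un-left-aligned in the tumor VCF and
#' normalized in the normal VCF), tumor-exclusive variants partitioned into
#' dbSNP-like members, other-database members and novel variants, the novel
#' set split into non-exonic classes and exonic variants with the prescribed
#' synonymous / functional-SNV / indel composition, gene assignment yielding
#' exactly `n_genes` unique genes, and a Cancer Gene Census mock overlapping
#' in exactly `n_cgc_common` genes. Regenerating with the same seed is
#' byte-identical and every planted variant lies inside the target regions.
#'
#' @param profile a [funnel_profile()].
#' @param seed master RNG seed.
#' @param out_dir optional directory; when given, the complete fixture
#'   (FASTA, transcript TSV + CDS FASTA, BED, two VCFs, database tables, CGC
#'   table, pathway GMT, predictor calls, truth tables, manifest) is written.
#' @return cohort object (list) with the in-memory inputs, the planted-truth
#'   key sets under `$truth`, and `$paths` when files were written.
#' @export
generate_cohort <- function(profile = funnel_profile(), seed = 230L,
                            out_dir = NULL) {
  validate_profile(profile)
  reftx <- generate_reference_and_transcripts(
    seed, n_genes = max(profile$n_genes + 5L, 12L))
  chrom <- reftx$chrom
  genestring <- reftx$reference[[chrom]]
  db <- prepare_tx_db(reftx$transcripts)
  models <- db$models
  cdspos <- lapply(models, cds_genomic_positions)
  st <- new_plant_state(nchar(genestring))
  for (i in seq_len(nrow(reftx$hp_runs)))   # keep bulk SNVs out of the runs
    res_take(st, reftx$hp_runs$start[i] - 2L, reftx$hp_runs$start[i] + 9L)

  set.seed(seed + 1L)
  ng <- profile$n_genes
  gene_syms <- vapply(models[seq_len(ng)], `[[`, "", "gene_symbol")

  # --- novel exonic: functional slot plan -----------------------------------
  n_show <- if (ng >= 4L && profile$n_functional_snv >= 4L) 4L else 0L
  extra_pool <- if (ng > n_show) (n_show + 1L):ng else seq_len(ng)
  extra_idx <- extra_pool[((seq_len(profile$multi_hit_extra) - 1L) %%
                             length(extra_pool)) + 1L]
  slot_gene <- c(seq_len(ng), extra_idx)
  indel_types <- rep_len(c("fs_del", "fs_ins", "nf_del", "nf_ins"),
                         profile$n_functional_other)
  open_types <- sample(c(rep("snv", profile$n_functional_snv - n_show),
                         indel_types))
  slot_type <- character(length(slot_gene))
  slot_type[seq_len(n_show)] <- "showcase"
  slot_type[(n_show + 1L):length(slot_gene)] <- open_types

  showcase_cds <- list(CSF2RB = c(689L, NA), KCNQ3 = c(293L, NA),
                       NRCAM = c(4L, NA), SCN11A = c(3253L, NA))
  showcase_alt <- c(CSF2RB = "T", KCNQ3 = "G", NRCAM = "G", SCN11A = "C")

  fun_rows <- vector("list", length(slot_gene))
  for (s in seq_along(slot_gene)) {
    gi <- slot_gene[s]
    m <- models[[gi]]
    if (slot_type[s] == "showcase") {
      sym <- m$gene_symbol
      pv <- plant_specific_snv(m, cdspos[[gi]], showcase_cds[[sym]][1],
                               showcase_alt[[sym]], st)
      fun_rows[[s]] <- data.frame(pos = pv$pos, ref = pv$ref, alt = pv$alt,
                                  pos_raw = pv$pos, ref_raw = pv$ref,
                                  alt_raw = pv$alt, gene = sym,
                                  category = "functional_snv",
                                  stringsAsFactors = FALSE)
    } else if (slot_type[s] == "snv") {
      pv <- plant_coding_snv(m, cdspos[[gi]], want_syn = FALSE, st)
      fun_rows[[s]] <- data.frame(pos = pv$pos, ref = pv$ref, alt = pv$alt,
                                  pos_raw = pv$pos, ref_raw = pv$ref,
                                  alt_raw = pv$alt, gene = m$gene_symbol,
                                  category = "functional_snv",
                                  stringsAsFactors = FALSE)
    } else {
      pv <- plant_coding_indel(m, slot_type[s], genestring, st)
      fun_rows[[s]] <- data.frame(pos = pv$pos, ref = pv$ref, alt = pv$alt,
                                  pos_raw = pv$pos_raw, ref_raw = pv$ref_raw,
                                  alt_raw = pv$alt_raw, gene = m$gene_symbol,
                                  category = "functional_other",
                                  stringsAsFactors = FALSE)
    }
  }
  fun <- do.call(rbind, fun_rows)

  # --- novel synonymous and non-exonic --------------------------------------
  syn_gene <- rep_len(seq_len(ng), profile$n_synonymous)
  syn_rows <- lapply(syn_gene, function(gi) {
    pv <- plant_coding_snv(models[[gi]], cdspos[[gi]], want_syn = TRUE, st)
    data.frame(pos = pv$pos, ref = pv$ref, alt = pv$alt, stringsAsFactors = FALSE)
  })
  syn <- if (length(syn_rows)) do.call(rbind, syn_rows) else
    data.frame(pos = integer(0), ref = character(0), alt = character(0))

  n_ne <- profile$n_novel - profile$n_exonic
  ne_class <- rep_len(c("intronic", "splicing", "UTR5", "UTR3",
                        "upstream", "downstream"), n_ne)
  ne_gene <- rep_len(seq_along(models), n_ne)
  ne_rows <- lapply(seq_len(n_ne), function(i) {
    pv <- plant_nonexonic(models[[ne_gene[i]]], ne_class[i], genestring, st)
    data.frame(pos = pv$pos, ref = pv$ref, alt = pv$alt,
               class = ne_class[i], stringsAsFactors = FALSE)
  })
  ne <- if (n_ne) do.call(rbind, ne_rows) else
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               class = character(0))

  # --- bulk germline / database / normal-only SNVs and shared indels --------
  runs <- reftx$hp_runs
  n_shared_indel <- min(600L, profile$n_shared %/% 4L, nrow(runs))
  n_shared_snv <- profile$n_shared - n_shared_indel
  n_normal_only <- profile$n_normal_total - profile$n_shared

  tvec <- logical(nchar(genestring))
  for (i in seq_len(nrow(reftx$targets)))
    tvec[reftx$targets$start[i]:reftx$targets$end[i]] <- TRUE
  pool <- which(tvec & !st$used)
  n_bulk <- n_shared_snv + profile$n_in_avsnp150 + profile$n_in_other_dbs +
    n_normal_only
  n_decoy_pool <- min(6000L, length(pool) - n_bulk)
  if (length(pool) < n_bulk + 100L)
    stopf("reference too small for the requested profile")
  draw <- sample(pool, n_bulk + n_decoy_pool)
  bulk_pos <- draw[seq_len(n_bulk)]
  decoy_pos <- sort(draw[-seq_len(n_bulk)])
  bulk_ref <- substring(genestring, bulk_pos, bulk_pos)
  bulk_alt <- ti_biased_alt(bulk_ref)
  cut <- cumsum(c(n_shared_snv, profile$n_in_avsnp150, profile$n_in_other_dbs,
                  n_normal_only))
  grp <- rep(c("shared", "avsnp", "otherdb", "normal_only"),
             c(n_shared_snv, profile$n_in_avsnp150, profile$n_in_other_dbs,
               n_normal_only))

  ri <- if (n_shared_indel) sample(nrow(runs), n_shared_indel) else integer(0)
  x <- substring(genestring, runs$start[ri] - 1L, runs$start[ri] - 1L)
  b <- runs$base[ri]
  ind_norm <- data.frame(pos = runs$start[ri] - 1L, ref = paste0(x, b), alt = x,
                         stringsAsFactors = FALSE)
  ind_denorm <- data.frame(pos = runs$start[ri] + 3L, ref = paste0(b, b), alt = b,
                           stringsAsFactors = FALSE)
  if (!n_shared_indel) ind_norm <- ind_denorm <-
    data.frame(pos = integer(0), ref = character(0), alt = character(0))

  # --- assemble sample tables ------------------------------------------------
  shared_snv_pos <- bulk_pos[grp == "shared"]
  shared_snv_ref <- bulk_ref[grp == "shared"]
  shared_snv_alt <- bulk_alt[grp == "shared"]

  tumor <- with_metrics(chrom,
    pos = c(shared_snv_pos, ind_denorm$pos, bulk_pos[grp == "avsnp"],
            bulk_pos[grp == "otherdb"], fun$pos_raw, syn$pos, ne$pos),
    ref = c(shared_snv_ref, ind_denorm$ref, bulk_ref[grp == "avsnp"],
            bulk_ref[grp == "otherdb"], fun$ref_raw, syn$ref, ne$ref),
    alt = c(shared_snv_alt, ind_denorm$alt, bulk_alt[grp == "avsnp"],
            bulk_alt[grp == "otherdb"], fun$alt_raw, syn$alt, ne$alt),
    sample_id = "TUMOR")
  normal <- with_metrics(chrom,
    pos = c(shared_snv_pos, ind_norm$pos, bulk_pos[grp == "normal_only"]),
    ref = c(shared_snv_ref, ind_norm$ref, bulk_ref[grp == "normal_only"]),
    alt = c(shared_snv_alt, ind_norm$alt, bulk_alt[grp == "normal_only"]),
    sample_id = "NORMAL")
  tumor <- tumor[order(tumor$pos), ]
  normal <- normal[order(normal$pos), ]
  rownames(tumor) <- rownames(normal) <- NULL

  truth <- list(
    keys_shared = c(key_of(chrom, shared_snv_pos, shared_snv_ref, shared_snv_alt),
                    key_of(chrom, ind_norm$pos, ind_norm$ref, ind_norm$alt)),
    keys_avsnp = key_of(chrom, bulk_pos[grp == "avsnp"],
                        bulk_ref[grp == "avsnp"], bulk_alt[grp == "avsnp"]),
    keys_otherdb = key_of(chrom, bulk_pos[grp == "otherdb"],
                          bulk_ref[grp == "otherdb"], bulk_alt[grp == "otherdb"]),
    keys_novel = key_of(chrom, c(fun$pos, syn$pos, ne$pos),
                        c(fun$ref, syn$ref, ne$ref),
                        c(fun$alt, syn$alt, ne$alt)),
    functional = data.frame(
      variant_key = key_of(chrom, fun$pos, fun$ref, fun$alt),
      gene = fun$gene, category = fun$category, stringsAsFactors = FALSE),
    keys_synonymous = key_of(chrom, syn$pos, syn$ref, syn$alt),
    nonexonic = data.frame(
      variant_key = key_of(chrom, ne$pos, ne$ref, ne$alt),
      class = ne$class, stringsAsFactors = FALSE))
  all_keys <- c(truth$keys_shared, truth$keys_avsnp, truth$keys_otherdb,
                truth$keys_novel)
  if (anyDuplicated(all_keys))
    stopf("internal error: planted variant keys collide")

  cohort <- list(
    profile = profile, seed = seed, chrom = chrom,
    reference = reftx$reference, transcripts = reftx$transcripts,
    targets = reftx$targets, tumor = tumor, normal = normal,
    truth = truth,
    decoy_pool = data.frame(pos = decoy_pos,
                            ref = substring(genestring, decoy_pos, decoy_pos),
                            stringsAsFactors = FALSE))
  cohort$databases <- generate_databases(cohort, profile, seed + 3L)

  # --- CGC mock ---------------------------------------------------------------
  common <- sample(gene_syms, profile$n_cgc_common)
  tiers <- c(rep(1L, profile$n_cgc_tier1),
             rep(2L, profile$n_cgc_common - profile$n_cgc_tier1))
  n_dec <- profile$cgc_total - profile$n_cgc_common
  cohort$cgc <- data.frame(
    gene_symbol = toupper(c(common, sprintf("CGCD%04d", seq_len(n_dec)))),
    tier = c(tiers, sample(1:2, n_dec, replace = TRUE, prob = c(0.8, 0.2))),
    stringsAsFactors = FALSE)

  cohort$predictor_calls <- make_predictor_calls(cohort, n_show)
  cohort$pathway_fixture <- generate_pathway_db(seed + 7L)

  if (!is.null(out_dir)) cohort$paths <- write_cohort(cohort, out_dir)
  invisible(cohort)
}

make_predictor_calls <- function(cohort, n_show) {
  methods <- names(PREDICTOR_VOCAB)
  rows <- list()
  fun <- cohort$truth$functional
  if (n_show == 4L) {
    show_keys <- fun$variant_key[match(c("CSF2RB", "KCNQ3", "NRCAM", "SCN11A"),
                                       fun$gene)]
    verdicts <- list(
      c("deleterious", "probably_damaging", "probably_damaging",
        "disease_causing", "deleterious"),
      c("deleterious", "possibly_damaging", "benign", "disease_causing", "neutral"),
      c("tolerated", "benign", "benign", "polymorphism", "neutral"),
      c("deleterious", "probably_damaging", "possibly_damaging",
        "disease_causing", "deleterious"))
    for (i in 1:4)
      rows[[i]] <- data.frame(variant_key = show_keys[i], method = methods,
                              raw_verdict = verdicts[[i]], stringsAsFactors = FALSE)
  }
  extra <- setdiff(fun$variant_key, unlist(lapply(rows, `[[`, "variant_key")))
  extra <- utils::head(extra, 50L)
  for (k in extra) {
    rv <- vapply(methods, function(m) sample(names(PREDICTOR_VOCAB[[m]]), 1), "")
    rows[[length(rows) + 1L]] <- data.frame(variant_key = k, method = methods,
                                            raw_verdict = unname(rv),
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate the pathway over-representation fixture
#'
#' A 13,870-gene universe, a 309-gene query with exactly 178 members in the
#' universe, and a pathway database in which exactly 695 pathways contain at
#' least one query gene; the first ten pathways mirror realistic small-set
#' sizes (33, 8, 8, 9, 52, 13, 53, 32, 2, 2).
#'
#' @param seed RNG seed.
#' @return list with `pathways` (GMT-style list), `universe`, `query`.
#' @export
generate_pathway_db <- function(seed = 230L) {
  set.seed(seed)
  universe <- sprintf("RG%05d", seq_len(13870L))
  found <- sample(universe, 178L)
  query <- sample(c(found, sprintf("QX%04d", seq_len(131L))))
  bg <- setdiff(universe, found)
  sizes <- c(33L, 8L, 8L, 9L, 52L, 13L, 53L, 32L, 2L, 2L)
  hits <- c(4L, 2L, 2L, 2L, 4L, 2L, 4L, 3L, 1L, 1L)
  mk <- function(id, K, k) {
    list(pathway_id = sprintf("PW%05d", id),
         name = sprintf("synthetic pathway %d (size %d)", id, K),
         genes = c(sample(found, k), sample(bg, K - k)))
  }
  pw <- vector("list", 895L)
  for (i in 1:10) pw[[i]] <- mk(i, sizes[i], hits[i])
  for (i in 11:695) {
    K <- sample(5:120, 1)
    pw[[i]] <- mk(i, K, sample(seq_len(min(6L, K)), 1))
  }
  for (i in 696:895) {
    K <- sample(5:120, 1)
    pw[[i]] <- list(pathway_id = sprintf("PW%05d", i),
                    name = sprintf("synthetic pathway %d (no query overlap)", i),
                    genes = sample(bg, K))
  }
  list(pathways = pw, universe = universe, query = query)
}

#' Generate a dose-response plate fixture
#'
#' An 8-point half-log dilution series in triplicate with multiplicative
#' Gaussian noise plus DMSO control wells. The default compound is a
#' ruxolitinib-like inhibitor with true IC50 0.94 uM, hill -1, top 100,
#' bottom 5 (concentrations are treated as micromolar throughout).
#'
#' @param compound_params list (or list of lists) with compound, ic50, hill,
#'   top, bottom.
#' @param noise_sd multiplicative noise standard deviation (0.05 = 5%).
#' @param seed RNG seed.
#' @param path optional CSV output path.
#' @return long-format plate data.frame (compound, concentration, replicate,
#'   luminescence), including DMSO wells at concentration 0.
#' @export
generate_dose_response <- function(compound_params = list(
                                     list(compound = "ruxolitinib", ic50 = 0.94,
                                          hill = -1, top = 100, bottom = 5)),
                                   noise_sd = 0.05, seed = 11L, path = NULL) {
  if (!is.null(compound_params$compound)) compound_params <- list(compound_params)
  set.seed(seed)
  conc <- 10^seq(2, -1.5, by = -0.5)
  lum0 <- 20000
  rows <- lapply(compound_params, function(p) {
    y <- fourpl_value(log10(conc), p$top, p$bottom, p$hill, log10(p$ic50))
    d <- expand.grid(replicate = 1:3, concentration = conc)
    mu <- lum0 * rep(y, each = 3) / 100
    data.frame(compound = p$compound, concentration = d$concentration,
               replicate = d$replicate,
               luminescence = mu * (1 + stats::rnorm(nrow(d), 0, noise_sd)),
               stringsAsFactors = FALSE)
  })
  dmso <- data.frame(compound = "DMSO", concentration = 0, replicate = 1:6,
                     luminescence = lum0 * (1 + stats::rnorm(6, 0, noise_sd)),
                     stringsAsFactors = FALSE)
  plate <- rbind(do.call(rbind, rows), dmso)
  if (!is.null(path)) utils::write.csv(plate, path, row.names = FALSE)
  plate
}

#' Generate the QC metric fixtures
#'
#' `"titv-kaimrc"`: 3,700 SNVs with per-type substitution counts A>G 700,
#' G>A 650, C>T 720, T>C 630 and 125 of each of the eight transversion types
#' (Ti/Tv = 2.7). `"dbsnp-conc"`: 1,000 SNVs of which exactly 962 are planted
#' in the accompanying mock dbSNP key set (concordance 96.2%).
#'
#' @param name fixture name.
#' @param seed RNG seed.
#' @return list with `variants` and `dbsnp_keys`.
#' @export
generate_qc_fixture <- function(name = c("titv-kaimrc", "dbsnp-conc"),
                                seed = 230L) {
  name <- match.arg(name)
  set.seed(seed)
  if (name == "titv-kaimrc") {
    subs <- c(rep("A>G", 700), rep("G>A", 650), rep("C>T", 720), rep("T>C", 630),
              rep(c("A>C", "A>T", "C>A", "C>G", "G>C", "G>T", "T>A", "T>G"),
                  each = 125))
    subs <- sample(subs)
    v <- variant_tbl(chrom = "Q1", pos = seq_along(subs),
                     ref = substr(subs, 1, 1), alt = substr(subs, 3, 3),
                     sample_id = "QCFIX")
    return(list(variants = v, dbsnp_keys = character(0)))
  }
  ref <- sample(BASES, 1000L, replace = TRUE)
  v <- variant_tbl(chrom = "Q1", pos = seq_len(1000L), ref = ref,
                   alt = rand_alt(ref), sample_id = "QCFIX")
  inset <- sample(1000L, 962L)
  decoys <- key_of("Q1", 2000L + seq_len(200L), "A", "G")
  list(variants = v, dbsnp_keys = c(variant_key(v)[inset], decoys))
}

# ---- fixture serialization -------------------------------------------------

write_database_dir <- function(databases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(databases)) {
    parts <- strsplit(databases[[nm]], ":", fixed = TRUE)
    df <- data.frame(chrom = vapply(parts, `[[`, "", 1),
                     pos = vapply(parts, `[[`, "", 2),
                     ref = vapply(parts, `[[`, "", 3),
                     alt = vapply(parts, `[[`, "", 4), stringsAsFactors = FALSE)
    write_tsv_base(df, file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}

write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    reference = file.path(out_dir, "reference.fa"),
    transcripts = file.path(out_dir, "transcripts.tsv"),
    cds_fasta = file.path(out_dir, "cds.fa"),
    targets = file.path(out_dir, "targets.bed"),
    tumor_vcf = file.path(out_dir, "tumor.vcf"),
    normal_vcf = file.path(out_dir, "normal.vcf"),
    db_dir = file.path(out_dir, "db"),
    cgc = file.path(out_dir, "cgc.tsv"),
    pathways = file.path(out_dir, "pathways.gmt"),
    universe = file.path(out_dir, "universe.txt"),
    query_genes = file.path(out_dir, "query_genes.txt"),
    predictor_calls = file.path(out_dir, "predictor_calls.tsv"),
    truth_dir = file.path(out_dir, "truth"),
    manifest = file.path(out_dir, "manifest.json"))
  write_reference_fasta(cohort$reference, p$reference)
  write_transcripts(cohort$transcripts, p$transcripts, p$cds_fasta)
  write_bed(cohort$targets, p$targets)
  write_vcf(cohort$tumor, p$tumor_vcf)
  write_vcf(cohort$normal, p$normal_vcf)
  write_database_dir(cohort$databases, p$db_dir)
  write_tsv_base(cohort$cgc, p$cgc)
  write_gmt(cohort$pathway_fixture$pathways, p$pathways)
  writeLines(cohort$pathway_fixture$universe, p$universe)
  writeLines(cohort$pathway_fixture$query, p$query_genes)
  write_tsv_base(cohort$predictor_calls, p$predictor_calls)
  dir.create(p$truth_dir, showWarnings = FALSE)
  write_tsv_base(cohort$truth$functional,
                 file.path(p$truth_dir, "novel_functional.tsv"))
  writeLines(cohort$truth$keys_novel, file.path(p$truth_dir, "novel_keys.txt"))
  jsonlite::write_json(
    list(seed = cohort$seed, profile = unclass(cohort$profile),
         chrom = cohort$chrom,
         files = lapply(p, basename)),
    p$manifest, auto_unbox = TRUE, pretty = TRUE)
  p
}
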