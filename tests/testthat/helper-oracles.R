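# Independent oracles and small fixtures shared across tests.

# Brute-force left-normalization oracle: enumerate every equivalent
# (pos, ref, alt) representation inside a window by exhaustive reconstruction
# of the mutated haplotype, then pick the parsimonious one (minimal total
# allele length) with minimal position. Independent of the package's
# truncate/extend algorithm.
bf_normalize <- function(pos, ref, alt, seq, window = 50L) {
  lo <- max(1L, pos - window)
  hi <- min(nchar(seq), pos + nchar(ref) + window)
  W <- substr(seq, lo, hi)
  M <- paste0(substr(seq, lo, pos - 1L), alt,
              substr(seq, pos + nchar(ref), hi))
  diff <- nchar(M) - nchar(W)
  best <- NULL
  for (p in seq_len(nchar(W))) {
    for (lr in 1:10) {
      la <- lr + diff
      if (la < 1L || p + lr - 1L > nchar(W)) next
      cref <- substr(W, p, p + lr - 1L)
      calt <- substr(M, p, p + la - 1L)
      if (cref == calt) next
      recon <- paste0(substr(W, 1L, p - 1L), calt,
                      substr(W, p + lr, nchar(W)))
      if (recon != M) next
      cand <- list(pos = lo + p - 1L, ref = cref, alt = calt, size = lr + la)
      if (is.null(best) || cand$size < best$size ||
          (cand$size == best$size && cand$pos < best$pos)) best <- cand
    }
  }
  best[c("pos", "ref", "alt")]
}

# random sequence with injected homopolymer runs
random_seq_with_runs <- function(len = 400L, n_runs = 12L) {
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  runs <- list()
  for (i in seq_len(n_runs)) {
    L <- sample(4:8, 1)
    r <- sample(20:(len - 20L), 1)
    b <- sample(c("A", "C", "G", "T"), 1)
    s[r:(r + L - 1L)] <- b
    runs[[i]] <- list(start = r, len = L, base = b)
  }
  list(seq = paste(s, collapse = ""), runs = runs)
}

# a random (possibly denormalized) indel representation inside a run
random_run_indel <- function(sq) {
  run <- sq$runs[[sample(length(sq$runs), 1)]]
  p <- run$start + sample(0:(run$len - 2L), 1)
  b <- substr(sq$seq, p, p)
  d <- sample(1:2, 1)
  if (stats::runif(1) < 0.5) {
    list(pos = p, ref = substr(sq$seq, p, p + d), alt = b)          # deletion
  } else {
    list(pos = p, ref = b, alt = paste0(b, strrep(b, d)))           # insertion
  }
}

# hand-built two-gene transcript fixture on a tiny reference, with a
# plus-strand gene and its strand-mirrored twin carrying the identical CDS
tiny_tx_fixture <- function() {
  # CDS (24 nt): ATG TAC GGA TTT CTG AAA CCC TAA
  cds <- "ATGTACGGATTTCTGAAACCCTAA"
  utr <- 6L
  pad <- "ACGTACGTAC"   # low-complexity-free padding
  # plus gene: exon1 = UTR5(6) + CDS 1..9, intron 20, exon2 = CDS 10..24 + UTR3(6)
  e1 <- paste0("TCTCTC", substr(cds, 1, 9))
  e2 <- paste0(substr(cds, 10, 24), "AGAGAG")
  intr <- "GTCCCCCCCCCCCCCCCCAG"
  left_flank <- strrep(pad, 120)   # 1200 bp
  right_gap <- strrep(pad, 300)    # 3000 bp between the two genes
  plus_start <- nchar(left_flank) + 1L
  plus_seq <- paste0(e1, intr, e2)
  minus_mrna <- paste0("TCTCTC", cds, "AGAGAG")
  # minus gene: identical exon widths; genomic sequence is the reverse
  # complement of (e1, intron, e2)
  minus_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus_seq)))
  genome <- paste0(left_flank, plus_seq, right_gap, minus_seq, strrep(pad, 120))
  p_es1 <- plus_start
  p_ee1 <- p_es1 + nchar(e1) - 1L
  p_es2 <- p_ee1 + nchar(intr) + 1L
  p_ee2 <- p_es2 + nchar(e2) - 1L
  m_es1 <- p_ee2 + nchar(right_gap) + 1L
  # minus gene exons mirror: genomic-first exon width = width(e2)
  m_ee1 <- m_es1 + nchar(e2) - 1L
  m_es2 <- m_ee1 + nchar(intr) + 1L
  m_ee2 <- m_es2 + nchar(e1) - 1L
  tx <- data.frame(
    transcript_id = c("TX_PLUS", "TX_MINUS"),
    gene_symbol = c("GPLUS", "GMINUS"),
    chrom = "T1", strand = c("+", "-"),
    exon_starts = c(paste(c(p_es1, p_es2), collapse = ","),
                    paste(c(m_es1, m_es2), collapse = ",")),
    exon_ends = c(paste(c(p_ee1, p_ee2), collapse = ","),
                  paste(c(m_ee1, m_ee2), collapse = ",")),
    cds_start = c(p_es1 + utr, m_es1 + utr),
    cds_end = c(p_ee2 - utr, m_ee2 - utr),
    cds_seq = cds, stringsAsFactors = FALSE)
  list(reference = c(T1 = genome), tx = tx, cds = cds,
       plus = list(es = c(p_es1, p_es2), ee = c(p_ee1, p_ee2)),
       minus = list(es = c(m_es1, m_es2), ee = c(m_ee1, m_ee2)))
}

# memoised full-size default cohort (shared by the acceptance tests)
.cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function() {
  if (is.null(.cohort_cache$co))
    .cohort_cache$co <- generate_cohort(funnel_profile(), seed = 230L)
  .cohort_cache$co
}

tiny_profile <- function() {
  funnel_profile(n_tumor_total = 40L, n_normal_total = 35L, n_shared = 20L,
                 n_in_avsnp150 = 8L, n_in_other_dbs = 3L, n_novel = 9L,
                 n_exonic = 6L, n_synonymous = 1L, n_functional_snv = 4L,
                 n_functional_other = 1L, n_genes = 5L, multi_hit_extra = 0L,
                 n_cgc_common = 2L, n_cgc_tier1 = 1L, cgc_total = 10L)
}

run_funnel_in_memory <- function(co, ...) {
  run_funnel(co$tumor, co$normal, co$reference, co$targets, co$transcripts,
             databases = co$databases, cgc = co$cgc, ...)
}
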