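# Region classification and coding consequences against transcript models.

test_that("region classes and precedence follow the declared rules", {
  fx <- tiny_tx_fixture()
  db <- prepare_tx_db(fx$tx)
  p <- fx$plus
  at <- function(pos) classify_region(variant_tbl("T1", pos, "A", "C"), db)
  # CDS exon base
  expect_equal(at(fx$tx$cds_start[1])$region, "exonic")
  expect_equal(at(fx$tx$cds_start[1])$genes, "GPLUS")
  # first and second intronic bases are splice sites; the third is intronic
  expect_equal(at(p$ee[1] + 1L)$region, "splicing")
  expect_equal(at(p$ee[1] + 2L)$region, "splicing")
  expect_equal(at(p$ee[1] + 3L)$region, "intronic")
  expect_equal(at(p$es[2] - 1L)$region, "splicing")
  # UTRs (plus strand: left UTR is 5')
  expect_equal(at(p$es[1])$region, "UTR5")
  expect_equal(at(p$ee[2])$region, "UTR3")
  # flanks, strand-aware
  expect_equal(at(p$es[1] - 500L)$region, "upstream")
  expect_equal(at(p$ee[2] + 500L)$region, "downstream")
  m <- fx$minus
  expect_equal(at(m$ee[2] + 500L)$region, "upstream")   # 5' side of minus gene
  expect_equal(at(m$es[1] - 500L)$region, "downstream")
  # far away is intergenic with no genes
  far <- at(p$ee[2] + 1500L)
  expect_equal(far$region, "intergenic")
  expect_equal(far$genes, "")
})

test_that("exonic beats intronic across overlapping transcripts and input order", {
  fx <- tiny_tx_fixture()
  # second transcript of the same gene region whose intron covers the
  # plus gene CDS position: same span, exons shifted so pos is intronic
  p <- fx$plus
  tx2 <- fx$tx[1, ]
  tx2$transcript_id <- "TX_ALT"
  tx2$gene_symbol <- "GALT"
  tx2$exon_starts <- paste(c(p$es[1] - 300L, p$es[2]), collapse = ",")
  tx2$exon_ends <- paste(c(p$es[1] - 250L, p$ee[2]), collapse = ",")
  tx2$cds_start <- p$es[2]
  tx2$cds_end <- fx$tx$cds_end[1]
  pos <- fx$tx$cds_start[1]  # exonic for TX_PLUS, intronic for TX_ALT
  for (ord in list(rbind(fx$tx, tx2), rbind(tx2, fx$tx))) {
    cls <- classify_region(variant_tbl("T1", pos, "A", "C"), prepare_tx_db(ord))
    expect_equal(cls$region, "exonic")
    expect_equal(cls$genes, "GPLUS")
  }
})

test_that("SNV consequences: nonsynonymous, wobble synonymous, stopgain, stoploss", {
  fx <- tiny_tx_fixture()
  db <- prepare_tx_db(fx$tx)
  m <- db$models[[1]]
  cpos <- somaticfunnel:::cds_genomic_positions(m)
  # CDS: ATG TAC GGA TTT CTG AAA CCC TAA
  # codon 2 TAC -> TAA is a stopgain (third base C>A)
  cc <- coding_consequence(variant_tbl("T1", cpos[6], "C", "A"), m)
  expect_equal(cc$kind, "stopgain")
  expect_equal(cc$protein_change, "p.Y2X")
  # codon 3 GGA -> GGG is synonymous wobble
  cc <- coding_consequence(variant_tbl("T1", cpos[9], "A", "G"), m)
  expect_equal(cc$kind, "synonymous SNV")
  expect_equal(cc$cdna_change, "c.A9G")
  expect_equal(cc$protein_change, "p.G3G")
  # codon 4 TTT -> TAT is nonsynonymous with positions in the second exon
  cc <- coding_consequence(variant_tbl("T1", cpos[11], "T", "A"), m)
  expect_equal(cc$kind, "nonsynonymous SNV")
  expect_equal(cc$cdna_change, "c.T11A")
  expect_equal(cc$protein_change, "p.F4Y")
  expect_equal(cc$exon_number, 2L)
  # stop codon 8 TAA -> CAA is a stoploss
  cc <- coding_consequence(variant_tbl("T1", cpos[22], "T", "C"), m)
  expect_equal(cc$kind, "stoploss")
  # a variant outside the CDS errors
  expect_error(coding_consequence(variant_tbl("T1", fx$plus$es[1], "T", "C"), m),
               "outside the CDS")
  # a REF disagreeing with the CDS errors
  expect_error(coding_consequence(variant_tbl("T1", cpos[9], "G", "T"), m),
               "disagrees")
})

test_that("minus-strand transcripts give the identical consequence as their mirror", {
  fx <- tiny_tx_fixture()
  db <- prepare_tx_db(fx$tx)
  mp <- db$models[[1]]; mm <- db$models[[2]]
  cp <- somaticfunnel:::cds_genomic_positions(mp)
  cm <- somaticfunnel:::cds_genomic_positions(mm)
  for (i in c(4L, 6L, 9L, 11L, 17L)) {
    ref_p <- substr(fx$cds, i, i)
    alt_p <- setdiff(c("A", "C", "G", "T"), ref_p)[1]
    ccp <- coding_consequence(variant_tbl("T1", cp[i], ref_p, alt_p), mp)
    ccm <- coding_consequence(
      variant_tbl("T1", cm[i], chartr("ACGT", "TGCA", ref_p),
                  chartr("ACGT", "TGCA", alt_p)), mm)
    expect_equal(ccm$kind, ccp$kind)
    expect_equal(ccm$cdna_change, ccp$cdna_change)
    expect_equal(ccm$protein_change, ccp$protein_change)
    expect_equal(ccm$exon_number, ccp$exon_number)
  }
})

test_that("synonymous calls leave the full translation unchanged", {
  fx <- tiny_tx_fixture()
  db <- prepare_tx_db(fx$tx)
  m <- db$models[[1]]
  cpos <- somaticfunnel:::cds_genomic_positions(m)
  # plain standard-code translation (no initiator-codon special casing)
  translate <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), no.init.codon = TRUE))
  for (i in seq_len(nchar(fx$cds))) {
    ref <- substr(fx$cds, i, i)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      cc <- coding_consequence(variant_tbl("T1", cpos[i], ref, alt), m)
      mut <- fx$cds
      substr(mut, i, i) <- alt
      same_protein <- identical(translate(mut), translate(fx$cds))
      expect_identical(cc$kind == "synonymous SNV", same_protein)
    }
  }
})

test_that("indels classify as frameshift by length modulo 3", {
  fx <- tiny_tx_fixture()
  m <- prepare_tx_db(fx$tx)$models[[1]]
  cpos <- somaticfunnel:::cds_genomic_positions(m)
  anchor <- cpos[4]
  base <- substr(fx$reference[["T1"]], anchor, anchor)
  nxt <- substr(fx$reference[["T1"]], anchor, anchor + 1L)
  expect_equal(coding_consequence(
    variant_tbl("T1", anchor, nxt, base), m)$kind, "frameshift deletion")
  expect_equal(coding_consequence(
    variant_tbl("T1", anchor, base, paste0(base, "T")), m)$kind,
    "frameshift insertion")
  expect_equal(coding_consequence(
    variant_tbl("T1", anchor, base, paste0(base, "TAG")), m)$kind,
    "nonframeshift insertion")
})

test_that("annotate_variants attaches database membership flags by key", {
  fx <- tiny_tx_fixture()
  pos <- fx$tx$cds_start[1]
  ref <- substr(fx$reference[["T1"]], pos, pos)
  v <- variant_tbl("T1", pos, ref, setdiff(c("A", "C", "G", "T"), ref)[1])
  dbs <- list(avsnp150 = variant_key(v), COSMIC = character(0))
  ann <- annotate_variants(v, fx$tx, dbs)
  expect_true(ann$in_avsnp150)
  expect_false(ann$in_COSMIC)
  expect_equal(ann$region, "exonic")
})
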