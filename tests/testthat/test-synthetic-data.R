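# Generators: determinism, structural validity, planted composition.

test_that("reference and transcript generation is deterministic and valid", {
  a <- generate_reference_and_transcripts(seed = 230, n_genes = 10)
  b <- generate_reference_and_transcripts(seed = 230, n_genes = 10)
  expect_identical(a$reference, b$reference)
  expect_identical(a$transcripts, b$transcripts)
  # every CDS is a valid ORF: starts ATG, ends with a stop, no internal stops
  for (cds in a$transcripts$cds_seq) {
    expect_equal(nchar(cds) %% 3L, 0L)
    expect_equal(substr(cds, 1, 3), "ATG")
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds))), "")[[1]]
    expect_equal(aa[length(aa)], "*")
    expect_false("*" %in% aa[-length(aa)])
  }
  # the receptor-like worked-example transcript has codon 230 = AGC
  cds <- a$transcripts$cds_seq[a$transcripts$transcript_id == "NM_000395"]
  expect_equal(substr(cds, 688, 690), "AGC")
  # the spliced CDS matches the genome at its exon coordinates
  db <- prepare_tx_db(a$transcripts)
  for (m in db$models[1:5]) {
    pos <- somaticfunnel:::cds_genomic_positions(m)
    g <- vapply(pos, function(p) substr(a$reference[[m$chrom]], p, p), "")
    spliced <- paste(if (m$strand == "+") g else chartr("ACGT", "TGCA", g),
                     collapse = "")
    expect_equal(spliced, m$cds_seq)
  }
})

test_that("profile identities are validated with informative errors", {
  expect_error(funnel_profile(n_shared = 40000L), "n_shared")
  expect_error(funnel_profile(n_novel = 984L), "tumor-exclusive")
  expect_error(funnel_profile(n_synonymous = 92L), "must equal n_exonic")
  expect_error(funnel_profile(n_genes = 424L), "n_genes")
  expect_error(funnel_profile(n_cgc_tier1 = 22L), "n_cgc_tier1")
})

test_that("cohort generation is reproducible and respects planted sets", {
  prof <- tiny_profile()
  a <- generate_cohort(prof, seed = 99L)
  b <- generate_cohort(prof, seed = 99L)
  expect_identical(a$tumor, b$tumor)
  expect_identical(a$normal, b$normal)
  expect_identical(a$databases, b$databases)
  expect_identical(a$reference, b$reference)
  # planted novel keys are absent from every database
  for (db in a$databases)
    expect_length(intersect(a$truth$keys_novel, db), 0L)
  # database members and decoys never collide with other cohort categories
  expect_length(intersect(a$databases$avsnp150, a$truth$keys_otherdb), 0L)
  # all tumor variants are inside the targets
  ref <- a$reference
  tum <- left_normalize(a$tumor, ref)
  expect_equal(off_target_count(tum, a$targets), 0L)
})

test_that("decoys vary with the database seed while members stay constant", {
  co <- generate_cohort(tiny_profile(), seed = 5L)
  d1 <- generate_databases(co, co$profile, seed = 1L)
  d2 <- generate_databases(co, co$profile, seed = 2L)
  expect_false(identical(d1$avsnp150, d2$avsnp150))
  expect_true(all(co$truth$keys_avsnp %in% d1$avsnp150))
  expect_true(all(co$truth$keys_avsnp %in% d2$avsnp150))
  onine <- function(d) sort(intersect(unlist(d[-1]), co$truth$keys_otherdb))
  expect_equal(onine(d1), sort(co$truth$keys_otherdb))
  expect_equal(onine(d2), sort(co$truth$keys_otherdb))
})

test_that("written fixtures are byte-identical across regeneration", {
  d1 <- tempfile("fx1"); d2 <- tempfile("fx2")
  generate_cohort(tiny_profile(), seed = 42L, out_dir = d1)
  generate_cohort(tiny_profile(), seed = 42L, out_dir = d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("the dose-response generator is exact at zero noise and seeded", {
  p0 <- generate_dose_response(noise_sd = 0, seed = 1)
  drug <- p0[p0$compound != "DMSO", ]
  y <- somaticfunnel:::fourpl_value(log10(drug$concentration), 100, 5, -1,
                                    log10(0.94))
  expect_equal(drug$luminescence, 20000 * y / 100, tolerance = 1e-12)
  expect_equal(length(unique(drug$concentration)), 8L)
  expect_equal(log10(max(drug$concentration) / min(drug$concentration)), 3.5,
               tolerance = 1e-12)
  # DMSO wells normalize to mean 100 by construction
  pn <- generate_dose_response(seed = 8)
  dm <- pn[pn$compound == "DMSO", ]
  expect_equal(mean(100 * dm$luminescence / mean(dm$luminescence)), 100)
  expect_identical(generate_dose_response(seed = 4),
                   generate_dose_response(seed = 4))
})

test_that("an invalid profile passed to the cohort generator errors early", {
  p <- tiny_profile()
  p$n_shared <- p$n_tumor_total + 1L
  expect_error(generate_cohort(p, seed = 1L), "invalid funnel profile")
})
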