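# Germline subtraction, novelty cascade, functional filtering, gene
# extraction and CGC comparison.

test_that("subtract_germline removes shared keys and reports counts", {
  t <- variant_tbl("1", c(10L, 20L), "A", "G", sample_id = "TUMOR")
  n <- variant_tbl("1", 20L, "A", "G", sample_id = "NORMAL")
  s <- subtract_germline(t, n)
  expect_equal(s$n_shared, 1L)
  expect_equal(s$n_exclusive, 1L)
  expect_equal(s$exclusive$pos, 10L)
  # identical sample ids on both sides look like swapped inputs
  bad <- variant_tbl("1", 30L, "C", "T", sample_id = "TUMOR")
  expect_error(subtract_germline(t, bad), "swapped")
})

test_that("subtraction is representation-independent after normalization", {
  ref <- c(Z = "GGATTTTCAGG")
  # same one-T deletion written right-shifted in the tumor, normalized in the
  # normal sample
  tum <- left_normalize(variant_tbl("Z", 6L, "TT", "T", sample_id = "TUMOR"), ref)
  nor <- left_normalize(variant_tbl("Z", 3L, "AT", "A", sample_id = "NORMAL"), ref)
  s <- subtract_germline(tum, nor)
  expect_equal(s$n_exclusive, 0L)
})

test_that("the cascade removes members in order with monotone survivor counts", {
  v <- variant_tbl("1", 1:10, "A", "G")
  keys <- variant_key(v)
  dbs <- list(avsnp150 = keys[1:5], COSMIC = keys[6], ExAC_ALL = character(0),
              GME = character(0), esp = keys[7], gnomAD = character(0),
              clinvar = character(0), ICGC = character(0),
              Nci60 = character(0), `1000g` = keys[1:2])
  out <- apply_filter_cascade(v, dbs)
  expect_equal(unname(out$survivors["avsnp150"]), 5L)
  expect_equal(unname(out$survivors["1000g"]), 3L)
  expect_true(all(diff(out$survivors) <= 0))
  expect_equal(out$novel$pos, c(8L, 9L, 10L))
  # all-empty databases: identity
  empty <- lapply(dbs, function(x) character(0))
  expect_equal(nrow(apply_filter_cascade(v, empty)$novel), 10L)
  # missing table is a configuration error
  expect_error(apply_filter_cascade(v, dbs[-2]), "missing database")
})

test_that("the final novel set is independent of database order", {
  set.seed(31)
  v <- variant_tbl("1", 1:200, "A", "G")
  keys <- variant_key(v)
  names <- funnel_config()$novelty_db_order
  dbs <- lapply(seq_along(names), function(i) sample(keys, 25))
  names(dbs) <- names
  base <- apply_filter_cascade(v, dbs)
  for (r in 1:5) {
    cfg <- funnel_config(novelty_db_order = sample(names))
    out <- apply_filter_cascade(v, dbs, cfg)
    expect_setequal(variant_key(out$novel), variant_key(base$novel))
  }
})

test_that("functional filtering keeps exonic non-synonymous variants only", {
  fx <- tiny_tx_fixture()
  m <- prepare_tx_db(fx$tx)$models[[1]]
  cpos <- somaticfunnel:::cds_genomic_positions(m)
  g <- fx$reference[["T1"]]
  mk <- function(pos, ref, alt) variant_tbl("T1", pos, ref, alt)
  v <- rbind(
    mk(cpos[11], "T", "A"),                       # nonsynonymous
    mk(cpos[9], "A", "G"),                        # synonymous (dropped)
    mk(cpos[6], "C", "A"),                        # stopgain
    mk(cpos[4], substr(g, cpos[4], cpos[4] + 1L),
       substr(g, cpos[4], cpos[4])),              # frameshift deletion
    mk(fx$plus$ee[1] + 1L, substr(g, fx$plus$ee[1] + 1L, fx$plus$ee[1] + 1L),
       setdiff(c("A", "C", "G", "T"),
               substr(g, fx$plus$ee[1] + 1L, fx$plus$ee[1] + 1L))[1]))  # splicing
  out <- classify_and_filter_functional(v, fx$tx)
  expect_equal(out$n_exonic, 4L)
  expect_equal(out$n_synonymous, 1L)
  expect_equal(out$n_functional, 3L)
  expect_equal(out$n_snv, 2L)
  expect_equal(out$n_other, 1L)
  # a set of only synonymous exonic variants retains nothing
  syn_only <- mk(cpos[9], "A", "G")
  expect_equal(classify_and_filter_functional(syn_only, fx$tx)$n_functional, 0L)
})

test_that("gene extraction uses union semantics over unique symbols", {
  fun <- data.frame(genes = c("GA", "GA", "GB,GC"), stringsAsFactors = FALSE)
  expect_setequal(extract_genes(fun), c("GA", "GB", "GC"))
  expect_equal(length(extract_genes(fun[c(1, 2), , drop = FALSE])), 1L)
  expect_error(extract_genes(data.frame(genes = c("GA", ""))), "unannotated")
  expect_equal(extract_genes(fun[0, , drop = FALSE]), character(0))
})

test_that("CGC comparison reports tier breakdown and handles edge cases", {
  cgc <- data.frame(gene_symbol = c("GA", "GB", "GC", "GD"),
                    tier = c(1L, 1L, 2L, 2L), stringsAsFactors = FALSE)
  cmp <- cgc_compare(c("ga", "GC", "ZZ"), cgc)
  expect_equal(cmp$n_common, 2L)
  expect_equal(cmp$n_tier1, 1L)
  expect_equal(cmp$tier1_pct, 50.0)
  # disjoint sets: zero overlap, percentage undefined
  d <- cgc_compare(c("X1", "X2"), cgc)
  expect_equal(d$n_common, 0L)
  expect_true(is.na(d$tier1_pct))
  # all common, all tier 2
  t2 <- cgc_compare(c("GC", "GD"), cgc)
  expect_equal(t2$tier1_pct, 0.0)
  expect_error(cgc_compare("GA", cgc[0, ]), "empty CGC")
})

test_that("a tiny planted profile is reproduced end to end, in memory", {
  prof <- tiny_profile()
  co <- generate_cohort(prof, seed = 77L)
  rep <- run_funnel_in_memory(co)
  expect_equal(rep$n_tumor_total, prof$n_tumor_total)
  expect_equal(rep$n_normal_total, prof$n_normal_total)
  expect_equal(rep$n_shared, prof$n_shared)
  expect_equal(rep$n_exclusive, prof$n_tumor_total - prof$n_shared)
  expect_equal(rep$n_after_first_db, prof$n_in_other_dbs + prof$n_novel)
  expect_equal(rep$n_novel, prof$n_novel)
  expect_equal(rep$n_exonic, prof$n_exonic)
  expect_equal(rep$n_functional, prof$n_functional_snv + prof$n_functional_other)
  expect_equal(rep$n_snv, prof$n_functional_snv)
  expect_equal(rep$n_other, prof$n_functional_other)
  expect_equal(rep$n_genes, prof$n_genes)
  expect_equal(rep$n_cgc_common, prof$n_cgc_common)
  expect_equal(rep$n_cgc_tier1, prof$n_cgc_tier1)
  expect_equal(rep$n_off_target, 0L)
  # tumor == normal leaves nothing downstream of the subtraction
  s <- subtract_germline(
    variant_tbl("1", 1:5, "A", "G", sample_id = "TUMOR"),
    variant_tbl("1", 1:5, "A", "G", sample_id = "NORMAL"))
  expect_equal(s$n_exclusive, 0L)
})
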