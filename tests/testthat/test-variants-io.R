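# VCF/BED I/O, multi-allelic decomposition, left-normalization and keys.

write_mini_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"), lines), path)
  path
}

test_that("read_vcf yields one record per data line and errors on bad input", {
  p <- write_mini_vcf(c("1\t100\t.\tG\tA\t50\tPASS\tDP=80;VD=20;PV=0.001",
                        "1\t200\t.\tT\tC\t60\tPASS\tDP=90;VD=30;PV=0.002"))
  rec <- read_vcf(p, "S1")
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$pos, c(100L, 200L))
  expect_equal(rec$total_depth, c(80L, 90L))
  expect_equal(rec$call_p, c(0.001, 0.002))
  expect_equal(rec$sample_id, c("S1", "S1"))

  multi <- read_vcf(write_mini_vcf("1\t100\t.\tG\tA,T\t50\tPASS\t."), "S1")
  expect_equal(nrow(multi), 1L)
  expect_equal(multi$alt, "A,T")

  headerless <- tempfile(fileext = ".vcf")
  writeLines("1\t100\t.\tG\tA\t50\tPASS\t.", headerless)
  expect_error(read_vcf(headerless, "S1"), "format error")
})

test_that("write/read round trip preserves variant fields exactly", {
  set.seed(42)
  n <- 50L
  ref <- sample(c("A", "C", "G", "T", "AT", "GCC"), n, replace = TRUE)
  alt <- ifelse(nchar(ref) > 1, substr(ref, 1, 1), "X")
  alt[alt == "X"] <- vapply(ref[alt == "X"],
                            function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  v <- variant_tbl("7", pos = sort(sample(1000:9999, n)), ref = ref, alt = alt,
                   qual = round(runif(n, 10, 999), 1),
                   total_depth = sample(60:200, n, TRUE),
                   variant_depth = sample(16:50, n, TRUE),
                   call_p = round(runif(n, 0, 0.009), 6))
  for (ext in c(".vcf", ".vcf.gz")) {
    p <- tempfile(fileext = ext)
    write_vcf(v, p)
    back <- read_vcf(p, "S")
    expect_equal(back$chrom, v$chrom)
    expect_equal(back$pos, v$pos)
    expect_equal(back$ref, v$ref)
    expect_equal(back$alt, v$alt)
    expect_equal(back$qual, v$qual)
    expect_equal(back$total_depth, v$total_depth)
    expect_equal(back$call_p, v$call_p)
  }
})

test_that("split_multiallelic conserves allele counts and order", {
  rec <- data.frame(chrom = "1", pos = c(100L, 300L, 500L),
                    ref = c("G", "A", "C"), alt = c("A,T", "G", "CA,CAT,G"),
                    qual = 1, total_depth = 60L, variant_depth = 20L,
                    call_p = 0.001, sample_id = "S", stringsAsFactors = FALSE)
  out <- split_multiallelic(rec)
  expect_equal(nrow(out), sum(lengths(strsplit(rec$alt, ","))))
  expect_equal(out$alt[1:2], c("A", "T"))
  expect_equal(out$pos[1:2], c(100L, 100L))
  expect_equal(out$alt[4:6], c("CA", "CAT", "G"))
  # single-alt record passes through identically
  expect_equal(unname(unlist(out[3, c("pos", "ref", "alt")])),
               c("300", "A", "G"))
})

test_that("left_normalize reproduces the worked homopolymer example", {
  ref_seq <- c(Z = "ATTTTC")
  v <- variant_tbl("Z", 4L, "TT", "T")
  out <- left_normalize(v, ref_seq)
  expect_equal(out$pos, 1L)
  expect_equal(out$ref, "AT")
  expect_equal(out$alt, "A")
  # matches the independent brute-force representation search
  bf <- bf_normalize(4L, "TT", "T", ref_seq[["Z"]])
  expect_equal(list(out$pos, out$ref, out$alt), unname(bf))
  # SNVs are fixed points
  s <- left_normalize(variant_tbl("Z", 3L, "T", "G"), ref_seq)
  expect_equal(s$pos, 3L)
  expect_equal(s$ref, "T")
  expect_equal(s$alt, "G")
  # boundary: extension past position 1 is an error
  expect_error(left_normalize(variant_tbl("Z", 1L, "AT", "A"),
                              c(Z = "ATTTTC")), NA)  # A != T, already normal
  expect_error(left_normalize(variant_tbl("Z", 1L, "AA", "A"),
                              c(Z = "AATTTC")), "boundary")
  # REF mismatch with the reference is an error
  expect_error(left_normalize(variant_tbl("Z", 2L, "GG", "G"), ref_seq),
               "disagrees")
})

test_that("left_normalize agrees with the brute-force oracle on random homopolymer indels", {
  set.seed(101)
  n_cases <- 0L
  while (n_cases < 1000L) {
    sq <- random_seq_with_runs()
    for (i in 1:25) {
      iv <- random_run_indel(sq)
      v <- variant_tbl("R", iv$pos, iv$ref, iv$alt)
      got <- tryCatch(left_normalize(v, c(R = sq$seq)), error = function(e) NULL)
      if (is.null(got)) next  # boundary case; oracle window also breaks down
      bf <- bf_normalize(iv$pos, iv$ref, iv$alt, sq$seq)
      expect_equal(got$pos, bf$pos)
      expect_equal(got$ref, bf$ref)
      expect_equal(got$alt, bf$alt)
      # idempotence
      again <- left_normalize(got[, 1:9], c(R = sq$seq))
      expect_equal(again[, c("pos", "ref", "alt")],
                   got[, c("pos", "ref", "alt")])
      n_cases <- n_cases + 1L
    }
  }
  expect_gte(n_cases, 1000L)
})

test_that("variant_key identifies alleles independent of representation and sample", {
  ref_seq <- c(Z = "GGATTTTCA")
  a <- left_normalize(variant_tbl("Z", 4L, "TT", "T", sample_id = "TUMOR"), ref_seq)
  b <- left_normalize(variant_tbl("Z", 6L, "TT", "T", sample_id = "NORMAL"), ref_seq)
  expect_equal(variant_key(a), variant_key(b))
  # same site, different alt: different keys
  expect_false(variant_key(variant_tbl("Z", 3L, "A", "T")) ==
                 variant_key(variant_tbl("Z", 3L, "A", "C")))
  # detectably un-normalized input errors
  expect_error(variant_key(variant_tbl("Z", 4L, "TT", "T")), "un-normalized")
})

test_that("the load-time quality gate filters on depth and p-value", {
  v <- variant_tbl("1", 1:4, "A", "G",
                   total_depth = c(60L, 40L, 60L, 60L),
                   variant_depth = c(20L, 20L, 10L, 20L),
                   call_p = c(0.001, 0.001, 0.001, 0.05))
  expect_equal(nrow(apply_gate(v)), 1L)
  expect_equal(apply_gate(v)$pos, 1L)
  # missing fields pass with a warning
  vm <- variant_tbl("1", 9L, "A", "G")
  expect_warning(out <- apply_gate(rbind(v, vm)), "missing")
  expect_true(9L %in% out$pos)
  # disabled gate is the identity
  expect_equal(nrow(apply_gate(v, variant_gate(enabled = FALSE))), 4L)
})

test_that("BED intervals convert to 1-based inclusive coordinates", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("1\t0\t10", "2\t99\t200"), p)
  b <- read_bed(p)
  expect_equal(b$start, c(1L, 100L))
  expect_equal(b$end, c(10L, 200L))
  p2 <- tempfile(fileext = ".bed")
  write_bed(b, p2)
  expect_equal(readLines(p2), c("1\t0\t10", "2\t99\t200"))
})

test_that("symbolic alleles pass through flagged, never normalized", {
  v <- data.frame(chrom = "Z", pos = 3L, ref = "A", alt = "<DEL>",
                  qual = NA_real_, total_depth = NA_integer_,
                  variant_depth = NA_integer_, call_p = NA_real_,
                  sample_id = NA_character_, stringsAsFactors = FALSE)
  out <- left_normalize(v, c(Z = "GGATT"))
  expect_false(out$normalized)
  expect_equal(out$alt, "<DEL>")
})
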