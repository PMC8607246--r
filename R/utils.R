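`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    comp_base(paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

last_char <- function(x) substr(x, nchar(x), nchar(x))

#' Read a reference genome FASTA into named per-chromosome strings
#'
#' @param path FASTA file (optionally gzipped).
#' @return Named character vector, one uppercase sequence per chromosome,
#'   addressed 1-based by `substr()` downstream.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a reference genome to FASTA
#'
#' @param reference named character vector of chromosome sequences.
#' @param path output file.
#' @export
write_reference_fasta <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Standard genetic code lookup; stop codons render as "X" in protein strings.
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[toupper(codon)]
  aa[is.na(aa)] <- "?"
  aa[aa == "*"] <- "X"
  unname(aa)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

read_tsv_base <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE, ...)
}

write_tsv_base <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
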