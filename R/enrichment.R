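# Gene-set over-representation in the Reactome style: a binomial upper-tail
# test per pathway over gene-level counts, with Benjamini-Hochberg correction
# across the pathways hit by at least one query gene.

#' Read gene sets from a GMT file
#'
#' Tab-separated: pathway_id, name, then member gene symbols. (The name column
#' is retained, which is why this reader is in-package.)
#'
#' @param path GMT file.
#' @return list of pathways, each `list(pathway_id, name, genes)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line: %s", substr(l, 1, 60))
    list(pathway_id = f[1], name = f[2], genes = unique(toupper(f[-c(1, 2)])))
  })
}

#' Write gene sets to a GMT file
#' @param pathways list as returned by [read_gmt()].
#' @param path output file.
#' @export
write_gmt <- function(pathways, path) {
  writeLines(vapply(pathways, function(p)
    paste(c(p$pathway_id, p$name, p$genes), collapse = "\t"), character(1)), path)
  invisible(path)
}

#' Binomial over-representation test for one pathway
#'
#' With `n` query genes found in the universe of size `N` and a pathway of
#' size `K`, the overlap `k` is compared against Binomial(n, K/N):
#' p = P(X >= k), computed with a numerically stable tail sum.
#'
#' @param query_genes character vector (deduplicated internally).
#' @param pathway `list(pathway_id, name, genes)`.
#' @param universe character vector of all annotated genes.
#' @return list with pathway_id, name, k, K, n, N, entities_ratio (= K/N),
#'   p_value and found_genes.
#' @export
binomial_overrepresentation <- function(query_genes, pathway, universe) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stopf("empty universe")
  query <- intersect(unique(toupper(query_genes)), universe)
  members <- intersect(unique(toupper(pathway$genes)), universe)
  found <- intersect(query, members)
  k <- length(found); K <- length(members); n <- length(query); N <- length(universe)
  if (K == 0) {
    warnf("pathway %s has no members in the universe; p = 1", pathway$pathway_id)
    p <- 1
  } else if (n == 0) {
    p <- NA_real_
  } else {
    p <- stats::pbinom(k - 1L, size = n, prob = K / N, lower.tail = FALSE)
  }
  list(pathway_id = pathway$pathway_id, name = pathway$name %||% pathway$pathway_id,
       k = k, K = K, n = n, N = N, entities_ratio = K / N, p_value = p,
       found_genes = found)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up: sort ascending, `adj_i = min_{j >= i} (p_j * m / j)`
#' capped at 1, returned in the input order.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted values.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis across a pathway database
#'
#' Tests every pathway overlapping the query in at least one gene (k >= 1),
#' sorts by p-value ascending (ties broken by pathway_id), and attaches the
#' Benjamini-Hochberg FDR computed over the tested set.
#'
#' @param query_genes character vector of query gene symbols.
#' @param pathway_db list of pathways ([read_gmt()]).
#' @param universe character vector of all annotated genes.
#' @param all_pathways correct over every pathway instead of only those hit.
#' @return list with `results` (data.frame: pathway_id, name, k, K, n, N,
#'   entities_ratio, p_value, fdr, found_genes), `n_found` (query genes in the
#'   universe) and `n_pathways_hit`.
#' @export
run_ora <- function(query_genes, pathway_db, universe, all_pathways = FALSE) {
  if (!length(pathway_db)) stopf("empty pathway database")
  res <- lapply(pathway_db, binomial_overrepresentation,
                query_genes = query_genes, universe = universe)
  k <- vapply(res, `[[`, 0L, "k")
  n_hit <- sum(k >= 1L)
  if (!all_pathways) res <- res[k >= 1L]
  df <- data.frame(
    pathway_id = vapply(res, `[[`, "", "pathway_id"),
    name = vapply(res, `[[`, "", "name"),
    k = vapply(res, `[[`, 0L, "k"),
    K = vapply(res, `[[`, 0L, "K"),
    n = vapply(res, `[[`, 0L, "n"),
    N = vapply(res, `[[`, 0L, "N"),
    entities_ratio = vapply(res, `[[`, 0, "entities_ratio"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    found_genes = vapply(res, function(r) paste(sort(r$found_genes), collapse = ","), ""),
    stringsAsFactors = FALSE)
  df$fdr <- if (nrow(df)) bh_adjust(df$p_value) else numeric(0)
  df <- df[order(df$p_value, df$pathway_id), , drop = FALSE]
  rownames(df) <- NULL
  n_found <- length(intersect(unique(toupper(query_genes)), unique(toupper(universe))))
  list(results = df[, c("pathway_id", "name", "k", "K", "n", "N",
                        "entities_ratio", "p_value", "fdr", "found_genes")],
       n_found = n_found, n_pathways_hit = n_hit)
}
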