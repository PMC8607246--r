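# Consensus over heterogeneous functional-impact predictor verdicts.

# method vocabulary -> {damaging, benign}; anything unrecognized is "unknown".
PREDICTOR_VOCAB <- list(
  SIFT = c(deleterious = "damaging", tolerated = "benign"),
  PolyPhen2_HDIV = c(probably_damaging = "damaging", possibly_damaging = "damaging",
                     benign = "benign"),
  PolyPhen2_HVAR = c(probably_damaging = "damaging", possibly_damaging = "damaging",
                     benign = "benign"),
  MutationTaster = c(disease_causing = "damaging", polymorphism = "benign"),
  PROVEAN = c(deleterious = "damaging", neutral = "benign")
)

#' Normalize a predictor verdict to damaging / benign / unknown
#'
#' @param method predictor name (registered in the vocabulary map; see
#'   `vocab`). Both PolyPhen2 "probably" and "possibly damaging" normalize to
#'   damaging.
#' @param raw_verdict the method's own vocabulary string.
#' @param vocab vocabulary map, by default [PREDICTOR_VOCAB].
#' @return "damaging", "benign" or "unknown".
#' @export
normalize_call <- function(method, raw_verdict, vocab = PREDICTOR_VOCAB) {
  if (!method %in% names(vocab))
    stopf("unregistered predictor method: %s", method)
  v <- unname(vocab[[method]][tolower(gsub("[ -]", "_", raw_verdict))])
  ifelse(is.na(v), "unknown", v)
}

#' Consensus verdict over one variant's predictor calls
#'
#' @param calls data.frame with columns method and raw_verdict (one row per
#'   method; duplicates are an error).
#' @param vocab vocabulary map.
#' @return list with n_methods, n_damaging, n_benign, n_unknown,
#'   unanimous_damaging (all methods damaging with no unknowns) and the
#'   per-method normalized verdicts.
#' @export
consensus_verdict <- function(calls, vocab = PREDICTOR_VOCAB) {
  if (nrow(calls) < 1) stopf("at least one predictor call required")
  if (anyDuplicated(calls$method))
    stopf("duplicate predictor entries for method %s",
          calls$method[duplicated(calls$method)][1])
  verdicts <- mapply(normalize_call, calls$method, calls$raw_verdict,
                     MoreArgs = list(vocab = vocab))
  names(verdicts) <- calls$method
  nd <- sum(verdicts == "damaging")
  list(n_methods = length(verdicts),
       n_damaging = nd,
       n_benign = sum(verdicts == "benign"),
       n_unknown = sum(verdicts == "unknown"),
       unanimous_damaging = nd == length(verdicts) && length(verdicts) >= 1,
       verdicts = verdicts)
}

#' Read predictor calls keyed by variant key and method
#' @param path TSV with columns variant_key, method, raw_verdict (optional
#'   score).
#' @export
read_predictor_calls <- function(path) read_tsv_base(path)

#' Consensus table across variants
#'
#' @param calls data.frame with variant_key, method, raw_verdict.
#' @param vocab vocabulary map.
#' @return data.frame, one row per variant key, with n_methods, n_damaging and
#'   unanimous_damaging columns, suitable for appending to an annotated
#'   variant table.
#' @export
consensus_table <- function(calls, vocab = PREDICTOR_VOCAB) {
  keys <- unique(calls$variant_key)
  rows <- lapply(keys, function(k) {
    cv <- consensus_verdict(calls[calls$variant_key == k, , drop = FALSE], vocab)
    data.frame(variant_key = k, n_methods = cv$n_methods,
               n_damaging = cv$n_damaging, n_benign = cv$n_benign,
               n_unknown = cv$n_unknown,
               unanimous_damaging = cv$unanimous_damaging,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
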