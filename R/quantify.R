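# Read-level QC filtering, RPKM quantification, detected-gene filter.

#' Filter reads on base quality and unknown-base content
#'
#' A read is discarded iff more than `max_lowq_frac` of its bases have
#' Phred quality <= `q_value`, or more than `max_n_frac` of its bases are
#' `N`. Both fraction comparisons are strict (`>`), the quality comparison
#' inclusive (`<=`). Qualities are Phred+33 encoded.
#'
#' @param reads Tibble with columns `read_id`, `bases`, `qualities`.
#' @param max_lowq_frac Maximum tolerated fraction of low-quality bases
#'   (default 0.5).
#' @param q_value Quality value at or below which a base counts as
#'   low-quality (default 5).
#' @param max_n_frac Maximum tolerated fraction of unknown (`N`) bases
#'   (default 0.1).
#' @return List with `kept` (reads tibble) and `log` (tibble `read_id`,
#'   `rule` in `low_quality`/`unknown_bases` recording why each discarded
#'   read was dropped; the low-quality rule is reported when both fire).
#' @export
qc_filter_reads <- function(reads, max_lowq_frac = 0.5, q_value = 5,
                            max_n_frac = 0.1) {
  if (nrow(reads) == 0) {
    return(list(kept = reads,
                log = tibble::tibble(read_id = character(),
                                     rule = character())))
  }
  qual_frac <- vapply(reads$qualities, function(q) {
    phred <- utf8ToInt(q) - 33L
    mean(phred <= q_value)
  }, numeric(1), USE.NAMES = FALSE)
  n_frac <- stringr::str_count(reads$bases, stringr::fixed("N")) /
    nchar(reads$bases)
  lowq <- qual_frac > max_lowq_frac
  manyn <- n_frac > max_n_frac
  drop <- lowq | manyn
  list(
    kept = reads[!drop, , drop = FALSE],
    log = tibble::tibble(
      read_id = reads$read_id[drop],
      rule = ifelse(lowq[drop], "low_quality", "unknown_bases")
    )
  )
}

#' RPKM expression values from raw counts
#'
#' RPKM(g, s) = 1e9 * count(g, s) / (total(s) * length(g)), where
#' total(s) is the column sum of counts (reads uniquely aligned to all
#' genes in sample s) and length(g) the gene model length in bases.
#' A sample with total 0 yields all-zero values with a warning.
#'
#' @param counts Wide count tibble (`gene_id` + sample columns).
#' @param catalog Gene catalog supplying `length_bases` for every gene.
#' @return Wide tibble of RPKM values, same shape as `counts`.
#' @export
compute_rpkm <- function(counts, catalog) {
  assert_df_has(counts, "gene_id", "counts")
  len <- catalog$length_bases[match(counts$gene_id, catalog$gene_id)]
  if (anyNA(len)) {
    ams_abort(sprintf(
      "gene(s) missing from catalog: %s",
      paste(utils::head(counts$gene_id[is.na(len)], 5), collapse = ", ")
    ))
  }
  out <- counts
  for (s in setdiff(names(counts), "gene_id")) {
    total <- sum(counts[[s]])
    if (total == 0) {
      rlang::warn(sprintf("sample '%s' has zero total counts; RPKM set to 0", s))
      out[[s]] <- rep(0, nrow(counts))
    } else {
      out[[s]] <- 1e9 * counts[[s]] / (total * len)
    }
  }
  out
}

#' Genes detected in every sample
#'
#' A gene is "detected" when it has at least one read in every sample
#' (all biological replicates of both conditions).
#'
#' @param counts Wide count tibble.
#' @return Character vector of detected gene ids, in input order.
#' @export
detect_expressed <- function(counts) {
  samples <- setdiff(names(counts), "gene_id")
  if (nrow(counts) == 0 || length(samples) == 0) return(character(0))
  ok <- Reduce(`&`, lapply(samples, function(s) counts[[s]] >= 1))
  counts$gene_id[ok]
}
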