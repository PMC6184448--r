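# Promoter cis-element scanning: report every window on either strand
# whose Hamming distance to the motif is at most max_mismatch. Coordinates
# are 1-based on the forward strand; a minus-strand match is reported at
# the leftmost forward-strand base of its window. `N` never matches.

reverse_complement <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(seq, "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), character(1)))
}

# mismatch count of motif against every window of seq (byte comparison)
hamming_profile <- function(seq, motif) {
  n <- nchar(seq)
  m <- nchar(motif)
  if (m > n) return(integer(0))
  sb <- utf8ToInt(seq)
  mb <- utf8ToInt(motif)
  mism <- integer(n - m + 1L)
  for (j in seq_len(m)) {
    mism <- mism + (sb[j:(n - m + j)] != mb[j])
  }
  mism
}

#' Scan one promoter sequence for a motif allowing mismatches
#'
#' Every window (both strands by default) within Hamming distance
#' `max_mismatch` of the motif is reported; overlapping matches are all
#' kept. `N` in the sequence counts as a mismatch against any motif base.
#'
#' @param seq Promoter sequence (ACGTN string).
#' @param motif Motif consensus (ACGT string; N allowed but never
#'   matches).
#' @param max_mismatch Maximum Hamming mismatches (default 1).
#' @param both_strands Scan the reverse strand too? Default `TRUE`.
#' @param sequence_id Identifier copied into the output.
#' @return Tibble `sequence_id`, `start` (1-based, forward strand,
#'   leftmost base of the window), `strand` (`+`/`-`), `mismatches`,
#'   `matched_substring`, sorted by start then strand.
#' @export
scan_promoter <- function(seq, motif, max_mismatch = 1,
                          both_strands = TRUE, sequence_id = "seq") {
  seq <- toupper(seq)
  motif <- toupper(motif)
  if (stringr::str_detect(motif, "[^ACGTN]")) {
    ams_abort("motif must be an ACGTN string")
  }
  empty <- tibble::tibble(
    sequence_id = character(), start = integer(), strand = character(),
    mismatches = integer(), matched_substring = character()
  )
  if (nchar(motif) > nchar(seq)) {
    rlang::warn("motif longer than sequence: no windows to scan")
    return(empty)
  }
  m <- nchar(motif)
  hits <- list()
  fwd <- hamming_profile(seq, motif)
  idx <- which(fwd <= max_mismatch)
  if (length(idx) > 0) {
    hits$fwd <- tibble::tibble(
      sequence_id = sequence_id, start = idx, strand = "+",
      mismatches = fwd[idx],
      matched_substring = stringr::str_sub(seq, idx, idx + m - 1L)
    )
  }
  if (both_strands) {
    rev <- hamming_profile(seq, reverse_complement(motif))
    idx <- which(rev <= max_mismatch)
    if (length(idx) > 0) {
      hits$rev <- tibble::tibble(
        sequence_id = sequence_id, start = idx, strand = "-",
        mismatches = rev[idx],
        matched_substring = stringr::str_sub(seq, idx, idx + m - 1L)
      )
    }
  }
  if (length(hits) == 0) return(empty)
  dplyr::bind_rows(hits) |>
    dplyr::arrange(.data$start, .data$strand)
}

#' Scan a set of promoters and summarise motif presence
#'
#' @param promoters Tibble `sequence_id`, `sequence` (e.g. from
#'   [read_promoters()]).
#' @inheritParams scan_promoter
#' @return List with `hits` (bound per-sequence match tables) and
#'   `summary` (per sequence: `n_exact`, `n_1mm` (hits with >= 1
#'   mismatch), `n_hits`, `any_hit`).
#' @export
scan_promoter_set <- function(promoters, motif, max_mismatch = 1,
                              both_strands = TRUE) {
  empty_hits <- tibble::tibble(
    sequence_id = character(), start = integer(), strand = character(),
    mismatches = integer(), matched_substring = character()
  )
  hits <- purrr::map2(
    promoters$sequence, promoters$sequence_id,
    function(s, id) scan_promoter(s, motif, max_mismatch, both_strands, id)
  ) |>
    dplyr::bind_rows(empty_hits)
  summary <- promoters |>
    dplyr::select("sequence_id") |>
    dplyr::left_join(
      hits |>
        dplyr::group_by(.data$sequence_id) |>
        dplyr::summarise(
          n_exact = sum(.data$mismatches == 0),
          n_1mm = sum(.data$mismatches >= 1),
          n_hits = dplyr::n(), .groups = "drop"
        ),
      by = "sequence_id"
    ) |>
    dplyr::mutate(
      dplyr::across(c("n_exact", "n_1mm", "n_hits"),
                    ~ tidyr::replace_na(.x, 0L)),
      any_hit = .data$n_hits > 0
    )
  list(hits = hits, summary = summary)
}
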