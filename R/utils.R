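#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider unnest replace_na
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap list_rbind
NULL

# condition labels used throughout: numerator first
.AMS_CONDITIONS <- c("mycorrhizal", "control")

`%||%` <- rlang::`%||%`

# stop with a classed error so tests can match on class
ams_abort <- function(msg, class = "amcoreset_error") {
  rlang::abort(msg, class = class)
}

assert_df_has <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    ams_abort(sprintf(
      "%s must contain column(s): %s", what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Validate a gene catalog
#'
#' A gene catalog records, per species, every gene identifier and its gene
#' model length in bases (the denominator of the RPKM normalization).
#'
#' @param catalog Tibble with columns `species`, `gene_id`, `length_bases`.
#' @return The validated catalog, invisibly usable in pipes.
#' @export
validate_catalog <- function(catalog) {
  assert_df_has(catalog, c("species", "gene_id", "length_bases"), "catalog")
  if (any(catalog$length_bases < 1)) {
    ams_abort("catalog: length_bases must be >= 1 for every gene")
  }
  dup <- catalog |>
    dplyr::count(.data$species, .data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    ams_abort(sprintf(
      "catalog: duplicated gene_id within species: %s",
      paste(utils::head(dup$gene_id, 5), collapse = ", ")
    ))
  }
  tibble::as_tibble(catalog)
}

#' Validate a count matrix against its condition map (and optional catalog)
#'
#' Counts are a wide tibble: a `gene_id` column followed by one integer
#' column per sample. `conditions` maps each sample to exactly one of the
#' two condition labels `"mycorrhizal"` and `"control"`.
#'
#' @param counts Wide tibble of non-negative integer counts.
#' @param conditions Tibble with columns `sample`, `condition`.
#' @param catalog Optional gene catalog; if given, every gene must be present.
#' @return `counts`, validated.
#' @export
validate_counts <- function(counts, conditions, catalog = NULL) {
  assert_df_has(counts, "gene_id", "counts")
  samples <- setdiff(names(counts), "gene_id")
  if (length(samples) == 0) ams_abort("counts: no sample columns")
  if (anyDuplicated(counts$gene_id)) {
    dup <- counts$gene_id[duplicated(counts$gene_id)][1]
    ams_abort(sprintf("counts: duplicate gene_id '%s'", dup))
  }
  for (s in samples) {
    bad <- which(counts[[s]] < 0 | !is.finite(counts[[s]]))
    if (length(bad) > 0) {
      ams_abort(sprintf(
        "counts: negative or non-finite count for gene '%s' in sample '%s'",
        counts$gene_id[bad[1]], s
      ))
    }
  }
  assert_df_has(conditions, c("sample", "condition"), "conditions")
  unknown <- setdiff(samples, conditions$sample)
  if (length(unknown) > 0) {
    ams_abort(sprintf(
      "counts: sample(s) missing from condition map: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  cond <- conditions$condition[match(samples, conditions$sample)]
  if (!all(cond %in% .AMS_CONDITIONS)) {
    ams_abort(sprintf(
      "conditions: labels must be one of: %s",
      paste(.AMS_CONDITIONS, collapse = ", ")
    ))
  }
  if (!all(.AMS_CONDITIONS %in% cond)) {
    ams_abort("conditions: both 'mycorrhizal' and 'control' must be present")
  }
  if (!is.null(catalog)) {
    missing <- setdiff(counts$gene_id, catalog$gene_id)
    if (length(missing) > 0) {
      ams_abort(sprintf(
        "counts: gene(s) absent from catalog: %s",
        paste(utils::head(missing, 5), collapse = ", ")
      ))
    }
  }
  tibble::as_tibble(counts)
}

#' Validate an orthogroup table
#'
#' Long tibble, one row per (orthogroup, species, gene). Each gene may occur
#' in at most one orthogroup across the whole table: orthogroups partition
#' the genes they contain.
#'
#' @param orthogroups Tibble with columns `orthogroup_id`, `species`,
#'   `gene_id`.
#' @return The validated table.
#' @export
validate_orthogroups <- function(orthogroups) {
  assert_df_has(orthogroups, c("orthogroup_id", "species", "gene_id"),
                "orthogroups")
  dup <- orthogroups |>
    dplyr::distinct(.data$orthogroup_id, .data$species, .data$gene_id) |>
    dplyr::count(.data$species, .data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    ams_abort(sprintf(
      "orthogroups: gene '%s' (%s) occurs in more than one orthogroup",
      dup$gene_id[1], dup$species[1]
    ))
  }
  tibble::as_tibble(orthogroups)
}

#' Validate a set of per-species, per-direction DEG identifiers
#'
#' @param degs Tibble with columns `species`, `direction` (`"up"`/`"down"`),
#'   `gene_id`. A gene may appear in at most one direction per species.
#' @return De-duplicated, validated tibble.
#' @export
validate_degs <- function(degs) {
  assert_df_has(degs, c("species", "direction", "gene_id"), "degs")
  if (!all(degs$direction %in% c("up", "down"))) {
    ams_abort("degs: direction must be 'up' or 'down'")
  }
  degs <- dplyr::distinct(tibble::as_tibble(degs))
  both <- degs |>
    dplyr::count(.data$species, .data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(both) > 0) {
    ams_abort(sprintf(
      "degs: gene '%s' (%s) listed in both directions",
      both$gene_id[1], both$species[1]
    ))
  }
  degs
}

#' Pipeline configuration with the study's default thresholds
#'
#' Bundles every tunable threshold of the pipeline. Defaults follow the
#' study design: DEGs are genes with expression change >= 2-fold and
#' empirical probability P >= 0.8; reads are discarded when more than 50%
#' of bases have quality Q <= 5 or more than 10% of bases are unknown;
#' core-set membership requires same-direction support from at least two
#' non-focal species.
#'
#' @param fold_threshold Minimum fold change (linear scale), default 2.
#' @param p_threshold Minimum empirical probability, default 0.8.
#' @param zero_substitute Value substituted for zero expression inside
#'   log-ratios only, default 0.5 (RPKM).
#' @param core_min_other_species Minimum number of supporting non-focal
#'   species for core membership, default 2.
#' @param conserved_min_species Minimum supporting species for a
#'   conserved-but-not-focal orthogroup, default 3.
#' @param focal_species Focal species label, default `"Ptr"`.
#' @param motif Cis-element consensus to scan for (ACGT string); default is
#'   the CTTC consensus `"CTTCTTGTTC"`.
#' @param max_mismatch Maximum Hamming mismatches in a motif hit, default 1.
#' @param qc_max_lowq_frac,qc_q_value,qc_max_n_frac Read-filter thresholds:
#'   discard when frac(Q <= qc_q_value) > qc_max_lowq_frac or
#'   frac(N) > qc_max_n_frac.
#' @param trouvelot_weights Colonization class weights for classes 5..1.
#' @param arbuscule_weights Arbuscule class weights for A3..A1.
#' @param random_seed Seed governing all stochastic stages.
#' @return A named list of class `ams_config`.
#' @export
ams_config <- function(fold_threshold = 2,
                       p_threshold = 0.8,
                       zero_substitute = 0.5,
                       core_min_other_species = 2,
                       conserved_min_species = 3,
                       focal_species = "Ptr",
                       motif = "CTTCTTGTTC",
                       max_mismatch = 1,
                       qc_max_lowq_frac = 0.5,
                       qc_q_value = 5,
                       qc_max_n_frac = 0.1,
                       trouvelot_weights = c(95, 70, 30, 5, 1),
                       arbuscule_weights = c(100, 50, 10),
                       random_seed = 1L) {
  if (p_threshold < 0 || p_threshold > 1) {
    ams_abort("p_threshold must lie in [0, 1]")
  }
  if (fold_threshold <= 1) ams_abort("fold_threshold must be > 1")
  if (zero_substitute <= 0) ams_abort("zero_substitute must be positive")
  if (any(diff(trouvelot_weights) >= 0) || any(diff(arbuscule_weights) >= 0)) {
    ams_abort("class weights must be strictly decreasing")
  }
  structure(
    list(
      fold_threshold = fold_threshold, p_threshold = p_threshold,
      zero_substitute = zero_substitute,
      core_min_other_species = core_min_other_species,
      conserved_min_species = conserved_min_species,
      focal_species = focal_species,
      motif = motif, max_mismatch = max_mismatch,
      qc_max_lowq_frac = qc_max_lowq_frac, qc_q_value = qc_q_value,
      qc_max_n_frac = qc_max_n_frac,
      trouvelot_weights = trouvelot_weights,
      arbuscule_weights = arbuscule_weights,
      random_seed = as.integer(random_seed)
    ),
    class = "ams_config"
  )
}
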