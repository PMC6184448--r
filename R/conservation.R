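# Orthogroup-based cross-species conservation analysis: map per-species DEG
# sets into orthogroups, partition regulated orthogroups across species,
# extract the focal-species core set, conserved-but-not-focal orthogroups,
# and curated-gene cross-references.
#
# An orthogroup is "regulated in species s (direction d)" when it contains
# at least one DEG of s with direction d; orthogroups, not genes, are the
# unit of the cross-species comparison, and gene-level results are derived
# by listing focal members afterwards.

#' Map DEG sets into orthogroups
#'
#' Each DEG annotates the (unique) orthogroup containing it, or is recorded
#' as unassigned for its species. Regulation is tracked per direction.
#'
#' @param degs Validated DEG tibble (`species`, `direction`, `gene_id`).
#' @param orthogroups Validated orthogroup tibble.
#' @return Object of class `ams_regulation`: list with `status` (tibble
#'   `orthogroup_id`, `species`, `direction`, `gene_id`, one row per
#'   assigned DEG), `unassigned` (DEGs in no orthogroup), `orthogroups`
#'   (the table), and `species` (the orthogroup table's species universe).
#' @export
map_degs_to_orthogroups <- function(degs, orthogroups) {
  degs <- validate_degs(degs)
  orthogroups <- validate_orthogroups(orthogroups)
  og_species <- unique(orthogroups$species)
  missing <- setdiff(unique(degs$species), og_species)
  if (length(missing) > 0) {
    ams_abort(sprintf(
      "DEG species absent from orthogroup table: %s",
      paste(missing, collapse = ", ")
    ))
  }
  status <- degs |>
    dplyr::inner_join(orthogroups, by = c("species", "gene_id")) |>
    dplyr::select("orthogroup_id", "species", "direction", "gene_id") |>
    dplyr::arrange(.data$orthogroup_id, .data$species, .data$gene_id)
  unassigned <- degs |>
    dplyr::anti_join(orthogroups, by = c("species", "gene_id")) |>
    dplyr::arrange(.data$species, .data$gene_id)
  structure(
    list(status = status, unassigned = unassigned,
         orthogroups = orthogroups, species = og_species),
    class = "ams_regulation"
  )
}

#' @export
print.ams_regulation <- function(x, ...) {
  cat(sprintf(
    "Orthogroup regulation status: %d regulated orthogroups, %d assigned DEGs, %d unassigned DEGs, %d species\n",
    dplyr::n_distinct(x$status$orthogroup_id), nrow(x$status),
    nrow(x$unassigned), length(x$species)
  ))
  invisible(x)
}

# per-orthogroup supporting species (direction-restricted)
og_support <- function(reg, direction) {
  reg$status |>
    dplyr::filter(.data$direction == !!direction) |>
    dplyr::distinct(.data$orthogroup_id, .data$species)
}

#' Venn partition of regulated orthogroups across species
#'
#' Assigns each orthogroup regulated in the given direction to exactly one
#' region: the exact subset of species supporting it. All non-empty
#' subsets of `species` are listed, zero counts included, so the result
#' enumerates the full Venn diagram.
#'
#' @param reg `ams_regulation` object.
#' @param direction `"up"` or `"down"`.
#' @param species Species order defining the patterns; defaults to the
#'   orthogroup table's species.
#' @return Object of class `ams_venn`: tibble with columns `pattern`
#'   (species names joined by `+`, in `species` order), `n_species`, and
#'   `n` (orthogroup count); plus attributes `direction`, `species` and
#'   `unassigned` (per-species count of DEGs outside all orthogroups).
#' @export
venn_partition <- function(reg, direction = c("up", "down"),
                           species = reg$species) {
  direction <- match.arg(direction)
  sp_order <- species
  supp <- og_support(reg, direction) |>
    dplyr::filter(.data$species %in% sp_order)
  patt_of <- supp |>
    dplyr::group_by(.data$orthogroup_id) |>
    dplyr::summarise(
      pattern = paste(sp_order[sp_order %in% .data$species], collapse = "+"),
      .groups = "drop"
    )
  all_patterns <- unlist(lapply(seq_along(species), function(k) {
    utils::combn(species, k, FUN = paste, collapse = "+")
  }))
  counts <- table(factor(patt_of$pattern, levels = all_patterns))
  out <- tibble::tibble(
    pattern = all_patterns,
    n_species = stringr::str_count(all_patterns, stringr::fixed("+")) + 1L,
    n = as.integer(counts)
  )
  unassigned <- reg$unassigned |>
    dplyr::filter(.data$direction == !!direction) |>
    dplyr::count(.data$species, name = "n_unassigned")
  structure(out, direction = direction, species = species,
            unassigned = unassigned,
            class = c("ams_venn", class(out)))
}

#' Orthogroups supported by at least n species
#'
#' Cumulative query over a Venn partition.
#'
#' @param venn `ams_venn` tibble.
#' @param n Minimum number of supporting species.
#' @return Integer count of orthogroups whose support set has size >= n.
#' @export
venn_support_ge <- function(venn, n) {
  sum(venn$n[venn$n_species >= n])
}

#' Focal-species core set
#'
#' Focal DEGs of the given direction whose orthogroup is also regulated in
#' at least `min_other_species` non-focal species (same direction by
#' default; any direction with `same_direction = FALSE`).
#'
#' @param reg `ams_regulation` object.
#' @param focal Focal species label.
#' @param direction `"up"` or `"down"` (the focal genes' direction).
#' @param min_other_species Minimum supporting non-focal species
#'   (default 2, i.e. regulated in >= 3 of 5 species overall).
#' @param same_direction Require supporters to share the direction?
#' @return Tibble with one row per core gene: `gene_id`, `orthogroup_id`,
#'   `n_support`, `supporting_species` (comma-joined), sorted by
#'   orthogroup then gene.
#' @export
core_set <- function(reg, focal, direction = c("up", "down"),
                     min_other_species = 2, same_direction = TRUE) {
  direction <- match.arg(direction)
  if (!focal %in% reg$species) {
    ams_abort(sprintf("focal species '%s' not in orthogroup table", focal))
  }
  support <- if (same_direction) {
    og_support(reg, direction)
  } else {
    dplyr::distinct(reg$status, .data$orthogroup_id, .data$species)
  }
  support <- support |>
    dplyr::filter(.data$species != focal) |>
    dplyr::group_by(.data$orthogroup_id) |>
    dplyr::summarise(
      n_support = dplyr::n(),
      supporting_species = paste(sort(.data$species), collapse = ","),
      .groups = "drop"
    )
  reg$status |>
    dplyr::filter(.data$species == focal, .data$direction == !!direction) |>
    dplyr::inner_join(support, by = "orthogroup_id") |>
    dplyr::filter(.data$n_support >= min_other_species) |>
    dplyr::select("gene_id", "orthogroup_id", "n_support",
                  "supporting_species") |>
    dplyr::arrange(.data$orthogroup_id, .data$gene_id)
}

#' Conserved orthogroups lacking focal-species regulation
#'
#' Orthogroups regulated (given direction) in at least `min_species`
#' non-focal species while containing no focal DEG of that direction.
#'
#' @inheritParams core_set
#' @param min_species Minimum number of supporting non-focal species
#'   (default 3).
#' @return Tibble `orthogroup_id`, `n_support`, `supporting_species`.
#' @export
conserved_not_focal <- function(reg, focal, direction = c("up", "down"),
                                min_species = 3) {
  direction <- match.arg(direction)
  supp <- og_support(reg, direction)
  focal_ogs <- supp$orthogroup_id[supp$species == focal]
  supp |>
    dplyr::filter(.data$species != focal) |>
    dplyr::group_by(.data$orthogroup_id) |>
    dplyr::summarise(
      n_support = dplyr::n(),
      supporting_species = paste(sort(.data$species), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_support >= min_species,
                  !.data$orthogroup_id %in% focal_ogs) |>
    dplyr::arrange(.data$orthogroup_id)
}

#' Classify every focal DEG by cross-species sharing
#'
#' Categories (a partition of the focal DEG set, per direction):
#' `no_ortholog` (gene in no orthogroup, or in an orthogroup with no genes
#' from other species), `ortholog_not_regulated` (orthogroup has other
#' species' genes but none regulated in the same direction), `shared_1`
#' (exactly one other species with same-direction regulation), and
#' `shared_ge2` (two or more).
#'
#' @param reg `ams_regulation` object.
#' @param focal Focal species label.
#' @return Tibble `gene_id`, `direction`, `orthogroup_id` (`NA` when
#'   unassigned), `n_support`, `category`.
#' @export
classify_focal_degs <- function(reg, focal) {
  assigned <- reg$status |>
    dplyr::filter(.data$species == focal) |>
    dplyr::select("gene_id", "direction", "orthogroup_id")
  unassigned <- reg$unassigned |>
    dplyr::filter(.data$species == focal) |>
    dplyr::transmute(.data$gene_id, .data$direction,
                     orthogroup_id = NA_character_)
  has_other <- reg$orthogroups |>
    dplyr::filter(.data$species != focal) |>
    dplyr::distinct(.data$orthogroup_id)
  support <- reg$status |>
    dplyr::filter(.data$species != focal) |>
    dplyr::distinct(.data$orthogroup_id, .data$species, .data$direction) |>
    dplyr::count(.data$orthogroup_id, .data$direction, name = "n_support")
  dplyr::bind_rows(assigned, unassigned) |>
    dplyr::left_join(support, by = c("orthogroup_id", "direction")) |>
    dplyr::mutate(
      n_support = tidyr::replace_na(.data$n_support, 0L),
      category = dplyr::case_when(
        is.na(.data$orthogroup_id) ~ "no_ortholog",
        !.data$orthogroup_id %in% has_other$orthogroup_id ~ "no_ortholog",
        .data$n_support == 0 ~ "ortholog_not_regulated",
        .data$n_support == 1 ~ "shared_1",
        TRUE ~ "shared_ge2"
      )
    ) |>
    dplyr::arrange(.data$direction, .data$gene_id)
}

#' Cross-reference a curated gene list against regulation status
#'
#' For each curated entry: its orthogroup (if any), the species whose
#' same-direction regulation supports it, the support count, and whether
#' the focal species regulates the orthogroup. Entries in no orthogroup
#' are flagged with support 0.
#'
#' @param curated Tibble `name`, `species`, `gene_id`.
#' @param reg `ams_regulation` object.
#' @param focal Focal species label.
#' @param direction Direction of regulation checked (default `"up"`).
#' @return Tibble `name`, `species`, `gene_id`, `orthogroup_id`,
#'   `n_support` (species with same-direction regulation, focal included),
#'   `supporting_species`, `focal_regulated`, `in_orthogroup`.
#' @export
curated_crossref <- function(curated, reg, focal,
                             direction = c("up", "down")) {
  direction <- match.arg(direction)
  supp <- og_support(reg, direction) |>
    dplyr::group_by(.data$orthogroup_id) |>
    dplyr::summarise(
      n_support = dplyr::n(),
      supporting_species = paste(sort(.data$species), collapse = ","),
      focal_regulated = focal %in% .data$species,
      .groups = "drop"
    )
  curated |>
    dplyr::left_join(reg$orthogroups, by = c("species", "gene_id")) |>
    dplyr::left_join(supp, by = "orthogroup_id") |>
    dplyr::mutate(
      in_orthogroup = !is.na(.data$orthogroup_id),
      n_support = tidyr::replace_na(.data$n_support, 0L),
      supporting_species = dplyr::coalesce(.data$supporting_species, ""),
      focal_regulated = tidyr::replace_na(.data$focal_regulated, FALSE)
    ) |>
    dplyr::arrange(.data$name)
}

#' Support-count summary of a curated cross-reference
#'
#' @param crossref Result of [curated_crossref()].
#' @return Tibble `min_support`, `n_entries` giving, for each n, how many
#'   entries have support >= n.
#' @export
curated_support_summary <- function(crossref) {
  maxn <- max(crossref$n_support, 1L)
  tibble::tibble(
    min_support = seq_len(maxn),
    n_entries = vapply(seq_len(maxn),
                       function(k) sum(crossref$n_support >= k), integer(1))
  )
}
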