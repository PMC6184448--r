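# End-to-end orchestration: validate a manifest, run the enabled stages,
# and write a report directory of TSV tables plus a JSON run summary.

#' Run the full analysis pipeline
#'
#' Stages (each individually optional, controlled by what the manifest
#' provides and by `stages`): `quantify` (counts -> RPKM + detected-gene
#' filter), `deg` (empirical-noise DE calling for the focal species),
#' `conservation` (orthogroup mapping, Venn partitions, core set,
#' conserved-not-focal, curated cross-reference), `motif` (promoter
#' scanning). Manifest inputs are validated before any computation
#' starts; a missing input for an enabled stage fails fast.
#'
#' @param manifest Named list of inputs; recognised elements: `counts`,
#'   `conditions`, `catalog` (tibbles) or `counts_path` +
#'   `condition_map`; `degs` (tibble; focal DEGs are added from the
#'   `deg` stage when both are present); `orthogroups` (tibble or path);
#'   `promoters` (tibble or FASTA path); `curated` (tibble).
#' @param config `ams_config()` object.
#' @param out_dir Report directory (created; files are overwritten).
#' @param stages Character vector of stages to run; default all whose
#'   inputs are present.
#' @return Invisibly, a list of in-memory results (`rpkm`, `deg_fit`,
#'   `degs`, `regulation`, `venn_up`, `venn_down`, `core_up`,
#'   `conserved_not_focal_up`, `curated`, `motif`, `summary`).
#' @export
run_pipeline <- function(manifest, config = ams_config(), out_dir,
                         stages = NULL) {
  available <- c(
    quantify = !is.null(manifest$counts),
    deg = !is.null(manifest$counts),
    conservation = !is.null(manifest$orthogroups) &&
      (!is.null(manifest$degs) || !is.null(manifest$counts)),
    motif = !is.null(manifest$promoters)
  )
  stages <- stages %||% names(available)[available]
  bad <- setdiff(stages, names(available))
  if (length(bad) > 0) {
    ams_abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  missing <- stages[!available[stages]]
  if (length(missing) > 0) {
    ams_abort(sprintf("manifest lacks inputs for enabled stage(s): %s",
                      paste(missing, collapse = ", ")))
  }
  if (any(c("quantify", "deg") %in% stages)) {
    validate_counts(manifest$counts, manifest$conditions, manifest$catalog)
  }
  if ("conservation" %in% stages && !is.null(manifest$degs)) {
    validate_degs(manifest$degs)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  if ("quantify" %in% stages) {
    res$rpkm <- compute_rpkm(manifest$counts, manifest$catalog)
    readr::write_tsv(res$rpkm, file.path(out_dir, "rpkm.tsv"),
                     progress = FALSE)
  }
  if ("deg" %in% stages) {
    res$deg_fit <- noiseq(
      manifest$counts, manifest$conditions, manifest$catalog,
      fold_threshold = config$fold_threshold,
      p_threshold = config$p_threshold,
      zero_substitute = config$zero_substitute
    )
    focal_degs <- deg_sets(res$deg_fit, config$focal_species)
    for (dir in c("up", "down")) {
      readr::write_tsv(
        res$deg_fit$stats |>
          dplyr::filter(.data$is_deg, .data$direction == dir),
        file.path(out_dir, sprintf("deg_%s.tsv", dir)), progress = FALSE
      )
    }
    manifest$degs <- dplyr::bind_rows(
      manifest$degs |>
        (\(d) if (is.null(d)) NULL
         else dplyr::filter(d, .data$species != config$focal_species))(),
      focal_degs
    )
  }
  if ("conservation" %in% stages) {
    res$degs <- validate_degs(manifest$degs)
    res$regulation <- map_degs_to_orthogroups(res$degs,
                                              manifest$orthogroups)
    res$venn_up <- venn_partition(res$regulation, "up")
    res$venn_down <- venn_partition(res$regulation, "down")
    res$core_up <- core_set(
      res$regulation, config$focal_species, "up",
      min_other_species = config$core_min_other_species
    )
    res$conserved_not_focal_up <- conserved_not_focal(
      res$regulation, config$focal_species, "up",
      min_species = config$conserved_min_species
    )
    readr::write_tsv(res$venn_up, file.path(out_dir, "venn_up.tsv"),
                     progress = FALSE)
    readr::write_tsv(res$venn_down, file.path(out_dir, "venn_down.tsv"),
                     progress = FALSE)
    readr::write_tsv(res$core_up, file.path(out_dir, "core_set.tsv"),
                     progress = FALSE)
    readr::write_tsv(res$conserved_not_focal_up,
                     file.path(out_dir, "conserved_not_focal.tsv"),
                     progress = FALSE)
    if (!is.null(manifest$curated)) {
      res$curated <- curated_crossref(manifest$curated, res$regulation,
                                      config$focal_species)
      readr::write_tsv(res$curated,
                       file.path(out_dir, "curated_crossref.tsv"),
                       progress = FALSE)
    }
  }
  if ("motif" %in% stages) {
    promoters <- manifest$promoters
    if (is.character(promoters)) promoters <- read_promoters(promoters)
    res$motif <- scan_promoter_set(promoters, config$motif,
                                   config$max_mismatch)
    readr::write_tsv(res$motif$hits, file.path(out_dir, "motif_hits.tsv"),
                     progress = FALSE)
  }

  summary <- list(
    stages = stages,
    seed = config$random_seed,
    thresholds = list(
      fold_threshold = config$fold_threshold,
      p_threshold = config$p_threshold,
      core_min_other_species = config$core_min_other_species,
      conserved_min_species = config$conserved_min_species,
      max_mismatch = config$max_mismatch
    ),
    focal_species = config$focal_species,
    counts = list()
  )
  if (!is.null(res$deg_fit)) {
    summary$counts$deg_up <- sum(res$deg_fit$stats$is_deg &
                                   res$deg_fit$stats$direction == "up")
    summary$counts$deg_down <- sum(res$deg_fit$stats$is_deg &
                                     res$deg_fit$stats$direction == "down")
  }
  if (!is.null(res$core_up)) {
    summary$counts$core_up <- nrow(res$core_up)
    summary$counts$venn_all_species_up <-
      res$venn_up$n[res$venn_up$n_species == length(attr(res$venn_up,
                                                         "species"))]
    summary$counts$conserved_not_focal_up <-
      nrow(res$conserved_not_focal_up)
  }
  if (!is.null(res$motif)) {
    summary$counts$promoters_with_hit <- sum(res$motif$summary$any_hit)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$summary <- summary
  invisible(res)
}

#' Summarise a pipeline report directory
#'
#' Reads `summary.json` from a report directory and formats a short
#' per-stage account of counts and thresholds.
#'
#' @param report_dir Directory written by [run_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
summarize_report <- function(report_dir) {
  path <- file.path(report_dir, "summary.json")
  if (!file.exists(path)) {
    ams_abort(sprintf("no summary.json under '%s'", report_dir))
  }
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  lines <- character(0)
  if (length(s$stages) == 0) {
    lines <- "no stages run"
  } else {
    lines <- c(lines, sprintf("stages run: %s",
                              paste(s$stages, collapse = ", ")))
    lines <- c(lines, sprintf(
      "thresholds: fold >= %g, P >= %g; core support >= %d other species",
      s$thresholds$fold_threshold, s$thresholds$p_threshold,
      s$thresholds$core_min_other_species
    ))
    for (nm in names(s$counts)) {
      lines <- c(lines, sprintf("%s: %s", nm, s$counts[[nm]]))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
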