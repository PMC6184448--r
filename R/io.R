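# Readers and writers for every on-disk format the pipeline touches.
# All tabular files are TSV with one header line; '#'-prefixed lines are
# ignored on read. Gene identifiers are opaque, case-sensitive strings.

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Read a gene-by-sample count table
#'
#' The file is TSV: first column `gene_id`, optional second column `length`
#' (gene model length in bases), then one column per sample. Sample columns
#' must all be present in `condition_map`.
#'
#' @param path TSV file path.
#' @param condition_map Tibble with columns `sample`, `condition`
#'   (`"mycorrhizal"` or `"control"`), or a named character vector
#'   sample -> condition.
#' @param species Species label stored in the catalog (default `"Ptr"`).
#' @return A list with elements `counts` (wide tibble), `conditions`
#'   (tibble) and `catalog` (tibble or `NULL` if no length column).
#' @export
read_count_table <- function(path, condition_map, species = "Ptr") {
  if (!is.data.frame(condition_map)) {
    condition_map <- tibble::tibble(
      sample = names(condition_map),
      condition = unname(condition_map)
    )
  }
  df <- read_tsv_quiet(path)
  if (names(df)[1] != "gene_id") names(df)[1] <- "gene_id"
  catalog <- NULL
  if (ncol(df) >= 2 && tolower(names(df)[2]) %in% c("length", "length_bases")) {
    catalog <- tibble::tibble(
      species = species, gene_id = df$gene_id,
      length_bases = as.integer(df[[2]])
    )
    df[[2]] <- NULL
    catalog <- validate_catalog(catalog)
  }
  counts <- validate_counts(df, condition_map, catalog)
  list(counts = counts,
       conditions = tibble::as_tibble(condition_map),
       catalog = catalog)
}

#' Write a count table (round-trips with [read_count_table()])
#'
#' @param counts Wide count tibble (`gene_id` + sample columns).
#' @param path Output TSV path.
#' @param catalog Optional catalog; if given a `length` column is written.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, catalog = NULL) {
  out <- counts
  if (!is.null(catalog)) {
    out <- out |>
      dplyr::mutate(
        length = catalog$length_bases[match(.data$gene_id, catalog$gene_id)],
        .after = "gene_id"
      )
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an orthogroup table (OrthoFinder `Orthogroups.tsv` dialect)
#'
#' One orthogroup per row: first column the orthogroup id, then one column
#' per species holding a comma-separated gene list. The header line must
#' start with `Orthogroup`; species column order is taken from the header.
#' Rows whose gene columns are all empty are skipped with a warning.
#'
#' @param path Tab-separated orthogroup file.
#' @return Long tibble with columns `orthogroup_id`, `species`, `gene_id`.
#' @export
read_orthogroups <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  if (!startsWith(names(df)[1], "Orthogroup")) {
    ams_abort("orthogroup file must have a header starting with 'Orthogroup'")
  }
  names(df)[1] <- "orthogroup_id"
  long <- df |>
    tidyr::pivot_longer(-"orthogroup_id", names_to = "species",
                        values_to = "genes") |>
    dplyr::mutate(genes = dplyr::coalesce(.data$genes, "")) |>
    dplyr::mutate(gene_id = strsplit(.data$genes, ",", fixed = TRUE)) |>
    tidyr::unnest("gene_id") |>
    dplyr::mutate(gene_id = stringr::str_trim(.data$gene_id)) |>
    dplyr::filter(.data$gene_id != "") |>
    dplyr::select("orthogroup_id", "species", "gene_id")
  empty <- setdiff(df$orthogroup_id, long$orthogroup_id)
  if (length(empty) > 0) {
    rlang::warn(sprintf("skipping %d empty orthogroup row(s): %s",
                        length(empty),
                        paste(utils::head(empty, 3), collapse = ", ")))
  }
  validate_orthogroups(long)
}

#' Write an orthogroup table in the dialect [read_orthogroups()] accepts
#'
#' @param orthogroups Long orthogroup tibble.
#' @param path Output path.
#' @param species Column order; defaults to order of appearance.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(orthogroups, path,
                              species = unique(orthogroups$species)) {
  wide <- orthogroups |>
    dplyr::group_by(.data$orthogroup_id, .data$species) |>
    dplyr::summarise(genes = paste(.data$gene_id, collapse = ","),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "species", values_from = "genes",
                       values_fill = "") |>
    dplyr::arrange(.data$orthogroup_id)
  missing <- setdiff(species, names(wide))
  for (sp in missing) wide[[sp]] <- ""
  wide <- wide[, c("orthogroup_id", species)]
  names(wide)[1] <- "Orthogroup"
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a DEG identifier list
#'
#' Accepts either one gene id per line or a TSV with a `gene_id` column.
#' Duplicate ids collapse silently; an empty file yields an empty set.
#'
#' @param path Input file.
#' @param species Species label attached to every gene.
#' @param direction `"up"` or `"down"`.
#' @return Tibble with columns `species`, `direction`, `gene_id`.
#' @export
read_deg_list <- function(path, species, direction = c("up", "down")) {
  direction <- match.arg(direction)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(stringr::str_trim(lines))]
  ids <- character(0)
  if (length(lines) > 0) {
    if (grepl("\t", lines[1]) || identical(lines[1], "gene_id")) {
      df <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
      assert_df_has(df, "gene_id", "DEG list")
      ids <- df$gene_id
    } else {
      ids <- stringr::str_trim(lines)
    }
  }
  validate_degs(tibble::tibble(
    species = species, direction = direction, gene_id = unique(ids)
  ))
}

#' Combine per-species, per-direction DEG sets
#'
#' Errors when a gene appears in both directions for one species.
#'
#' @param ... DEG tibbles as returned by [read_deg_list()].
#' @return One validated DEG tibble.
#' @export
bind_deg_sets <- function(...) {
  validate_degs(dplyr::bind_rows(...))
}

#' Read promoter sequences from a FASTA file
#'
#' Sequences are uppercased and must be over the ACGTN alphabet.
#'
#' @param path FASTA file.
#' @return Tibble with columns `sequence_id`, `sequence`, in file order.
#' @export
read_promoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tb <- tibble::tibble(
    sequence_id = stringr::word(names(seqs), 1),
    sequence = unname(toupper(as.character(seqs)))
  )
  bad <- stringr::str_detect(tb$sequence, "[^ACGTN]")
  if (any(bad)) {
    ams_abort(sprintf("non-ACGTN character in sequence '%s'",
                      tb$sequence_id[which(bad)[1]]))
  }
  tb
}

#' Read sequencing reads from a FASTQ file (Phred+33)
#'
#' @param path FASTQ file.
#' @return Tibble with columns `read_id`, `bases` (uppercased),
#'   `qualities` (Phred+33 string).
#' @export
read_reads_fastq <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4 != 0) {
    ams_abort("FASTQ file length is not a multiple of 4 lines")
  }
  n <- length(lines) / 4
  ids <- sub("^@", "", stringr::word(lines[seq(1, by = 4, length.out = n)], 1))
  bases <- toupper(lines[seq(2, by = 4, length.out = n)])
  quals <- lines[seq(4, by = 4, length.out = n)]
  if (any(nchar(bases) != nchar(quals))) {
    i <- which(nchar(bases) != nchar(quals))[1]
    ams_abort(sprintf(
      "FASTQ record '%s': %d bases but %d quality symbols",
      ids[i], nchar(bases[i]), nchar(quals[i])
    ))
  }
  if (any(stringr::str_detect(bases, "[^ACGTN]"))) {
    i <- which(stringr::str_detect(bases, "[^ACGTN]"))[1]
    ams_abort(sprintf("FASTQ record '%s': non-IUPAC (ACGTN) base", ids[i]))
  }
  tibble::tibble(read_id = ids, bases = bases, qualities = quals)
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with `read_id`, `bases`, `qualities`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  out <- rbind(paste0("@", reads$read_id), reads$bases, "+", reads$qualities)
  readr::write_lines(as.vector(out), path)
  invisible(path)
}

#' Read a root-fragment colonization score table
#'
#' TSV with columns `root_id`, `colonization_class` (0..5) and
#' `arbuscule_class` (`A0`..`A3`); an optional
#' `degrading_arbuscule_class` column carries the re-scored degrading
#' arbuscule classes.
#'
#' @param path TSV path.
#' @return Validated fragment tibble.
#' @export
read_fragment_table <- function(path) {
  df <- read_tsv_quiet(path)
  validate_fragments(df)
}

#' Read a qPCR Ct table
#'
#' TSV with columns `sample`, `group`, `gene`, `ct` (threshold cycle).
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv_quiet(path)
  assert_df_has(df, c("sample", "group", "gene", "ct"), "Ct table")
  tibble::as_tibble(df)
}

#' Read a curated gene list
#'
#' TSV with columns `name`, `species`, `gene_id`; entry names must be
#' unique.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_curated_list <- function(path) {
  df <- read_tsv_quiet(path)
  assert_df_has(df, c("name", "species", "gene_id"), "curated list")
  if (anyDuplicated(df$name)) {
    ams_abort(sprintf("curated list: duplicate entry name '%s'",
                      df$name[duplicated(df$name)][1]))
  }
  tibble::as_tibble(df)
}
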