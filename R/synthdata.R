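# Seed-deterministic generators for every input the pipeline consumes,
# each returning planted ground truth alongside the data, plus the
# deterministic reference fixture whose conservation-analysis outputs
# reproduce the study's published summary counts.

.SPECIES5 <- c("Ptr", "Mtr", "Lja", "Osa", "Sly")

gene_id_style <- function(species, i) {
  prefix <- c(Ptr = "Cs", Mtr = "Medtr", Lja = "Lj", Osa = "Os",
              Sly = "Solyc")[species]
  prefix[is.na(prefix)] <- species[is.na(prefix)]
  sprintf("%s%s_%05d", prefix, "g", i)
}

#' Generate a random multi-species orthogroup universe
#'
#' Each orthogroup receives 0 or more genes per species: one gene with
#' probability `presence_rate`, plus extra paralogs with probability
#' `paralog_rate` each (geometric tail). Orphan genes belonging to no
#' orthogroup are added per species at `orphan_rate` relative to the
#' number of orthogroup genes. No gene ever occurs in two orthogroups.
#'
#' @param n_species Number of species (labels from the 5-species panel,
#'   then `sp6`, `sp7`, ...).
#' @param n_orthogroups Number of orthogroups (>= 1).
#' @param paralog_rate Probability of each additional paralog in \[0, 1).
#' @param orphan_rate Expected orphan genes per orthogroup gene, in \[0, 1].
#' @param presence_rate Probability a species is represented in an
#'   orthogroup (default 0.9).
#' @param seed Integer seed (required; same seed, identical universe).
#' @return List with `catalog` (tibble `species`, `gene_id`,
#'   `length_bases`), `orthogroups` (long tibble) and `orphans` (tibble
#'   `species`, `gene_id`).
#' @export
gen_orthogroup_universe <- function(n_species = 5, n_orthogroups = 100,
                                    paralog_rate = 0.1, orphan_rate = 0.05,
                                    presence_rate = 0.9, seed) {
  if (n_orthogroups < 1) ams_abort("n_orthogroups must be >= 1")
  if (paralog_rate < 0 || paralog_rate >= 1 || orphan_rate < 0 ||
      orphan_rate > 1) {
    ams_abort("rates must lie in [0, 1] (paralog_rate < 1)")
  }
  withr::local_seed(seed)
  species <- c(.SPECIES5, sprintf("sp%d", seq_len(max(0, n_species - 5)) + 5))
  species <- species[seq_len(n_species)]
  counter <- stats::setNames(rep(0L, n_species), species)
  rows <- vector("list", n_orthogroups * n_species)
  k <- 0L
  for (og in seq_len(n_orthogroups)) {
    og_id <- sprintf("OG%07d", og)
    for (sp in species) {
      if (stats::runif(1) > presence_rate) next
      n_genes <- 1L + stats::rgeom(1, 1 - paralog_rate)
      ids <- gene_id_style(rep(sp, n_genes), counter[[sp]] + seq_len(n_genes))
      counter[[sp]] <- counter[[sp]] + n_genes
      k <- k + 1L
      rows[[k]] <- tibble::tibble(orthogroup_id = og_id, species = sp,
                                  gene_id = ids)
    }
  }
  orthogroups <- dplyr::bind_rows(rows[seq_len(k)])
  orphans <- purrr::map(species, function(sp) {
    n_sp <- sum(orthogroups$species == sp)
    n_orphan <- stats::rbinom(1, n_sp, orphan_rate)
    if (n_orphan == 0) return(NULL)
    ids <- gene_id_style(rep(sp, n_orphan), counter[[sp]] + seq_len(n_orphan))
    tibble::tibble(species = sp, gene_id = ids)
  }) |> dplyr::bind_rows()
  if (nrow(orphans) == 0) {
    orphans <- tibble::tibble(species = character(), gene_id = character())
  }
  all_genes <- dplyr::bind_rows(
    orthogroups[, c("species", "gene_id")], orphans
  )
  catalog <- all_genes |>
    dplyr::mutate(length_bases = 1000L)
  list(catalog = catalog,
       orthogroups = validate_orthogroups(orthogroups),
       orphans = orphans)
}

#' Plant cross-species regulation into an orthogroup universe
#'
#' Selects `n_conserved_up` + `n_conserved_down` orthogroups and marks one
#' gene per species as a DEG (same direction) in `species_support_per_og`
#' species each (always including species present in the orthogroup;
#' infeasible requests error). Additional species-specific DEGs are
#' sprinkled into untouched orthogroups at `species_specific_rate` per
#' species per orthogroup.
#'
#' @param universe Result of [gen_orthogroup_universe()].
#' @param n_conserved_up,n_conserved_down Planted conserved orthogroups
#'   per direction.
#' @param species_support_per_og How many species support each planted
#'   orthogroup.
#' @param species_specific_rate Rate of extra single-species regulated
#'   orthogroups.
#' @param seed Integer seed.
#' @return List with `degs` (tibble `species`, `direction`, `gene_id`)
#'   and `truth` (tibble `orthogroup_id`, `direction`, `species`,
#'   `gene_id` of every planted conserved DEG).
#' @export
gen_regulation <- function(universe, n_conserved_up = 10,
                           n_conserved_down = 0,
                           species_support_per_og = 3,
                           species_specific_rate = 0.02, seed) {
  withr::local_seed(seed)
  og <- universe$orthogroups
  species <- unique(og$species)
  if (species_support_per_og > length(species)) {
    ams_abort("species_support_per_og exceeds the number of species")
  }
  # orthogroups with at least the requested species present
  rich <- og |>
    dplyr::distinct(.data$orthogroup_id, .data$species) |>
    dplyr::count(.data$orthogroup_id) |>
    dplyr::filter(.data$n >= species_support_per_og)
  n_wanted <- n_conserved_up + n_conserved_down
  if (nrow(rich) < n_wanted) {
    ams_abort(sprintf(
      "only %d orthogroup(s) contain >= %d species; %d conserved requested",
      nrow(rich), species_support_per_og, n_wanted
    ))
  }
  chosen <- sample(rich$orthogroup_id, n_wanted)
  dir_of <- rep(c("up", "down"), c(n_conserved_up, n_conserved_down))
  truth <- purrr::map2(chosen, dir_of, function(id, dir) {
    members <- og |> dplyr::filter(.data$orthogroup_id == id)
    sp_here <- unique(members$species)
    supp <- sample(sp_here, species_support_per_og)
    members |>
      dplyr::filter(.data$species %in% supp) |>
      dplyr::group_by(.data$species) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::transmute(.data$orthogroup_id, direction = dir,
                       .data$species, .data$gene_id)
  }) |> dplyr::bind_rows()
  # species-specific extras in untouched orthogroups
  free <- setdiff(unique(og$orthogroup_id), chosen)
  extras <- purrr::map(species, function(sp) {
    cand <- og |>
      dplyr::filter(.data$orthogroup_id %in% free, .data$species == sp) |>
      dplyr::group_by(.data$orthogroup_id) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    pick <- stats::runif(nrow(cand)) < species_specific_rate
    cand[pick, ] |>
      dplyr::transmute(species = sp, direction = "up", .data$gene_id)
  }) |> dplyr::bind_rows()
  degs <- dplyr::bind_rows(
    truth |> dplyr::select("species", "direction", "gene_id"),
    extras
  ) |>
    dplyr::distinct(.data$species, .data$gene_id, .keep_all = TRUE) |>
    validate_degs()
  list(degs = degs, truth = truth)
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Gene-wise control means are drawn log-uniformly on
#' \[`mean_range[1]`, `mean_range[2]`\]; mycorrhizal means are the control
#' means times the planted fold change (1 for null genes). Counts are
#' negative binomial with the given dispersion (Poisson at dispersion 0).
#' All synthetic genes have length 1000 b so RPKM stays proportional to
#' counts.
#'
#' @param n_genes Number of genes.
#' @param n_reps_per_condition Replicates per condition (default 3).
#' @param planted_fold_changes Named or unnamed vector of fold changes
#'   (> 0) for the first `length(planted_fold_changes)` genes; remaining
#'   genes are null (fold 1).
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2);
#'   0 gives Poisson counts.
#' @param mean_range Range of the log-uniform control-mean distribution.
#' @param seed Integer seed.
#' @return List with `counts` (wide tibble), `conditions`, `catalog`
#'   (all lengths 1000), and `truth` (tibble `gene_id`, `mu_control`,
#'   `fold`, `is_planted`).
#' @export
gen_counts <- function(n_genes = 1000, n_reps_per_condition = 3,
                       planted_fold_changes = numeric(0),
                       nb_dispersion = 0.05,
                       mean_range = c(100, 1000), seed) {
  if (any(planted_fold_changes <= 0)) ams_abort("fold changes must be > 0")
  if (nb_dispersion < 0) ams_abort("dispersion must be >= 0")
  if (length(planted_fold_changes) > n_genes) {
    ams_abort("more planted fold changes than genes")
  }
  withr::local_seed(seed)
  gene_id <- sprintf("Csg%05d", seq_len(n_genes))
  mu <- exp(stats::runif(n_genes, log(mean_range[1]), log(mean_range[2])))
  fold <- rep(1, n_genes)
  fold[seq_along(planted_fold_changes)] <- planted_fold_changes
  samples <- c(sprintf("myc_%d", seq_len(n_reps_per_condition)),
               sprintf("ctl_%d", seq_len(n_reps_per_condition)))
  conditions <- tibble::tibble(
    sample = samples,
    condition = rep(c("mycorrhizal", "control"),
                    each = n_reps_per_condition)
  )
  draw <- function(mu_vec) {
    if (nb_dispersion == 0) {
      stats::rpois(length(mu_vec), mu_vec)
    } else {
      stats::rnbinom(length(mu_vec), size = 1 / nb_dispersion, mu = mu_vec)
    }
  }
  counts <- tibble::tibble(gene_id = gene_id)
  for (s in samples) {
    is_myc <- conditions$condition[conditions$sample == s] == "mycorrhizal"
    counts[[s]] <- draw(if (is_myc) mu * fold else mu)
  }
  catalog <- tibble::tibble(species = "Ptr", gene_id = gene_id,
                            length_bases = 1000L)
  truth <- tibble::tibble(gene_id = gene_id, mu_control = mu, fold = fold,
                          is_planted = fold != 1)
  list(counts = counts, conditions = conditions, catalog = catalog,
       truth = truth)
}

#' Generate promoter sequences with planted motif copies
#'
#' Background bases are i.i.d. with the given GC content; motif copies
#' (with a requested number of substitutions, on a requested strand) are
#' written over the background at the recorded positions.
#'
#' @param n Number of promoters.
#' @param length Promoter length in bases (>= motif length).
#' @param gc GC content of the background, in \[0, 1\].
#' @param motif Motif string the plants derive from.
#' @param plant_spec Tibble with columns `sequence` (index 1..n),
#'   `position` (1-based start), `strand` (`+`/`-`), `mismatches`
#'   (substitutions applied), or `NULL` for no plants.
#' @param seed Integer seed.
#' @return List with `promoters` (tibble `sequence_id`, `sequence`) and
#'   `truth` (the realised plant table).
#' @export
gen_promoters <- function(n = 5, length = 1000, gc = 0.4, motif,
                          plant_spec = NULL, seed) {
  withr::local_seed(seed)
  m <- nchar(motif)
  if (length < m) ams_abort("promoter length must be >= motif length")
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(names(base_probs), length, TRUE, base_probs),
          collapse = "")
  }, character(1))
  truth <- tibble::tibble(
    sequence = integer(), position = integer(), strand = character(),
    mismatches = integer(), planted = character()
  )
  if (!is.null(plant_spec)) {
    for (i in seq_len(nrow(plant_spec))) {
      row <- plant_spec[i, ]
      if (row$position < 1 || row$position + m - 1 > length) {
        ams_abort(sprintf("plant %d does not fit in the promoter", i))
      }
      copy <- if (row$strand == "-") reverse_complement(motif) else motif
      if (row$mismatches > 0) {
        pos <- sample(m, row$mismatches)
        chars <- strsplit(copy, "")[[1]]
        for (p in pos) {
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
        }
        copy <- paste(chars, collapse = "")
      }
      s <- seqs[row$sequence]
      stringr::str_sub(s, row$position, row$position + m - 1) <- copy
      seqs[row$sequence] <- s
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        sequence = row$sequence, position = row$position,
        strand = row$strand, mismatches = row$mismatches, planted = copy
      ))
    }
  }
  list(
    promoters = tibble::tibble(
      sequence_id = sprintf("prom_%03d", seq_len(n)), sequence = seqs
    ),
    truth = truth
  )
}

#' Generate a root-fragment score table with known class composition
#'
#' Fragment colonization classes are multinomial with
#' `class_probabilities` (classes 0..5); arbuscule classes of mycorrhizal
#' fragments are multinomial with `arbuscule_probabilities` (A0..A3);
#' class-0 fragments are always A0. Alongside the table, the analytic
#' expectation of each Trouvelot parameter under the sampling
#' distribution is returned.
#'
#' @param n_fragments Number of fragments.
#' @param class_probabilities Length-6 probability vector for classes
#'   0..5 (sums to 1).
#' @param arbuscule_probabilities Length-4 probability vector for A0..A3
#'   given colonization class >= 1.
#' @param seed Integer seed.
#' @param root_id Root identifier written on each row.
#' @return List with `fragments` (tibble) and `expected` (tibble `F`,
#'   `M`, `m`, `a`, `A` — expectations under the generative distribution,
#'   ratios of expectations for the ratio-form parameters).
#' @export
gen_fragment_table <- function(n_fragments = 100,
                               class_probabilities =
                                 c(0.2, 0.1, 0.1, 0.2, 0.2, 0.2),
                               arbuscule_probabilities =
                                 c(0.1, 0.2, 0.3, 0.4),
                               seed, root_id = "root_1") {
  if (abs(sum(class_probabilities) - 1) > 1e-8 ||
      abs(sum(arbuscule_probabilities) - 1) > 1e-8) {
    ams_abort("probability vectors must sum to 1")
  }
  withr::local_seed(seed)
  cls <- sample(0:5, n_fragments, TRUE, class_probabilities)
  arb <- ifelse(
    cls == 0, "A0",
    sample(paste0("A", 0:3), n_fragments, TRUE, arbuscule_probabilities)
  )
  fragments <- tibble::tibble(
    root_id = root_id, colonization_class = cls, arbuscule_class = arb
  )
  # analytic expectations (ratio parameters as ratios of expectations)
  w <- c(0, 1, 5, 30, 70, 95)            # weight of class 0..5
  p <- class_probabilities
  p_myc <- sum(p[-1])
  e_M <- sum(w * p)
  e_m <- if (p_myc == 0) 0 else e_M / p_myc
  pa <- arbuscule_probabilities          # A0..A3 given myc
  aw <- c(0, 10, 50, 100)                # weight of A0..A3
  # E[a] = sum_j aw_j/100 * 100 * E[w | myc, class A_j] P(A_j | myc) / e_m
  e_a <- if (e_m == 0) 0 else sum(aw * pa) * (e_M / p_myc) / e_m
  e_A <- e_a * e_M / 100
  expected <- tibble::tibble(F = 100 * p_myc, M = e_M, m = e_m,
                             a = e_a, A = e_A)
  list(fragments = validate_fragments(fragments), expected = expected)
}
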