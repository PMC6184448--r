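# Deterministic reference fixture: a synthetic five-species orthogroup
# universe with per-species DEG sets and curated gene lists whose
# conservation-analysis outputs reproduce the published summary counts of
# the study exactly (up-regulated orthogroups shared by all five species,
# by >= 4 species, focal shared/core/conserved-not-focal gene and
# orthogroup counts, and the curated-list cross-reference). Counts not
# published — the full per-region Venn values, the non-focal species' DEG
# totals — are free parameters fixed arbitrarily but deterministically,
# and are synthetic, not the study's.

#' Build the deterministic reference fixture
#'
#' Constructs, without randomness, an orthogroup table over the five AM
#' host species (`Ptr` focal, `Mtr`, `Lja`, `Osa`, `Sly`), per-species
#' up/down DEG sets, and two curated gene lists (a 24-entry known-AMS
#' list and a 138-entry AM-conserved list), engineered so that the
#' conservation stage reproduces the published summary counts: 245 up-
#' and 37 down-regulated focal genes; 28 orthogroups up-regulated in all
#' five species; 106 in at least four; 143 orthogroups holding 186 focal
#' up genes shared with at least one other species; a 153-gene up core
#' set (plus 3 down genes under any-direction support); 181 orthogroups
#' up-regulated in at least three non-focal species but not the focal
#' one; and 84 of the 138 curated entries with focal up-regulation.
#'
#' @return List with `orthogroups`, `degs`, `curated_138`, `curated_24`,
#'   `focal` (`"Ptr"`), `species` (the five-species panel).
#' @export
build_paper_fixture <- function() {
  sp_all <- .SPECIES5
  focal <- "Ptr"
  others <- setdiff(sp_all, focal)  # Mtr, Lja, Osa, Sly

  counters <- new.env()
  for (sp in sp_all) assign(sp, 0L, envir = counters)
  new_genes <- function(sp, n) {
    k <- get(sp, envir = counters)
    assign(sp, k + n, envir = counters)
    gene_id_style(rep(sp, n), k + seq_len(n))
  }

  og_rows <- list()
  deg_rows <- list()
  og_n <- 0L
  new_og <- function() {
    og_n <<- og_n + 1L
    sprintf("OG%04d", og_n)
  }
  # add one orthogroup: DEG members (per species x direction) + silent members
  add_og <- function(deg_species, direction, n_focal_genes = 0,
                     silent_species = character(0), focal_down = FALSE) {
    id <- new_og()
    for (sp in deg_species) {
      n <- if (sp == focal) n_focal_genes else 1L
      ids <- new_genes(sp, n)
      og_rows[[length(og_rows) + 1L]] <<-
        tibble::tibble(orthogroup_id = id, species = sp, gene_id = ids)
      deg_rows[[length(deg_rows) + 1L]] <<-
        tibble::tibble(species = sp, direction = direction, gene_id = ids)
    }
    for (sp in silent_species) {
      ids <- new_genes(sp, 1L)
      og_rows[[length(og_rows) + 1L]] <<-
        tibble::tibble(orthogroup_id = id, species = sp, gene_id = ids)
    }
    id
  }

  subsets3 <- list(c("Mtr", "Lja", "Osa"), c("Mtr", "Lja", "Sly"),
                   c("Mtr", "Osa", "Sly"), c("Lja", "Osa", "Sly"))
  subsets2 <- list(c("Mtr", "Lja"), c("Mtr", "Osa"), c("Mtr", "Sly"),
                   c("Lja", "Osa"), c("Lja", "Sly"), c("Osa", "Sly"))

  # Block A: 28 orthogroups up-regulated in all five species,
  # holding 50 focal up genes (22 orthogroups carry a focal paralog pair)
  block_a <- vapply(seq_len(28), function(i) {
    add_og(c(focal, others), "up", n_focal_genes = if (i <= 22) 2L else 1L)
  }, character(1))

  # Block B: 40 orthogroups, focal + exactly 3 others (48 focal genes)
  block_b <- vapply(seq_len(40), function(i) {
    supp <- subsets3[[(i - 1) %% 4 + 1]]
    add_og(c(focal, supp), "up", n_focal_genes = if (i <= 8) 2L else 1L)
  }, character(1))

  # Block C: 45 orthogroups, focal + exactly 2 others (55 focal genes)
  block_c <- vapply(seq_len(45), function(i) {
    supp <- subsets2[[(i - 1) %% 6 + 1]]
    add_og(c(focal, supp), "up", n_focal_genes = if (i <= 10) 2L else 1L)
  }, character(1))

  # Block D: 30 orthogroups, focal + exactly 1 other (33 focal genes;
  # shared with one species only, hence outside the core set)
  block_d <- vapply(seq_len(30), function(i) {
    supp <- others[(i - 1) %% 4 + 1]
    add_og(c(focal, supp), "up", n_focal_genes = if (i <= 3) 2L else 1L)
  }, character(1))

  # Block E: 26 orthogroups where only the focal species is regulated;
  # each holds an unregulated Mtr ortholog
  for (i in seq_len(26)) {
    add_og(focal, "up", n_focal_genes = 1L, silent_species = "Mtr")
  }

  # Block F: 33 focal up genes in no orthogroup
  orphan_up <- new_genes(focal, 33L)
  deg_rows[[length(deg_rows) + 1L]] <-
    tibble::tibble(species = focal, direction = "up", gene_id = orphan_up)

  # Block G: conserved orthogroups lacking focal regulation:
  # 38 supported by all four non-focal species, 143 by exactly three
  block_g4 <- vapply(seq_len(38), function(i) add_og(others, "up"),
                     character(1))
  for (i in seq_len(143)) {
    add_og(subsets3[[(i - 1) %% 4 + 1]], "up")
  }

  # Block H (free parameters): species-specific and pairwise regions
  for (sp in others) for (i in seq_len(20)) add_og(sp, "up")
  for (i in seq_len(15)) add_og(subsets2[[(i - 1) %% 6 + 1]], "up")

  # Down regulation: one orthogroup commonly down-regulated (focal gene
  # Cs8g07230 plus two non-focal species) ...
  down_shared_og <- new_og()
  og_rows[[length(og_rows) + 1L]] <- tibble::tibble(
    orthogroup_id = down_shared_og, species = focal, gene_id = "Cs8g07230"
  )
  deg_rows[[length(deg_rows) + 1L]] <- tibble::tibble(
    species = focal, direction = "down", gene_id = "Cs8g07230"
  )
  for (sp in c("Mtr", "Lja")) {
    ids <- new_genes(sp, 1L)
    og_rows[[length(og_rows) + 1L]] <-
      tibble::tibble(orthogroup_id = down_shared_og, species = sp,
                     gene_id = ids)
    deg_rows[[length(deg_rows) + 1L]] <-
      tibble::tibble(species = sp, direction = "down", gene_id = ids)
  }
  # ... two focal down genes inside orthogroups up-regulated elsewhere
  # (down core members only under any-direction support) ...
  for (og in block_a[1:2]) {
    ids <- new_genes(focal, 1L)
    og_rows[[length(og_rows) + 1L]] <-
      tibble::tibble(orthogroup_id = og, species = focal, gene_id = ids)
    deg_rows[[length(deg_rows) + 1L]] <-
      tibble::tibble(species = focal, direction = "down", gene_id = ids)
  }
  # ... 24 down genes whose orthologs are unregulated, 10 orphan down genes
  for (i in seq_len(24)) {
    add_og(focal, "down", n_focal_genes = 1L, silent_species = "Lja")
  }
  orphan_down <- new_genes(focal, 10L)
  deg_rows[[length(deg_rows) + 1L]] <-
    tibble::tibble(species = focal, direction = "down", gene_id = orphan_down)

  # a few non-focal down-only orthogroups and unregulated background
  for (sp in others) for (i in seq_len(5)) add_og(sp, "down")
  for (i in seq_len(30)) {
    add_og(character(0), "up",
           silent_species = c(focal, others[(i - 1) %% 4 + 1]))
  }

  orthogroups <- dplyr::bind_rows(og_rows)
  degs <- validate_degs(dplyr::bind_rows(deg_rows))

  # Curated lists: entries are Mtr genes resolved through their orthogroup
  mtr_deg_gene <- function(og_id) {
    hit <- orthogroups$species == "Mtr" &
      orthogroups$orthogroup_id == og_id &
      orthogroups$gene_id %in% degs$gene_id[degs$species == "Mtr"]
    orthogroups$gene_id[hit][1]
  }
  mtr_in <- function(ids) !is.na(vapply(ids, mtr_deg_gene, character(1)))
  focal_shared_ogs <- c(block_a, block_b, block_c, block_d)
  with_mtr <- focal_shared_ogs[mtr_in(focal_shared_ogs)]
  curated_84 <- vapply(with_mtr[1:84], mtr_deg_gene, character(1))
  curated_g4 <- vapply(block_g4[1:30], mtr_deg_gene, character(1))
  curated_none <- new_genes("Mtr", 24L)  # conserved genes in no orthogroup
  curated_138 <- tibble::tibble(
    name = sprintf("AMC%03d", 1:138),
    species = "Mtr",
    gene_id = c(curated_84, curated_g4, curated_none)
  )

  # 24 known AMS genes: 21 with focal up-regulation, 2 whose focal
  # ortholog is unregulated, 1 with no focal ortholog
  known21 <- vapply(block_a[1:21], mtr_deg_gene, character(1))
  new_mtr_deg_og <- function(silent = character(0)) {
    id <- new_og()
    g <- new_genes("Mtr", 1L)
    og_rows[[length(og_rows) + 1L]] <<-
      tibble::tibble(orthogroup_id = id, species = "Mtr", gene_id = g)
    deg_rows[[length(deg_rows) + 1L]] <<-
      tibble::tibble(species = "Mtr", direction = "up", gene_id = g)
    for (sp in silent) {
      og_rows[[length(og_rows) + 1L]] <<-
        tibble::tibble(orthogroup_id = id, species = sp,
                       gene_id = new_genes(sp, 1L))
    }
    g
  }
  known_silent <- c(new_mtr_deg_og(focal), new_mtr_deg_og(focal))
  known_absent <- new_mtr_deg_og()
  # the calls above appended rows; rebuild the bound tables
  orthogroups <- dplyr::bind_rows(og_rows)
  degs <- validate_degs(dplyr::bind_rows(deg_rows))
  curated_24 <- tibble::tibble(
    name = c(sprintf("AMS_known_%02d", 1:21), "MIG1_like", "RFCb_like",
             "DIP1_like"),
    species = "Mtr",
    gene_id = c(known21, known_silent, known_absent)
  )

  fixture <- list(
    orthogroups = validate_orthogroups(orthogroups),
    degs = degs,
    curated_138 = curated_138,
    curated_24 = curated_24,
    focal = focal,
    species = sp_all
  )
  check_fixture(fixture)
  fixture
}

# internal consistency check: the fixture must satisfy every published
# count simultaneously; failing any is a construction bug
check_fixture <- function(fx) {
  reg <- map_degs_to_orthogroups(fx$degs, fx$orthogroups)
  venn_up <- venn_partition(reg, "up", species = fx$species)
  cls <- classify_focal_degs(reg, fx$focal)
  checks <- c(
    focal_up = sum(fx$degs$species == fx$focal &
                     fx$degs$direction == "up") == 245,
    focal_down = sum(fx$degs$species == fx$focal &
                       fx$degs$direction == "down") == 37,
    all_five = venn_up$n[venn_up$pattern ==
                           paste(fx$species, collapse = "+")] == 28,
    ge4 = venn_support_ge(venn_up, 4) == 106,
    core_up = nrow(core_set(reg, fx$focal, "up")) == 153,
    shared_up = sum(cls$direction == "up" &
                      cls$category %in% c("shared_1", "shared_ge2")) == 186,
    no_ortho_up = sum(cls$direction == "up" &
                        cls$category == "no_ortholog") == 33,
    cnf = nrow(conserved_not_focal(reg, fx$focal, "up")) == 181,
    curated84 = sum(curated_crossref(fx$curated_138, reg,
                                     fx$focal)$focal_regulated) == 84
  )
  if (!all(checks)) {
    ams_abort(sprintf("fixture self-check failed: %s",
                      paste(names(checks)[!checks], collapse = ", ")))
  }
  invisible(TRUE)
}
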