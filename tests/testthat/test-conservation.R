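og3 <- tibble::tibble(
  orthogroup_id = c("OG1", "OG1", "OG2", "OG2", "OG3"),
  species = c("A", "B", "A", "A", "C"),
  gene_id = c("a1", "b1", "a2", "a3", "c1")
)

test_that("DEGs map to orthogroups with per-direction bookkeeping", {
  degs <- tibble::tibble(
    species = c("A", "B", "A", "A", "A"),
    direction = c("up", "up", "up", "down", "up"),
    gene_id = c("a1", "b1", "a2", "a3", "a_orphan")
  )
  reg <- map_degs_to_orthogroups(degs, og3)
  expect_equal(nrow(reg$status), 4)
  # an orthogroup can hold both directions from one species
  og2 <- reg$status[reg$status$orthogroup_id == "OG2", ]
  expect_setequal(og2$direction, c("up", "down"))
  # orphan recorded as unassigned, never silently dropped
  expect_equal(reg$unassigned$gene_id, "a_orphan")
  # DEG species absent from the orthogroup table errors
  expect_error(
    map_degs_to_orthogroups(
      tibble::tibble(species = "Z", direction = "up", gene_id = "z1"), og3
    ),
    "absent"
  )
})

test_that("venn partition assigns each orthogroup to its exact support set", {
  degs <- tibble::tibble(
    species = c("A", "A", "B", "A", "B", "C"),
    direction = "up",
    gene_id = c("a1", "a2", "b1", "a4", "b2", "c1")
  )
  og <- tibble::tibble(
    orthogroup_id = c("OG1", "OG2", "OG2", "OG3", "OG3", "OG3"),
    species = c("A", "A", "B", "A", "B", "C"),
    gene_id = c("a1", "a2", "b1", "a4", "b2", "c1")
  )
  reg <- map_degs_to_orthogroups(degs, og)
  venn <- venn_partition(reg, "up", species = c("A", "B", "C"))
  expect_equal(venn$n[venn$pattern == "A"], 1)
  expect_equal(venn$n[venn$pattern == "A+B"], 1)
  expect_equal(venn$n[venn$pattern == "A+B+C"], 1)
  expect_equal(sum(venn$n), 3)  # conservation: regions partition the OGs
  expect_equal(venn_support_ge(venn, 2), 2)
})

test_that("venn partition equals the brute-force oracle on random universes", {
  for (i in 1:60) {
    n_sp <- 2 + (i %% 5)            # up to 6 species
    n_og <- 10 + 13 * (i %% 20)
    uni <- random_universe(n_sp, n_og, seed = 1000 + i)
    og <- uni[, c("orthogroup_id", "species", "gene_id")]
    degs <- uni[, c("species", "direction", "gene_id")]
    reg <- map_degs_to_orthogroups(degs, og)
    species <- sprintf("s%d", seq_len(n_sp))
    venn <- venn_partition(reg, "up", species = species)
    want <- oracle_venn(reg$status, species, "up")
    expect_equal(stats::setNames(venn$n, venn$pattern), want)
  }
})

test_that("core set requires same-direction support from other species", {
  og <- tibble::tibble(
    orthogroup_id = c("OG1", "OG1", "OG1", "OG2", "OG2", "OG3", "OG3"),
    species = c("F", "X", "Y", "F", "X", "F", "X"),
    gene_id = c("f1", "x1", "y1", "f2", "x2", "f3", "x3")
  )
  degs <- tibble::tibble(
    species = c("F", "X", "Y", "F", "X", "F", "X"),
    direction = c("up", "up", "up", "up", "up", "up", "down"),
    gene_id = c("f1", "x1", "y1", "f2", "x2", "f3", "x3")
  )
  reg <- map_degs_to_orthogroups(degs, og)
  core2 <- core_set(reg, "F", "up", min_other_species = 2)
  expect_equal(core2$gene_id, "f1")
  expect_equal(core2$n_support, 2)
  expect_equal(core2$supporting_species, "X,Y")
  # support 1 excluded at the default threshold, included at 1
  core1 <- core_set(reg, "F", "up", min_other_species = 1)
  expect_setequal(core1$gene_id, c("f1", "f2"))
  # any-direction support admits f3
  core_any <- core_set(reg, "F", "up", min_other_species = 1,
                       same_direction = FALSE)
  expect_setequal(core_any$gene_id, c("f1", "f2", "f3"))
  # monotone in the threshold
  expect_true(all(core2$gene_id %in% core1$gene_id))
  expect_equal(nrow(core_set(reg, "F", "up", min_other_species = 3)), 0)
})

test_that("conserved-not-focal orthogroups exclude any focal regulation", {
  og <- tibble::tibble(
    orthogroup_id = rep(c("OG1", "OG2", "OG3"), each = 4),
    species = rep(c("F", "X", "Y", "Z"), 3),
    gene_id = sprintf("g%d", 1:12)
  )
  degs <- tibble::tibble(
    species = c("X", "Y", "Z",  "F", "X", "Y", "Z",  "X", "Y"),
    direction = "up",
    gene_id = c("g2", "g3", "g4", "g5", "g6", "g7", "g8", "g10", "g11")
  )
  reg <- map_degs_to_orthogroups(degs, og)
  cnf <- conserved_not_focal(reg, "F", "up", min_species = 3)
  expect_equal(cnf$orthogroup_id, "OG1")   # OG2 has focal DEG, OG3 only 2
})

test_that("focal DEG classification partitions the DEG set", {
  fx <- build_paper_fixture()
  reg <- map_degs_to_orthogroups(fx$degs, fx$orthogroups)
  cls <- classify_focal_degs(reg, fx$focal)
  n_focal <- sum(fx$degs$species == fx$focal)
  expect_equal(nrow(cls), n_focal)
  expect_equal(anyDuplicated(cls$gene_id), 0)
  expect_true(all(cls$category %in% c("no_ortholog",
                                      "ortholog_not_regulated",
                                      "shared_1", "shared_ge2")))
})

test_that("noise-free planted universes are recovered exactly", {
  uni <- gen_orthogroup_universe(n_species = 5, n_orthogroups = 150,
                                 paralog_rate = 0, orphan_rate = 0,
                                 presence_rate = 1, seed = 42)
  regn <- gen_regulation(uni, n_conserved_up = 12,
                         species_support_per_og = 3,
                         species_specific_rate = 0, seed = 43)
  reg <- map_degs_to_orthogroups(regn$degs, uni$orthogroups)
  # any focal species among the supporters: planted focal genes = core set
  for (focal in unique(regn$truth$species)) {
    planted <- regn$truth |>
      dplyr::filter(species == focal, direction == "up")
    core <- core_set(reg, focal, "up", min_other_species = 2)
    expect_setequal(core$gene_id, planted$gene_id)  # precision = recall = 1
  }
  # planted orthogroups without focal support = conserved_not_focal
  focal <- "Ptr"
  expected_cnf <- regn$truth |>
    dplyr::group_by(orthogroup_id) |>
    dplyr::filter(!focal %in% species) |>
    dplyr::distinct(orthogroup_id)
  cnf <- conserved_not_focal(reg, focal, "up", min_species = 3)
  expect_setequal(cnf$orthogroup_id, expected_cnf$orthogroup_id)
})

test_that("removing a species' DEG set never raises other support counts", {
  fx <- build_paper_fixture()
  reg_full <- map_degs_to_orthogroups(fx$degs, fx$orthogroups)
  core_full <- core_set(reg_full, "Ptr", "up")
  reg_drop <- map_degs_to_orthogroups(
    fx$degs |> dplyr::filter(species != "Sly"), fx$orthogroups
  )
  core_drop <- core_set(reg_drop, "Ptr", "up", min_other_species = 0)
  merged <- dplyr::inner_join(core_full, core_drop, by = "gene_id")
  expect_true(all(merged$n_support.y <= merged$n_support.x))
})

test_that("curated cross-reference reports support and flags unplaced genes", {
  og <- tibble::tibble(
    orthogroup_id = c("OG1", "OG1", "OG1", "OG1"),
    species = c("F", "X", "Y", "M"),
    gene_id = c("f1", "x1", "y1", "m1")
  )
  degs <- tibble::tibble(
    species = c("F", "X", "Y"), direction = "up",
    gene_id = c("f1", "x1", "y1")
  )
  reg <- map_degs_to_orthogroups(degs, og)
  curated <- tibble::tibble(
    name = c("gene_in", "gene_out"),
    species = c("M", "M"), gene_id = c("m1", "m_absent")
  )
  cross <- curated_crossref(curated, reg, "F")
  expect_equal(cross$n_support, c(3, 0))
  expect_equal(cross$focal_regulated, c(TRUE, FALSE))
  expect_equal(cross$in_orthogroup, c(TRUE, FALSE))
  summ <- curated_support_summary(cross)
  expect_equal(summ$n_entries[summ$min_support == 1], 1)
})
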