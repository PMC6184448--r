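test_that("orthogroup universes respect rates, invariants, and seeds", {
  u <- gen_orthogroup_universe(n_species = 4, n_orthogroups = 60,
                               paralog_rate = 0, orphan_rate = 0, seed = 3)
  per <- u$orthogroups |> dplyr::count(orthogroup_id, species)
  expect_true(all(per$n == 1))  # no paralogs
  expect_equal(nrow(u$orphans), 0)

  # determinism: same seed, identical universe
  u2 <- gen_orthogroup_universe(n_species = 4, n_orthogroups = 60,
                                paralog_rate = 0, orphan_rate = 0, seed = 3)
  expect_identical(u, u2)
  u3 <- gen_orthogroup_universe(n_species = 4, n_orthogroups = 60,
                                paralog_rate = 0, orphan_rate = 0, seed = 4)
  expect_false(identical(u$orthogroups, u3$orthogroups))

  expect_error(gen_orthogroup_universe(n_orthogroups = 0, seed = 1), ">= 1")

  # invariant sweep: a gene never lands in two orthogroups
  for (s in 1:40) {
    us <- gen_orthogroup_universe(n_species = 3, n_orthogroups = 25,
                                  paralog_rate = 0.3, orphan_rate = 0.2,
                                  seed = s)
    expect_silent(validate_orthogroups(us$orthogroups))
    expect_equal(nrow(dplyr::intersect(
      us$orphans, us$orthogroups[, c("species", "gene_id")]
    )), 0)
  }
})

test_that("planted regulation is recovered by construction", {
  u <- gen_orthogroup_universe(n_species = 5, n_orthogroups = 80,
                               paralog_rate = 0, orphan_rate = 0,
                               presence_rate = 1, seed = 9)
  r <- gen_regulation(u, n_conserved_up = 10, species_support_per_og = 5,
                      species_specific_rate = 0, seed = 10)
  reg <- map_degs_to_orthogroups(r$degs, u$orthogroups)
  venn <- venn_partition(reg, "up")
  full <- paste(reg$species, collapse = "+")
  expect_equal(venn$n[venn$pattern == full], 10)

  # planting only up leaves the down Venn empty
  venn_down <- venn_partition(reg, "down")
  expect_equal(sum(venn_down$n), 0)

  # infeasible request errors with the limiting quantity
  expect_error(
    gen_regulation(u, n_conserved_up = 500, species_support_per_og = 5,
                   seed = 1),
    "orthogroup"
  )
})

test_that("count simulation plants fold changes at the requested depth", {
  # few planted genes so the library-size shift stays negligible
  sim <- gen_counts(n_genes = 1000, planted_fold_changes = rep(4, 10),
                    nb_dispersion = 0.001, mean_range = c(1000, 2000),
                    seed = 6)
  expect_equal(sum(sim$truth$is_planted), 10)
  # near-zero dispersion, fold 4, large mu: M close to 2 for most genes
  # (checked on the counts themselves, where the fold change is planted)
  md <- md_statistics(sim$counts, sim$conditions)
  planted_M <- md$M[sim$truth$is_planted]
  expect_gte(mean(abs(planted_M - 2) < 0.1), 0.95)

  # determinism
  sim2 <- gen_counts(n_genes = 1000, planted_fold_changes = rep(4, 10),
                     nb_dispersion = 0.001, mean_range = c(1000, 2000),
                     seed = 6)
  expect_identical(sim$counts, sim2$counts)

  expect_error(gen_counts(planted_fold_changes = -1, seed = 1), "> 0")
})

test_that("promoter generation plants verifiable motif copies", {
  motif <- "CTTCTTGTTC"
  spec <- tibble::tibble(sequence = c(1, 2), position = c(11, 41),
                         strand = c("+", "-"), mismatches = c(0, 1))
  gp <- gen_promoters(n = 3, length = 120, gc = 0.45, motif = motif,
                      plant_spec = spec, seed = 20)
  expect_equal(nchar(gp$promoters$sequence), rep(120, 3))
  expect_equal(nrow(gp$truth), 2)
  res <- scan_promoter_set(gp$promoters, motif, max_mismatch = 1)
  h1 <- res$hits[res$hits$sequence_id == "prom_001", ]
  expect_true(any(h1$start == 11 & h1$mismatches == 0))
  h2 <- res$hits[res$hits$sequence_id == "prom_002", ]
  expect_true(any(h2$start == 41 & h2$strand == "-" & h2$mismatches == 1))

  gp2 <- gen_promoters(n = 3, length = 120, gc = 0.45, motif = motif,
                       plant_spec = spec, seed = 20)
  expect_identical(gp, gp2)
  expect_error(
    gen_promoters(n = 1, length = 50, gc = 0.5, motif = motif,
                  plant_spec = tibble::tibble(sequence = 1, position = 45,
                                              strand = "+", mismatches = 0),
                  seed = 1),
    "fit"
  )
})

test_that("random-background hit counts match the binomial expectation", {
  # no plants: expected hits ~ 2 (L - m + 1) * P(Hamming <= 1) at gc = 0.5
  motif <- strrep("ACGT", 2)  # 8-mer, uniform background
  m <- 8
  L <- 20000
  gp <- gen_promoters(n = 5, length = L, gc = 0.5, motif = motif, seed = 30)
  res <- scan_promoter_set(gp$promoters, motif, max_mismatch = 1)
  p_hit <- 0.25^m + m * 0.75 * 0.25^(m - 1)
  windows <- 2 * (L - m + 1) * 5
  expected <- windows * p_hit
  sd3 <- 3 * sqrt(windows * p_hit * (1 - p_hit))
  expect_lt(abs(sum(res$summary$n_hits) - expected), sd3)
})

test_that("fragment tables match their analytic expectations", {
  g <- gen_fragment_table(n_fragments = 40,
                          class_probabilities = c(0, 0, 0, 0, 0, 1),
                          arbuscule_probabilities = c(0, 0, 0, 1),
                          seed = 2)
  expect_equal(unlist(g$expected),
               c(F = 100, M = 95, m = 95, a = 100, A = 95))
  obs <- trouvelot_summary(g$fragments)
  expect_equal(unlist(obs), unlist(g$expected))

  # class 0 always forces A0
  g2 <- gen_fragment_table(n_fragments = 500,
                           class_probabilities = c(0.5, 0.1, 0.1, 0.1,
                                                   0.1, 0.1),
                           arbuscule_probabilities = c(0.25, 0.25, 0.25,
                                                       0.25),
                           seed = 3)
  zero <- g2$fragments[g2$fragments$colonization_class == 0, ]
  expect_true(all(zero$arbuscule_class == "A0"))

  # Monte-Carlo convergence towards the expectation with growing n
  g3 <- gen_fragment_table(n_fragments = 20000, seed = 4)
  obs3 <- suppressWarnings(trouvelot_summary(g3$fragments))
  expect_lt(abs(obs3$F - g3$expected$F), 2)
  expect_lt(abs(obs3$M - g3$expected$M), 2)
  expect_lt(abs(obs3$a - g3$expected$a), 3)

  expect_error(
    gen_fragment_table(class_probabilities = c(1, 1, 0, 0, 0, 0), seed = 1),
    "sum to 1"
  )
})

test_that("the reference fixture reproduces its published construction", {
  fx <- build_paper_fixture()
  expect_identical(fx, build_paper_fixture())  # deterministic
  expect_equal(sum(fx$degs$species == "Ptr" & fx$degs$direction == "up"),
               245)
  expect_equal(sum(fx$degs$species == "Ptr" & fx$degs$direction == "down"),
               37)
  expect_equal(nrow(fx$curated_138), 138)
  expect_equal(nrow(fx$curated_24), 24)
  expect_silent(validate_orthogroups(fx$orthogroups))
})
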