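test_that("M and D statistics follow the zero-substitution rule", {
  # means: myc = 4, ctl = 1 -> M = 2, D = 3
  expr <- tiny_counts(rbind(c(4, 4, 4, 1, 1, 1),
                            c(7, 7, 7, 7, 7, 7),
                            c(2, 2, 2, 0, 0, 0)))
  md <- md_statistics(expr, tiny_conditions())
  expect_equal(md$M, c(2, 0, 2))  # g3: log2(2 / 0.5) = 2 under k = 0.5
  expect_equal(md$D, c(3, 0, 2))

  # a condition with no samples errors
  bad_cond <- tibble::tibble(sample = names(expr)[-1],
                             condition = "control")
  expect_error(md_statistics(expr, bad_cond), "both conditions")
})

test_that("noise distribution pools within-condition replicate pairs", {
  g <- 7
  set.seed(4)
  expr <- tiny_counts(matrix(rpois(g * 6, 100), nrow = g))
  noise <- noise_distribution(expr, tiny_conditions())
  # 3 vs 3 replicates: (C(3,2) + C(3,2)) * G = 6G points
  expect_equal(nrow(noise), 6 * g)
  expect_true(all(noise$d >= 0) && all(noise$m >= 0))

  # identical replicates within conditions -> all points at (0, 0)
  flat <- tiny_counts(matrix(rep(c(5, 5, 5, 9, 9, 9), each = 3),
                             nrow = 3, byrow = FALSE))
  n0 <- noise_distribution(flat, tiny_conditions())
  expect_true(all(n0$m == 0) && all(n0$d == 0))

  # 1 vs 1 replicates is unsupported
  one <- tiny_counts(cbind(1:3, 4:6), samples = c("myc_1", "ctl_1"))
  expect_error(
    noise_distribution(one, tiny_conditions(1)),
    "replicate-free"
  )
})

test_that("empirical probability is a strict-dominance count", {
  noise <- tibble::tibble(m = c(0, 1, 3, 0.5), d = c(0, 1, 4, 0.2))
  stats <- tibble::tibble(gene_id = c("a", "b", "c"),
                          M = c(2, 0, 5), D = c(3, 0, 100))
  p <- deg_probability(stats, noise)
  expect_equal(p$P, c(3 / 4, 0, 1))

  # agrees exactly with the double-loop oracle on a large random instance
  set.seed(11)
  big_noise <- tibble::tibble(m = abs(rnorm(10000)), d = abs(rnorm(10000)))
  qs <- tibble::tibble(gene_id = sprintf("g%d", 1:25),
                       M = rnorm(25), D = abs(rnorm(25)))
  got <- deg_probability(qs, big_noise)
  want <- vapply(seq_len(25), function(i) {
    oracle_probability(qs$M[i], qs$D[i], big_noise$m, big_noise$d)
  }, numeric(1))
  expect_equal(got$P, want)

  # monotone: increasing |M| or D never decreases P
  base <- deg_probability(tibble::tibble(gene_id = "g", M = 1, D = 1),
                          big_noise)$P
  up_m <- deg_probability(tibble::tibble(gene_id = "g", M = 2, D = 1),
                          big_noise)$P
  up_d <- deg_probability(tibble::tibble(gene_id = "g", M = 1, D = 2),
                          big_noise)$P
  expect_gte(up_m, base)
  expect_gte(up_d, base)

  expect_error(deg_probability(stats, noise[0, ]), "empty")
})

test_that("odds transform matches P / (1 - P) with the limit at P = 1", {
  expect_equal(deg_odds(0.8), 4)
  expect_equal(deg_odds(0.5), 1)
  expect_equal(deg_odds(1), Inf)
  expect_error(deg_odds(1.2), "\\[0, 1\\]")
})

test_that("DEG calling applies inclusive fold and probability thresholds", {
  stats <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    M = c(1.2, 0.8, -1.0, 3),
    D = 1,
    P = c(0.85, 0.95, 0.80, 0.79)
  )
  called <- call_degs(stats)
  expect_equal(called$is_deg, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(called$direction[called$is_deg], c("up", "down"))
})

test_that("relabeling conditions swaps the sign of M and the DEG sets", {
  set.seed(21)
  sim <- gen_counts(n_genes = 120, planted_fold_changes = rep(4, 15),
                    seed = 77)
  fit <- noiseq(sim$counts, sim$conditions, sim$catalog)
  flipped <- sim$conditions |>
    dplyr::mutate(condition = dplyr::recode(condition,
                                            mycorrhizal = "control",
                                            control = "mycorrhizal"))
  fit2 <- noiseq(sim$counts, flipped, sim$catalog)
  expect_equal(fit2$stats$M, -fit$stats$M)
  expect_equal(fit2$stats$P, fit$stats$P)
  up1 <- fit$stats$gene_id[fit$stats$is_deg & fit$stats$direction == "up"]
  down2 <- fit2$stats$gene_id[fit2$stats$is_deg &
                                fit2$stats$direction == "down"]
  expect_equal(sort(up1), sort(down2))
})

test_that("false-call fraction on null data is small and shrinks with P", {
  sim <- gen_counts(n_genes = 600, planted_fold_changes = numeric(0),
                    seed = 5)
  fit <- noiseq(sim$counts, sim$conditions, sim$catalog)
  frac_ge <- function(p) mean(fit$stats$P >= p)
  expect_lt(frac_ge(0.8), 0.1)
  # monotone false-call curve
  expect_true(all(diff(vapply(c(0.5, 0.7, 0.8, 0.9, 0.99),
                              frac_ge, numeric(1))) <= 0))
})

test_that("tidiers and fit accessors expose the per-gene table", {
  sim <- gen_counts(n_genes = 60, planted_fold_changes = rep(8, 5),
                    seed = 13)
  fit <- noiseq(sim$counts, sim$conditions, sim$catalog)
  td <- tidy(fit)
  expect_true(all(c("gene_id", "M", "D", "P", "odds", "is_deg",
                    "direction") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_genes, nrow(td))
  expect_equal(gl$n_up + gl$n_down, sum(td$is_deg))
  sets <- deg_sets(fit, "Ptr")
  expect_equal(nrow(sets), sum(td$is_deg))
  expect_s3_class(autoplot(fit), "ggplot")
})
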