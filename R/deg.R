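# Empirical-noise (NOISeq-style) differential expression caller.
#
# Signal: per-gene (M, D) contrasting mean RPKM between the mycorrhizal and
# control conditions. Noise: the same statistics computed for every
# within-condition replicate pair, pooled across genes and conditions. The
# probability P of a gene being differentially expressed is the fraction of
# noise points it strictly dominates in both coordinates.

cond_samples <- function(conditions, label) {
  conditions$sample[conditions$condition == label]
}

expr_matrix <- function(expr) {
  m <- as.matrix(expr[, setdiff(names(expr), "gene_id"), drop = FALSE])
  rownames(m) <- expr$gene_id
  m
}

#' Per-gene M and D signal statistics
#'
#' With `x1` the mean expression over mycorrhizal samples and `x2` over
#' control samples, M = log2(x1'/x2') where zeros are replaced by
#' `zero_substitute` before the ratio only, and D = |x1 - x2| on the
#' unsubstituted means.
#'
#' @param expr Wide expression (RPKM) tibble (`gene_id` + sample columns).
#' @param conditions Tibble mapping `sample` to `condition`.
#' @param zero_substitute Positive value replacing zero means inside the
#'   log-ratio (default 0.5).
#' @return Tibble with columns `gene_id`, `M`, `D`.
#' @export
md_statistics <- function(expr, conditions, zero_substitute = 0.5) {
  m <- expr_matrix(expr)
  s1 <- cond_samples(conditions, "mycorrhizal")
  s2 <- cond_samples(conditions, "control")
  if (length(s1) == 0 || length(s2) == 0) {
    ams_abort("both conditions need at least one sample")
  }
  x1 <- unname(rowMeans(m[, s1, drop = FALSE]))
  x2 <- unname(rowMeans(m[, s2, drop = FALSE]))
  k <- zero_substitute
  tibble::tibble(
    gene_id = expr$gene_id,
    M = log2(ifelse(x1 == 0, k, x1) / ifelse(x2 == 0, k, x2)),
    D = abs(x1 - x2)
  )
}

#' Empirical noise distribution from within-condition replicate pairs
#'
#' For every unordered pair of replicates within the same condition and
#' every gene, contributes the point (|log2(a'/b')|, |a - b|) with the same
#' zero-substitution rule as [md_statistics()]. Points are pooled across
#' genes and both conditions.
#'
#' @inheritParams md_statistics
#' @return Tibble with columns `m` (absolute log-ratio) and `d` (absolute
#'   difference), one row per (gene, replicate pair).
#' @export
noise_distribution <- function(expr, conditions, zero_substitute = 0.5) {
  m <- expr_matrix(expr)
  k <- zero_substitute
  pts <- list()
  for (label in .AMS_CONDITIONS) {
    ss <- cond_samples(conditions, label)
    ss <- ss[ss %in% colnames(m)]
    if (length(ss) < 2) next
    for (pair in utils::combn(ss, 2, simplify = FALSE)) {
      a <- m[, pair[1]]
      b <- m[, pair[2]]
      pts[[length(pts) + 1]] <- tibble::tibble(
        m = abs(log2(ifelse(a == 0, k, a) / ifelse(b == 0, k, b))),
        d = abs(a - b)
      )
    }
  }
  if (length(pts) == 0) {
    ams_abort(paste(
      "no condition has >= 2 replicates:",
      "replicate-free differential calling is unsupported"
    ))
  }
  dplyr::bind_rows(pts)
}

#' Empirical probability of differential expression
#'
#' P(gene) is the fraction of noise points (m, d) the gene's signal
#' strictly dominates: m < |M| and d < D. Ties count against the gene.
#'
#' @param stats Tibble with columns `gene_id`, `M`, `D` (from
#'   [md_statistics()]).
#' @param noise Noise tibble from [noise_distribution()].
#' @return `stats` with columns `P` and `odds` appended.
#' @export
deg_probability <- function(stats, noise) {
  if (nrow(noise) == 0) ams_abort("noise distribution is empty")
  nm <- noise$m
  nd <- noise$d
  n <- length(nm)
  absM <- abs(stats$M)
  D <- stats$D
  p <- numeric(nrow(stats))
  chunk <- 256L
  for (start in seq(1, nrow(stats), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(stats))
    dom <- outer(absM[idx], nm, `>`) & outer(D[idx], nd, `>`)
    p[idx] <- rowSums(dom) / n
  }
  stats |>
    dplyr::mutate(P = p, odds = deg_odds(p))
}

#' Odds of being differentially expressed
#'
#' odds = P / (1 - P); P = 1 maps to `Inf`. P >= 0.8 is equivalent to
#' odds > 4.
#'
#' @param p Probability vector in \[0, 1\].
#' @return Numeric vector of odds.
#' @export
deg_odds <- function(p) {
  if (any(p < 0 | p > 1)) ams_abort("P must lie in [0, 1]")
  ifelse(p == 1, Inf, p / (1 - p))
}

#' Call differentially expressed genes
#'
#' A gene is a DEG iff |M| >= log2(fold_threshold) and P >= p_threshold
#' (both inclusive); direction is `up` iff M > 0.
#'
#' @param stats Tibble with columns `gene_id`, `M`, `D`, `P` (and
#'   optionally `odds`).
#' @param fold_threshold Minimum linear fold change (default 2).
#' @param p_threshold Minimum probability (default 0.8).
#' @return `stats` with `direction` (`up`/`down`/`NA`) and logical
#'   `is_deg` appended.
#' @export
call_degs <- function(stats, fold_threshold = 2, p_threshold = 0.8) {
  stats |>
    dplyr::mutate(
      is_deg = abs(.data$M) >= log2(fold_threshold) &
        .data$P >= p_threshold,
      direction = dplyr::if_else(.data$M > 0, "up", "down")
    )
}

#' Empirical-noise differential expression analysis
#'
#' End-to-end caller: RPKM normalization (optional), signal statistics,
#' pooled within-condition noise, empirical probability, thresholding.
#'
#' @param counts Wide count tibble, or an already-normalized expression
#'   tibble when `normalize = FALSE`.
#' @param conditions Tibble mapping `sample` to `condition`.
#' @param catalog Gene catalog (needed when `normalize = TRUE`).
#' @param normalize Compute RPKM from counts first? Default `TRUE`.
#' @param detected_only Restrict to genes detected (count >= 1) in every
#'   sample before calling? Default `TRUE`; only meaningful with counts.
#' @param fold_threshold,p_threshold DEG thresholds (defaults 2 and 0.8).
#' @param zero_substitute Zero-substitution constant for log-ratios.
#' @return An object of class `ams_deg_fit`: list with `stats` (per-gene
#'   tibble `gene_id`, `M`, `D`, `P`, `odds`, `is_deg`, `direction`),
#'   `noise` (noise tibble), and the thresholds used.
#' @export
noiseq <- function(counts, conditions, catalog = NULL, normalize = TRUE,
                   detected_only = TRUE, fold_threshold = 2,
                   p_threshold = 0.8, zero_substitute = 0.5) {
  if (normalize) {
    if (is.null(catalog)) ams_abort("normalize = TRUE requires a catalog")
    validate_counts(counts, conditions, catalog)
    if (detected_only) {
      counts <- counts[counts$gene_id %in% detect_expressed(counts), ]
    }
    expr <- compute_rpkm(counts, catalog)
  } else {
    expr <- counts
  }
  noise <- noise_distribution(expr, conditions, zero_substitute)
  stats <- md_statistics(expr, conditions, zero_substitute) |>
    deg_probability(noise) |>
    call_degs(fold_threshold, p_threshold)
  structure(
    list(
      stats = stats,
      noise = noise,
      fold_threshold = fold_threshold,
      p_threshold = p_threshold,
      zero_substitute = zero_substitute
    ),
    class = "ams_deg_fit"
  )
}

#' Extract DEG sets from a fit
#'
#' @param fit `ams_deg_fit` object.
#' @param species Species label attached to the sets.
#' @return Validated DEG tibble (`species`, `direction`, `gene_id`).
#' @export
deg_sets <- function(fit, species = "Ptr") {
  fit$stats |>
    dplyr::filter(.data$is_deg) |>
    dplyr::transmute(species = species, direction = .data$direction,
                     gene_id = .data$gene_id) |>
    validate_degs()
}

#' @export
print.ams_deg_fit <- function(x, ...) {
  n_up <- sum(x$stats$is_deg & x$stats$direction == "up")
  n_down <- sum(x$stats$is_deg & x$stats$direction == "down")
  cat(sprintf(
    "Empirical-noise DE fit: %d genes, %d noise points\n  thresholds: fold >= %g, P >= %g\n  DEGs: %d up, %d down\n",
    nrow(x$stats), nrow(x$noise), x$fold_threshold, x$p_threshold,
    n_up, n_down
  ))
  invisible(x)
}
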