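# Shared builders and independent oracles for the test suite.

tiny_conditions <- function(n_per = 3) {
  tibble::tibble(
    sample = c(sprintf("myc_%d", seq_len(n_per)),
               sprintf("ctl_%d", seq_len(n_per))),
    condition = rep(c("mycorrhizal", "control"), each = n_per)
  )
}

tiny_counts <- function(mat, genes = sprintf("g%d", seq_len(nrow(mat))),
                        samples = NULL) {
  samples <- samples %||% c(sprintf("myc_%d", seq_len(ncol(mat) / 2)),
                            sprintf("ctl_%d", seq_len(ncol(mat) / 2)))
  out <- tibble::tibble(gene_id = genes)
  for (j in seq_along(samples)) out[[samples[j]]] <- mat[, j]
  out
}

tiny_catalog <- function(genes, lengths = 1000L, species = "Ptr") {
  tibble::tibble(species = species, gene_id = genes,
                 length_bases = rep_len(lengths, length(genes)))
}

make_read <- function(id, bases, quals_phred) {
  tibble::tibble(
    read_id = id, bases = bases,
    qualities = intToUtf8(quals_phred + 33L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -------------------------------------------------

# brute-force Venn oracle: enumerate all 2^S - 1 species subsets and count
# orthogroups whose support set equals each subset exactly
oracle_venn <- function(status, species, direction) {
  st <- status[status$direction == direction, ]
  supp <- split(st$species, st$orthogroup_id)
  supp <- lapply(supp, unique)
  patterns <- unlist(lapply(seq_along(species), function(k) {
    utils::combn(species, k, FUN = paste, collapse = "+")
  }))
  counts <- stats::setNames(integer(length(patterns)), patterns)
  for (s in supp) {
    pat <- paste(species[species %in% s], collapse = "+")
    counts[pat] <- counts[pat] + 1L
  }
  counts
}

# naive O(n*m) Hamming scan oracle over both strands
oracle_scan <- function(seq, motif, max_mismatch, both_strands = TRUE) {
  revcomp <- function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  n <- nchar(seq)
  m <- nchar(motif)
  out <- list()
  targets <- list(`+` = motif)
  if (both_strands) targets$`-` <- revcomp(motif)
  for (strand in names(targets)) {
    pat <- strsplit(targets[[strand]], "")[[1]]
    for (start in seq_len(max(0, n - m + 1))) {
      win <- strsplit(substr(seq, start, start + m - 1), "")[[1]]
      mm <- sum(win != pat)
      if (mm <= max_mismatch) {
        out[[length(out) + 1]] <- data.frame(
          start = start, strand = strand, mismatches = mm
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), ]
}

# double-loop dominance-count oracle for the empirical probability
oracle_probability <- function(M, D, noise_m, noise_d) {
  n_dom <- 0L
  for (i in seq_along(noise_m)) {
    if (noise_m[i] < abs(M) && noise_d[i] < D) n_dom <- n_dom + 1L
  }
  n_dom / length(noise_m)
}

# pooled-variance two-sample t statistic, textbook closed form
oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# random regulated universe for the Venn oracle sweep
random_universe <- function(n_species, n_ogs, seed) {
  withr::with_seed(seed, {
    species <- sprintf("s%d", seq_len(n_species))
    rows <- list()
    for (i in seq_len(n_ogs)) {
      supp <- sample(species, sample(n_species, 1))
      rows[[i]] <- tibble::tibble(
        orthogroup_id = sprintf("OG%05d", i),
        species = supp,
        direction = "up",
        gene_id = sprintf("OG%05d_%s", i, supp)
      )
    }
    dplyr::bind_rows(rows)
  })
}
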