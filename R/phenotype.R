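# Mycorrhization and expression quantification used in functional
# validation: Trouvelot colonization parameters from per-fragment class
# scores, the degrading-arbuscule variant, qPCR relative expression, and
# the two-group comparison.

#' Validate a root-fragment score table
#'
#' Columns: `root_id`, `colonization_class` (integer 0..5, 0 = no
#' colonization, 5 = >90% of the fragment colonized), `arbuscule_class`
#' (`A0`..`A3`). Class 0 forces `A0`. A root scored on fewer than 30
#' fragments triggers a warning (the recommended minimum), not an error.
#'
#' @param fragments Fragment tibble.
#' @return The validated tibble.
#' @export
validate_fragments <- function(fragments) {
  assert_df_has(fragments,
                c("root_id", "colonization_class", "arbuscule_class"),
                "fragments")
  if (nrow(fragments) == 0) ams_abort("fragment table is empty")
  if (!all(fragments$colonization_class %in% 0:5)) {
    ams_abort("colonization_class must be an integer in 0..5")
  }
  arb_cols <- intersect(c("arbuscule_class", "degrading_arbuscule_class"),
                        names(fragments))
  for (col in arb_cols) {
    if (!all(fragments[[col]] %in% paste0("A", 0:3))) {
      ams_abort(sprintf("%s must be one of A0..A3", col))
    }
  }
  bad <- fragments$colonization_class == 0 &
    fragments$arbuscule_class != "A0"
  if (any(bad)) {
    ams_abort("colonization_class 0 forces arbuscule_class A0")
  }
  small <- fragments |>
    dplyr::count(.data$root_id) |>
    dplyr::filter(.data$n < 30)
  if (nrow(small) > 0) {
    rlang::warn(sprintf(
      "root(s) scored on < 30 fragments: %s",
      paste(small$root_id, collapse = ", ")
    ))
  }
  tibble::as_tibble(fragments)
}

trouvelot_once <- function(col_class, arb_class,
                           weights = c(95, 70, 30, 5, 1),
                           arbuscule_weights = c(100, 50, 10)) {
  n_total <- length(col_class)
  myc <- col_class >= 1
  n_myc <- sum(myc)
  f <- 100 * n_myc / n_total
  # M: weighted colonization intensity over the whole root system
  w <- c(0, rev(weights))[col_class + 1L]  # class 0..5 -> 0,1,5,30,70,95
  m_big <- sum(w) / n_total
  m_small <- if (n_myc == 0) 0 else m_big * n_total / n_myc
  # arbuscule abundance: weighted intensity of fragments in each arbuscule
  # class, relative to total colonization of mycorrhizal fragments
  a_pct <- 0
  if (n_myc > 0 && m_small > 0) {
    mA <- vapply(paste0("A", 3:1), function(cl) {
      sum(w[myc][arb_class[myc] == cl]) / n_myc * 100 / m_small
    }, numeric(1))
    a_pct <- sum(arbuscule_weights * mA) / 100
  }
  a_big <- a_pct * m_big / 100
  tibble::tibble(F = f, M = m_big, m = m_small, a = a_pct, A = a_big)
}

#' Trouvelot mycorrhizal colonization parameters
#'
#' From per-fragment colonization classes (0..5) and arbuscule classes
#' (A0..A3) computes, per root: F (% of fragments colonized), M
#' (colonization intensity in the root system), m (intensity restricted
#' to mycorrhizal fragments), a (arbuscule abundance in mycorrhizal root
#' parts) and A (arbuscule abundance in the root system). With n_i
#' fragments of class i over N fragments, M = (95 n5 + 70 n4 + 30 n3 +
#' 5 n2 + n1) / N, m = M N / N_myc, a is the arbuscule-weighted mean of
#' the per-class relative intensities, and A = a M / 100. All values are
#' percentages in \[0, 100\].
#'
#' @param fragments Fragment tibble (see [validate_fragments()]).
#' @param weights Colonization class weights for classes 5..1.
#' @param arbuscule_weights Arbuscule class weights for A3..A1.
#' @param by_root Summarise each `root_id` separately? Default `FALSE`
#'   (whole table as one root system).
#' @return Tibble with columns `F`, `M`, `m`, `a`, `A` (and `root_id`
#'   when `by_root = TRUE`).
#' @export
trouvelot_summary <- function(fragments, weights = c(95, 70, 30, 5, 1),
                              arbuscule_weights = c(100, 50, 10),
                              by_root = FALSE) {
  fragments <- validate_fragments(fragments)
  if (by_root) {
    fragments |>
      dplyr::group_by(.data$root_id) |>
      dplyr::reframe(trouvelot_once(.data$colonization_class,
                                    .data$arbuscule_class,
                                    weights, arbuscule_weights))
  } else {
    trouvelot_once(fragments$colonization_class, fragments$arbuscule_class,
                   weights, arbuscule_weights)
  }
}

#' Degrading-arbuscule abundance (a, A)
#'
#' Applies the Trouvelot a/A formulas to the
#' `degrading_arbuscule_class` column (fragments re-scored for degrading
#' arbuscules), quantifying degrading arbuscules in mycorrhizal root
#' parts (a) and in the total root system (A).
#'
#' @inheritParams trouvelot_summary
#' @return Tibble with columns `a`, `A` (plus `root_id` if `by_root`).
#' @export
degrading_arbuscule_summary <- function(fragments,
                                        weights = c(95, 70, 30, 5, 1),
                                        arbuscule_weights = c(100, 50, 10),
                                        by_root = FALSE) {
  assert_df_has(fragments, "degrading_arbuscule_class", "fragments")
  fragments <- validate_fragments(fragments)
  relabel <- fragments |>
    dplyr::mutate(arbuscule_class = dplyr::if_else(
      .data$colonization_class == 0, "A0",
      .data$degrading_arbuscule_class
    ))
  res <- trouvelot_summary(relabel, weights, arbuscule_weights, by_root)
  res[, intersect(c("root_id", "a", "A"), names(res))]
}

#' qPCR relative expression from threshold cycles
#'
#' `dCt` mode: per-sample abundance of each target gene relative to the
#' reference gene, 2^-(Ct_target - Ct_ref), assuming perfect doubling per
#' cycle. `ddCt` mode: per-sample fold change 2^-ddCt where ddCt is the
#' sample's dCt minus the calibrator group's mean dCt for that gene.
#'
#' @param ct Tibble with columns `sample`, `group`, `gene`, `ct`.
#' @param reference_gene Housekeeping gene id (must be measured in every
#'   sample).
#' @param mode `"dCt"` or `"ddCt"`.
#' @param calibrator Calibrator group label (required for `"ddCt"`).
#' @return Tibble `sample`, `group`, `gene`, `dct`, plus `relative_abundance`
#'   (`dCt` mode) or `ddct` and `fold_change` (`ddCt` mode). The reference
#'   gene itself is omitted from the output.
#' @export
relative_expression <- function(ct, reference_gene,
                                mode = c("dCt", "ddCt"),
                                calibrator = NULL) {
  mode <- match.arg(mode)
  assert_df_has(ct, c("sample", "group", "gene", "ct"), "Ct table")
  ref <- ct |> dplyr::filter(.data$gene == reference_gene)
  targets <- ct |> dplyr::filter(.data$gene != reference_gene)
  missing <- setdiff(unique(targets$sample), ref$sample)
  if (length(missing) > 0) {
    ams_abort(sprintf(
      "reference gene '%s' not measured in sample(s): %s",
      reference_gene, paste(missing, collapse = ", ")
    ))
  }
  out <- targets |>
    dplyr::mutate(
      dct = .data$ct - ref$ct[match(.data$sample, ref$sample)]
    )
  if (mode == "dCt") {
    return(out |>
             dplyr::mutate(relative_abundance = 2^(-.data$dct)) |>
             dplyr::select(-"ct"))
  }
  if (is.null(calibrator)) ams_abort("ddCt mode requires a calibrator group")
  if (!calibrator %in% out$group) {
    ams_abort(sprintf("calibrator group '%s' absent from Ct table",
                      calibrator))
  }
  cal <- out |>
    dplyr::filter(.data$group == calibrator) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(cal_dct = mean(.data$dct), .groups = "drop")
  out |>
    dplyr::left_join(cal, by = "gene") |>
    dplyr::mutate(
      ddct = .data$dct - .data$cal_dct,
      fold_change = 2^(-.data$ddct)
    ) |>
    dplyr::select(-"ct", -"cal_dct")
}

#' Two-group comparison by t-test
#'
#' Student's pooled-variance t-test by default (as used for the
#' mycorrhization and qPCR comparisons); Welch's variant available.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param test `"student"` (pooled variance) or `"welch"`.
#' @param sides 2 (default) or 1 (one-sided, `values_a` greater).
#' @return Tibble `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("student", "welch"), sides = 2) {
  test <- match.arg(test)
  if (length(values_a) < 2 || length(values_b) < 2) {
    ams_abort("each group needs at least 2 values")
  }
  alternative <- if (sides == 2) "two.sided" else "greater"
  ht <- stats::t.test(values_a, values_b,
                      var.equal = (test == "student"),
                      alternative = alternative)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_a = mean(values_a),
    mean_b = mean(values_b)
  )
}
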