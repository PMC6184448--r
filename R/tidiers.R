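# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
generics::tidy

#' @export
ggplot2::autoplot

#' @export
generics::glance

#' Tidy a differential expression fit
#'
#' @param x `ams_deg_fit` object from [noiseq()].
#' @param ... Unused.
#' @return Per-gene tibble: `gene_id`, `M`, `D`, `P`, `odds`, `is_deg`,
#'   `direction`.
#' @method tidy ams_deg_fit
#' @export
tidy.ams_deg_fit <- function(x, ...) {
  x$stats
}

#' One-row summary of a differential expression fit
#'
#' @param x `ams_deg_fit` object.
#' @param ... Unused.
#' @return Tibble with `n_genes`, `n_noise_points`, `n_up`, `n_down`,
#'   `fold_threshold`, `p_threshold`.
#' @method glance ams_deg_fit
#' @export
glance.ams_deg_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$stats),
    n_noise_points = nrow(x$noise),
    n_up = sum(x$stats$is_deg & x$stats$direction == "up"),
    n_down = sum(x$stats$is_deg & x$stats$direction == "down"),
    fold_threshold = x$fold_threshold,
    p_threshold = x$p_threshold
  )
}

#' Tidy an orthogroup regulation status
#'
#' @param x `ams_regulation` object.
#' @param ... Unused.
#' @return The per-DEG assignment tibble (`orthogroup_id`, `species`,
#'   `direction`, `gene_id`).
#' @method tidy ams_regulation
#' @export
tidy.ams_regulation <- function(x, ...) {
  x$status
}

#' One-row summary of an orthogroup regulation status
#'
#' @param x `ams_regulation` object.
#' @param ... Unused.
#' @return Tibble with `n_orthogroups_regulated`, `n_assigned_degs`,
#'   `n_unassigned_degs`, `n_species`.
#' @method glance ams_regulation
#' @export
glance.ams_regulation <- function(x, ...) {
  tibble::tibble(
    n_orthogroups_regulated = dplyr::n_distinct(x$status$orthogroup_id),
    n_assigned_degs = nrow(x$status),
    n_unassigned_degs = nrow(x$unassigned),
    n_species = length(x$species)
  )
}

#' MD plot of a differential expression fit
#'
#' Noise points in grey, per-gene signal coloured by call.
#'
#' @param object `ams_deg_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ams_deg_fit
#' @export
autoplot.ams_deg_fit <- function(object, ...) {
  stats <- object$stats |>
    dplyr::mutate(call = dplyr::if_else(
      .data$is_deg, paste0("DEG (", .data$direction, ")"), "not DE"
    ))
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = object$noise |> dplyr::slice_sample(n = min(5000,
                                                         nrow(object$noise))),
      ggplot2::aes(x = .data$m, y = .data$d),
      colour = "grey80", size = 0.4
    ) +
    ggplot2::geom_point(
      data = stats,
      ggplot2::aes(x = abs(.data$M), y = .data$D, colour = .data$call),
      size = 0.8
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "|M| (|log2 fold change|)",
                  y = "D (|difference of means|, RPKM)",
                  colour = NULL,
                  title = "Signal vs pooled within-condition noise")
}

#' Bar chart of a Venn partition
#'
#' Non-empty regions of the orthogroup Venn partition, ordered by the
#' number of supporting species.
#'
#' @param object `ams_venn` tibble from [venn_partition()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ams_venn
#' @export
autoplot.ams_venn <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$n > 0) |>
    dplyr::arrange(.data$n_species, dplyr::desc(.data$n)) |>
    dplyr::mutate(pattern = factor(.data$pattern, levels = .data$pattern))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, y = .data$n,
                                   fill = factor(.data$n_species))) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "orthogroups", fill = "species",
      title = sprintf("%s-regulated orthogroups by species support",
                      attr(object, "direction"))
    )
}

#' Bar chart of Trouvelot colonization parameters
#'
#' @param summary Tibble from [trouvelot_summary()] (optionally with a
#'   `group` column for side-by-side comparison).
#' @return A ggplot.
#' @export
plot_colonization <- function(summary) {
  long <- summary |>
    tidyr::pivot_longer(dplyr::any_of(c("F", "M", "m", "a", "A")),
                        names_to = "parameter", values_to = "percent") |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = c("F", "M", "m", "a", "A")))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter,
                                          y = .data$percent))
  if ("group" %in% names(summary)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$group),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = NULL, y = "percent",
                    title = "Mycorrhizal colonization parameters")
}
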