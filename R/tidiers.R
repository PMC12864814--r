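#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for snpheat result objects
#'
#' `tidy()` returns the per-observation table of a result (one row per node,
#' patient or module); `glance()` returns a one-row summary.
#'
#' @param x A snpheat result object.
#' @param ... Unused.
#' @return A tibble.
#' @name snpheat-tidiers
NULL

#' @rdname snpheat-tidiers
#' @export
tidy.snpheat_zscores <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "snpheat_zscores")
  out
}

#' @rdname snpheat-tidiers
#' @export
glance.snpheat_zscores <- function(x, ...) {
  tibble(layer = attr(x, "layer") %||% NA_character_,
         n_nodes = nrow(x), n_significant = sum(x$significant),
         threshold = attr(x, "threshold") %||% NA_real_,
         total_heat = sum(x$heat))
}

#' @rdname snpheat-tidiers
#' @export
tidy.snpheat_patient <- function(x, ...) {
  bind_rows(
    tidy(x$signalling) |> mutate(layer = "signalling"),
    tidy(x$regulatory) |> mutate(layer = "regulatory"))
}

#' @rdname snpheat-tidiers
#' @export
glance.snpheat_patient <- function(x, ...) {
  tibble(patient = x$patient, n_seeds = length(x$seeds),
         n_dropped_seeds = length(x$dropped_seeds),
         n_significant_signalling = length(x$sig_nodes),
         n_subnetwork_edges = nrow(x$subnetwork),
         n_significant_regulatory = sum(x$regulatory$significant),
         n_regulatory_edges = nrow(x$reg_edges),
         empty = !is.null(x$reason))
}

#' @rdname snpheat-tidiers
#' @export
tidy.snpheat_cohort <- function(x, ...) x$node_counts

#' @rdname snpheat-tidiers
#' @export
glance.snpheat_cohort <- function(x, ...) {
  tibble(n_patients = x$n_patients, threshold = x$threshold,
         n_perturbed_nodes = nrow(x$node_counts),
         n_common_nodes = sum(x$node_counts$common),
         n_regulatory_edges = nrow(x$edge_counts),
         n_common_edges = sum(x$edge_counts$common))
}

#' @rdname snpheat-tidiers
#' @export
tidy.snpheat_clusters <- function(x, ...) x$assignment

#' @rdname snpheat-tidiers
#' @export
glance.snpheat_clusters <- function(x, ...) {
  tibble(k = x$k, silhouette = x$silhouette, inertia = x$inertia)
}

#' @rdname snpheat-tidiers
#' @export
tidy.snpheat_kselect <- function(x, ...) x$diagnostics

#' @rdname snpheat-tidiers
#' @export
glance.snpheat_kselect <- function(x, ...) {
  best <- x$diagnostics[x$diagnostics$k == x$k, ]
  tibble(k = x$k, silhouette = best$silhouette, inertia = best$inertia)
}

#' @rdname snpheat-tidiers
#' @export
tidy.snpheat_modules <- function(x, ...) x$membership

#' @rdname snpheat-tidiers
#' @export
glance.snpheat_modules <- function(x, ...) {
  tibble(n_modules = x$n_modules, modularity = x$modularity)
}

#' @rdname snpheat-tidiers
#' @export
tidy.snpheat_null <- function(x, ...) {
  bind_rows(
    tibble(node = names(x$sig_mean), layer = "signalling",
           null_mean = unname(x$sig_mean), null_sd = unname(x$sig_sd)),
    if (!is.null(x$reg_mean)) {
      tibble(node = names(x$reg_mean), layer = "regulatory",
             null_mean = unname(x$reg_mean), null_sd = unname(x$reg_sd))
    })
}

#' Plot methods for snpheat result objects
#'
#' @param object A snpheat result object.
#' @param top_n How many top items to display.
#' @param clusters Optional `snpheat_clusters` used to colour an embedding.
#' @param ... Unused.
#' @return A ggplot object.
#' @name snpheat-plots
NULL

#' @rdname snpheat-plots
#' @export
autoplot.snpheat_zscores <- function(object, top_n = 30, ...) {
  thr <- attr(object, "threshold") %||% 2
  df <- as_tibble(object) |>
    filter(is.finite(.data$z) | .data$significant) |>
    mutate(z_plot = ifelse(is.finite(.data$z), .data$z,
                           max(.data$z[is.finite(.data$z)], thr) + 1)) |>
    arrange(dplyr::desc(.data$z_plot)) |>
    head(top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$node, .data$z_plot),
                                   y = .data$z_plot,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Z vs random-seed null",
                  fill = paste0("Z > ", thr)) +
    ggplot2::theme_minimal()
}

#' @rdname snpheat-plots
#' @export
autoplot.snpheat_kselect <- function(object, ...) {
  df <- tidyr::pivot_longer(object$diagnostics, c("silhouette", "inertia"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "k", y = NULL,
                  title = paste0("Model selection (chosen k = ", object$k, ")")) +
    ggplot2::theme_minimal()
}

#' @rdname snpheat-plots
#' @export
autoplot.snpheat_embedding <- function(object, clusters = NULL, ...) {
  df <- as_tibble(object$scores, rownames = "patient")
  if (!is.null(clusters)) {
    df <- left_join(df, clusters$assignment, by = "patient") |>
      mutate(cluster = factor(.data$cluster))
  }
  aes <- if (is.null(clusters)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$cluster)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = paste0("PC1 (", round(100 * object$ev_ratio[1], 1), "%)"),
      y = paste0("PC2 (", round(100 * object$ev_ratio[2], 1), "%)")) +
    ggplot2::theme_minimal()
}

#' @rdname snpheat-plots
#' @export
autoplot.snpheat_cohort <- function(object, top_n = 25, ...) {
  df <- object$node_counts |>
    group_by(.data$layer) |>
    dplyr::slice_max(.data$n_patients, n = top_n, with_ties = FALSE) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$node, .data$n_patients),
    y = .data$n_patients, fill = .data$common)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~layer, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "patients perturbed",
                  fill = paste0("> ", object$threshold, " patients")) +
    ggplot2::theme_minimal()
}
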