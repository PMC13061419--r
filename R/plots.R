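#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_ribbon
#'   geom_point geom_col facet_wrap labs scale_fill_gradient theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Heatmap of reciprocal classification similarity
#'
#' @param object a [reciprocal_similarity()] result
#' @param ... unused
#' @return a ggplot
#' @method autoplot similarity_matrix
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- as.data.frame(object$values) |>
    tibble::rownames_to_column("hrc_a") |>
    tidyr::pivot_longer(-"hrc_a", names_to = "hrc_b", values_to = "similarity")
  ggplot(df, aes(.data$hrc_a, .data$hrc_b, fill = .data$similarity)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "darkred", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, title = "Reciprocal classification similarity") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' OCC composition bar plot
#'
#' Cells per orthologous cell type cluster, colored by species; excluded
#' OCCs are marked in the facet label.
#'
#' @param object an [assign_occ()] result
#' @param ... unused
#' @return a ggplot
#' @method autoplot occ_assignment
#' @export
autoplot.occ_assignment <- function(object, ...) {
  df <- dplyr::left_join(object$mapping,
                         dplyr::select(object$occ_info, "occ", "status"),
                         by = "occ") |>
    dplyr::mutate(occ_lab = paste0(.data$occ,
                                   ifelse(.data$status == "excluded",
                                          " (excl.)", "")))
  ggplot(df, aes(.data$occ_lab, .data$n_cells, fill = .data$species)) +
    geom_col() +
    labs(x = "OCC", y = "cells", title = "OCC composition by species") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Marker-panel F1 curves
#'
#' Macro-averaged F1 against marker panel size per test dataset, with the
#' 95% bootstrap band.
#'
#' @param object a [knn_marker_eval()] result
#' @param ... unused
#' @return a ggplot
#' @method autoplot f1_curve
#' @export
autoplot.f1_curve <- function(object, ...) {
  df <- dplyr::filter(object, .data$cell_type == "macro")
  ggplot(df, aes(.data$m, .data$f1, color = .data$test, fill = .data$test)) +
    geom_ribbon(aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                alpha = 0.15, color = NA) +
    geom_line() +
    labs(x = "markers per cell type (m)", y = "macro F1",
         title = "Marker transferability (kNN, k = 3)") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    theme_minimal()
}

#' Conservation score against cell type specificity
#'
#' @param object a [conservation_score()] result
#' @param species which species' specificity to plot against (default the
#'   first `specificity_*` column)
#' @param ... unused
#' @return a ggplot
#' @method autoplot conservation_record
#' @export
autoplot.conservation_record <- function(object, species = NULL, ...) {
  col <- if (is.null(species)) {
    grep("^specificity_", names(object), value = TRUE)[1]
  } else paste0("specificity_", species)
  df <- dplyr::filter(object, !is.na(.data$score))
  ggplot(df, aes(factor(.data[[col]]), .data$score)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    labs(x = sub("^specificity_", "specificity (", paste0(col, ")")),
         y = "expression conservation",
         title = "Conservation by cell type specificity") +
    theme_minimal()
}

#' Detection-threshold fit diagnostic
#'
#' Putative status against detection fraction for one species and cell
#' type, with the fitted Firth logistic curve and the solved threshold.
#'
#' @param stats a [putative_status()] tibble
#' @param thresholds a [fit_detection_threshold()] result
#' @param species,cell_type stratum to plot
#' @return a ggplot
#' @export
plot_threshold_fit <- function(stats, thresholds, species, cell_type) {
  df <- dplyr::filter(stats, .data$species == !!species,
                      .data$cell_type == !!cell_type)
  fit <- dplyr::filter(thresholds$per_species, .data$species == !!species,
                       .data$cell_type == !!cell_type)
  grid <- tibble::tibble(f = seq(0, 1, length.out = 200))
  grid$p <- stats::plogis(fit$a + fit$b * grid$f)
  ggplot(df, aes(.data$f, .data$status)) +
    geom_point(alpha = 0.3, size = 0.7) +
    geom_line(data = grid, aes(.data$f, .data$p), color = "steelblue") +
    ggplot2::geom_vline(xintercept = fit$threshold, linetype = 2) +
    labs(x = "detection fraction f", y = "putative status / P(expressed)",
         title = sprintf("%s / %s: f* = %.3f", species, cell_type,
                         fit$threshold)) +
    theme_minimal()
}
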