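# broom-style accessors and ggplot2 autoplot methods for the package's
# result objects.

#' Tidy a calibration result
#'
#' @param x `ssr_calibration` from [calibrate_markers()].
#' @param ... Unused.
#' @return A plain tibble, one row per marker, with the dropout list
#'   flattened to a `;`-separated string.
#' @exportS3Method generics::tidy
tidy.ssr_calibration <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$dropout_varieties <- vapply(out$dropout_varieties, paste,
                                  character(1), collapse = ";")
  out$mismatches <- NULL
  out
}

#' One-line summary of a calibration
#'
#' @param x `ssr_calibration` from [calibrate_markers()].
#' @param ... Unused.
#' @return One-row tibble: marker counts by outcome, mean optimum alpha
#'   and widest/narrowest alpha interval among feasible markers.
#' @exportS3Method generics::glance
glance.ssr_calibration <- function(x, ...) {
  feas <- x[x$feasible, ]
  width <- feas$alpha_max - feas$alpha_min
  tibble::tibble(
    n_markers = nrow(x),
    n_suitable = sum(x$classification == "suitable"),
    n_low_depth = sum(x$classification == "low_depth"),
    n_dropout = sum(x$classification == "dropout"),
    n_discordant = sum(x$classification %in% c("discordant", "stutter_error")),
    mean_alpha_opt = if (nrow(feas) > 0) mean(feas$alpha_opt) else NA_real_,
    max_alpha_width = if (nrow(feas) > 0) max(width) else NA_real_,
    min_alpha_width = if (nrow(feas) > 0) min(width) else NA_real_
  )
}

#' Plot calibrated alpha intervals
#'
#' Feasible markers are drawn as vertical interval bars with the optimum
#' marked; unsuitable markers are greyed out by classification.
#'
#' @param object `ssr_calibration` from [calibrate_markers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ssr_calibration <- function(object, ...) {
  df <- tidy(object)
  df$marker <- factor(df$marker, levels = df$marker)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$marker)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$alpha_min, ymax = .data$alpha_max,
                   colour = .data$classification),
      linewidth = 1.5, na.rm = TRUE
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$alpha_opt), size = 2,
                        na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = expression(alpha), x = NULL,
                  title = "Feasible genotyping thresholds per marker") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot allele profiles
#'
#' Bar chart of top-allele frequencies per variety for one marker: the
#' visual used to judge zygosity, stutter bands and artifacts.
#'
#' @param object `ssr_profiles` from [allele_profiles()].
#' @param marker Marker to display (default: first present).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ssr_profiles <- function(object, marker = NULL, ...) {
  marker <- marker %||% object$marker[1]
  df <- object[object$marker == marker, ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$allele_length),
                                   y = .data$freq,
                                   fill = factor(.data$rank))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~variety) +
    ggplot2::labs(x = "digital allele length (bp)",
                  y = "read frequency", fill = "rank",
                  title = paste0("Allele profiles: ", marker)) +
    ggplot2::theme_minimal()
}

#' Plot a marker panel dendrogram
#'
#' UPGMA dendrogram of varieties from a genotype table, via
#' [shared_allele_distance()] and [upgma_tree()].
#'
#' @param table Long-format genotype table.
#' @param ... Passed to [ape::plot.phylo()].
#' @return The tree, invisibly.
#' @export
plot_variety_dendrogram <- function(table, ...) {
  tree <- upgma_tree(shared_allele_distance(table))
  ape::plot.phylo(tree, ...)
  invisible(tree)
}
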