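#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a scan result
#'
#' @param x A `synapo_scan` result.
#' @param ... Unused.
#' @return A plain tibble of the reported characters (attributes dropped).
#' @method tidy synapo_scan
#' @export
tidy.synapo_scan <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row summary of a scan result
#'
#' @param x A `synapo_scan` result.
#' @param ... Unused.
#' @return Tibble with the number of reported characters by kind, the
#'   worst missing count among them, and the scan parameters.
#' @method glance synapo_scan
#' @export
glance.synapo_scan <- function(x, ...) {
  p <- attr(x, "params")
  tibble(n_characters = nrow(x),
         n_derived = sum(x$kind == "derived"),
         n_retained_not = sum(x$kind == "retained_not"),
         n_state_only = sum(x$kind == "state_only"),
         max_missing_count = if (nrow(x)) max(x$missing_count) else NA_integer_,
         outgroup_majority_threshold = p$outgroup_majority_threshold,
         forbid_derived_in_outgroup = p$forbid_derived_in_outgroup,
         top_k = p$top_k)
}

#' Plot a scan result
#'
#' Positions of reported diagnostic characters by locus, colored by
#' character kind and sized by minimum focal coverage when available.
#'
#' @param object A `synapo_scan` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synapo_scan
#' @export
autoplot.synapo_scan <- function(object, ...) {
  df <- tidy(object)
  if (!nrow(df)) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no characters") +
             ggplot2::theme_void())
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$locus_id,
                                        colour = .data$kind))
  p <- if (all(is.na(df$min_coverage))) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(size = .data$min_coverage))
  }
  p + ggplot2::labs(x = "position (1-based, within exon)", y = NULL,
                    colour = "kind", size = "min coverage") +
    ggplot2::theme_minimal()
}

#' Tidy a rank decision
#'
#' @param x A `rank_decision`.
#' @param ... Unused.
#' @return The per-clause outcomes as a tibble.
#' @method tidy rank_decision
#' @export
tidy.rank_decision <- function(x, ...) attr(x, "clauses")

#' @rdname tidy.rank_decision
#' @return `glance()` returns the one-row decision.
#' @method glance rank_decision
#' @export
glance.rank_decision <- function(x, ...) {
  out <- as_tibble(x)
  out$strong_threshold <- attr(x, "strong_threshold")
  class(out) <- class(tibble())
  out
}

#' Tidy specimen groups
#'
#' @param x A `specimen_groups` result.
#' @param ... Unused.
#' @return Tibble of specimens and group ids.
#' @method tidy specimen_groups
#' @export
tidy.specimen_groups <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.specimen_groups
#' @return `glance()` returns group count, threshold and the smallest
#'   between-group distance.
#' @method glance specimen_groups
#' @export
glance.specimen_groups <- function(x, ...) {
  between <- attr(x, "between")
  tibble(n_specimens = nrow(x), n_groups = max(x$group),
         threshold = attr(x, "threshold"),
         min_between_distance = if (is.null(between)) NA_real_ else min(between$min_distance))
}

#' Plot a clade-support report
#'
#' Bootstrap support of each reference clade (and the focal placement) in
#' each partition tree, with a reference line at a chosen threshold.
#'
#' @param report A tibble from [support_report()].
#' @param strong_threshold Threshold line to draw (default 95).
#' @return A ggplot object.
#' @export
plot_support_report <- function(report, strong_threshold = 95) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$tree, y = .data$support,
                                       colour = .data$role, group = .data$clade)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line(linetype = "dotted") +
    ggplot2::geom_hline(yintercept = strong_threshold, linetype = "dashed") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(y = "bootstrap support (%)", x = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot pairwise barcode distances
#'
#' Heatmap of p-distances with a conspecificity threshold marked in the
#' fill scale midpoint.
#'
#' @param d Symmetric p-distance matrix.
#' @param threshold Conspecificity threshold (default 0.02).
#' @return A ggplot object.
#' @export
plot_distance_matrix <- function(d, threshold = 0.02) {
  df <- as_tibble(d, rownames = "specimen1")
  df <- tidyr::pivot_longer(df, -"specimen1", names_to = "specimen2",
                            values_to = "p_distance")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$specimen1, y = .data$specimen2,
                                   fill = .data$p_distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "white", mid = "steelblue",
                                  high = "firebrick", midpoint = threshold) +
    ggplot2::labs(x = NULL, y = NULL, fill = "p-distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
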