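#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_violin geom_raster
#'   geom_tile geom_col geom_contour_filled labs facet_wrap theme_minimal
#'   scale_fill_gradient2 scale_fill_viridis_c
#' @export
ggplot2::autoplot

.metric_units <- c(rmsd = "RMSD (Å)", rg = "Rg (Å)",
                   sasa = "SASA (Å²)")

#' Plot a metric series
#'
#' Line plot over time, or violins by condition with `type = "violin"`
#' (the usual distribution view). Rows from several series may be bound
#' together before plotting.
#'
#' @param object a `metric_series` tibble.
#' @param type `"line"` or `"violin"`.
#' @param ... unused.
#' @export
autoplot.metric_series <- function(object, type = c("line", "violin"), ...) {
  type <- match.arg(type)
  if (type == "violin") {
    ggplot(object, aes(x = .data$label, y = .data$value, fill = .data$label)) +
      geom_violin() +
      facet_wrap(~kind, scales = "free_y") +
      labs(x = NULL, y = NULL) +
      theme_minimal()
  } else {
    ggplot(object, aes(x = .data$time / 1000, y = .data$value,
                       colour = .data$label,
                       group = interaction(.data$label, .data$replicate))) +
      geom_line(linewidth = 0.3) +
      facet_wrap(~kind, scales = "free_y", ncol = 1) +
      labs(x = "time (ns)", y = NULL) +
      theme_minimal()
  }
}

#' Plot per-residue RMSF profiles
#'
#' @param object an `rmsf_profile` tibble (conditions may be bound together).
#' @param ... unused.
#' @export
autoplot.rmsf_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$resid, y = .data$value, colour = .data$label,
                     group = interaction(.data$label, .data$replicate))) +
    geom_line() +
    labs(x = "residue", y = "RMSF (Å)") +
    theme_minimal()
}

#' Heatmap of a DCCM
#'
#' @param object a `dccm_matrix`.
#' @param ... unused.
#' @export
autoplot.dccm_matrix <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$resid_i, y = .data$resid_j,
                           fill = .data$correlation)) +
    geom_raster() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         limits = c(-1, 1)) +
    labs(x = "residue i", y = "residue j", title = object$label) +
    theme_minimal()
}

#' Heatmap of an absolute DCCM difference
#'
#' Entries at or above the stored threshold are the "altered" cells.
#'
#' @param object a `dccm_difference`.
#' @param ... unused.
#' @export
autoplot.dccm_difference <- function(object, ...) {
  d <- tidy(object)
  d$above <- d$difference >= object$threshold
  ggplot(d, aes(x = .data$resid_i, y = .data$resid_j)) +
    geom_raster(aes(fill = .data$difference)) +
    geom_tile(data = d[d$above, ], fill = "magenta", alpha = 0.6) +
    scale_fill_viridis_c() +
    labs(x = "residue i", y = "residue j",
         title = paste(object$labels, collapse = " vs ")) +
    theme_minimal()
}

#' Scree / profile plots for an essential subspace
#'
#' @param object an `essential_subspace`.
#' @param pcs PCs to draw residue profiles for (default 1:5).
#' @param ... unused.
#' @export
autoplot.essential_subspace <- function(object, pcs = 1:5, ...) {
  prof <- dplyr::bind_rows(lapply(pcs, function(k) pc_profile(object, k)))
  ggplot(prof, aes(x = .data$resid, y = .data$value)) +
    geom_line() +
    facet_wrap(~pc, ncol = 1, labeller = ggplot2::label_both) +
    labs(x = "residue", y = "PC displacement (Å)",
         title = object$label) +
    theme_minimal()
}

#' Heatmap of RMSIP squared inner products
#'
#' @param object an `rmsip_result`.
#' @param ... unused.
#' @export
autoplot.rmsip_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$pc_a, y = .data$pc_b,
                           fill = .data$inner_product_sq)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = object$labels[["a"]], y = object$labels[["b"]],
         title = sprintf("RMSIP = %.3f (k = %d)", object$value, object$k)) +
    theme_minimal()
}

#' Contour map of a free-energy landscape
#'
#' @param object a `fel_grid`.
#' @param ... unused.
#' @export
autoplot.fel_grid <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$rc1, y = .data$rc2, z = .data$energy)) +
    geom_contour_filled() +
    labs(x = "RMSD (Å)", y = "Rg (Å)",
         fill = "G (kcal/mol)") +
    theme_minimal()
}

#' Stacked occupancy bars
#'
#' @param object an `occupancy_profile`.
#' @param ... unused.
#' @export
autoplot.occupancy_profile <- function(object, ...) {
  ggplot(object$overall, aes(x = 1, y = .data$percent, fill = .data$class)) +
    geom_col() +
    labs(x = NULL, y = "occupancy (%)", title = object$label) +
    theme_minimal()
}

#' Per-residue SSE difference profile
#'
#' @param object an `sse_difference`.
#' @param classes classes to facet (default all with any nonzero delta).
#' @param ... unused.
#' @export
autoplot.sse_difference <- function(object, classes = NULL, ...) {
  d <- object$per_residue
  if (is.null(classes)) {
    keep <- unique(d$class[abs(d$delta) > 0])
    if (length(keep) > 0) d <- d[d$class %in% keep, ]
  } else d <- d[d$class %in% classes, ]
  ggplot(d, aes(x = .data$resid, y = .data$delta)) +
    geom_col() +
    facet_wrap(~class) +
    labs(x = "residue", y = "occupancy delta (pp, variant - wild)",
         title = paste(object$labels[["variant"]], "vs",
                       object$labels[["wild"]])) +
    theme_minimal()
}
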