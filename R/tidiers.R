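#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an essential subspace
#'
#' One row per principal component: eigenvalue (A^2), variance fraction and
#' cumulative variance.
#'
#' @param x an `essential_subspace`.
#' @param n_modes rows to return (default 10).
#' @param ... unused.
#' @export
tidy.essential_subspace <- function(x, n_modes = 10, ...) {
  n <- min(n_modes, length(x$values))
  tibble::tibble(
    pc = seq_len(n),
    eigenvalue = x$values[seq_len(n)],
    variance_fraction = x$variance_fraction[seq_len(n)],
    cumulative = cumsum(x$variance_fraction)[seq_len(n)]
  )
}

#' @export
glance.essential_subspace <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    n_modes = length(x$values),
    total_variance = sum(x$values),
    pc1_fraction = x$variance_fraction[1],
    pc123_fraction = sum(x$variance_fraction[1:min(3, length(x$values))])
  )
}

#' Tidy a free-energy grid
#'
#' One row per populated bin: bin centres on both reaction coordinates,
#' count and Gibbs energy.
#'
#' @param x a `fel_grid`.
#' @param ... unused.
#' @export
tidy.fel_grid <- function(x, ...) {
  cx <- (x$rc1_edges[-1] + x$rc1_edges[-length(x$rc1_edges)]) / 2
  cy <- (x$rc2_edges[-1] + x$rc2_edges[-length(x$rc2_edges)]) / 2
  idx <- which(x$counts > 0, arr.ind = TRUE)
  tibble::tibble(
    rc1 = cx[idx[, 1]], rc2 = cy[idx[, 2]],
    count = x$counts[idx], energy = x$energy[idx]
  )
}

#' @export
glance.fel_grid <- function(x, ...) {
  tibble::tibble(
    n_bins = x$n_bins,
    populated = sum(x$counts > 0),
    n_frames = sum(x$counts),
    max_energy = max(x$energy, na.rm = TRUE),
    temperature = x$temperature
  )
}

#' @export
tidy.basin_set <- function(x, ...) x$basins

#' @export
glance.basin_set <- function(x, ...) {
  tibble::tibble(
    n_basins = nrow(x$basins),
    depth_cutoff = x$depth_cutoff,
    rank1_frames = x$basins$n_frames[x$basins$rank == 1],
    assigned_fraction = sum(x$basins$n_frames) / sum(x$grid$counts)
  )
}

#' Tidy a DCCM into long format
#'
#' @param x a `dccm_matrix`.
#' @param ... unused.
#' @export
tidy.dccm_matrix <- function(x, ...) {
  tibble::tibble(
    resid_i = rep(x$resid, times = length(x$resid)),
    resid_j = rep(x$resid, each = length(x$resid)),
    correlation = as.numeric(x$matrix)
  )
}

#' @export
tidy.dccm_difference <- function(x, ...) {
  tibble::tibble(
    resid_i = rep(x$resid, times = length(x$resid)),
    resid_j = rep(x$resid, each = length(x$resid)),
    difference = as.numeric(x$matrix)
  )
}

#' @export
tidy.rmsip_result <- function(x, ...) {
  k <- x$k
  tibble::tibble(
    pc_a = rep(seq_len(k), times = k),
    pc_b = rep(seq_len(k), each = k),
    inner_product_sq = as.numeric(x$matrix)
  )
}

#' @export
glance.rmsip_result <- function(x, ...) {
  tibble::tibble(value = x$value, k = x$k,
                 label_a = x$labels[["a"]], label_b = x$labels[["b"]])
}

#' @export
tidy.occupancy_profile <- function(x, ...) x$per_residue

#' @export
glance.occupancy_profile <- function(x, ...) {
  out <- tidyr::pivot_wider(x$overall[, c("class", "percent")],
                            names_from = "class", values_from = "percent")
  dplyr::bind_cols(tibble::tibble(label = x$label, n_frames = x$n_frames), out)
}

#' @export
tidy.sse_difference <- function(x, ...) x$per_residue

#' @export
glance.sse_difference <- function(x, ...) {
  tidyr::pivot_wider(x$overall[, c("class", "delta")],
                     names_from = "class", values_from = "delta")
}
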