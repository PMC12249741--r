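#' Dynamic cross-correlation matrix
#'
#' Normalised covariance of residue displacement vectors about their
#' time-mean positions after iterative superposition onto the mean
#' structure:
#' \deqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#'   \sqrt{\langle \Delta r_i^2\rangle \langle \Delta r_j^2\rangle}}
#' Values lie in \[-1, 1\] with a unit diagonal; +1 is fully correlated
#' motion, -1 fully anticorrelated. Residues with zero positional variance
#' get a zeroed row/column (diagonal kept at 1) and a warning.
#'
#' @param traj a [trajectory()].
#' @param mask atom selection, one atom per residue (default `"CA"`).
#' @return object of class `dccm_matrix`: list with `matrix` (n_res x n_res,
#'   dimnames = author resids), `resid`, `label`, `replicate`.
#' @export
dccm <- function(traj, mask = "CA") {
  sp <- superpose_mean(traj, mask)
  X <- mask_xyz(sp$xyz, sp$mask)
  Xc <- sweep(X, 2, colMeans(X))
  nf <- nrow(Xc)
  n <- length(sp$mask)
  num <- matrix(0, n, n)
  for (axis in 1:3) {
    A <- Xc[, seq(axis, 3 * n, by = 3), drop = FALSE]
    num <- num + crossprod(A) / nf
  }
  v <- diag(num)
  zero <- v <= 1e-12
  if (any(zero)) {
    rlang::warn(paste("zero-variance residue(s):",
                      paste(which(zero), collapse = ", ")))
    v[zero] <- 1
  }
  C <- num / sqrt(outer(v, v))
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  resid <- mask_resids(traj$topology, sp$mask)
  dimnames(C) <- list(resid, resid)
  structure(list(matrix = C, resid = resid, label = traj$label,
                 replicate = traj$replicate),
            class = "dccm_matrix")
}

#' @export
print.dccm_matrix <- function(x, ...) {
  cat("<dccm_matrix> '", x$label, "': ", nrow(x$matrix), " residues, range [",
      sprintf("%.3f", min(x$matrix)), ", ", sprintf("%.3f", max(x$matrix)),
      "]\n", sep = "")
  invisible(x)
}

#' Average several DCCMs entrywise
#'
#' The per-replicate, then averaged mode of pooling.
#'
#' @param dccms list of `dccm_matrix` objects over the same residues.
#' @return a `dccm_matrix`.
#' @export
average_dccm <- function(dccms) {
  stopifnot(length(dccms) >= 1)
  r0 <- dccms[[1]]$resid
  for (d in dccms) {
    if (!identical(d$resid, r0)) rlang::abort("DCCMs cover different residues")
  }
  M <- Reduce(`+`, lapply(dccms, `[[`, "matrix")) / length(dccms)
  out <- dccms[[1]]
  out$matrix <- M
  out$replicate <- NA_integer_
  out
}

#' Absolute difference of two DCCMs
#'
#' Entrywise `|wild - variant|`; the comparison surface from which altered
#' regions are extracted at the 0.2 threshold.
#'
#' @param wild,variant `dccm_matrix` objects over the same residue range.
#' @param threshold stored threshold used by [detect_regions()] (default 0.2).
#' @return object of class `dccm_difference`.
#' @export
dccm_difference <- function(wild, variant, threshold = 0.2) {
  stopifnot(inherits(wild, "dccm_matrix"), inherits(variant, "dccm_matrix"))
  if (!identical(wild$resid, variant$resid)) {
    rlang::abort("DCCMs cover different residue ranges")
  }
  D <- abs(wild$matrix - variant$matrix)
  structure(list(matrix = D, resid = wild$resid, threshold = threshold,
                 labels = c(wild = wild$label, variant = variant$label)),
            class = "dccm_difference")
}

#' @export
print.dccm_difference <- function(x, ...) {
  cat("<dccm_difference> ", x$labels[["wild"]], " vs ", x$labels[["variant"]],
      ": ", sprintf("%.1f%%", 100 * mean(x$matrix >= x$threshold)),
      " of entries >= ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Extract residue regions with altered correlation
#'
#' A residue counts as affected when the fraction of its difference-matrix
#' row at or above `threshold` exceeds `row_fraction`. Affected residues are
#' merged into maximal runs allowing single-residue gaps; runs shorter than
#' `min_len` are dropped. Intervals are reported in author numbering,
#' inclusive.
#'
#' @param diff a `dccm_difference`.
#' @param threshold absolute-difference threshold (default the stored one,
#'   0.2).
#' @param row_fraction minimum affected fraction of a row (default 0.05).
#' @param min_len minimum region length in residues (default 2).
#' @param gap largest run gap bridged (default 1).
#' @return a tibble (class `region_set`) with columns `start`, `end`,
#'   `score` (mean above-threshold difference in the region's rows).
#' @export
detect_regions <- function(diff, threshold = NULL, row_fraction = 0.05,
                           min_len = 2, gap = 1) {
  stopifnot(inherits(diff, "dccm_difference"))
  if (is.null(threshold)) threshold <- diff$threshold
  if (threshold <= 0 || threshold > 2) rlang::abort("threshold must be in (0, 2]")
  M <- diff$matrix
  n <- nrow(M)
  offdiag <- !diag(n)
  frac <- vapply(seq_len(n), function(i) {
    mean(M[i, offdiag[i, ]] >= threshold)
  }, numeric(1))
  affected <- frac > row_fraction
  runs <- list()
  i <- 1
  while (i <= n) {
    if (!affected[i]) { i <- i + 1; next }
    j <- i
    while (j < n) {
      nxt <- which(affected & seq_len(n) > j & seq_len(n) <= j + gap + 1)
      if (length(nxt) == 0) break
      j <- max(nxt)
    }
    runs[[length(runs) + 1]] <- c(i, j)
    i <- j + 1
  }
  out <- tibble::tibble(start = integer(), end = integer(), score = numeric())
  for (r in runs) {
    if (r[2] - r[1] + 1 < min_len) next
    rows <- r[1]:r[2]
    vals <- M[rows, , drop = FALSE][M[rows, , drop = FALSE] >= threshold]
    out <- dplyr::bind_rows(out, tibble::tibble(
      start = diff$resid[r[1]], end = diff$resid[r[2]],
      score = if (length(vals)) mean(vals) else 0
    ))
  }
  class(out) <- c("region_set", class(out))
  out
}
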