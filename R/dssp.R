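#' Kabsch-Sander secondary-structure assignment
#'
#' A self-contained implementation of the classic 1983 dictionary: amide
#' hydrogens are reconstructed on the backbone, hydrogen bonds are scored
#' with the electrostatic model, and the usual eight states are assigned
#' (H alpha helix, G 3-10 helix, I pi helix, E extended strand, B isolated
#' beta bridge, T hydrogen-bonded turn, S bend, "-" coil).
#'
#' @name dssp
NULL

.hb_cutoff <- -0.5        # kcal/mol; bond recorded below this
.hb_q <- 0.084 * 332      # coupling constant, kcal*A/mol
.chain_break <- 2.5       # peptide C-N distance above this ends a chain

# Gather per-residue backbone coordinates for one frame.
# Returns list of matrices N, CA, C, O (n_res x 3, NA rows where incomplete)
backbone_frame <- function(top, coords) {
  n <- nrow(top$residues)
  out <- list()
  for (nm in c("N", "CA", "C", "O")) {
    m <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      k <- top$backbone[[i]][[nm]]
      if (!is.na(k)) m[i, ] <- coords[k, ]
    }
    out[[nm]] <- m
  }
  out$complete <- top$residues$complete
  out$proline <- toupper(top$residues$resname) == "PRO"
  out
}

#' Place amide hydrogens
#'
#' Reconstructs the backbone amide hydrogen of each residue at 1.0 Angstrom
#' from N, directed along the previous residue's O-to-C carbonyl vector (the
#' classic DSSP construction). Prolines, chain N-termini and residues after
#' a chain break get no hydrogen and cannot act as donors.
#'
#' @param top a [topology()].
#' @param coords one frame as an `n_atoms x 3` matrix.
#' @return an `n_residues x 3` matrix of H coordinates (NA rows where no H).
#' @export
place_amide_hydrogens <- function(top, coords) {
  bb <- backbone_frame(top, coords)
  n <- nrow(bb$N)
  H <- matrix(NA_real_, n, 3)
  same_chain <- c(FALSE, top$residues$chain[-1] == top$residues$chain[-n])
  for (i in seq_len(n)) {
    if (i == 1 || !same_chain[i] || bb$proline[i]) next
    if (anyNA(bb$N[i, ]) || anyNA(bb$C[i - 1, ]) || anyNA(bb$O[i - 1, ])) next
    # chain break: no peptide bond, no donor
    if (sqrt(sum((bb$N[i, ] - bb$C[i - 1, ])^2)) > .chain_break) next
    v <- bb$C[i - 1, ] - bb$O[i - 1, ]
    H[i, ] <- bb$N[i, ] + v / sqrt(sum(v^2))
  }
  H
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic energy of the N-H...O=C interaction between a donor and an
#' acceptor residue: `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)`
#' kcal/mol with distances in Angstrom. Any participating distance below
#' 0.5 Angstrom clamps the energy to -9.9 (the dictionary's convention for
#' overlapping atoms).
#'
#' @param n_d,h_d donor backbone N and amide H coordinates (3-vectors).
#' @param c_a,o_a acceptor backbone C and O coordinates.
#' @return energy in kcal/mol (large distances give values near 0).
#' @export
hbond_energy <- function(n_d, h_d, c_a, o_a) {
  rON <- sqrt(sum((n_d - o_a)^2))
  rCH <- sqrt(sum((h_d - c_a)^2))
  rOH <- sqrt(sum((h_d - o_a)^2))
  rCN <- sqrt(sum((n_d - c_a)^2))
  if (min(rON, rCH, rOH, rCN) < 0.5) return(-9.9)
  e <- .hb_q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  max(e, -9.9)
}

# n_res x n_res matrix: E[i, j] = energy of bond donated by NH of i to CO of j
hbond_matrix <- function(bb, H) {
  n <- nrow(bb$N)
  E <- matrix(0, n, n)
  donors <- which(!is.na(H[, 1]))
  acceptors <- which(!is.na(bb$C[, 1]) & !is.na(bb$O[, 1]))
  if (length(donors) == 0 || length(acceptors) == 0) return(E)
  # distance prefilter on CA-CA < 9 A, as in the reference implementations
  ca_ok <- !is.na(bb$CA[, 1])
  for (i in donors) {
    if (!ca_ok[i]) next
    dca <- rowSums(sweep(bb$CA, 2, bb$CA[i, ])^2)
    for (j in acceptors) {
      if (j == i || !ca_ok[j]) next
      if (dca[j] > 81) next
      E[i, j] <- hbond_energy(bb$N[i, ], H[i, ], bb$C[j, ], bb$O[j, ])
    }
  }
  E
}

# core single-frame assignment; returns a character vector over residues
dssp_frame <- function(top, coords) {
  bb <- backbone_frame(top, coords)
  n <- nrow(bb$N)
  ss <- rep("-", n)
  if (n < 3) return(ss)
  H <- place_amide_hydrogens(top, coords)
  E <- hbond_matrix(bb, H)
  hb <- E < .hb_cutoff                    # hb[i, j]: NH(i) -> CO(j)
  # chain continuity between consecutive residues
  cont <- rep(FALSE, n)                   # cont[i]: peptide bond i-1 -> i intact
  for (i in 2:n) {
    if (top$residues$chain[i] != top$residues$chain[i - 1]) next
    if (anyNA(bb$C[i - 1, ]) || anyNA(bb$N[i, ])) next
    cont[i] <- sqrt(sum((bb$N[i, ] - bb$C[i - 1, ])^2)) <= .chain_break
  }
  run_ok <- function(i, j) {              # residues i..j on one unbroken chain
    if (i < 1 || j > n) return(FALSE)
    if (i == j) return(TRUE)
    all(cont[(i + 1):j])
  }
  # n-turns: turn_n[i] TRUE if CO(i) accepts from NH(i+n)
  turn <- list()
  for (nn in 3:5) {
    t <- rep(FALSE, n)
    for (i in seq_len(max(0, n - nn))) {
      if (hb[i + nn, i] && run_ok(i, i + nn)) t[i] <- TRUE
    }
    turn[[nn]] <- t
  }
  # bridges: i, j with |i - j| >= 3 (j > i + 2)
  para <- matrix(FALSE, n, n); anti <- matrix(FALSE, n, n)
  for (i in seq_len(max(0, n - 5)) + 1) {
    if (!run_ok(i - 1, i + 1)) next
    for (j in seq(i + 3, n - 1)) {
      if (!run_ok(j - 1, j + 1)) next
      p <- (hb[j, i - 1] && hb[i + 1, j]) || (hb[i, j - 1] && hb[j + 1, i])
      a <- (hb[j, i] && hb[i, j]) || (hb[j + 1, i - 1] && hb[i + 1, j - 1])
      if (p) { para[i, j] <- TRUE; para[j, i] <- TRUE }
      if (a) { anti[i, j] <- TRUE; anti[j, i] <- TRUE }
    }
  }
  # ladders: runs of consecutive bridges of one type
  bp <- which(upper.tri(para) & para, arr.ind = TRUE)
  ba <- which(upper.tri(anti) & anti, arr.ind = TRUE)
  bridges <- rbind(
    if (nrow(bp) > 0) cbind(bp, type = rep(1, nrow(bp))),
    if (nrow(ba) > 0) cbind(ba, type = rep(2, nrow(ba)))
  )
  if (is.null(bridges)) bridges <- matrix(0, 0, 3)
  ladders <- list()
  if (nrow(bridges) > 0) {
    bridges <- bridges[order(bridges[, 3], bridges[, 1], bridges[, 2]), ,
                       drop = FALSE]
    used <- rep(FALSE, nrow(bridges))
    for (b in seq_len(nrow(bridges))) {
      if (used[b]) next
      i0 <- bridges[b, 1]; j0 <- bridges[b, 2]; ty <- bridges[b, 3]
      li <- i0; lj <- j0
      repeat {
        nxt_j <- if (ty == 1) lj[length(lj)] + 1 else lj[length(lj)] - 1
        cand <- which(!used & bridges[, 1] == li[length(li)] + 1 &
                        bridges[, 2] == nxt_j & bridges[, 3] == ty)
        if (length(cand) == 0) break
        used[cand[1]] <- TRUE
        li <- c(li, bridges[cand[1], 1]); lj <- c(lj, bridges[cand[1], 2])
      }
      used[b] <- TRUE
      ladders[[length(ladders) + 1]] <- list(i = li, j = sort(lj), type = ty)
    }
  }
  # bulge linking: merge ladders of equal type separated by <= 2 residues on
  # one strand and <= 5 on the other (classic beta-bulge criterion, with the
  # bulge residues joining the sheet)
  merged <- rep(FALSE, length(ladders))
  if (length(ladders) > 1) {
    for (x in seq_along(ladders)) {
      for (y in seq_along(ladders)) {
        if (x >= y) next
        lx <- ladders[[x]]; ly <- ladders[[y]]
        if (lx$type != ly$type) next
        gi <- min(abs(min(ly$i) - max(lx$i)), abs(min(lx$i) - max(ly$i)))
        gj <- min(abs(min(ly$j) - max(lx$j)), abs(min(lx$j) - max(ly$j)))
        if ((gi <= 2 && gj <= 5) || (gj <= 2 && gi <= 5)) {
          merged[x] <- TRUE; merged[y] <- TRUE
        }
      }
    }
  }
  is_E <- rep(FALSE, n); is_B <- rep(FALSE, n)
  for (x in seq_along(ladders)) {
    l <- ladders[[x]]
    res <- c(l$i, l$j)
    if (length(l$i) > 1 || merged[x]) is_E[res] <- TRUE else is_B[res] <- TRUE
  }
  # helices: minimal helix of type nn at i when turn_nn at i-1 and i
  helix4 <- rep(FALSE, n); helix3 <- rep(FALSE, n); helix5 <- rep(FALSE, n)
  if (n >= 6) {
    for (i in 2:(n - 4)) {
      if (turn[[4]][i - 1] && turn[[4]][i]) helix4[i:(i + 3)] <- TRUE
    }
  }
  for (i in seq_len(n)) if (helix4[i]) ss[i] <- "H"
  if (n >= 5) {
    for (i in 2:(n - 3)) {
      if (turn[[3]][i - 1] && turn[[3]][i]) {
        res <- i:(i + 2)
        if (all(ss[res] %in% c("-", "G"))) helix3[res] <- TRUE
      }
    }
  }
  if (n >= 7) {
    for (i in 2:(n - 5)) {
      if (turn[[5]][i - 1] && turn[[5]][i]) {
        res <- i:(i + 4)
        # pi helix may not steal residues from an alpha helix
        if (all(ss[res] %in% c("-", "I"))) helix5[res] <- TRUE
      }
    }
  }
  # priority: H > E > B > G > I > T > S
  for (i in seq_len(n)) {
    if (ss[i] == "H") next
    if (is_E[i]) { ss[i] <- "E"; next }
    if (is_B[i]) { ss[i] <- "B"; next }
    if (helix3[i]) { ss[i] <- "G"; next }
    if (helix5[i]) { ss[i] <- "I"; next }
  }
  # turns: interior residues of any n-turn
  for (nn in 3:5) {
    for (i in which(turn[[nn]])) {
      res <- (i + 1):(i + nn - 1)
      res <- res[res <= n]
      for (r in res) if (ss[r] == "-") ss[r] <- "T"
    }
  }
  # bends: kink of the Calpha trace > 70 degrees
  if (n >= 5) for (i in 3:(n - 2)) {
    if (ss[i] != "-") next
    if (!run_ok(i - 2, i + 2)) next
    if (anyNA(bb$CA[i - 2, ]) || anyNA(bb$CA[i, ]) || anyNA(bb$CA[i + 2, ])) next
    u <- bb$CA[i, ] - bb$CA[i - 2, ]
    v <- bb$CA[i + 2, ] - bb$CA[i, ]
    cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    if (acos(pmin(pmax(cosang, -1), 1)) > 70 * pi / 180) ss[i] <- "S"
  }
  ss[!bb$complete] <- "-"
  ss
}

#' Assign DSSP codes to one frame
#'
#' @param top a [topology()] with backbone indices.
#' @param xyz one frame, length `3 * n_atoms` or `n_atoms x 3`.
#' @return character vector of 8-state codes, one per residue; incomplete
#'   residues are always `"-"`.
#' @export
assign_dssp <- function(top, xyz) {
  coords <- if (is.matrix(xyz)) xyz else xyz_to_coords(xyz)
  dssp_frame(top, coords)
}

#' Assign DSSP codes to every frame of a trajectory
#'
#' @param traj a [trajectory()] with full backbone.
#' @return object of class `sse_timeline`: a list with `codes` (n_frames x
#'   n_residues character matrix), `resid`, `label`, `replicate`.
#' @export
assign_dssp_trajectory <- function(traj) {
  top <- traj$topology
  if (!any(top$residues$complete)) {
    rlang::abort("no residue has a complete backbone; DSSP needs N, CA, C, O")
  }
  codes <- t(vapply(seq_len(n_frames(traj)), function(i) {
    dssp_frame(top, frame_coords(traj, i))
  }, character(nrow(top$residues))))
  structure(list(codes = codes, resid = top$residues$resid,
                 label = traj$label, replicate = traj$replicate),
            class = "sse_timeline")
}

#' @export
print.sse_timeline <- function(x, ...) {
  cat("<sse_timeline> '", x$label, "': ", nrow(x$codes), " frames x ",
      ncol(x$codes), " residues\n", sep = "")
  invisible(x)
}

# reported class names for the 8 DSSP codes
.sse_classes <- c(H = "alpha-helix", G = "3-10-helix", I = "pi-helix",
                  E = "beta-sheet", B = "beta-bridge", T = "turn",
                  S = "bend", `-` = "coil")

#' Secondary-structure occupancy
#'
#' Per-residue fraction of frames spent in each of the eight classes, and
#' the overall percentage of residue-frames per class (which sums to 100).
#'
#' @param timeline an `sse_timeline`.
#' @return object of class `occupancy_profile`: list with `per_residue`
#'   (tibble resid x class fractions, long format) and `overall` (tibble of
#'   class percentages).
#' @export
sse_occupancy <- function(timeline) {
  stopifnot(inherits(timeline, "sse_timeline"))
  codes <- timeline$codes
  nf <- nrow(codes)
  per_res <- lapply(names(.sse_classes), function(cl) {
    tibble::tibble(
      resid = timeline$resid,
      code = cl,
      class = .sse_classes[[cl]],
      fraction = colSums(codes == cl) / nf
    )
  })
  per_res <- dplyr::bind_rows(per_res)
  overall <- dplyr::summarise(dplyr::group_by(per_res, .data$code, .data$class),
                              percent = 100 * mean(.data$fraction),
                              .groups = "drop")
  structure(list(per_residue = per_res, overall = overall,
                 label = timeline$label, n_frames = nf,
                 resid = timeline$resid),
            class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat("<occupancy_profile> '", x$label, "' (", x$n_frames, " frames)\n", sep = "")
  o <- x$overall[order(-x$overall$percent), ]
  for (i in seq_len(nrow(o))) {
    cat(sprintf("  %-12s %6.2f%%\n", o$class[i], o$percent[i]))
  }
  invisible(x)
}

#' Secondary-structure difference profile (variant minus wild)
#'
#' Per-residue, per-class occupancy deltas in percentage points, plus overall
#' class deltas both unrounded and rounded to integer percent (the
#' granularity at which such shifts are usually quoted).
#'
#' @param variant,wild `occupancy_profile` objects over the same residues.
#' @return object of class `sse_difference`: list with `per_residue` tibble
#'   (`delta` in percentage points) and `overall` tibble (`delta`,
#'   `delta_rounded`).
#' @export
sse_difference <- function(variant, wild) {
  stopifnot(inherits(variant, "occupancy_profile"),
            inherits(wild, "occupancy_profile"))
  if (!identical(variant$resid, wild$resid)) {
    rlang::abort("occupancy profiles cover different residue ranges")
  }
  pr <- dplyr::inner_join(variant$per_residue, wild$per_residue,
                          by = c("resid", "code", "class"),
                          suffix = c("_variant", "_wild"))
  pr$delta <- 100 * (pr$fraction_variant - pr$fraction_wild)
  ov <- dplyr::inner_join(variant$overall, wild$overall,
                          by = c("code", "class"), suffix = c("_variant", "_wild"))
  ov$delta <- ov$percent_variant - ov$percent_wild
  ov$delta_rounded <- round(ov$delta)
  structure(list(per_residue = pr[, c("resid", "code", "class", "delta")],
                 overall = ov[, c("code", "class", "delta", "delta_rounded")],
                 labels = c(variant = variant$label, wild = wild$label)),
            class = "sse_difference")
}

#' Count extended-strand segments
#'
#' Number of maximal runs of "E" per frame, averaged over frames; together
#' with the B (isolated bridge) occupancy this distinguishes sheet content
#' from strand count.
#'
#' @param timeline an `sse_timeline`.
#' @return tibble with `frame` and `n_strands`.
#' @export
strand_segments <- function(timeline) {
  stopifnot(inherits(timeline, "sse_timeline"))
  n <- vapply(seq_len(nrow(timeline$codes)), function(i) {
    r <- rle(timeline$codes[i, ] == "E")
    sum(r$values)
  }, numeric(1))
  tibble::tibble(frame = seq_along(n), n_strands = n)
}

#' Write per-frame DSSP strings
#'
#' One line per frame, one character per residue.
#'
#' @param timeline an `sse_timeline`.
#' @param path output text file.
#' @export
write_sse_timeline <- function(timeline, path) {
  writeLines(apply(timeline$codes, 1, paste, collapse = ""), path)
  invisible(path)
}
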