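#' Select atoms by a small expression grammar
#'
#' The grammar is a conjunction of terms joined by `and`:
#' \describe{
#'   \item{`CA`}{alpha carbons (one per complete residue)}
#'   \item{`backbone`}{N, CA, C, O atoms}
#'   \item{`heavy`}{all non-hydrogen atoms}
#'   \item{`all`}{every atom}
#'   \item{`name X`}{atoms named `X` (exact match after trimming)}
#'   \item{`resid a-b` / `resid a`}{author residue-number range (inclusive)}
#'   \item{`chain X`}{chain identifier}
#' }
#' Selections are deterministic, idempotent and returned in ascending atom
#' order; an empty result is an error.
#'
#' @param top a [topology()].
#' @param expression selection string, e.g. `"resid 46-56 and CA"`.
#' @return an integer vector of atom indices (class `selection_mask`) with a
#'   `description` attribute.
#' @export
select_atoms <- function(top, expression) {
  at <- top$atoms
  terms <- strsplit(trimws(expression), "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(at))
  for (tm in terms) {
    tok <- strsplit(trimws(tm), "\\s+")[[1]]
    head_tok <- tolower(tok[1])
    hit <- switch(
      head_tok,
      ca = at$name == "CA",
      backbone = at$name %in% c("N", "CA", "C", "O"),
      heavy = toupper(at$element) != "H",
      all = rep(TRUE, nrow(at)),
      name = {
        if (length(tok) < 2) rlang::abort("'name' requires an atom name")
        at$name %in% tok[-1]
      },
      resid = {
        if (length(tok) != 2) rlang::abort("'resid' requires a number or range a-b")
        rng <- as.integer(strsplit(tok[2], "-")[[1]])
        if (anyNA(rng)) rlang::abort(paste("bad resid range:", tok[2]))
        if (length(rng) == 1) rng <- c(rng, rng)
        at$resid >= rng[1] & at$resid <= rng[2]
      },
      chain = {
        if (length(tok) < 2) rlang::abort("'chain' requires a chain id")
        at$chain %in% tok[-1]
      },
      rlang::abort(paste("unknown selection term:", tm))
    )
    keep <- keep & hit
  }
  idx <- which(keep)
  if (length(idx) == 0) {
    rlang::abort(paste0("selection '", expression, "' matches no atoms"))
  }
  structure(idx, class = "selection_mask", description = expression)
}

#' @export
print.selection_mask <- function(x, ...) {
  cat("<selection_mask> '", attr(x, "description"), "': ", length(x),
      " atoms\n", sep = "")
  invisible(x)
}

# resolve a mask argument: selection_mask, expression string, or raw indices
resolve_mask <- function(top, mask) {
  if (is.character(mask)) return(select_atoms(top, mask))
  idx <- as.integer(mask)
  if (length(idx) == 0 || anyNA(idx) || any(idx < 1) || any(idx > n_atoms(top))) {
    rlang::abort("invalid atom mask")
  }
  sort(unique(idx))
}

# residue ids (author numbering) corresponding to the atoms of a mask,
# in mask order
mask_resids <- function(top, idx) top$atoms$resid[idx]
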