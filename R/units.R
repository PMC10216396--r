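#' Structural units
#'
#' A structural unit is an ordered set of residues, each reduced to one
#' "effective atom" (the mean position of its heavy atoms), analyzed as a
#' whole: a single chain, a proto-fibril (one stack of chains) or a
#' super-fibril (all stacks of the assembly).
#'
#' @name structural_unit
#' @keywords internal
NULL

new_structural_unit <- function(residues, level, provenance = list()) {
  stopifnot(is.data.frame(residues))
  level <- match.arg(level, c("chain", "proto-fibril", "super-fibril"))
  req <- c("chain_id", "seq_id", "aa", "x", "y", "z")
  if (!all(req %in% names(residues)))
    stop("residue table must have columns: ", paste(req, collapse = ", "))
  if (nrow(residues) < 2)
    stop("a structural unit needs at least 2 residues, got ", nrow(residues))
  key <- paste(residues$chain_id, residues$seq_id,
               if (!is.null(residues$ins)) residues$ins else "")
  if (anyDuplicated(key))
    stop("duplicate (chain_id, seq_id) pairs in unit")
  if (!all(is.finite(as.matrix(residues[, c("x", "y", "z")]))))
    stop("non-finite effective-atom coordinates")
  if (is.null(residues$hydro)) residues$hydro <- NA_real_
  rownames(residues) <- NULL
  structure(list(residues = residues, level = level, provenance = provenance),
            class = "structural_unit")
}

#' Effective-atom coordinates of a unit
#' @param unit a \code{structural_unit}
#' @return numeric matrix, one row per residue, columns x/y/z (Angstrom)
#' @export
unit_coords <- function(unit) {
  stopifnot(inherits(unit, "structural_unit"))
  as.matrix(unit$residues[, c("x", "y", "z")])
}

#' @export
length.structural_unit <- function(x) nrow(x$residues)

#' @export
print.structural_unit <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("Structural unit (%s): %d residues, %d chain(s)\n",
              x$level, nrow(x$residues), length(unique(x$residues$chain_id))))
  if (!is.null(p$id)) cat("  structure:", p$id,
                          if (!is.null(p$model)) paste0("(model ", p$model, ")"),
                          "\n")
  rng <- range(x$residues$seq_id)
  cat("  chains:", paste(unique(x$residues$chain_id), collapse = ","),
      " residues:", rng[1], "-", rng[2], "\n")
  invisible(x)
}

# apply a hydrophobicity scale to the unit's residues
assign_hydrophobicity <- function(unit, scale) {
  stopifnot(inherits(unit, "structural_unit"), inherits(scale, "hydro_scale"))
  idx <- match(unit$residues$aa, names(scale))
  if (anyNA(idx))
    stop("residues not covered by scale '", attr(scale, "name"), "': ",
         paste(unique(unit$residues$aa[is.na(idx)]), collapse = ", "))
  unit$residues$hydro <- as.numeric(scale)[idx]
  unit
}

# subset a unit by row index, preserving class/level/provenance
subset_unit <- function(unit, keep) {
  new_structural_unit(unit$residues[keep, , drop = FALSE],
                      level = unit$level, provenance = unit$provenance)
}
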