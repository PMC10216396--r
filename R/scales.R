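#' Amino-acid hydrophobicity scales
#'
#' The observed hydrophobicity profile weighs every residue by an intrinsic
#' hydrophobicity \eqn{H^r}. Divergence arithmetic requires all values to be
#' nonnegative, so every registered scale is normalized to the interval
#' \eqn{[0, 1]}.
#'
#' Two scales are built in:
#' \describe{
#'   \item{\code{"black_mould"}}{Relative hydrophobicity of Black & Mould
#'     (1991), already published on a 0--1 range (Phe = 1, Arg = 0). The
#'     package default.}
#'   \item{\code{"kyte_doolittle"}}{The Kyte--Doolittle hydropathy index,
#'     min--max rescaled to 0--1 so that it is nonnegative.}
#' }
#'
#' @param name scale name (\code{"black_mould"} or \code{"kyte_doolittle"}),
#'   or a path to a two-column plain-text file (one-letter code, value;
#'   \code{#} comments allowed).
#' @return An object of class \code{hydro_scale}: a named numeric vector over
#'   the 20 one-letter codes with attributes \code{name}.
#' @examples
#' sc <- hydro_scale("black_mould")
#' sc[["F"]]  # most hydrophobic, 1.0
#' @export
hydro_scale <- function(name = "black_mould") {
  if (file.exists(name)) return(read_scale_file(name))
  values <- switch(name,
    black_mould = c(
      A = 0.616, R = 0.000, N = 0.236, D = 0.028, C = 0.680,
      Q = 0.251, E = 0.043, G = 0.501, H = 0.165, I = 0.943,
      L = 0.943, K = 0.283, M = 0.738, F = 1.000, P = 0.711,
      S = 0.359, T = 0.450, W = 0.878, Y = 0.880, V = 0.825),
    kyte_doolittle = {
      kd <- c(
        A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
        Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
        L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
        S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
      (kd - min(kd)) / (max(kd) - min(kd))
    },
    stop("unknown hydrophobicity scale '", name,
         "' (and no file of that name exists)", call. = FALSE)
  )
  new_hydro_scale(values, name)
}

new_hydro_scale <- function(values, name) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  missing <- setdiff(aa, names(values))
  if (length(missing))
    stop("scale '", name, "' does not cover residues: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("scale '", name, "' must be finite and nonnegative", call. = FALSE)
  values <- values[aa]
  structure(values, name = name, class = c("hydro_scale", "numeric"))
}

read_scale_file <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("aa", "value"),
                           colClasses = c("character", "numeric"))
  new_hydro_scale(stats::setNames(tab$value, toupper(tab$aa)),
                  name = basename(path))
}

#' @export
print.hydro_scale <- function(x, ...) {
  cat("Hydrophobicity scale:", attr(x, "name"), "\n")
  print(unclass(stats::setNames(as.numeric(x), names(x))))
  invisible(x)
}

# three-letter -> one-letter for the 20 standard residues
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
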