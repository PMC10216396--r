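#' Specification of a synthetic chain-like unit
#'
#' Seeded fixtures emulating the geometry and hydrophobicity organization
#' the analysis is designed to discriminate: residues become effective
#' atoms ~3.8 Angstrom apart, carrying a planted radial hydrophobicity
#' pattern.
#'
#' @param kind \describe{
#'   \item{\code{"micelle"}}{hydrophobicity increasing toward the geometric
#'     center (centric core, the water-directed organization).}
#'   \item{\code{"inverted"}}{hydrophobicity increasing toward the surface
#'     (membrane-like, the opposite organization).}
#'   \item{\code{"uniform"}}{a single residue type everywhere.}
#'   \item{\code{"planted_outlier"}}{micelle plus one maximally hydrophobic
#'     residue forced onto the surface.}}
#' @param n_residues residues per chain (>= 10).
#' @param n_chains number of chains; > 1 stacks chains as in a fibril.
#' @param geometry \code{"globule"} (self-avoiding walk in a sphere) or
#'   \code{"ribbon_stack"} (planar zig-zag strands stacked 4.8 Angstrom
#'   apart, the cross-beta repeat of amyloid fibrils).
#' @param seed integer; fully determines the output.
#' @param noise_sd Gaussian noise on the target hydrophobicity before
#'   amino-acid mapping.
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(kind = c("micelle", "inverted", "uniform",
                                    "planted_outlier"),
                           n_residues = 80, n_chains = 1,
                           geometry = c("globule", "ribbon_stack"),
                           seed = 1, noise_sd = 0) {
  kind <- match.arg(kind)
  geometry <- match.arg(geometry)
  if (n_residues < 10) stop("n_residues must be >= 10")
  if (n_chains < 1) stop("n_chains must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(kind = kind, n_residues = n_residues, n_chains = n_chains,
                 geometry = geometry, seed = as.integer(seed),
                 noise_sd = noise_sd),
            class = "synthetic_spec")
}

#' Generate a synthetic structural unit
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param scale scale used to map the planted continuous hydrophobicity to
#'   the nearest real amino acid, so fixtures remain valid inputs for the
#'   scale-dependent observed profile.
#' @return a \code{structural_unit}; attribute \code{"target_hydro"} holds
#'   the planted continuous values (ground truth), attribute
#'   \code{"outlier_index"} the planted outlier's row (if any).
#' @export
generate_unit <- function(spec, scale = hydro_scale()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  xyz <- switch(spec$geometry,
    globule = saw_globule(spec$n_residues * spec$n_chains),
    ribbon_stack = ribbon_stack(spec$n_residues, spec$n_chains))
  n <- nrow(xyz)
  center <- colMeans(xyz)
  d <- sqrt(rowSums(sweep(xyz, 2, center)^2))
  # plant the micelle-like pattern itself: an isotropic Gaussian whose
  # width follows the same +-3 sigma convention as the fitted envelope
  s <- max(d, 1e-9) / 3
  g <- exp(-d^2 / (2 * s^2))
  target <- switch(spec$kind,
    micelle = g,
    planted_outlier = g,
    inverted = 1 - g,
    uniform = rep(0.5, n))
  if (spec$noise_sd > 0)
    target <- pmin(1, pmax(0, target + stats::rnorm(n, 0, spec$noise_sd)))
  outlier <- NA_integer_
  if (spec$kind == "planted_outlier") {
    # surface residue (outer shell by radius) with the most neighbors, so
    # its misplaced hydrophobicity registers strongly in the observed sum
    shell <- which(d >= stats::quantile(d, 0.85))
    dm <- as.matrix(stats::dist(xyz))
    outlier <- shell[which.max(rowSums(dm[shell, , drop = FALSE] <= 9))]
    target[outlier] <- 1
  }
  aa <- if (spec$kind == "uniform") rep("A", n)
        else map_to_residues(target, scale)
  if (spec$kind == "planted_outlier")
    aa[outlier] <- names(scale)[which.max(as.numeric(scale))]
  chain_id <- rep(LETTERS[seq_len(spec$n_chains)], each = spec$n_residues)
  res <- data.frame(chain_id = chain_id,
                    seq_id = rep(seq_len(spec$n_residues), spec$n_chains),
                    ins = "", aa = aa,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    stringsAsFactors = FALSE)
  unit <- new_structural_unit(
    res, level = if (spec$n_chains == 1) "chain" else "proto-fibril",
    provenance = list(id = paste0("synthetic-", spec$kind),
                      seed = spec$seed, geometry = spec$geometry))
  attr(unit, "target_hydro") <- target
  attr(unit, "outlier_index") <- outlier
  unit
}

# self-avoiding walk: 3.8 A steps inside a sphere sized for protein-like
# density, minimum 3.0 A between non-consecutive points
saw_globule <- function(n, step = 3.8, min_sep = 3.0, radius = NULL,
                        restarts = 60) {
  if (is.null(radius)) radius <- 3.0 * n^(1 / 3)
  for (attempt in seq_len(restarts)) {
    xyz <- matrix(NA_real_, n, 3)
    xyz[1, ] <- stats::runif(3, -radius / 4, radius / 4)
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:100) {
        u <- stats::rnorm(3)
        cand <- xyz[i - 1, ] + step * u / sqrt(sum(u^2))
        if (sqrt(sum(cand^2)) > radius) next
        if (i > 2) {
          d2 <- rowSums(sweep(xyz[1:(i - 2), , drop = FALSE], 2, cand)^2)
          if (min(d2) < min_sep^2) next
        }
        xyz[i, ] <- cand; placed <- TRUE; break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xyz)
  }
  stop("self-avoiding placement failed after ", restarts,
       " restarts; increase the sphere radius")
}

# planar zig-zag strands (3.8 A bonds) stacked 4.8 A apart along z
ribbon_stack <- function(n_res, n_chains, bond = 3.8, zig = 0.95,
                         spacing = 4.8) {
  dx <- sqrt(bond^2 - (2 * zig)^2)
  one <- cbind(x = (seq_len(n_res) - 1) * dx,
               y = zig * (-1)^(seq_len(n_res)),
               z = 0)
  do.call(rbind, lapply(seq_len(n_chains) - 1,
                        function(k) sweep(one, 2, c(0, 0, k * spacing), "+")))
}

# nearest amino acid by scale value (scale spans [0,1]); deterministic ties
map_to_residues <- function(target, scale) {
  v <- as.numeric(scale)
  names(scale)[vapply(target, function(t) which.min(abs(v - t)), integer(1))]
}

#' Brute-force observed profile (test oracle)
#'
#' Independent plain double-loop evaluation of the pairwise Levitt sum,
#' sharing no code with \code{\link{observed_profile}}. Intended for tests.
#'
#' @inheritParams observed_profile
#' @return numeric vector summing to 1.
#' @export
oracle_observed <- function(unit, scale = hydro_scale(), cutoff_c = 9.0,
                            include_self = TRUE) {
  r <- unit$residues
  h <- as.numeric(scale)[match(r$aa, names(scale))]
  n <- nrow(r)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j == i && !include_self) next
      rij <- sqrt((r$x[i] - r$x[j])^2 + (r$y[i] - r$y[j])^2 +
                  (r$z[i] - r$z[j])^2)
      if (rij > cutoff_c) next
      q <- rij / cutoff_c
      br <- 1 - 0.5 * (7 * q^2 - 9 * q^4 + 5 * q^6 - q^8)
      acc <- acc + (h[i] + h[j]) * br
    }
    raw[i] <- acc
  }
  raw / sum(raw)
}

#' Brute-force divergences and RD (test oracle)
#'
#' Independent per-term summation of the Kullback-Leibler divergences and
#' the RD ratio. Intended for tests.
#'
#' @param O,T,R probability vectors of equal length.
#' @return list: \code{dkl_OT}, \code{dkl_OR}, \code{rd}.
#' @export
oracle_dkl_rd <- function(O, T, R = rep(1 / length(O), length(O))) {
  dk <- function(P, Q) {
    s <- 0
    for (i in seq_along(P))
      if (P[i] > 0) s <- s + P[i] * log(P[i] / Q[i], base = 2)
    s
  }
  d_ot <- dk(O, T); d_or <- dk(O, R)
  list(dkl_OT = d_ot, dkl_OR = d_or,
       rd = if (d_ot + d_or > 0) d_ot / (d_ot + d_or) else 0.5)
}
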