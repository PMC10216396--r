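#' Fit the 3D Gaussian envelope to a structural unit
#'
#' The idealized micelle-like hydrophobicity field is a 3D Gaussian spanned
#' over the body of the unit. Its center is the mean effective-atom
#' position; its axes are the principal axes of the positional covariance
#' (descending eigenvalue, right-handed); its widths reflect the shape of
#' the molecule along each axis.
#'
#' Two sigma rules are provided. \code{"extent_over_3"} (default) sets
#' \eqn{\sigma} to the maximal absolute centered coordinate along the axis
#' divided by 3, so the whole unit lies within \eqn{\pm 3\sigma}.
#' \code{"std_dev"} uses the sample standard deviation along the axis.
#' Both are floored at 1 Angstrom so that flat amyloid ribbons cannot
#' produce a singular Gaussian.
#'
#' @param unit a \code{structural_unit}.
#' @param sigma_rule \code{"extent_over_3"} or \code{"std_dev"}.
#' @param sigma_floor minimal sigma, Angstrom.
#' @return An object of class \code{gaussian_envelope}: list with
#'   \code{center} (3-vector), \code{axes} (3x3 orthonormal, columns =
#'   principal axes) and \code{sigma} (3-vector, Angstrom).
#' @export
fit_envelope <- function(unit, sigma_rule = c("extent_over_3", "std_dev"),
                         sigma_floor = 1.0) {
  sigma_rule <- match.arg(sigma_rule)
  xyz <- unit_coords(unit)
  if (nrow(xyz) < 2) stop("envelope fit needs at least 2 residues")
  center <- colMeans(xyz)
  cen <- sweep(xyz, 2, center)
  if (max(abs(cen)) < 1e-9) stop("all effective atoms coincide")
  ev <- eigen(stats::cov(cen), symmetric = TRUE)
  axes <- ev$vectors                       # columns, descending eigenvalue
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]   # right-handed frame
  proj <- cen %*% axes
  sigma <- switch(sigma_rule,
    extent_over_3 = apply(abs(proj), 2, max) / 3,
    std_dev       = apply(proj, 2, stats::sd))
  degen <- sigma < sigma_floor
  if (any(degen)) {
    if (all(sigma[!degen] > sigma_floor) && sum(degen) >= 1 &&
        any(sigma < 1e-6))
      warning("degenerate geometry along ", sum(sigma < 1e-6),
              " axis/axes; sigma floored at ", sigma_floor, " Angstrom")
    sigma[degen] <- sigma_floor
  }
  structure(list(center = center, axes = axes, sigma = as.numeric(sigma),
                 sigma_rule = sigma_rule),
            class = "gaussian_envelope")
}

#' @export
print.gaussian_envelope <- function(x, ...) {
  cat(sprintf("3D Gaussian envelope (%s): sigma = %.2f, %.2f, %.2f A\n",
              x$sigma_rule, x$sigma[1], x$sigma[2], x$sigma[3]))
  invisible(x)
}

#' Theoretical (T) hydrophobicity profile
#'
#' Evaluates the 3D Gaussian at every effective atom in the principal frame
#' and normalizes to unit sum. All entries are strictly positive.
#'
#' @param unit a \code{structural_unit}.
#' @param envelope a \code{gaussian_envelope}; fitted from \code{unit} if
#'   missing.
#' @return numeric vector of length \code{N}, summing to 1.
#' @export
theoretical_profile <- function(unit, envelope = fit_envelope(unit)) {
  xyz <- unit_coords(unit)
  proj <- sweep(xyz, 2, envelope$center) %*% envelope$axes
  # log-space evaluation keeps far-flung residues positive after exp
  logt <- -0.5 * (sweep(proj, 2, envelope$sigma, "/"))^2
  t_raw <- exp(rowSums(logt))
  t_raw <- pmax(t_raw, .Machine$double.xmin)
  as.numeric(t_raw / sum(t_raw))
}

# Levitt pairwise attenuation: 1 at r = 0, 0 at r = c, zero beyond
levitt_bracket <- function(r, c) {
  u <- (r / c)^2
  b <- 1 - 0.5 * (7 * u - 9 * u^2 + 5 * u^3 - u^4)
  ifelse(r > c, 0, b)
}

#' Observed (O) hydrophobicity profile
#'
#' The observed per-residue hydrophobicity collects pairwise hydrophobic
#' interactions: every pair of residues within the cutoff contributes the
#' sum of their intrinsic hydrophobicities attenuated by Levitt's
#' polynomial of the inter-residue distance (1 at contact, 0 at the
#' cutoff). The raw sums are normalized to a unit-sum distribution.
#'
#' @param unit a \code{structural_unit} (hydrophobicities assigned from
#'   \code{scale} if not already present).
#' @param scale a \code{\link{hydro_scale}}.
#' @param cutoff_c interaction cutoff, Angstrom.
#' @param include_self whether the \eqn{j = i} term (distance 0,
#'   contribution \eqn{2 H_i}) enters the sum; default \code{TRUE}.
#' @return numeric vector of length \code{N}, summing to 1.
#' @export
observed_profile <- function(unit, scale = hydro_scale(), cutoff_c = 9.0,
                             include_self = TRUE) {
  if (cutoff_c <= 0) stop("cutoff_c must be positive")
  unit <- assign_hydrophobicity(unit, scale)
  h <- unit$residues$hydro
  xyz <- unit_coords(unit)
  d <- as.matrix(stats::dist(xyz))
  w <- levitt_bracket(d, cutoff_c)
  if (!include_self) diag(w) <- 0
  # sum_j (H_i + H_j) w_ij = H_i * rowsum(w) + w %*% H
  raw <- unname(h * rowSums(w)) + as.numeric(w %*% h)
  s <- sum(raw)
  if (s <= 0) stop("degenerate observed distribution: all pairwise ",
                   "hydrophobicity contributions are zero")
  raw / s
}

#' Aligned hydrophobicity profiles of a unit
#'
#' Bundles the four per-residue distributions over a unit: theoretical
#' \code{T}, observed \code{O}, uniform reference \code{R} (\eqn{1/N}) and,
#' once an environment parameter has been fitted, the modified field
#' \code{M} with its \code{K}.
#'
#' @param unit a \code{structural_unit}.
#' @param T,O numeric probability vectors over the unit's residues.
#' @param M optional modified field; \code{K} its parameter.
#' @param K see \code{M}.
#' @return object of class \code{hydro_profile}.
#' @export
hydro_profile <- function(unit, T, O, M = NULL, K = NULL) {
  n <- length(unit)
  for (v in list(T = T, O = O)) stopifnot(length(v) == n)
  check_simplex(T, "T"); check_simplex(O, "O")
  if (any(T <= 0)) stop("T entries must be strictly positive")
  if (!is.null(M)) check_simplex(M, "M")
  structure(list(unit = unit, T = as.numeric(T), O = as.numeric(O),
                 R = rep(1 / n, n), M = M, K = K),
            class = "hydro_profile")
}

check_simplex <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0))
    stop(what, " must be a nonnegative finite vector")
  if (abs(sum(p) - 1) > 1e-9)
    stop(what, " must sum to 1 (got ", format(sum(p)), ")")
  invisible(p)
}

#' @export
print.hydro_profile <- function(x, ...) {
  cat(sprintf("Hydrophobicity profiles over %d residues (T/O/R%s)\n",
              length(x$T), if (!is.null(x$M)) sprintf("/M, K = %.1f", x$K)
                           else ""))
  invisible(x)
}

#' Per-residue profile table
#'
#' @param profile a \code{hydro_profile}.
#' @return data frame with columns chain, seq_id, aa, T, O, M (NA when no
#'   modified field was fitted) and O_minus_T.
#' @export
profile_table <- function(profile) {
  stopifnot(inherits(profile, "hydro_profile"))
  r <- profile$unit$residues
  data.frame(chain = r$chain_id, seq_id = r$seq_id, aa = r$aa,
             T = profile$T, O = profile$O,
             M = if (is.null(profile$M)) NA_real_ else profile$M,
             O_minus_T = profile$O - profile$T,
             stringsAsFactors = FALSE)
}
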