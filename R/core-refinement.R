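#' Stepwise residue elimination toward a micelle-like core
#'
#' When a unit's RD exceeds the 0.5 threshold, the residues responsible for
#' the discordance can be identified by stepwise elimination: repeatedly
#' drop the residue with the largest absolute observed-minus-theoretical
#' discrepancy, recompute both profiles on the kept set (the distributions
#' are renormalized; by default the Gaussian envelope is refitted, since
#' removal changes the shape), and stop once RD falls below the target.
#' Alternatively a caller-named segment is removed in one step.
#'
#' @param unit a \code{structural_unit}.
#' @param settings a \code{\link{fod_settings}}.
#' @param mode \code{"greedy_residue"} (one residue per step, largest
#'   \eqn{|O_i - T_i|}) or \code{"named_segment"} (remove \code{segment}
#'   at once).
#' @param target_rd stop once RD drops below this (default 0.5, the
#'   core-presence threshold).
#' @param max_fraction greedy mode never removes more than this fraction of
#'   the unit (guards against degenerate runs).
#' @param segment for \code{named_segment}: with \code{segment_type =
#'   "range"} (default) a length-2 inclusive range of author residue
#'   numbers; with \code{"index"} an integer vector of residue positions in
#'   the unit.
#' @param segment_type how to interpret \code{segment}.
#' @param refit_envelope refit sigma after each removal (default) or freeze
#'   the envelope fitted to the full unit.
#' @return list of class \code{elimination_trace}: \code{steps} (data frame:
#'   chain, seq_id, aa, discrepancy, rd_after, k_after), \code{initial}
#'   and \code{final} \code{fod_result}s, \code{kept}/\code{removed}
#'   residue tables, \code{terminated_reason} in
#'   \{\code{reached_target}, \code{max_fraction}, \code{exhausted}\}.
#' @examples
#' u <- generate_unit(synthetic_spec("inverted", n_residues = 40, seed = 2))
#' tr <- eliminate_residues(u, max_fraction = 0.2)
#' tr$terminated_reason
#' @export
eliminate_residues <- function(unit, settings = fod_settings(),
                               mode = c("greedy_residue", "named_segment"),
                               target_rd = 0.5, max_fraction = 0.25,
                               segment = NULL,
                               segment_type = c("range", "index"),
                               refit_envelope = TRUE) {
  mode <- match.arg(mode)
  segment_type <- match.arg(segment_type)
  initial <- analyze_unit(unit, settings)
  n0 <- length(unit)
  steps <- data.frame(chain = character(), seq_id = integer(),
                      aa = character(), discrepancy = numeric(),
                      rd_after = numeric(), k_after = numeric(),
                      stringsAsFactors = FALSE)
  frozen_env <- if (refit_envelope) NULL else initial$envelope
  reanalyze <- function(u) {
    if (is.null(frozen_env)) return(analyze_unit(u, settings))
    Tv <- theoretical_profile(u, frozen_env)
    Tv <- Tv / sum(Tv)
    Ov <- observed_profile(u, settings$scale, settings$cutoff_c,
                           settings$include_self)
    rd <- rd_statistic(Ov, Tv)
    scan <- fit_k(Ov, Tv, settings$k_min, settings$k_max, settings$k_step)
    structure(list(rd = rd$rd, k = scan$k, dkl_OT = rd$dkl_OT,
                   dkl_OR = rd$dkl_OR, dkl_OM = scan$dkl_OM,
                   profile = hydro_profile(u, Tv, Ov,
                                           M = m_profile(Tv, scan$k),
                                           K = scan$k),
                   envelope = frozen_env, k_scan = scan,
                   settings = settings_snapshot(settings),
                   provenance = u$provenance, level = u$level),
              class = "fod_result")
  }

  if (mode == "named_segment") {
    keep <- !segment_mask(unit, segment, segment_type)
    if (all(keep)) {          # empty segment: identity
      return(structure(list(steps = steps, initial = initial,
                            final = initial, kept = unit$residues,
                            removed = unit$residues[0, ],
                            terminated_reason = "reached_target"),
                       class = "elimination_trace"))
    }
    cur <- subset_unit(unit, keep)
    res <- reanalyze(cur)
    drop <- unit$residues[!keep, , drop = FALSE]
    disc <- abs(initial$profile$O - initial$profile$T)[!keep]
    steps <- data.frame(chain = drop$chain_id, seq_id = drop$seq_id,
                        aa = drop$aa, discrepancy = disc,
                        rd_after = res$rd, k_after = res$k,
                        stringsAsFactors = FALSE)
    reason <- if (res$rd < target_rd) "reached_target" else "exhausted"
    return(structure(list(steps = steps, initial = initial, final = res,
                          kept = cur$residues, removed = drop,
                          terminated_reason = reason),
                     class = "elimination_trace"))
  }

  cur <- unit
  res <- initial
  reason <- "reached_target"
  max_remove <- floor(max_fraction * n0)
  while (res$rd >= target_rd) {
    if (nrow(steps) >= max_remove) { reason <- "max_fraction"; break }
    if (length(cur) <= 3) { reason <- "exhausted"; break }
    disc <- abs(res$profile$O - res$profile$T)
    worst <- which.max(disc)
    rec <- cur$residues[worst, ]
    cur <- subset_unit(cur, -worst)
    res <- reanalyze(cur)
    steps <- rbind(steps, data.frame(
      chain = rec$chain_id, seq_id = rec$seq_id, aa = rec$aa,
      discrepancy = disc[worst], rd_after = res$rd, k_after = res$k,
      stringsAsFactors = FALSE))
  }
  removed_key <- paste(steps$chain, steps$seq_id)
  all_key <- paste(unit$residues$chain_id, unit$residues$seq_id)
  structure(list(steps = steps, initial = initial, final = res,
                 kept = cur$residues,
                 removed = unit$residues[all_key %in% removed_key, ,
                                         drop = FALSE],
                 terminated_reason = reason),
            class = "elimination_trace")
}

segment_mask <- function(unit, segment, segment_type) {
  if (is.null(segment) || length(segment) == 0)
    return(rep(FALSE, length(unit)))
  if (segment_type == "range") {
    if (length(segment) != 2 || segment[1] > segment[2])
      stop("segment range must be c(start, end) with start <= end")
    return(unit$residues$seq_id >= segment[1] &
           unit$residues$seq_id <= segment[2])
  }
  if (any(segment < 1 | segment > length(unit)))
    stop("segment indices out of range")
  mask <- rep(FALSE, length(unit))
  mask[as.integer(segment)] <- TRUE
  mask
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf(
    "Elimination: RD %.3f -> %.3f after removing %d residue(s) (%s)\n",
    x$initial$rd, x$final$rd, nrow(x$steps), x$terminated_reason))
  if (nrow(x$steps)) print(utils::head(x$steps, 10))
  invisible(x)
}

#' Rank residues by observed-vs-theoretical discordance
#'
#' Residues maladjusted to the micelle-like status: \code{"excess"} ranks
#' by the most positive \eqn{O_i - T_i} (local hydrophobicity excess, e.g.
#' hydrophobic residues exposed on the surface), \code{"deficit"} by the
#' most negative (polar residues where the core expects hydrophobicity).
#'
#' @param profile a \code{hydro_profile}.
#' @param direction \code{"excess"} or \code{"deficit"}.
#' @param top_n how many residues to return; more than N returns all.
#' @return data frame: chain, seq_id, aa, T, O, delta (= O - T), rank.
#' @export
discordant_residues <- function(profile, direction = c("excess", "deficit"),
                                top_n = 10) {
  direction <- match.arg(direction)
  stopifnot(inherits(profile, "hydro_profile"))
  r <- profile$unit$residues
  delta <- profile$O - profile$T
  ord <- order(if (direction == "excess") -delta else delta,
               seq_along(delta))
  out <- data.frame(chain = r$chain_id, seq_id = r$seq_id, aa = r$aa,
                    T = profile$T, O = profile$O, delta = delta,
                    stringsAsFactors = FALSE)[ord, ]
  out$rank <- seq_len(nrow(out))
  utils::head(out, min(top_n, nrow(out)))
}
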