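#' Analyze one structural unit of a structure file and write reports
#'
#' End-to-end single-unit run: read the structure, reduce to effective
#' atoms, select the unit, analyze it, and (optionally) write the
#' per-residue profile table, a one-row summary, a JSON sidecar with the
#' settings snapshot and K-scan curve, and a profile plot.
#'
#' @param structure path to a PDB/mmCIF file.
#' @param chains chain ids forming the unit, in order.
#' @param range inclusive author-numbering range, or \code{NULL}.
#' @param level structural-unit level, see \code{\link{select_unit}}.
#' @param settings a \code{\link{fod_settings}}.
#' @param model model index.
#' @param format file format, see \code{\link{read_structure}}.
#' @param out_prefix if non-\code{NULL}, files
#'   \code{<prefix>_profile.tsv}, \code{<prefix>_summary.tsv},
#'   \code{<prefix>_scan.json} (and \code{<prefix>_profile.png} when
#'   \code{plot}) are written.
#' @param plot also write the T/O/M profile plot.
#' @return the \code{fod_result}, invisibly; attribute \code{"files"}
#'   lists anything written.
#' @export
run_single <- function(structure, chains, range = NULL, level = "chain",
                       settings = fod_settings(), model = 1,
                       format = "auto", out_prefix = NULL, plot = FALSE) {
  st <- read_structure(structure, format = format)
  rec <- effective_atoms(st, model = model)
  unit <- select_unit(rec, chains = chains, range = range, level = level,
                      id = st$id, model = model)
  res <- analyze_unit(unit, settings)
  files <- character()
  if (!is.null(out_prefix)) {
    pf <- paste0(out_prefix, "_profile.tsv")
    write_profile(res$profile, pf)
    sf <- paste0(out_prefix, "_summary.tsv")
    write_report(report_row(res), sf)
    jf <- paste0(out_prefix, "_scan.json")
    jsonlite::write_json(
      list(settings = res$settings,
           k_grid = res$k_scan$grid, dkl_at_k = res$k_scan$dkl_at_k,
           rd = res$rd, k = res$k),
      jf, auto_unbox = TRUE, digits = NA)
    files <- c(pf, sf, jf)
    if (plot) {
      gf <- paste0(out_prefix, "_profile.png")
      grDevices::png(gf, width = 1200, height = 500, res = 120)
      plot_profile(res)
      grDevices::dev.off()
      files <- c(files, gf)
    }
  }
  attr(res, "files") <- files
  invisible(res)
}

#' Write / read a per-residue profile table
#'
#' Tab-separated, columns chain, seq_id, aa, T, O, M, O_minus_T; full
#' precision. Re-reading reproduces the residue sequence.
#'
#' @param profile a \code{hydro_profile}.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile_table(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(chain = "character", aa = "character"),
                    stringsAsFactors = FALSE)
}

#' One summary row for a FOD result
#'
#' @param result a \code{fod_result}.
#' @return data frame with structure id, chains, fragment, level, N, RD, K,
#'   the three divergences (bits) and a settings tag.
#' @export
report_row <- function(result) {
  p <- result$provenance
  s <- result$settings
  data.frame(
    structure = if (!is.null(p$id)) p$id else NA_character_,
    chains = if (!is.null(p$chains)) paste(p$chains, collapse = ",")
             else paste(unique(result$profile$unit$residues$chain_id),
                        collapse = ","),
    fragment = if (!is.null(p$range)) paste(p$range, collapse = "-")
               else NA_character_,
    level = result$level, n = length(result$profile$T),
    RD = result$rd, K = result$k,
    dkl_OT = result$dkl_OT, dkl_OR = result$dkl_OR, dkl_OM = result$dkl_OM,
    settings = settings_tag(s),
    stringsAsFactors = FALSE)
}

settings_tag <- function(s) {
  paste(s$scale, s$cutoff_c, s$sigma_rule,
        if (s$include_self) "self" else "noself",
        paste(s$k_grid, collapse = ":"), sep = "|")
}

#' Write / read a summary report
#'
#' Full precision is kept in the file; \code{format_report} renders the
#' conventional display precision (RD to 3 decimals, K to 1).
#'
#' @param report data frame of \code{\link{report_row}}s.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(structure = "character",
                                   chains = "character",
                                   fragment = "character",
                                   level = "character",
                                   settings = "character"),
                    stringsAsFactors = FALSE)
}

#' @rdname write_report
#' @export
format_report <- function(report) {
  out <- report
  out$RD <- sprintf("%.3f", report$RD)
  out$K <- sprintf("%.1f", report$K)
  out
}

#' Read a unit catalog
#'
#' Tab-separated batch catalog mirroring the columns of a structure list:
#' \code{structure} (accession or file path), \code{chains} (chain ids,
#' \code{,} within a proto-fibril group, \code{+} between groups),
#' \code{fragment} (\code{start-end} or empty for the full chain) and
#' \code{levels} (comma list of unit levels to compute). Lines starting
#' with \code{#} are comments.
#'
#' @param path catalog file.
#' @return data frame of class \code{unit_catalog}.
#' @export
read_catalog <- function(path) {
  cat <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("structure", "chains", "fragment", "levels")
  if (!all(need %in% names(cat)))
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  if (nrow(cat) == 0) stop("empty catalog: ", path)
  class(cat) <- c("unit_catalog", class(cat))
  cat
}

parse_fragment <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- as.integer(strsplit(s, "-")[[1]])
  if (length(parts) != 2 || anyNA(parts))
    stop("bad fragment specification: ", s)
  parts
}

parse_chain_groups <- function(s)
  lapply(strsplit(s, "+", fixed = TRUE)[[1]],
         function(g) strsplit(g, ",", fixed = TRUE)[[1]])

#' Batch analysis over a catalog
#'
#' Computes one summary row per catalog row and requested level (chain:
#' first chain of the first group; proto-fibril: each group's chains as one
#' unit, first group reported; super-fibril: all groups). Failures are
#' collected per row and do not stop the run. Rows are ordered by
#' ascending single-chain RD (ties by structure id), the conventional
#' ordering of such summary tables.
#'
#' @param catalog a \code{unit_catalog} (or path to one).
#' @param settings a \code{\link{fod_settings}}.
#' @param resolve function mapping the catalog \code{structure} field to a
#'   local file path; the default accepts existing paths and otherwise
#'   fetches by accession via \code{\link{fetch_structure}}.
#' @param model model index used for every structure.
#' @return list: \code{report} (data frame), \code{failures} (named
#'   character vector of error messages).
#' @export
run_batch <- function(catalog, settings = fod_settings(),
                      resolve = default_resolver, model = 1) {
  if (is.character(catalog)) catalog <- read_catalog(catalog)
  rows <- list(); fails <- character()
  for (i in seq_len(nrow(catalog))) {
    entry <- catalog[i, ]
    res <- tryCatch({
      path <- resolve(entry$structure)
      st <- read_structure(path)
      rec <- effective_atoms(st, model = model)
      rng <- parse_fragment(entry$fragment)
      groups <- parse_chain_groups(entry$chains)
      levels <- strsplit(entry$levels, ",", fixed = TRUE)[[1]]
      out <- list()
      for (lv in trimws(levels)) {
        chains <- switch(lv,
          chain = groups[[1]][1],
          `proto-fibril` = groups[[1]],
          `super-fibril` = unlist(groups),
          stop("unknown level in catalog: ", lv))
        unit <- select_unit(rec, chains = chains, range = rng, level = lv,
                            id = st$id, model = model)
        out[[lv]] <- report_row(analyze_unit(unit, settings))
      }
      do.call(rbind, out)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[entry$structure] <- conditionMessage(res)
    } else rows[[length(rows) + 1]] <- res
  }
  report <- do.call(rbind, rows)
  if (!is.null(report)) {
    # order structures by their single-chain RD, ties lexicographic
    chain_rd <- tapply(ifelse(report$level == "chain", report$RD, Inf),
                       report$structure, min)
    key <- chain_rd[report$structure]
    report <- report[order(key, report$structure,
                           match(report$level,
                                 c("chain", "proto-fibril",
                                   "super-fibril"))), ]
    rownames(report) <- NULL
  }
  list(report = report, failures = fails)
}

#' @keywords internal
default_resolver <- function(structure) {
  if (file.exists(structure)) structure else fetch_structure(structure)
}

#' Plot T/O/M profiles along the sequence
#'
#' Per-residue theoretical (T), observed (O) and, when fitted, modified (M)
#' distributions against residue index, the standard way of displaying
#' hydrophobicity (mis)match along a chain.
#'
#' @param x a \code{fod_result} or \code{hydro_profile}.
#' @param main plot title.
#' @export
plot_profile <- function(x, main = NULL) {
  prof <- if (inherits(x, "fod_result")) x$profile else x
  stopifnot(inherits(prof, "hydro_profile"))
  n <- length(prof$T)
  if (is.null(main))
    main <- if (inherits(x, "fod_result"))
      sprintf("%s  RD = %.3f, K = %.1f",
              if (!is.null(x$provenance$id)) x$provenance$id else "",
              x$rd, x$k) else "hydrophobicity profiles"
  ylim <- range(0, prof$T, prof$O, prof$M)
  graphics::plot(seq_len(n), prof$T, type = "l", col = "blue", lwd = 2,
                 xlab = "residue index", ylab = "normalized hydrophobicity",
                 ylim = ylim, main = main)
  graphics::lines(seq_len(n), prof$O, col = "red", lwd = 2)
  if (!is.null(prof$M))
    graphics::lines(seq_len(n), prof$M, col = "darkgreen", lty = 2)
  graphics::legend("topright", bty = "n",
                   legend = c("T (theoretical)", "O (observed)",
                              if (!is.null(prof$M))
                                sprintf("M (K = %.1f)", prof$K)),
                   col = c("blue", "red",
                           if (!is.null(prof$M)) "darkgreen"),
                   lty = c(1, 1, if (!is.null(prof$M)) 2), lwd = 2)
  invisible(x)
}
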