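#' Read a protein structure from a PDB or mmCIF file
#'
#' Thin wrapper around \pkg{bio3d}'s parsers that presents a uniform atom
#' table for downstream effective-atom reduction. All models, chains and
#' residues are retained; hydrogens are kept but flagged so that the
#' effective-atom step can exclude them.
#'
#' @param path path to a structure file.
#' @param format \code{"pdb"}, \code{"mmcif"} or \code{"auto"} (sniff from
#'   the file: an mmCIF file starts with \code{data_}/\code{loop_} records,
#'   a PDB file with fixed-column \code{ATOM}/\code{HETATM}/header records).
#' @return An object of class \code{fod_structure}: a list with
#'   \code{atoms} (data frame: chain, resno, ins, resid, elety, alt, occ,
#'   hydrogen flag), \code{xyz} (n_models x 3n coordinate matrix),
#'   \code{n_models}, \code{id} and \code{format}.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") format <- sniff_format(path)
  parsed <- tryCatch(
    switch(format,
      pdb   = bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                              verbose = FALSE),
      mmcif = suppressWarnings(bio3d::read.cif(path, multi = TRUE,
                                               rm.alt = FALSE,
                                               verbose = FALSE))),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: ", path)
  xyz <- parsed$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  elem <- at$elesy
  if (is.null(elem)) elem <- NA_character_
  elem <- ifelse(is.na(elem) | elem == "", guess_element(at$elety), elem)
  atoms <- data.frame(
    type  = at$type,
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    ins   = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    alt   = ifelse(is.na(at$alt), "", as.character(at$alt)),
    occ   = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    elem  = toupper(trimws(elem)),
    stringsAsFactors = FALSE)
  atoms$hydrogen <- atoms$elem %in% c("H", "D")
  structure(list(atoms = atoms, xyz = xyz, n_models = nrow(xyz),
                 id = sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "",
                          basename(path), ignore.case = TRUE),
                 format = format, path = path),
            class = "fod_structure")
}

sniff_format <- function(path) {
  head <- readLines(path, n = 50, warn = FALSE)
  head <- head[nzchar(trimws(head))]
  if (length(head) == 0) stop("empty structure file: ", path)
  if (any(grepl("^(data_|loop_|_atom_site\\.)", head))) return("mmcif")
  if (any(grepl("^(ATOM  |HETATM|HEADER|MODEL |REMARK|CRYST1|TITLE )", head)))
    return("pdb")
  stop("cannot identify format of ", path,
       ": first records match neither mmCIF (data_/loop_) nor PDB (ATOM ...)")
}

guess_element <- function(elety) {
  # strip leading digits (e.g. 1HB1), take leading letters; two-letter metals
  # do not occur among standard amino-acid atoms, so first letter suffices
  substr(gsub("^[0-9]+", "", trimws(elety)), 1, 1)
}

#' @export
print.fod_structure <- function(x, ...) {
  cat(sprintf("Structure %s (%s): %d model(s), chains %s, %d atoms\n",
              x$id, x$format, x$n_models,
              paste(unique(x$atoms$chain), collapse = ","), nrow(x$atoms)))
  invisible(x)
}

#' Reduce a structure to effective atoms
#'
#' Every standard amino acid is represented by a single point, the
#' unweighted arithmetic mean of its heavy-atom coordinates. For residues
#' with alternate locations only the highest-occupancy alternate (tie:
#' first label alphabetically) contributes, together with the shared
#' un-labelled atoms.
#'
#' @param structure a \code{fod_structure} from \code{\link{read_structure}}.
#' @param model model index (1-based); relevant for multi-model (NMR-style)
#'   depositions.
#' @return data frame of residue records: \code{chain_id}, \code{seq_id},
#'   \code{ins}, \code{aa} (one-letter), \code{x}, \code{y}, \code{z}.
#' @export
effective_atoms <- function(structure, model = 1) {
  stopifnot(inherits(structure, "fod_structure"))
  if (model < 1 || model > structure$n_models)
    stop("model ", model, " not present (structure has ",
         structure$n_models, ")")
  at <- structure$atoms
  xyz <- matrix(structure$xyz[model, ], ncol = 3, byrow = TRUE)
  keep <- at$resid %in% names(AA_THREE_TO_ONE) & !at$hydrogen &
    at$type %in% c("ATOM", "HETATM")
  if (!any(keep)) stop("no standard amino-acid residues in model ", model)
  at <- at[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]

  rkey <- paste(at$chain, at$resno, at$ins, at$resid, sep = "\r")
  # preserve file order of residues
  rkey <- factor(rkey, levels = unique(rkey))
  pick <- unlist(lapply(split(seq_len(nrow(at)), rkey), function(idx) {
    alt <- at$alt[idx]
    labs <- setdiff(unique(alt), "")
    if (length(labs) == 0) return(idx)
    occ <- vapply(labs, function(l) sum(at$occ[idx][alt == l]), numeric(1))
    best <- sort(labs[occ == max(occ)])[1]
    idx[alt %in% c("", best)]
  }), use.names = FALSE)
  at <- at[pick, , drop = FALSE]
  xyz <- xyz[pick, , drop = FALSE]
  rkey <- droplevels(rkey[pick])

  ok <- rowSums(is.finite(xyz)) == 3
  if (!all(ok)) {
    warning(sum(!ok), " atoms with non-finite coordinates dropped")
    at <- at[ok, , drop = FALSE]; xyz <- xyz[ok, , drop = FALSE]
    rkey <- droplevels(rkey[ok])
  }
  first <- !duplicated(rkey)
  out <- data.frame(
    chain_id = at$chain[first],
    seq_id   = at$resno[first],
    ins      = at$ins[first],
    aa       = unname(AA_THREE_TO_ONE[at$resid[first]]),
    x = as.numeric(tapply(xyz[, 1], rkey, mean)),
    y = as.numeric(tapply(xyz[, 2], rkey, mean)),
    z = as.numeric(tapply(xyz[, 3], rkey, mean)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble a structural unit from residue records
#'
#' Selects the residues of the named chains (in the given order) whose
#' author numbering falls in \code{range}, and tags the result with the
#' structural-unit level: a single \code{"chain"}, a \code{"proto-fibril"}
#' (one stack of chains) or a \code{"super-fibril"} (all stacks).
#'
#' @param records residue records from \code{\link{effective_atoms}}.
#' @param chains character vector of chain ids, concatenated in this order.
#' @param range length-2 integer vector, inclusive author-numbering residue
#'   range; \code{NULL} keeps the full chains.
#' @param level \code{"chain"}, \code{"proto-fibril"} or
#'   \code{"super-fibril"}.
#' @param id optional structure identifier recorded in the provenance.
#' @param model model index recorded in the provenance.
#' @return a \code{structural_unit}.
#' @export
select_unit <- function(records, chains, range = NULL,
                        level = c("chain", "proto-fibril", "super-fibril"),
                        id = NULL, model = 1) {
  level <- match.arg(level)
  if (!is.null(range)) {
    if (length(range) != 2 || range[1] > range[2])
      stop("range must be c(start, end) with start <= end, got: ",
           paste(range, collapse = "-"))
  }
  avail <- unique(records$chain_id)
  missing <- setdiff(chains, avail)
  if (length(missing))
    stop("chain(s) not in structure: ", paste(missing, collapse = ","),
         "; available: ", paste(avail, collapse = ","))
  parts <- lapply(chains, function(ch) {
    r <- records[records$chain_id == ch, , drop = FALSE]
    if (!is.null(range))
      r <- r[r$seq_id >= range[1] & r$seq_id <= range[2], , drop = FALSE]
    # insertion codes sort after their base number within original order
    r[order(r$seq_id, r$ins, seq_len(nrow(r))), , drop = FALSE]
  })
  res <- do.call(rbind, parts)
  if (is.null(res) || nrow(res) == 0) {
    rngs <- vapply(chains, function(ch) {
      s <- records$seq_id[records$chain_id == ch]
      paste0(ch, ":", min(s), "-", max(s))
    }, character(1))
    stop("empty selection; available ranges: ", paste(rngs, collapse = " "))
  }
  new_structural_unit(res, level = level,
                      provenance = list(id = id, model = model,
                                        chains = chains, range = range))
}

#' Fetch a structure from the wwPDB by accession
#'
#' Downloads \code{<id>.pdb} (falling back to \code{<id>.cif}) from the
#' RCSB file server into a local cache directory, and returns the cached
#' path. All computation accepts local files, so this helper is only a
#' convenience; it fails with a clear message when offline.
#'
#' @param id 4-character PDB accession.
#' @param dir cache directory.
#' @param timeout download timeout in seconds.
#' @return path to the cached file.
#' @export
fetch_structure <- function(id, dir = file.path(tempdir(), "fodm-pdb"),
                            timeout = 60) {
  id <- tolower(id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ext in c("pdb", "cif")) {
    dest <- file.path(dir, paste0(id, ".", ext))
    if (file.exists(dest) && file.size(dest) > 0) return(dest)
  }
  old <- options(timeout = timeout); on.exit(options(old))
  for (ext in c("pdb", "cif")) {
    dest <- file.path(dir, paste0(id, ".", ext))
    url <- sprintf("https://files.rcsb.org/download/%s.%s", id, ext)
    ok <- tryCatch({
      utils::download.file(url, dest, quiet = TRUE, mode = "wb")
      file.exists(dest) && file.size(dest) > 0
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (ok) return(dest)
    unlink(dest)
  }
  stop("could not fetch ", id, " from the wwPDB (offline?); ",
       "place ", id, ".pdb or ", id, ".cif in ", dir, " manually")
}

#' Write a unit as a minimal PDB file
#'
#' One pseudo-atom (CA) per residue at the effective-atom position, so that
#' synthetic units can be fed back through the file-reading path.
#'
#' @param unit a \code{structural_unit}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_unit_pdb <- function(unit, path) {
  stopifnot(inherits(unit, "structural_unit"))
  r <- unit$residues
  three <- names(AA_THREE_TO_ONE)[match(r$aa, AA_THREE_TO_ONE)]
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(r)), three, substr(r$chain_id, 1, 1), r$seq_id,
    r$x, r$y, r$z, 1.0, 0.0)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
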