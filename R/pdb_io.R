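# Multi-model PDB ingestion and export (one MODEL record per ensemble member).

#' Read a multi-model PDB file as an ensemble
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records is read as a single-frame ensemble.  Atom counts must agree across
#' models.  Alternate locations: the first altloc is kept; insertion codes
#' are rejected (simulated ensembles never carry them, so their presence
#' signals corrupt input).  Residue numbering is taken verbatim from the file.
#'
#' @param path Path to a PDB file.
#' @param mode Atom selection applied on read: `"all"` (default), `"CA"`,
#'   `"backbone"` or `"heavy"`.
#' @param residues Optional inclusive residue-number range `c(first, last)`.
#' @param label Label stored on the ensemble (default: file name).
#' @return An `ensemble` with uniform frame weights.
#' @export
read_multimodel_pdb <- function(path, mode = "all", residues = NULL,
                                label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_model_atom_counts(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type %in% c("ATOM", "HETATM")
  if (any(nzchar(trimws(at$insert[keep])) & !is.na(at$insert[keep])))
    stop("insertion codes present in ", path,
         "; refusing to guess author numbering")
  # first altloc kept: drop any altloc letter beyond "A"
  alt <- at$alt
  alt[is.na(alt)] <- ""
  keep <- keep & alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  aidx <- which(keep)
  resno_u <- unique(at$resno)
  res_index <- match(at$resno, resno_u)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem))))
    elem <- guess_element(at$elety)
  else elem <- trimws(elem)
  top <- structure(list(
    chain_id = if (all(is.na(at$chain))) "A" else at$chain[1],
    resno = as.integer(resno_u),
    resid = at$resid[match(resno_u, at$resno)],
    atoms = data.frame(elety = at$elety, res_index = res_index,
                       element = elem, stringsAsFactors = FALSE)),
    class = "topology")
  validate_topology(top)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  cols <- as.vector(rbind(3L * aidx - 2L, 3L * aidx - 1L, 3L * aidx))
  ens <- ensemble(top, xyz[, cols, drop = FALSE], label = label)
  if (mode != "all" || !is.null(residues))
    ens <- select_atoms(ens, mode = mode, residues = residues)
  ens
}

# element symbol from an atom name: strip digits, hydrogen variants start H/D
guess_element <- function(elety) {
  core <- sub("^[0-9']*", "", trimws(elety))
  ifelse(substr(core, 1, 1) %in% c("H", "D"), "H", substr(core, 1, 1))
}

# cheap pre-scan so inconsistent MODELs fail with the offending model named
check_model_atom_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) < 2L) return(invisible(NULL))
  model_ends <- which(trimws(rec) == "ENDMDL")
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  counts <- mapply(function(s, e)
    sum(rec[s:e] %in% c("ATOM  ", "HETATM")), model_starts, model_ends)
  if (length(unique(counts)) > 1L) {
    model_no <- trimws(substr(lines[model_starts], 7, 80))
    bad <- which(counts != counts[1])[1]
    stop("inconsistent atom count across models in ", path, ": MODEL ",
         model_no[bad], " has ", counts[bad], " atoms, MODEL ",
         model_no[1], " has ", counts[1])
  }
  invisible(NULL)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Emits one `MODEL`/`ENDMDL` pair per frame with fixed-width coordinate
#' fields (three decimals, the PDB standard), so a write/read round trip
#' preserves residue identity and numbering exactly and coordinates to
#' 1e-3 Angstrom.
#'
#' @param ens An `ensemble` with at least one frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_multimodel_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  if (n_frames(ens) < 1L) stop("refusing to write an empty ensemble")
  if (!dir.exists(dirname(path)))
    stop("cannot write to ", path, ": no such directory")
  top <- ens$topology
  bio3d::write.pdb(
    file = path,
    xyz = ens$xyz,
    resno = top$resno[top$atoms$res_index],
    resid = top$resid[top$atoms$res_index],
    elety = top$atoms$elety,
    chain = rep(top$chain_id, nrow(top$atoms)))
  if (n_frames(ens) == 1L) {
    # bio3d omits MODEL records for single structures; add the pair so
    # every ensemble file is uniformly multi-model
    lines <- readLines(path, warn = FALSE)
    first_atom <- which(grepl("^(ATOM|HETATM)", lines))[1]
    last_atom <- max(which(grepl("^(ATOM|HETATM|TER)", lines)))
    lines <- append(lines, "ENDMDL", after = last_atom)
    lines <- append(lines, "MODEL        1", after = first_atom - 1L)
    writeLines(lines, path)
  }
  invisible(path)
}
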