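## PDB reading, preparation (altloc resolution, solvent/ligand stripping)
## and the in-memory structure model.
##
## A `protein_structure` is a light wrapper around an atom table with one
## row per atom: chain, resno (author numbering), insert (insertion code,
## "" if none), resid (three-letter residue name), elety (atom label),
## element, x/y/z (Angstrom), het (logical, TRUE for HETATM records).
## Rows are kept ordered by (chain, resno, insert, file order).

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

new_structure <- function(atoms, id = "structure", source = NA_character_) {
  atoms$chain <- as.character(atoms$chain)
  atoms$insert <- ifelse(is.na(atoms$insert), "", as.character(atoms$insert))
  atoms$resid <- toupper(as.character(atoms$resid))
  atoms$elety <- toupper(trimws(as.character(atoms$elety)))
  ord <- order(atoms$chain, atoms$resno, atoms$insert)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(id = id, source = source, atoms = atoms),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<protein_structure> %s: %d atoms, %d residues, %d chain(s)\n",
              x$id, nrow(x$atoms), nrow(rt), length(unique(rt$chain))))
  invisible(x)
}

## Residue key shared by all per-residue operations.
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
}

#' Per-residue summary table of a structure
#'
#' @param structure a `protein_structure`.
#' @return data frame with one row per residue: chain, resno, insert,
#'   resid, aa (one-letter code or `NA` for non-standard residues),
#'   n_atoms, and key (internal residue identifier).
#' @export
residue_table <- function(structure) {
  atoms <- structure$atoms
  key <- residue_key(atoms)
  first <- !duplicated(key)
  out <- data.frame(
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    insert = atoms$insert[first],
    resid = atoms$resid[first],
    stringsAsFactors = FALSE
  )
  out$aa <- aa_one(out$resid)
  out$n_atoms <- as.integer(table(factor(key, levels = key[first])))
  out$key <- key[first]
  out
}

atom_xyz <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

## --------------------------------------------------------------------------

#' Read a PDB file
#'
#' Parses ATOM and HETATM records (via bio3d), preserves author chain and
#' residue numbering including insertion codes, and resolves alternate
#' locations by keeping, for each atom, the conformer with the highest
#' occupancy (ties broken by altloc label order, so 'A' wins).
#'
#' @param path path to a PDB file.
#' @param id structure label; defaults to the file name without extension.
#' @return a `protein_structure` (waters/ligands still present; see
#'   [strip_non_protein()]).
#' @seealso [strip_non_protein()], [write_pdb()]
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("failed to parse PDB file '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  if (sum(at$type == "ATOM") == 0) {
    stop("no ATOM records in '", path, "': not a protein structure file")
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))

  elem <- at$elesy
  bad <- is.na(elem) | trimws(elem) == ""
  elem[bad] <- element_from_name(at$elety[bad])
  elem <- toupper(trimws(elem))

  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    element = elem,
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM",
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE
  )
  atoms <- resolve_altloc(atoms)
  atoms$occ <- NULL
  atoms$alt <- NULL
  new_structure(atoms, id = id, source = path)
}

## Keep one conformer per (residue, atom name): highest occupancy, ties by
## altloc label order ('' sorts before 'A').
resolve_altloc <- function(atoms) {
  grp <- paste(residue_key(atoms), atoms$resid, atoms$elety, sep = "|")
  if (!anyDuplicated(grp)) return(atoms)
  ord <- order(grp, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(grp[ord]), , drop = FALSE]
  atoms
}

#' Strip non-protein content from a structure
#'
#' Removes waters, ions, ligands, nucleic acids and any residue that cannot
#' be mapped to one of the 20 standard amino acids.  Selenomethionine (MSE)
#' is mapped to MET (the SE atom becomes SD).  Hydrogen and deuterium atoms
#' are removed: all descriptor computation in this package is heavy-atom
#' based.  Idempotent.
#'
#' @param structure a `protein_structure`.
#' @param residue_map named character vector mapping non-standard residue
#'   names to standard ones.
#' @return protein-only `protein_structure`.
#' @export
strip_non_protein <- function(structure, residue_map = c(MSE = "MET")) {
  atoms <- structure$atoms
  ## map non-standard residues onto standard ones
  mapped <- match(atoms$resid, names(residue_map))
  hit <- !is.na(mapped)
  if (any(hit)) {
    se <- hit & atoms$resid == "MSE" & atoms$elety == "SE"
    atoms$elety[se] <- "SD"
    atoms$element[se] <- "S"
    atoms$resid[hit] <- unname(residue_map[mapped[hit]])
    atoms$het[hit] <- FALSE
  }
  keep <- atoms$resid %in% AA3 & !atoms$het & !(atoms$element %in% c("H", "D"))
  atoms <- atoms[keep, , drop = FALSE]
  if (nrow(atoms) == 0) stop("no protein content after stripping ('",
                             structure$id, "')")
  new_structure(atoms, id = structure$id, source = structure$source)
}

#' Write a structure to a PDB file
#'
#' @param structure a `protein_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(atom_xyz(structure))),
    type = ifelse(at$het, "HETATM", "ATOM"),
    resno = at$resno,
    resid = at$resid,
    eleno = seq_len(nrow(at)),
    elety = at$elety,
    chain = at$chain,
    insert = ifelse(at$insert == "", NA, at$insert),
    elesy = at$element
  )
  invisible(path)
}

## --------------------------------------------------------------------------

## Locate a residue by (chain, author position [+ insertion code]).
find_residue <- function(structure, chain, position, insert = "") {
  at <- structure$atoms
  idx <- which(at$chain == chain & at$resno == position & at$insert == insert)
  if (length(idx) == 0) {
    stop(sprintf("residue %s%s%s not found in structure '%s'",
                 chain, position, insert, structure$id))
  }
  idx
}

#' Check a mutant record against the structure
#'
#' Raises an error if the residue at (chain, position) does not match the
#' expected wild-type amino acid, instead of silently computing descriptors
#' for the wrong residue.
#'
#' @param structure a stripped `protein_structure`.
#' @param chain chain identifier.
#' @param position author residue number.
#' @param wt expected one-letter wild-type amino acid.
#' @return invisibly `TRUE`.
#' @export
validate_mutant_residue <- function(structure, chain, position, wt) {
  idx <- find_residue(structure, chain, position)
  found <- aa_one(structure$atoms$resid[idx[1]])
  if (is.na(found) || found != toupper(wt)) {
    stop(sprintf(
      "wild-type mismatch at %s%s of '%s': structure has %s, mutant table says %s",
      chain, position, structure$id,
      ifelse(is.na(found), structure$atoms$resid[idx[1]], found), wt))
  }
  invisible(TRUE)
}
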