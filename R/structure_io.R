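# PDB fixed-column I/O and the coarse-grained C-alpha representation.
#
# No pre-installed R package in this stack parses PDB, so the reader
# implements the minimal ATOM/HETATM/MODEL/ENDMDL subset needed here:
# HETATMs are excluded (CO2 enters the model as springs, never as atoms),
# the first-listed altloc conformer is kept, and (residue number, insertion
# code) is the residue key.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Coarse-grained structure of C-alpha pseudo-atoms
#'
#' A `CGStructure` holds one pseudo-atom per residue: chain identifier,
#' residue number (plus optional insertion code), 3-letter residue name and
#' Cartesian coordinates in Angstrom.  Atoms are stored in deterministic
#' order (chain, then residue number, then insertion code) and the
#' (chain, residue, icode) key is unique.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `x`, `y`, `z` and optionally `icode`.
#' @param source_label free-text provenance label.
#' @param model_index PDB model number the coordinates came from.
#' @return An object of class `CGStructure`.
#' @export
cg_structure <- function(atoms, source_label = "", model_index = 1L) {
  needed <- c("chain", "resno", "resname", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(needed %in% names(atoms))) {
    abort("`atoms` must be a data.frame with columns chain, resno, resname, x, y, z",
          "carbanm_parameter_error")
  }
  if (!"icode" %in% names(atoms)) atoms$icode <- ""
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resname <- as.character(atoms$resname)
  atoms$icode <- as.character(atoms$icode)
  if (nrow(atoms) < 2L) {
    abort("a CGStructure needs at least 2 atoms", "carbanm_empty_error")
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    abort("non-finite coordinates in structure", "carbanm_format_error")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$icode)
  if (anyDuplicated(key)) {
    abort("duplicate (chain, residue) keys in CGStructure", "carbanm_format_error")
  }
  ord <- order(atoms$chain, atoms$resno, atoms$icode)
  atoms <- atoms[ord, c("chain", "resno", "icode", "resname", "x", "y", "z")]
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, source_label = source_label,
         model_index = as.integer(model_index)),
    class = "CGStructure"
  )
}

#' All-atom structure used for side-chain distance measurements
#'
#' Unlike [cg_structure()], atoms are kept in file order and keyed by
#' (chain, residue number, insertion code, atom name).
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `x`, `y`, `z` and optionally `icode`, `altloc`.
#' @inheritParams cg_structure
#' @return An object of class `FullAtomStructure`.
#' @export
full_atom_structure <- function(atoms, source_label = "", model_index = 1L) {
  needed <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(needed %in% names(atoms))) {
    abort("`atoms` must be a data.frame with columns chain, resno, resname, atom, x, y, z",
          "carbanm_parameter_error")
  }
  if (!"icode" %in% names(atoms)) atoms$icode <- ""
  if (!"altloc" %in% names(atoms)) atoms$altloc <- ""
  if (nrow(atoms) == 0L) {
    abort("empty FullAtomStructure", "carbanm_empty_error")
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    abort("non-finite coordinates in structure", "carbanm_format_error")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom)
  if (anyDuplicated(key)) {
    abort("duplicate (chain, residue, atom) keys after altloc filtering",
          "carbanm_format_error")
  }
  atoms <- atoms[, c("chain", "resno", "icode", "resname", "atom", "altloc",
                     "x", "y", "z")]
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, source_label = source_label,
         model_index = as.integer(model_index)),
    class = "FullAtomStructure"
  )
}

#' Coordinate matrix of a structure
#'
#' @param structure a `CGStructure` or `FullAtomStructure`.
#' @return numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Number of atoms in a structure
#' @inheritParams coords
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' @export
print.CGStructure <- function(x, ...) {
  cat(sprintf("CGStructure: %d C-alpha atoms, %d chain(s) [%s], model %d%s\n",
              n_atoms(x), length(unique(x$atoms$chain)),
              paste(unique(x$atoms$chain), collapse = ""),
              x$model_index,
              if (nzchar(x$source_label)) paste0(", source ", x$source_label) else ""))
  invisible(x)
}

#' @export
print.FullAtomStructure <- function(x, ...) {
  cat(sprintf("FullAtomStructure: %d atoms, %d residue(s), %d chain(s), model %d\n",
              n_atoms(x), length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$icode))),
              length(unique(x$atoms$chain)), x$model_index))
  invisible(x)
}

#' Read a PDB file
#'
#' Parses ATOM records of the selected model into a [full_atom_structure()].
#' HETATM records (waters, ligands, ions) are excluded; for alternate
#' location duplicates the first-listed conformer is kept; atoms are retained
#' in file order.
#'
#' @param path path to a PDB file.
#' @param model model number to read (default 1; files without MODEL records
#'   are treated as a single model 1).
#' @param chain_filter optional character vector of chain identifiers to keep.
#' @return A `FullAtomStructure`.
#' @export
read_pdb <- function(path, model = 1L, chain_filter = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("PDB file not found: %s", path), "carbanm_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) abort("empty PDB file", "carbanm_format_error")

  rec <- substr(lines, 1L, 6L)
  model_counter <- cumsum(rec == "MODEL ")
  n_models <- max(model_counter)
  if (n_models == 0L) {
    model_counter <- rep(1L, length(lines))
    n_models <- 1L
  }
  if (model > n_models || model < 1L) {
    abort(sprintf("model %d not present (file has %d model(s))", model, n_models),
          "carbanm_format_error")
  }

  keep <- rec == "ATOM  " & model_counter == model
  al <- lines[keep]
  if (!length(al)) {
    abort("no ATOM records in the requested selection", "carbanm_empty_error")
  }

  atoms <- data.frame(
    chain   = substr(al, 22L, 22L),
    resno   = suppressWarnings(as.integer(substr(al, 23L, 26L))),
    icode   = trimws(substr(al, 27L, 27L)),
    resname = trimws(substr(al, 18L, 20L)),
    atom    = trimws(substr(al, 13L, 16L)),
    altloc  = trimws(substr(al, 17L, 17L)),
    x = suppressWarnings(as.numeric(substr(al, 31L, 38L))),
    y = suppressWarnings(as.numeric(substr(al, 39L, 46L))),
    z = suppressWarnings(as.numeric(substr(al, 47L, 54L))),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$resno) || anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    abort("malformed ATOM record (unparseable residue number or coordinates)",
          "carbanm_format_error")
  }
  if (!is.null(chain_filter)) {
    atoms <- atoms[atoms$chain %in% chain_filter, , drop = FALSE]
  }
  if (!nrow(atoms)) {
    abort("chain filter removed every atom", "carbanm_empty_error")
  }
  # altloc policy: keep the first occurrence of each (chain, res, icode, atom)
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom)), ,
                 drop = FALSE]
  full_atom_structure(atoms, source_label = basename(path), model_index = model)
}

#' Reduce an all-atom structure to its C-alpha trace
#'
#' One node per residue that possesses a CA atom.  Residues lacking a CA
#' (e.g. unresolved side-chain-only records) are skipped; the skipped
#' residues are reported in the `"skipped"` attribute of the result.
#'
#' @param full a `FullAtomStructure`.
#' @return A `CGStructure`; attribute `skipped` is a data.frame of residues
#'   that had no CA atom.
#' @export
to_calpha <- function(full) {
  if (!inherits(full, "FullAtomStructure")) {
    abort("`full` must be a FullAtomStructure", "carbanm_parameter_error")
  }
  a <- full$atoms
  reskey <- paste(a$chain, a$resno, a$icode)
  ca <- a[a$atom == "CA", , drop = FALSE]
  if (!nrow(ca)) abort("structure contains no CA atoms", "carbanm_empty_error")
  have_ca <- unique(paste(ca$chain, ca$resno, ca$icode))
  missing <- unique(reskey[!(reskey %in% have_ca)])
  skipped <- if (length(missing)) {
    idx <- match(missing, reskey)
    data.frame(chain = a$chain[idx], resno = a$resno[idx],
               icode = a$icode[idx], resname = a$resname[idx],
               stringsAsFactors = FALSE)
  } else {
    data.frame(chain = character(), resno = integer(), icode = character(),
               resname = character(), stringsAsFactors = FALSE)
  }
  cg <- cg_structure(ca[, c("chain", "resno", "icode", "resname", "x", "y", "z")],
                     source_label = full$source_label,
                     model_index = full$model_index)
  attr(cg, "skipped") <- skipped
  cg
}

#' Write a structure as PDB ATOM records
#'
#' Coordinates are written at the standard 3-decimal PDB precision; chain
#' identifiers and residue numbering are preserved.  `CGStructure` nodes are
#' written as CA atoms.
#'
#' @param structure a `CGStructure` or `FullAtomStructure`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  if (!inherits(structure, c("CGStructure", "FullAtomStructure"))) {
    abort("`structure` must be a CGStructure or FullAtomStructure",
          "carbanm_parameter_error")
  }
  a <- structure$atoms
  if (is.null(a) || nrow(a) == 0L) {
    abort("refusing to write an empty structure", "carbanm_empty_error")
  }
  atom_name <- if ("atom" %in% names(a)) a$atom else rep("CA", nrow(a))
  # PDB convention: names up to 3 chars start in column 14
  name_fmt <- ifelse(nchar(atom_name) >= 4L, substr(atom_name, 1L, 4L),
                     formatC(paste0(" ", atom_name), width = -4))
  elem <- substr(gsub("[^A-Za-z].*", "", atom_name), 1L, 1L)
  rl <- sprintf("ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                (seq_len(nrow(a)) - 1L) %% 99999L + 1L, name_fmt,
                a$resname, a$chain, a$resno,
                ifelse(nzchar(a$icode), a$icode, " "),
                a$x, a$y, a$z, 1, 0, elem)
  out <- tryCatch(file(path, "wb"), error = function(e) {
    abort(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
          "carbanm_io_error")
  })
  on.exit(close(out))
  # fixed "\n" (binary mode) so outputs are byte-identical across platforms
  writeLines(c(rl, "END"), out, sep = "\n")
  invisible(path)
}
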