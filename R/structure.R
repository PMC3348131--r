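#' Molecular structure objects
#'
#' A `mol_structure` holds the ordered atom records of (by convention) one
#' protein chain as a tibble, plus a `source_id`. It is the substrate of
#' every analysis stage: conformer generation, pocket detection, tracking
#' and Provar annotation all operate on it.
#'
#' @param atoms A tibble with columns `serial`, `atom_name`, `residue_name`,
#'   `chain_id`, `residue_number`, `insertion_code`, `element`, `x`, `y`,
#'   `z`, `occupancy`, `b_factor`.
#' @param source_id Character identifier carried through reports.
#' @return A `mol_structure` object.
#' @export
new_structure <- function(atoms, source_id = "structure") {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  atoms <- tibble::as_tibble(atoms)
  need <- c("serial", "atom_name", "residue_name", "chain_id",
            "residue_number", "insertion_code", "element",
            "x", "y", "z", "occupancy", "b_factor")
  missing <- setdiff(need, names(atoms))
  if (length(missing) > 0) {
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(atoms$serial)) stop("atom serial numbers must be unique")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  structure(list(atoms = atoms[need], source_id = source_id),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  rk <- residue_table(x)
  cat(sprintf("<mol_structure> %s: %d atoms, %d residues, chain(s) %s\n",
              x$source_id, nrow(x$atoms), nrow(rk),
              paste(unique(x$atoms$chain_id), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s A `mol_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Atom coordinates as a matrix
#' @param s A `mol_structure`.
#' @return Numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(s) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace atom coordinates
#' @param s A `mol_structure`.
#' @param xyz Numeric n-by-3 matrix in the structure's atom order.
#' @return The structure with updated coordinates.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == n_atoms(s), ncol(xyz) == 3)
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}

residue_key_of <- function(chain_id, residue_number, insertion_code) {
  ins <- ifelse(is.na(insertion_code), "", insertion_code)
  sprintf("%s:%d%s", chain_id, residue_number, ins)
}

#' Residue table of a structure
#'
#' Residues in order of first atom appearance, with the residue key used
#' throughout the package (`chain:number[insertion]`).
#'
#' @param s A `mol_structure`.
#' @return A tibble with columns `key`, `chain_id`, `residue_number`,
#'   `insertion_code`, `residue_name`.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- residue_key_of(a$chain_id, a$residue_number, a$insertion_code)
  first <- !duplicated(key)
  tibble::tibble(
    key = key[first],
    chain_id = a$chain_id[first],
    residue_number = a$residue_number[first],
    insertion_code = a$insertion_code[first],
    residue_name = a$residue_name[first]
  )
}

#' Per-atom residue keys
#' @param s A `mol_structure`.
#' @return Character vector, one key per atom.
#' @export
atom_residue_keys <- function(s) {
  residue_key_of(s$atoms$chain_id, s$atoms$residue_number,
                 s$atoms$insertion_code)
}

guess_element <- function(elesy, elety) {
  e <- toupper(trimws(elesy))
  bad <- is.na(e) | e == ""
  if (any(bad)) {
    # strip leading digits from the atom name, take the first letter
    nm <- toupper(gsub("^[0-9']+", "", trimws(elety[bad])))
    two <- substr(nm, 1, 2)
    one <- substr(nm, 1, 1)
    e[bad] <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE"),
                     two, one)
  }
  e
}

bio3d_atoms_to_tibble <- function(atom) {
  ins <- atom$insert
  ins[is.na(ins)] <- ""
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  chain <- atom$chain
  chain[is.na(chain)] <- " "
  tibble::tibble(
    record = atom$type,
    serial = as.integer(atom$eleno),
    atom_name = atom$elety,
    alt_loc = alt,
    residue_name = atom$resid,
    chain_id = chain,
    residue_number = as.integer(atom$resno),
    insertion_code = ins,
    element = guess_element(atom$elesy, atom$elety),
    x = atom$x, y = atom$y, z = atom$z,
    occupancy = ifelse(is.na(atom$o), 1, atom$o),
    b_factor = ifelse(is.na(atom$b), 0, atom$b)
  )
}

# Altloc resolution: one atom per (residue, atom name); keep the highest
# occupancy, ties broken by first occurrence in file order.
resolve_altlocs <- function(at) {
  if (all(at$alt_loc == "")) return(at)
  key <- paste(at$chain_id, at$residue_number, at$insertion_code,
               at$residue_name, at$atom_name, sep = "|")
  ord <- order(key, -at$occupancy, seq_len(nrow(at)))
  at2 <- at[ord, ]
  at2 <- at2[!duplicated(key[ord]), ]
  at2[order(match(at2$serial, at$serial)), ]
}

# First chain with >= 50 standard residues; else the first chain holding
# any ATOM record at all.
default_chain <- function(at) {
  chains <- unique(at$chain_id)
  for (ch in chains) {
    sub <- at[at$chain_id == ch & at$residue_name %in% .STANDARD_AA, ]
    if (length(unique(paste(sub$residue_number, sub$insertion_code))) >= 50) {
      return(ch)
    }
  }
  chains[1]
}

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records from PDB text (or a file path), resolves
#' alternate locations to a single atom per name per residue (highest
#' occupancy, first-listed tie-break), and restricts to one chain: the
#' requested one, or by default the first chain with at least 50 standard
#' residues (falling back to the first chain present).
#'
#' @param text PDB-format text (single string or character vector of lines),
#'   or a path to a PDB file.
#' @param chain Optional chain identifier to select.
#' @param source_id Identifier for the returned structure; defaults to the
#'   file name when a path is given.
#' @return A [new_structure()] object holding exactly one chain.
#' @export
parse_pdb <- function(text, chain = NULL, source_id = NULL) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    path <- text
    if (is.null(source_id)) source_id <- basename(path)
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(if (length(text) == 1) strsplit(text, "\n")[[1]] else text, path)
    if (is.null(source_id)) source_id <- "pdb_text"
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("PDB parse error: ", conditionMessage(e))
  )
  at <- bio3d_atoms_to_tibble(pdb$atom)
  if (!any(at$record == "ATOM")) stop("PDB parse error: no ATOM records")
  if (!is.null(chain)) {
    if (!chain %in% at$chain_id) {
      stop("chain not found: '", chain, "'")
    }
  } else {
    chain <- default_chain(at[at$record == "ATOM", ])
  }
  at <- at[at$chain_id == chain, ]
  at <- resolve_altlocs(at)
  at$record <- NULL
  at$alt_loc <- NULL
  new_structure(at, source_id = source_id)
}

#' Remove heteroatoms and hydrogens
#'
#' Keeps only standard amino-acid heavy atoms: ligands, waters and other
#' co-crystallised molecules are deleted, and hydrogens are removed so all
#' downstream geometry is defined on heavy atoms.
#'
#' @param s A `mol_structure`.
#' @return The cleaned structure.
#' @export
strip_heteroatoms <- function(s) {
  a <- s$atoms
  keep <- a$residue_name %in% .STANDARD_AA & a$element != "H" & a$element != "D"
  if (!any(keep)) stop("empty structure after heteroatom/hydrogen removal")
  new_structure(a[keep, ], source_id = s$source_id)
}

kabsch_fit <- function(P, Q) {
  # rotation R and translation t with x' = x %*% t(R) + t mapping P onto Q
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cq - as.vector(R %*% cp))
}

apply_rigid <- function(xyz, fit) {
  sweep(xyz %*% t(fit$R), 2, fit$t, "+")
}

#' Superpose one structure onto another
#'
#' Least-squares rigid-body superposition (Kabsch/SVD) of `mobile` onto
#' `reference` over a named-atom selection, by default the C-alpha trace.
#' Selected atoms are paired in order, so the two selections must have
#' identical lengths.
#'
#' @param mobile,reference `mol_structure` objects.
#' @param selection Atom names used for fitting (default `"CA"`); `NULL`
#'   uses all atoms.
#' @return A list with `structure` (the transformed mobile) and `rmsd`
#'   (Angstrom, over the selection after fitting).
#' @export
superpose <- function(mobile, reference, selection = "CA") {
  sel_m <- if (is.null(selection)) rep(TRUE, n_atoms(mobile)) else
    mobile$atoms$atom_name %in% selection
  sel_r <- if (is.null(selection)) rep(TRUE, n_atoms(reference)) else
    reference$atoms$atom_name %in% selection
  if (sum(sel_m) != sum(sel_r)) {
    stop("selection size mismatch: ", sum(sel_m), " vs ", sum(sel_r))
  }
  if (sum(sel_m) < 3) stop("underdetermined superposition: fewer than 3 atoms")
  P <- coords(mobile)[sel_m, , drop = FALSE]
  Q <- coords(reference)[sel_r, , drop = FALSE]
  fit <- kabsch_fit(P, Q)
  moved <- set_coords(mobile, apply_rigid(coords(mobile), fit))
  dev <- apply_rigid(P, fit) - Q
  list(structure = moved, rmsd = sqrt(mean(rowSums(dev^2))))
}

#' Write a structure as PDB text
#'
#' Optionally annotates the B-factor column with per-residue values (e.g.
#' Provar pocket-lining probabilities), written to every atom of the residue
#' at two decimals.
#'
#' @param s A `mol_structure`.
#' @param residue_values Optional named numeric vector, names being residue
#'   keys from [residue_table()]; every key must exist in `s`.
#' @param file Optional path; when given the text is also written there.
#' @return PDB-format text as a single string.
#' @export
write_pdb <- function(s, residue_values = NULL, file = NULL) {
  a <- s$atoms
  b <- a$b_factor
  if (!is.null(residue_values)) {
    if (is.null(names(residue_values))) stop("residue_values must be named")
    keys <- residue_table(s)$key
    unknown <- setdiff(names(residue_values), keys)
    if (length(unknown) > 0) {
      stop("unknown residue key(s): ", paste(head(unknown, 5), collapse = ", "))
    }
    if (any(residue_values < -999.99 | residue_values > 999.99)) {
      stop("residue value outside the PDB B-factor field range [-999.99, 999.99]")
    }
    akey <- atom_residue_keys(s)
    idx <- match(akey, names(residue_values))
    b <- ifelse(is.na(idx), b, residue_values[idx])
  }
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path))
  xyz <- as.vector(t(coords(s)))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
    resno = a$residue_number, resid = a$residue_name, eleno = a$serial,
    elety = a$atom_name, chain = a$chain_id, insert = a$insertion_code,
    o = a$occupancy, b = round(b, 2), elesy = a$element, end = TRUE
  )
  out <- paste0(paste(readLines(path), collapse = "\n"), "\n")
  if (!is.null(file)) writeLines(sub("\n$", "", out), file)
  out
}
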