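#' Molecular structure container
#'
#' An `acr_structure` is a light wrapper around an atom table. Each row is
#' one atom with its residue assignment (author chain id and 1-based author
#' residue numbering, as cited in the literature, e.g. C34, C283), Cartesian
#' coordinates in Angstrom, and the minimal force-field attributes filled in
#' by [assign_parameters()]: partial charge (elementary charges), van der
#' Waals minimum-distance radius and well depth (Angstrom, kcal/mol) and an
#' atomic solvation parameter (kcal/mol/A^2).
#'
#' @param atoms data frame with at least columns `name`, `element`,
#'   `resname`, `chain`, `resno`, `x`, `y`, `z`, `hetero`, `water`.
#' @param source optional provenance string.
#' @return object of class `acr_structure`.
#' @export
acr_structure <- function(atoms, source = NA_character_) {
  needed <- c("name", "element", "resname", "chain", "resno",
              "x", "y", "z", "hetero", "water")
  miss <- setdiff(needed, names(atoms))
  if (length(miss) > 0)
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty model: structure contains no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  for (col in c("charge", "rmin", "eps", "sigma_solv"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (is.null(atoms$is_polar_h)) atoms$is_polar_h <- atoms$element == "H"
  if (is.null(atoms$h_parent)) atoms$h_parent <- NA_integer_
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source), class = "acr_structure")
}

#' @export
print.acr_structure <- function(x, ...) {
  at <- x$atoms
  rid <- residue_ids(x)
  cat(sprintf("acr_structure: %d atoms, %d residues, %d chain(s)\n",
              nrow(at), length(rid), length(unique(at$chain))))
  cat(sprintf("  hetero atoms: %d, waters: %d, hydrogens: %d\n",
              sum(at$hetero & !at$water), sum(at$water), sum(at$element == "H")))
  if (!all(is.na(at$charge)))
    cat("  force-field parameters assigned\n")
  invisible(x)
}

#' Coordinates of a structure as an n x 3 matrix
#' @param s an `acr_structure`.
#' @return numeric matrix with one row per atom.
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

`coords<-` <- function(s, value) {
  s$atoms[, c("x", "y", "z")] <- value
  s
}

#' Unique residue identifiers, in atom order
#' @noRd
residue_ids <- function(s) {
  unique(paste(s$atoms$chain, s$atoms$resno, sep = ":"))
}

residue_key <- function(atoms) paste(atoms$chain, atoms$resno, sep = ":")

#' Row indices of the atoms of one residue
#' @param s an `acr_structure`.
#' @param chain chain identifier.
#' @param resno author residue number.
#' @export
residue_atoms <- function(s, chain, resno) {
  which(s$atoms$chain == chain & s$atoms$resno == resno)
}

#' Look up one named atom of a residue; NA when absent.
#' @noRd
atom_index <- function(s, chain, resno, name) {
  i <- which(s$atoms$chain == chain & s$atoms$resno == resno &
               s$atoms$name == name)
  if (length(i) == 0) NA_integer_ else i[1]
}

backbone_names <- c("N", "CA", "C", "O", "OXT", "H")

infer_element <- function(name, elesy = NULL) {
  el <- rep(NA_character_, length(name))
  if (!is.null(elesy)) {
    ok <- !is.na(elesy) & nzchar(trimws(elesy))
    el[ok] <- toupper(trimws(elesy[ok]))
  }
  bad <- is.na(el)
  if (any(bad)) {
    stripped <- gsub("[^A-Za-z]", "", name[bad])
    el[bad] <- toupper(substr(stripped, 1, 1))
  }
  el
}

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses the file with bio3d, resolves alternate locations to the highest
#' occupancy conformer (ties broken by altloc label order), and flags waters
#' and hetero ligands. SSBOND records of PDB files are retained as an
#' attribute and honoured by [enumerate_cysteines()].
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return an [acr_structure()].
#' @examples
#' pdb <- system.file("extdata", "pocket_example.pdb", package = "acrydock")
#' if (nzchar(pdb)) s <- read_structure(pdb)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    # read.cif emits beta-status / secondary-structure-record notices that
    # carry no information for atom parsing
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("could not parse ", path, " as ", format,
                             ": ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty model: no atoms in ", path)

  # altloc resolution: keep the highest-occupancy conformer per atom site
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  keep <- rep(TRUE, nrow(at))
  dupkeys <- unique(key[duplicated(key)])
  for (k in dupkeys) {
    idx <- which(key == k)
    best <- idx[order(-occ[idx], alt[idx])][1]
    keep[idx] <- FALSE
    keep[best] <- TRUE
  }
  at <- at[keep, , drop = FALSE]

  water <- at$resid %in% c("HOH", "WAT", "TIP3", "SOL")
  atoms <- data.frame(
    name = trimws(at$elety),
    element = infer_element(trimws(at$elety), at$elesy),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    resno = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z,
    hetero = at$type == "HETATM" | water,
    water = water,
    stringsAsFactors = FALSE
  )
  s <- acr_structure(atoms, source = path)

  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    ss <- lines[startsWith(lines, "SSBOND")]
    if (length(ss) > 0) {
      pairs <- do.call(rbind, lapply(ss, function(l) {
        data.frame(chain1 = trimws(substr(l, 16, 16)),
                   resno1 = as.integer(substr(l, 18, 21)),
                   chain2 = trimws(substr(l, 30, 30)),
                   resno2 = as.integer(substr(l, 32, 35)),
                   stringsAsFactors = FALSE)
      }))
      attr(s, "ssbond") <- pairs
    }
  }
  s
}

#' Combine a protein structure and a docked pose into one structure
#'
#' Applies the pose's moved protein coordinates (if any) and appends the
#' adduct atoms as a hetero residue named `PRD` on chain `X`, one residue per
#' ligand copy.
#'
#' @param s protein `acr_structure` (parameters assigned, hydrogens added).
#' @param pose an `acr_pose` from the docking stage.
#' @param template the [build_adduct_template()] used for docking.
#' @return an `acr_structure` of the complex.
#' @export
complex_structure <- function(s, pose, template) {
  at <- s$atoms
  if (!is.null(pose$moved_protein) && nrow(pose$moved_protein$xyz) > 0) {
    at[pose$moved_protein$index, c("x", "y", "z")] <- pose$moved_protein$xyz
  }
  ncopy <- n_ligand_copies(pose)
  nat <- nrow(template$atoms)
  lig_rows <- do.call(rbind, lapply(seq_len(ncopy), function(k) {
    xyz <- pose$xyz[(k - 1) * nat + seq_len(nat), , drop = FALSE]
    data.frame(
      name = template$atoms$name,
      element = template$atoms$element,
      resname = "PRD",
      chain = "X",
      resno = k,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      hetero = TRUE, water = FALSE,
      charge = template$atoms$charge,
      rmin = template$atoms$rmin,
      eps = template$atoms$eps,
      sigma_solv = template$atoms$sigma_solv,
      is_polar_h = template$atoms$element == "H",
      h_parent = ifelse(is.na(template$atoms$h_parent), NA_integer_,
                        template$atoms$h_parent + nrow(at) +
                          (k - 1) * nat),
      stringsAsFactors = FALSE
    )
  }))
  for (col in setdiff(names(at), names(lig_rows))) lig_rows[[col]] <- NA
  out <- s
  out$atoms <- rbind(at[, names(at)], lig_rows[, names(at)])
  attr(out, "ligand_index") <- nrow(at) + seq_len(nrow(lig_rows))
  out
}

#' Write a protein-adduct complex as a PDB file
#'
#' The adduct is written as HETATM records with residue name `PRD` on its
#' own chain, one residue per ligand copy; the file round-trips through
#' [read_structure()] with coordinates preserved to the PDB precision of
#' 1e-3 Angstrom.
#'
#' @param s protein `acr_structure`.
#' @param pose docked `acr_pose`, or `NULL` to write the protein alone.
#' @param path output file path.
#' @param template ligand template (required when `pose` is given).
#' @return `path`, invisibly.
#' @export
write_complex <- function(s, pose, path, template = NULL) {
  cx <- if (is.null(pose)) s else {
    if (is.null(template)) stop("template is required to write a pose")
    complex_structure(s, pose, template)
  }
  at <- cx$atoms
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to ", path, ": no such directory")
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = ifelse(at$hetero, "HETATM", "ATOM"),
    resno = at$resno, resid = at$resname, chain = at$chain,
    eleno = seq_len(nrow(at)), elety = at$name,
    o = rep(1, nrow(at)), b = rep(0, nrow(at)), elesy = at$element
  )
  invisible(path)
}
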