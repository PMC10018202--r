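#' Covalent distance restraints for a cysteine-adduct bond
#'
#' The covalent bond is emulated by two flat-bottom distance restraints:
#' the cysteine Sgamma to the ligand's reactive carbon at 1.8 +/- 0.1 A
#' (the length of a C-S single bond) and the cysteine Cbeta to the carbon
#' adjacent to the reactive one at 2.8 +/- 0.1 A, which enforces the proper
#' angular geometry (the Cgamma-Cepsilon separation of methionine).
#'
#' @param s structure containing the cysteine.
#' @param chain,resno the reactive cysteine.
#' @param template the adduct template ([build_adduct_template()]).
#' @param force_constant restraint force constant, kcal/mol/A^2.
#' @param copy ligand copy index (multibody docking places one adduct per
#'   site); ligand atom indices are offset accordingly.
#' @return data frame of class `acr_restraints` with columns
#'   `protein_atom` (row in the structure), `ligand_atom` (row in the pose
#'   coordinate block), `target`, `tolerance`, `force_constant`.
#' @export
make_covalent_restraints <- function(s, chain, resno, template,
                                     force_constant = 50, copy = 1L) {
  sg <- atom_index(s, chain, resno, "SG")
  cb <- atom_index(s, chain, resno, "CB")
  if (is.na(sg) || is.na(cb))
    stop("cysteine ", chain, ":", resno, " lacks SG/CB atoms")
  nat <- nrow(template$atoms)
  off <- (copy - 1L) * nat
  out <- data.frame(
    protein_atom = c(sg, cb),
    ligand_atom = off + c(template$reactive_carbon, template$adjacent_carbon),
    target = c(1.8, 2.8),
    tolerance = c(0.1, 0.1),
    force_constant = force_constant
  )
  class(out) <- c("acr_restraints", class(out))
  out
}

#' Restraint violations of a pose
#'
#' Violation is the distance beyond the flat-bottom band:
#' `max(0, |d - target| - tolerance)` per restraint, in Angstrom.
#'
#' @param restraints restraint table.
#' @param protein_xyz protein coordinate matrix.
#' @param ligand_xyz pose ligand coordinate matrix.
#' @return numeric vector, one violation per restraint.
#' @export
restraint_violations <- function(restraints, protein_xyz, ligand_xyz) {
  d <- sqrt(rowSums((protein_xyz[restraints$protein_atom, , drop = FALSE] -
                       ligand_xyz[restraints$ligand_atom, , drop = FALSE])^2))
  pmax(0, abs(d - restraints$target) - restraints$tolerance)
}

#' Flat-bottom quadratic restraint energy (kcal/mol)
#' @noRd
restraint_energy <- function(restraints, protein_xyz, ligand_xyz) {
  v <- restraint_violations(restraints, protein_xyz, ligand_xyz)
  sum(restraints$force_constant * v^2)
}
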