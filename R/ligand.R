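#' Propionamide adduct template
#'
#' Internal-coordinate model of the Michael-addition product that acrylamide
#' forms with a cysteine thiolate: the propionamide moiety
#' S-CH2-CH2-C(=O)NH2, with the sulfur supplied by the protein. Heavy atoms
#' are the reactive carbon `C1` (the former beta-carbon, which bonds to
#' Sgamma), the adjacent methylene `C2`, the carbonyl carbon `C3`, the
#' carbonyl oxygen `O1` (hydrogen-bond acceptor) and the amide nitrogen `N1`
#' (donor, carrying two polar hydrogens). Charges and vdW parameters come
#' from the packaged table ([default_parameters()]).
#'
#' @return object of class `acr_ligand_template`: a list with the atom table
#'   (`atoms`, template coordinates in Angstrom), marker indices
#'   (`reactive_carbon`, `adjacent_carbon`, `carbonyl_carbon`,
#'   `carbonyl_oxygen`, `amide_nitrogen`, `hydrophobic_carbons`) and
#'   `rotatable_torsions` (each a list with `axis`, two atom indices, and
#'   `moving`, the indices rotated by the torsion).
#' @examples
#' tpl <- build_adduct_template()
#' sum(tpl$atoms$element != "H")  # 5 heavy atoms
#' @export
build_adduct_template <- function() {
  c1 <- c(0, 0, 0)
  c2 <- c(1.53, 0, 0)
  c3 <- c2 + 1.52 * c(cos(deg2rad(69)), sin(deg2rad(69)), 0)
  o1 <- place_atom(c1, c2, c3, 1.23, 121, 0)
  n1 <- place_atom(c1, c2, c3, 1.33, 116, 180)
  h11 <- place_atom(c2, c3, n1, 1.01, 120, 0)
  h12 <- place_atom(c2, c3, n1, 1.01, 120, 180)
  xyz <- rbind(c1, c2, c3, o1, n1, h11, h12)

  pars <- default_parameters()
  ch <- pars$charges[pars$charges$resname == "PRD", ]
  el <- pars$elements
  name <- c("C1", "C2", "C3", "O1", "N1", "H11", "H12")
  element <- c("C", "C", "C", "O", "N", "H", "H")
  ei <- match(element, el$element)
  atoms <- data.frame(
    name = name, element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = ch$charge[match(name, ch$atom)],
    rmin = el$rmin[ei], eps = el$eps[ei], sigma_solv = el$sigma_solv[ei],
    h_parent = c(NA, NA, NA, NA, NA, 5L, 5L),
    stringsAsFactors = FALSE
  )
  structure(list(
    atoms = atoms,
    reactive_carbon = 1L,
    adjacent_carbon = 2L,
    carbonyl_carbon = 3L,
    carbonyl_oxygen = 4L,
    amide_nitrogen = 5L,
    hydrophobic_carbons = c(1L, 2L),
    # bonds within the ligand (heavy-atom connectivity + amide hydrogens)
    bonds = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(3L, 5L),
                  c(5L, 6L), c(5L, 7L)),
    rotatable_torsions = list(
      list(axis = c(1L, 2L), moving = c(3L, 4L, 5L, 6L, 7L)),
      list(axis = c(2L, 3L), moving = c(4L, 5L, 6L, 7L))
    )
  ), class = "acr_ligand_template")
}

template_xyz <- function(template) {
  as.matrix(template$atoms[, c("x", "y", "z")])
}
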