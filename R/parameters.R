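#' Packaged force-field parameter table
#'
#' A minimal additive force-field subset shipped with the package: per-atom
#' partial charges for the 20 standard amino acids (polar-hydrogen model;
#' aliphatic hydrogen charges are absorbed into their carbons), the
#' propionamide adduct (`PRD`) and water, plus per-element Lennard-Jones
#' parameters (`rmin` is the minimum-energy contact radius contribution in
#' Angstrom, `eps` the well depth in kcal/mol) and atomic solvation
#' parameters (kcal/mol/A^2; positive for apolar atoms, so that burying them
#' is favourable).
#'
#' Charges are self-consistent (each residue sums to its formal charge) and
#' reproduce the polarity classification used by the hydrophobic-contact
#' detector: backbone carbonyl carbons carry |q| >= 0.15 e while aliphatic
#' side-chain carbons carry |q| < 0.15 e. Cysteine has three charge states:
#' `CYS` (thiol), `CYX` (disulfide-bonded) and `CYM` (deprotonated thiolate,
#' used for reactive cysteines).
#'
#' @return list with elements `charges` (data frame: resname, atom, charge)
#'   and `elements` (data frame: element, rmin, eps, sigma_solv).
#' @export
default_parameters <- function() {
  ch <- utils::read.csv(system.file("extdata", "ff_charges.csv",
                                    package = "acrydock"),
                        stringsAsFactors = FALSE)
  el <- utils::read.csv(system.file("extdata", "ff_elements.csv",
                                    package = "acrydock"),
                        stringsAsFactors = FALSE)
  list(charges = ch, elements = el)
}

standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

deprotonated_keys <- function(s) {
  k <- attr(s, "deprotonated")
  if (is.null(k)) character(0) else k
}

#' Assign partial charges, vdW and solvation parameters to every atom
#'
#' Charges are looked up by residue and atom name (backbone atoms share one
#' entry across residues, with a proline override); Lennard-Jones radii,
#' well depths and atomic solvation parameters are looked up by element.
#' Cysteines flagged as disulfide-bonded use the `CYX` charge set and
#' cysteines marked deprotonated (see [add_polar_hydrogens()]) the thiolate
#' `CYM` set. Atoms absent from the table receive a zero charge and
#' element-default (or neutral) vdW parameters with a warning; the operation
#' never fails.
#'
#' @param s an [acr_structure()].
#' @param param_set parameter list as returned by [default_parameters()].
#' @return `s` with `charge`, `rmin`, `eps` and `sigma_solv` columns filled.
#' @export
assign_parameters <- function(s, param_set = default_parameters()) {
  at <- s$atoms
  ch <- param_set$charges
  el <- param_set$elements

  cysinfo <- enumerate_cysteines(s)
  ss_keys <- if (nrow(cysinfo) > 0)
    paste(cysinfo$chain[cysinfo$disulfide], cysinfo$resno[cysinfo$disulfide],
          sep = ":") else character(0)
  dep_keys <- deprotonated_keys(s)

  # effective residue name used for the charge lookup
  key <- residue_key(at)
  eff <- at$resname
  is_cys <- eff == "CYS"
  eff[is_cys & key %in% ss_keys] <- "CYX"
  eff[is_cys & key %in% dep_keys & !(key %in% ss_keys)] <- "CYM"
  bb <- at$name %in% backbone_names & !at$hetero & eff %in%
    c(standard_aa, "CYX", "CYM")

  lookup <- function(resname, atom) {
    i <- match(paste(resname, atom), paste(ch$resname, ch$atom))
    ch$charge[i]
  }
  q <- lookup(eff, at$name)
  q_bb <- lookup(rep("BB", nrow(at)), at$name)
  # side-chain entry wins (PRO N override); otherwise fall back to backbone
  q[bb & is.na(q)] <- q_bb[bb & is.na(q)]

  miss <- is.na(q)
  if (any(miss)) {
    q[miss] <- 0
    warning(sum(miss), " atom(s) absent from the charge table were ",
            "assigned charge 0 (e.g. ",
            paste(utils::head(unique(paste(at$resname[miss], at$name[miss])), 3),
                  collapse = ", "), ")")
  }

  ei <- match(at$element, el$element)
  rmin <- el$rmin[ei]
  eps <- el$eps[ei]
  sig <- el$sigma_solv[ei]
  unk <- is.na(ei)
  if (any(unk)) {
    rmin[unk] <- 1.8
    eps[unk] <- 0.05
    sig[unk] <- 0
    warning("element(s) ", paste(unique(at$element[unk]), collapse = ", "),
            " not in the parameter table; neutral defaults used")
  }

  s$atoms$charge <- q
  s$atoms$rmin <- rmin
  s$atoms$eps <- eps
  s$atoms$sigma_solv <- sig
  attr(s, "parameters_assigned") <- TRUE
  s
}

#' Scale down the vdW radius of a reactive cysteine sulfur
#'
#' Emulates covalent bond formation in the docking stage by dividing the
#' Lennard-Jones radius of the reactive Sgamma by 10, so that the ligand's
#' reactive carbon can approach to covalent-bond distance. Idempotent: a
#' sulfur already scaled is left untouched.
#'
#' @param s structure with parameters assigned.
#' @param chain,resno the reactive cysteine.
#' @return the modified structure.
#' @export
scale_sulfur_vdw <- function(s, chain, resno) {
  if (!isTRUE(attr(s, "parameters_assigned")))
    stop("assign_parameters() must be called first")
  i <- atom_index(s, chain, resno, "SG")
  if (is.na(i)) stop("residue ", chain, ":", resno, " has no SG atom")
  done <- attr(s, "sulfur_scaled")
  key <- paste(chain, resno, sep = ":")
  if (key %in% done) return(s)
  s$atoms$rmin[i] <- s$atoms$rmin[i] / 10
  attr(s, "sulfur_scaled") <- c(done, key)
  s
}
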