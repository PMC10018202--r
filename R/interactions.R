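# Geometric interaction detectors: hydrogen bonds (donor-acceptor distance
# <= 4.1 A and donor-H-acceptor angle >= 100 degrees, measured at the
# hydrogen) and hydrophobic contacts (ligand aliphatic carbons vs apolar
# protein carbons, |q| < 0.15 e, within 4.0 A). Waters are never considered:
# the analysis covers direct protein-ligand interactions only.

#' Row indices of hydrogen-bond acceptor atoms
#'
#' Acceptors are oxygens and sulfurs, plus nitrogens that carry no hydrogen
#' and are not backbone amides (e.g. the unprotonated imidazole nitrogen of
#' histidine). Waters are excluded.
#' @noRd
acceptor_indices <- function(atoms) {
  has_h <- seq_len(nrow(atoms)) %in% atoms$h_parent
  which(!atoms$water &
          (atoms$element %in% c("O", "S") |
             (atoms$element == "N" & !has_h & atoms$name != "N")))
}

#' All donor-H...acceptor triples passing the geometric criterion
#'
#' @param atoms atom table; hydrogens must carry `h_parent`.
#' @param h_idx candidate hydrogen rows (their parents are the donors).
#' @param acc_idx candidate acceptor rows.
#' @return data frame of hydrogen bonds (one row per triple).
#' @noRd
find_hbonds <- function(atoms, h_idx, acc_idx, dist_cutoff = 4.1,
                        angle_cutoff = 100) {
  out <- list()
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  for (h in h_idx) {
    d <- atoms$h_parent[h]
    if (is.na(d)) next
    acc <- setdiff(acc_idx, c(d, h))
    if (length(acc) == 0) next
    da <- sqrt(rowSums(sweep(xyz[acc, , drop = FALSE], 2, xyz[d, ], "-")^2))
    close <- which(da <= dist_cutoff)
    for (j in close) {
      a <- acc[j]
      ang <- bond_angle(xyz[d, ], xyz[h, ], xyz[a, ])
      if (ang >= angle_cutoff) {
        out[[length(out) + 1]] <- data.frame(
          donor = d, hydrogen = h, acceptor = a,
          distance = da[j], angle = ang)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  }
  do.call(rbind, out)
}

annotate_partner <- function(hb, atoms, lig_idx, template) {
  on_lig <- function(i) i %in% lig_idx
  lig_local <- function(i) match(i, lig_idx)
  n <- nrow(hb)
  hb$ligand_group <- rep("none", n)
  hb$partner_chain <- rep(NA_character_, n)
  hb$partner_resno <- rep(NA_integer_, n)
  hb$partner_restype <- rep(NA_character_, n)
  hb$partner_atom <- rep(NA_character_, n)
  hb$sidechain <- rep(NA, n)
  nat <- nrow(template$atoms)
  for (r in seq_len(n)) {
    don <- hb$donor[r]; acc <- hb$acceptor[r]
    lig_side <- if (on_lig(don)) don else acc
    pro_side <- if (on_lig(don)) acc else don
    local <- ((lig_local(lig_side) - 1) %% nat) + 1
    if (!on_lig(don) && local == template$carbonyl_oxygen)
      hb$ligand_group[r] <- "carbonyl"
    if (on_lig(don) && local == template$amide_nitrogen)
      hb$ligand_group[r] <- "amino"
    hb$partner_chain[r] <- atoms$chain[pro_side]
    hb$partner_resno[r] <- atoms$resno[pro_side]
    hb$partner_restype[r] <- atoms$resname[pro_side]
    hb$partner_atom[r] <- atoms$name[pro_side]
    pn <- atoms$name[pro_side]
    if (atoms$element[pro_side] == "H" && !is.na(atoms$h_parent[pro_side]))
      pn <- atoms$name[atoms$h_parent[pro_side]]
    hb$sidechain[r] <- !(pn %in% backbone_names)
  }
  hb
}

#' Detect protein-ligand hydrogen bonds in a docked complex
#'
#' Every donor-H...acceptor triple between the protein and the adduct with
#' donor-acceptor distance at most `dist_cutoff` and donor-hydrogen-acceptor
#' angle at least `angle_cutoff` is reported, in both directions: the ligand
#' amide N-H as donor and the ligand carbonyl oxygen as acceptor. Donor
#' heavy atoms without placed hydrogens cannot be detected; run
#' [add_polar_hydrogens()] first.
#'
#' @param s protein structure (hydrogens added, parameters assigned).
#' @param pose docked `acr_pose`; alternatively pass a ready-made complex
#'   from [complex_structure()] as `s` and leave `pose` `NULL`.
#' @param template ligand template used for docking.
#' @param dist_cutoff donor-acceptor distance cutoff (Angstrom).
#' @param angle_cutoff donor-H-acceptor angle tolerance (degrees).
#' @return data frame with one row per hydrogen bond: atom indices, the
#'   donor-acceptor `distance`, the `angle` at the hydrogen, the
#'   `ligand_group` involved (`"carbonyl"`, `"amino"` or `"none"`), the
#'   partner residue and a `sidechain` flag.
#' @export
detect_hbonds <- function(s, pose = NULL, template = NULL,
                          dist_cutoff = 4.1, angle_cutoff = 100) {
  cx <- if (is.null(pose)) s else complex_structure(s, pose, template)
  lig_idx <- attr(cx, "ligand_index")
  if (is.null(lig_idx)) stop("no ligand in the complex")
  atoms <- cx$atoms
  if (is.null(template)) stop("template is required")

  hs <- which(atoms$element == "H" & !is.na(atoms$h_parent) & !atoms$water)
  no_h_donors <- which(atoms$element %in% c("N", "O", "S") & !atoms$water &
                         !atoms$hetero & !(seq_len(nrow(atoms)) %in% atoms$h_parent) &
                         atoms$name == "N")
  if (length(no_h_donors) > 0 && !isTRUE(attr(cx, "hydrogens_added")) &&
      !isTRUE(attr(s, "hydrogens_added")))
    warning("backbone amide donors without hydrogens were skipped")
  acc <- acceptor_indices(atoms)

  hb <- find_hbonds(atoms, hs, acc, dist_cutoff, angle_cutoff)
  if (nrow(hb) == 0) return(annotate_partner(hb, atoms, lig_idx, template))
  inter <- xor(hb$donor %in% lig_idx, hb$acceptor %in% lig_idx)
  hb <- hb[inter, , drop = FALSE]
  rownames(hb) <- NULL
  annotate_partner(hb, atoms, lig_idx, template)
}

#' Detect hydrophobic contacts between the adduct and the protein
#'
#' Contacts are pairs formed by one of the two aliphatic adduct carbons (the
#' former vinyl carbons) and an apolar protein carbon, i.e. one whose
#' partial-charge magnitude is below `charge_thresh`, within `dist_cutoff`.
#'
#' @inheritParams detect_hbonds
#' @param dist_cutoff contact distance cutoff (Angstrom).
#' @param charge_thresh apolar-carbon charge threshold (elementary charges).
#' @return data frame with the ligand atom, partner residue/atom, distance
#'   and a `sidechain` flag.
#' @export
detect_hydrophobic_contacts <- function(s, pose = NULL, template = NULL,
                                        dist_cutoff = 4.0,
                                        charge_thresh = 0.15) {
  cx <- if (is.null(pose)) s else complex_structure(s, pose, template)
  lig_idx <- attr(cx, "ligand_index")
  if (is.null(lig_idx)) stop("no ligand in the complex")
  atoms <- cx$atoms
  if (all(is.na(atoms$charge[-lig_idx])))
    stop("charges missing: run assign_parameters()")
  nat <- nrow(template$atoms)
  ncopy <- length(lig_idx) / nat
  lig_c <- lig_idx[rep((seq_len(ncopy) - 1) * nat, each = 2) +
                     template$hydrophobic_carbons]
  pro_c <- setdiff(which(atoms$element == "C" & !atoms$water &
                           abs(atoms$charge) < charge_thresh),
                   lig_idx)
  if (length(pro_c) == 0 || length(lig_c) == 0) {
    return(data.frame(ligand_atom = character(0), partner_chain = character(0),
                      partner_resno = integer(0), partner_restype = character(0),
                      partner_atom = character(0), distance = numeric(0),
                      sidechain = logical(0)))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- sqrt(cross_dist2(xyz[lig_c, , drop = FALSE],
                        xyz[pro_c, , drop = FALSE]))
  hit <- which(d <= dist_cutoff, arr.ind = TRUE)
  data.frame(
    ligand_atom = atoms$name[lig_c[hit[, 1]]],
    partner_chain = atoms$chain[pro_c[hit[, 2]]],
    partner_resno = atoms$resno[pro_c[hit[, 2]]],
    partner_restype = atoms$resname[pro_c[hit[, 2]]],
    partner_atom = atoms$name[pro_c[hit[, 2]]],
    distance = d[hit],
    sidechain = !(atoms$name[pro_c[hit[, 2]]] %in% backbone_names),
    stringsAsFactors = FALSE
  )
}
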