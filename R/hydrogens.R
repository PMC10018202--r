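# Polar-hydrogen placement at ideal geometry. Only hydrogens that can act
# as hydrogen-bond donors are built (backbone N-H, side-chain O-H, N-H and
# S-H); aliphatic hydrogens are implicit in the polar-hydrogen charge model.

# Side-chain donor hydrogen recipes. Two rule kinds:
#  - "torsion": place from three named reference atoms + internal coords
#  - "bisector": place opposite the bisector of two named neighbours
h_recipes <- list(
  SER = list(list(name = "HG", parent = "OG", kind = "torsion",
                  refs = c("CA", "CB", "OG"), bond = 0.96, angle = 109.5,
                  torsion = 180)),
  THR = list(list(name = "HG1", parent = "OG1", kind = "torsion",
                  refs = c("CA", "CB", "OG1"), bond = 0.96, angle = 109.5,
                  torsion = 180)),
  TYR = list(list(name = "HH", parent = "OH", kind = "torsion",
                  refs = c("CE1", "CZ", "OH"), bond = 0.96, angle = 110,
                  torsion = 0)),
  CYS = list(list(name = "HG", parent = "SG", kind = "torsion",
                  refs = c("CA", "CB", "SG"), bond = 1.34, angle = 96,
                  torsion = 180)),
  LYS = list(
    list(name = "HZ1", parent = "NZ", kind = "torsion",
         refs = c("CD", "CE", "NZ"), bond = 1.01, angle = 109.5, torsion = 180),
    list(name = "HZ2", parent = "NZ", kind = "torsion",
         refs = c("CD", "CE", "NZ"), bond = 1.01, angle = 109.5, torsion = 60),
    list(name = "HZ3", parent = "NZ", kind = "torsion",
         refs = c("CD", "CE", "NZ"), bond = 1.01, angle = 109.5, torsion = -60)),
  ARG = list(
    list(name = "HE", parent = "NE", kind = "bisector", refs = c("CD", "CZ"),
         bond = 1.01),
    list(name = "HH11", parent = "NH1", kind = "torsion",
         refs = c("NE", "CZ", "NH1"), bond = 1.01, angle = 120, torsion = 0),
    list(name = "HH12", parent = "NH1", kind = "torsion",
         refs = c("NE", "CZ", "NH1"), bond = 1.01, angle = 120, torsion = 180),
    list(name = "HH21", parent = "NH2", kind = "torsion",
         refs = c("NE", "CZ", "NH2"), bond = 1.01, angle = 120, torsion = 0),
    list(name = "HH22", parent = "NH2", kind = "torsion",
         refs = c("NE", "CZ", "NH2"), bond = 1.01, angle = 120, torsion = 180)),
  HIS = list(list(name = "HE2", parent = "NE2", kind = "bisector",
                  refs = c("CE1", "CD2"), bond = 1.01)),
  ASN = list(
    list(name = "HD21", parent = "ND2", kind = "torsion",
         refs = c("CB", "CG", "ND2"), bond = 1.01, angle = 120, torsion = 0),
    list(name = "HD22", parent = "ND2", kind = "torsion",
         refs = c("CB", "CG", "ND2"), bond = 1.01, angle = 120, torsion = 180)),
  GLN = list(
    list(name = "HE21", parent = "NE2", kind = "torsion",
         refs = c("CG", "CD", "NE2"), bond = 1.01, angle = 120, torsion = 0),
    list(name = "HE22", parent = "NE2", kind = "torsion",
         refs = c("CG", "CD", "NE2"), bond = 1.01, angle = 120, torsion = 180)),
  TRP = list(list(name = "HE1", parent = "NE1", kind = "bisector",
                  refs = c("CD1", "CE2"), bond = 1.01))
)

place_h_bisector <- function(parent, ref1, ref2, bond) {
  d <- -(unitv(ref1 - parent) + unitv(ref2 - parent))
  parent + bond * unitv(d)
}

#' Add polar hydrogens at ideal geometry
#'
#' Places backbone amide hydrogens (skipped for proline and chain-initial
#' residues) and side-chain donor hydrogens (Ser/Thr/Tyr hydroxyl, Lys
#' ammonium, Arg guanidinium, His N-epsilon-2 under the default tautomer,
#' Asn/Gln amide, Trp indole, Cys thiol) at ideal bond lengths and angles.
#'
#' Cysteines selected as reactive are modelled deprotonated: no thiol
#' hydrogen is placed and the residue is marked so that
#' [assign_parameters()] uses the thiolate charge set. Disulfide-bonded
#' cysteines never receive a thiol hydrogen. Residues with missing heavy
#' anchor atoms have the affected hydrogens skipped with a warning.
#'
#' @param s an [acr_structure()].
#' @param deprotonate which cysteines to model as thiolate: `"free"` (every
#'   non-disulfide cysteine, the docking default), `"none"`, or a character
#'   vector of `"chain:resno"` keys.
#' @return structure with hydrogens appended after each residue's heavy
#'   atoms; hydrogen rows carry `h_parent` (row index of the bonded heavy
#'   atom) and `is_polar_h = TRUE`.
#' @export
add_polar_hydrogens <- function(s, deprotonate = "free") {
  at <- s$atoms
  if (any(at$element == "H" & !at$hetero))
    stop("structure already contains protein hydrogens")
  cys <- enumerate_cysteines(s)
  cys_keys <- paste(cys$chain, cys$resno, sep = ":")
  dep <- if (identical(deprotonate, "free")) {
    cys_keys[cys$candidate]
  } else if (identical(deprotonate, "none")) {
    character(0)
  } else as.character(deprotonate)
  ss_keys <- cys_keys[cys$disulfide]

  key <- residue_key(at)
  res_order <- unique(key)
  skipped <- 0L

  pieces <- vector("list", length(res_order))
  for (ri in seq_along(res_order)) {
    rows <- at[key == res_order[ri], , drop = FALSE]
    resname <- rows$resname[1]
    pieces[[ri]] <- rows
    if (rows$hetero[1] || !(resname %in% standard_aa)) next

    pos <- function(name) {
      j <- which(rows$name == name)
      if (length(j) == 0) NULL else as.numeric(rows[j[1], c("x", "y", "z")])
    }
    newh <- list()

    # backbone amide H: bisector of C(prev) and CA at N
    if (resname != "PRO") {
      prev <- which(key == paste(rows$chain[1], rows$resno[1] - 1, sep = ":") &
                      at$name == "C")
      n <- pos("N"); ca <- pos("CA")
      if (length(prev) == 1 && !is.null(n) && !is.null(ca)) {
        cprev <- as.numeric(at[prev[1], c("x", "y", "z")])
        newh$H <- list(xyz = place_h_bisector(n, cprev, ca, 1.01),
                       parent = "N")
      }
    }

    recipes <- h_recipes[[resname]]
    this_key <- res_order[ri]
    if (resname == "CYS" && (this_key %in% dep || this_key %in% ss_keys))
      recipes <- NULL
    for (rc in recipes) {
      refs <- lapply(rc$refs, pos)
      parent <- pos(rc$parent)
      if (any(vapply(refs, is.null, TRUE)) || is.null(parent)) {
        skipped <- skipped + 1L
        next
      }
      xyz <- if (rc$kind == "bisector") {
        place_h_bisector(parent, refs[[1]], refs[[2]], rc$bond)
      } else {
        place_atom(refs[[1]], refs[[2]], refs[[3]], rc$bond, rc$angle,
                   rc$torsion)
      }
      newh[[rc$name]] <- list(xyz = xyz, parent = rc$parent)
    }

    if (length(newh) > 0) {
      hdf <- do.call(rbind, lapply(names(newh), function(nm) {
        data.frame(name = nm, element = "H", resname = resname,
                   chain = rows$chain[1], resno = rows$resno[1],
                   x = newh[[nm]]$xyz[1], y = newh[[nm]]$xyz[2],
                   z = newh[[nm]]$xyz[3],
                   hetero = FALSE, water = FALSE,
                   charge = NA_real_, rmin = NA_real_, eps = NA_real_,
                   sigma_solv = NA_real_, is_polar_h = TRUE,
                   h_parent = NA_integer_,
                   parent_name = nm_parent <- newh[[nm]]$parent,
                   stringsAsFactors = FALSE)
      }))
      rows2 <- rows
      rows2$parent_name <- NA_character_
      pieces[[ri]] <- rbind(rows2, hdf[, names(rows2)])
    } else {
      rows$parent_name <- NA_character_
      pieces[[ri]] <- rows
    }
  }
  if (skipped > 0)
    warning(skipped, " hydrogen(s) skipped because heavy-atom anchors are missing")

  newat <- do.call(rbind, pieces)
  rownames(newat) <- NULL
  # resolve h_parent indices from parent names within each residue
  nk <- residue_key(newat)
  hrows <- which(!is.na(newat$parent_name))
  for (i in hrows) {
    j <- which(nk == nk[i] & newat$name == newat$parent_name[i])
    newat$h_parent[i] <- j[1]
  }
  newat$parent_name <- NULL

  out <- s
  out$atoms <- newat
  attr(out, "deprotonated") <- union(deprotonated_keys(s), dep)
  attr(out, "hydrogens_added") <- TRUE
  # parameters must be (re)assigned after insertion of new rows
  if (isTRUE(attr(s, "parameters_assigned"))) out <- assign_parameters(out)
  out
}
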