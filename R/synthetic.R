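# Synthetic mini-protein pockets with planted cysteine microenvironments.
# Backbones use ideal secondary-structure internal coordinates (canonical
# phi/psi, trans peptide bonds); side chains use ideal bond lengths and
# angles with chi angles either at canonical rotamer values or aimed by a
# deterministic grid search so that planted flank residues reach the
# cysteine sulfur. The generators are fully deterministic per seed.

# --- side-chain internal-coordinate recipes ---------------------------------
# refs name three previously placed atoms; tors is either a number or
# list(chi = k, offset = degrees).
sc_recipes <- list(
  ALA = list(),
  GLY = NULL,
  CYS = list(list(a = "SG", refs = c("N", "CA", "CB"), b = 1.81, ang = 114,
                  tors = list(chi = 1, offset = 0))),
  SER = list(list(a = "OG", refs = c("N", "CA", "CB"), b = 1.42, ang = 111,
                  tors = list(chi = 1, offset = 0))),
  THR = list(list(a = "OG1", refs = c("N", "CA", "CB"), b = 1.42, ang = 109.5,
                  tors = list(chi = 1, offset = 0)),
             list(a = "CG2", refs = c("N", "CA", "CB"), b = 1.52, ang = 111,
                  tors = list(chi = 1, offset = -120))),
  VAL = list(list(a = "CG1", refs = c("N", "CA", "CB"), b = 1.52, ang = 111,
                  tors = list(chi = 1, offset = 0)),
             list(a = "CG2", refs = c("N", "CA", "CB"), b = 1.52, ang = 111,
                  tors = list(chi = 1, offset = 122))),
  LEU = list(list(a = "CG", refs = c("N", "CA", "CB"), b = 1.52, ang = 116,
                  tors = list(chi = 1, offset = 0)),
             list(a = "CD1", refs = c("CA", "CB", "CG"), b = 1.52, ang = 111,
                  tors = list(chi = 2, offset = 0)),
             list(a = "CD2", refs = c("CA", "CB", "CG"), b = 1.52, ang = 111,
                  tors = list(chi = 2, offset = 120))),
  LYS = list(list(a = "CG", refs = c("N", "CA", "CB"), b = 1.52, ang = 114,
                  tors = list(chi = 1, offset = 0)),
             list(a = "CD", refs = c("CA", "CB", "CG"), b = 1.52, ang = 111,
                  tors = list(chi = 2, offset = 0)),
             list(a = "CE", refs = c("CB", "CG", "CD"), b = 1.52, ang = 111,
                  tors = list(chi = 3, offset = 0)),
             list(a = "NZ", refs = c("CG", "CD", "CE"), b = 1.49, ang = 112,
                  tors = 180)),
  ARG = list(list(a = "CG", refs = c("N", "CA", "CB"), b = 1.52, ang = 114,
                  tors = list(chi = 1, offset = 0)),
             list(a = "CD", refs = c("CA", "CB", "CG"), b = 1.52, ang = 111,
                  tors = list(chi = 2, offset = 0)),
             list(a = "NE", refs = c("CB", "CG", "CD"), b = 1.46, ang = 112,
                  tors = list(chi = 3, offset = 0)),
             list(a = "CZ", refs = c("CG", "CD", "NE"), b = 1.33, ang = 124,
                  tors = 180),
             list(a = "NH1", refs = c("CD", "NE", "CZ"), b = 1.33, ang = 120,
                  tors = 0),
             list(a = "NH2", refs = c("CD", "NE", "CZ"), b = 1.33, ang = 120,
                  tors = 180)),
  ASP = list(list(a = "CG", refs = c("N", "CA", "CB"), b = 1.52, ang = 113,
                  tors = list(chi = 1, offset = 0)),
             list(a = "OD1", refs = c("CA", "CB", "CG"), b = 1.25, ang = 118,
                  tors = list(chi = 2, offset = 0)),
             list(a = "OD2", refs = c("CA", "CB", "CG"), b = 1.25, ang = 118,
                  tors = list(chi = 2, offset = 180))),
  GLU = list(list(a = "CG", refs = c("N", "CA", "CB"), b = 1.52, ang = 114,
                  tors = list(chi = 1, offset = 0)),
             list(a = "CD", refs = c("CA", "CB", "CG"), b = 1.52, ang = 113,
                  tors = list(chi = 2, offset = 0)),
             list(a = "OE1", refs = c("CB", "CG", "CD"), b = 1.25, ang = 118,
                  tors = 0),
             list(a = "OE2", refs = c("CB", "CG", "CD"), b = 1.25, ang = 118,
                  tors = 180)),
  HIS = list(list(a = "CG", refs = c("N", "CA", "CB"), b = 1.50, ang = 113,
                  tors = list(chi = 1, offset = 0)),
             list(a = "ND1", refs = c("CA", "CB", "CG"), b = 1.38, ang = 122,
                  tors = list(chi = 2, offset = 0)),
             list(a = "CD2", refs = c("CA", "CB", "CG"), b = 1.36, ang = 129,
                  tors = list(chi = 2, offset = 180)),
             list(a = "CE1", refs = c("CB", "CG", "ND1"), b = 1.32, ang = 109,
                  tors = 180),
             list(a = "NE2", refs = c("CB", "CG", "CD2"), b = 1.37, ang = 107,
                  tors = 180)),
  ASN = list(list(a = "CG", refs = c("N", "CA", "CB"), b = 1.52, ang = 113,
                  tors = list(chi = 1, offset = 0)),
             list(a = "OD1", refs = c("CA", "CB", "CG"), b = 1.23, ang = 121,
                  tors = list(chi = 2, offset = 0)),
             list(a = "ND2", refs = c("CA", "CB", "CG"), b = 1.33, ang = 117,
                  tors = list(chi = 2, offset = 180))),
  TYR = list(list(a = "CG", refs = c("N", "CA", "CB"), b = 1.51, ang = 114,
                  tors = list(chi = 1, offset = 0)),
             list(a = "CD1", refs = c("CA", "CB", "CG"), b = 1.39, ang = 121,
                  tors = list(chi = 2, offset = 0)),
             list(a = "CD2", refs = c("CA", "CB", "CG"), b = 1.39, ang = 121,
                  tors = list(chi = 2, offset = 180)),
             list(a = "CE1", refs = c("CB", "CG", "CD1"), b = 1.39, ang = 121,
                  tors = 180),
             list(a = "CE2", refs = c("CB", "CG", "CD2"), b = 1.39, ang = 121,
                  tors = 180),
             list(a = "CZ", refs = c("CG", "CD1", "CE1"), b = 1.39, ang = 120,
                  tors = 0),
             list(a = "OH", refs = c("CD1", "CE1", "CZ"), b = 1.38, ang = 120,
                  tors = 180))
)

sc_terminal_atom <- c(CYS = "SG", SER = "OG", LYS = "NZ", ARG = "CZ",
                      ASP = "CG", GLU = "CD", HIS = "NE2", ASN = "ND2",
                      THR = "OG1", TYR = "OH", LEU = "CG", VAL = "CB",
                      ALA = "CB")

# backbone from phi/psi torsion lists (trans peptide bonds)
build_backbone <- function(phi, psi) {
  n <- length(phi)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- CA[1, ] + 1.525 * c(cos(deg2rad(69)), sin(deg2rad(69)), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], 1.458, 121.7, 180)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525, 111.2,
                             phi[i + 1])
    O[i, ] <- place_atom(N[i + 1, ], CA[i, ], C[i, ], 1.231, 120.8, 180)
  }
  nv <- place_atom(N[n, ], CA[n, ], C[n, ], 1.329, 116.2, 180)
  O[n, ] <- place_atom(nv, CA[n, ], C[n, ], 1.231, 120.8, 180)
  list(N = N, CA = CA, C = C, O = O)
}

# side-chain atoms of residue i given chi angles; returns named list of xyz
build_sidechain <- function(bb, i, resname, chi = c(-60, 180, 180)) {
  if (resname == "GLY") return(list())
  pos <- list(N = bb$N[i, ], CA = bb$CA[i, ], C = bb$C[i, ])
  pos$CB <- place_atom(pos$C, pos$N, pos$CA, 1.53, 110.4, 122.6)
  for (entry in sc_recipes[[resname]]) {
    tors <- entry$tors
    if (is.list(tors)) tors <- chi[tors$chi] + tors$offset
    refs <- lapply(entry$refs, function(r) pos[[r]])
    pos[[entry$a]] <- place_atom(refs[[1]], refs[[2]], refs[[3]],
                                 entry$b, entry$ang, tors)
  }
  pos[setdiff(names(pos), c("N", "CA", "C"))]
}

# torsion set of the tuned hairpin loop connecting the two helices
# (chosen so that the second helix runs antiparallel alongside the first
# at groove-forming distance); filled by the scaffold definitions below
helix_pair_torsions <- function(n_helix = 16, n_loop = 6,
                                loop_phi = c(40.2, -109.8, -23.4, 70.5,
                                             127.4, -112.0),
                                loop_psi = c(94.5, 75.8, 143.4, -34.0,
                                             119.3, 153.5)) {
  phi <- c(rep(-57, n_helix), loop_phi, rep(-57, n_helix))
  psi <- c(rep(-47, n_helix), loop_psi, rep(-47, n_helix))
  list(phi = phi, psi = psi, n = 2 * n_helix + n_loop)
}

#' Specification of a synthetic cysteine pocket
#'
#' @param scaffold `"helix-pair"` (a helix-loop-helix hairpin whose groove
#'   holds the cysteine) or `"loop-cradle"` (a single helix with the
#'   cysteine and flanks on one face).
#' @param flank_type residue family planted within 5 A of the cysteine
#'   sulfur: `"positive"` (Lys/Arg), `"neutral"` (Ala), `"acidic"`
#'   (Asp/Glu) or `"acceptor"` (His).
#' @param n_flank number of planted flank residues.
#' @param planted_hbond optional `list(donor_flank = 1, distance = 2.9,
#'   angle = 160)` used by [generate_known_complex()]: the flank index
#'   donating a hydrogen bond to the adduct carbonyl oxygen and the target
#'   donor-acceptor distance (Angstrom) / donor-H-acceptor angle (degrees).
#' @param seed integer seed controlling filler-sequence choice.
#' @return list of class `acr_pocket_spec`.
#' @export
pocket_spec <- function(scaffold = c("helix-pair", "loop-cradle"),
                        flank_type = c("positive", "neutral", "acidic",
                                       "acceptor"),
                        n_flank = 2, planted_hbond = NULL, seed = 1) {
  structure(list(scaffold = match.arg(scaffold),
                 flank_type = match.arg(flank_type),
                 n_flank = n_flank, planted_hbond = planted_hbond,
                 seed = seed),
            class = "acr_pocket_spec")
}

flank_residue_pool <- list(positive = c("LYS", "ARG"), neutral = c("ALA"),
                           acidic = c("ASP", "GLU"), acceptor = c("HIS"))

# grid-search chi1/chi2 so the terminal atom lands as close as possible to
# `target` without clashing into `avoid` coordinates
aim_sidechain <- function(bb, i, resname, target, avoid,
                          chi1_grid = seq(-180, 150, by = 30),
                          chi2_grid = seq(-180, 150, by = 30)) {
  term <- sc_terminal_atom[[resname]]
  # long side chains bend at chi3 as well; shorter ones ignore it
  step3 <- max(30, diff(chi1_grid[1:2]) * 2)
  chi3_grid <- if (resname %in% c("LYS", "ARG"))
    seq(-180, 180 - step3, by = step3) else 180
  best <- NULL
  for (c1 in chi1_grid) {
    for (c2 in chi2_grid) {
    for (c3 in chi3_grid) {
      sc <- build_sidechain(bb, i, resname, chi = c(c1, c2, c3))
      xyz <- do.call(rbind, sc)
      dmin <- if (nrow(avoid) > 0)
        sqrt(min(cross_dist2(xyz, avoid))) else Inf
      if (dmin < 2.6) next
      d <- vlen(sc[[term]] - target)
      score <- d - 0.2 * min(dmin, 4)
      if (is.null(best) || score < best$score)
        best <- list(sc = sc, score = score, dist = d, chi = c(c1, c2, c3))
    }
    }
  }
  best
}

pocket_geometry <- function(spec) {
  if (spec$scaffold == "helix-pair") {
    tt <- helix_pair_torsions()
    list(torsions = tt, cys_at = 29L,
         flank_slots = c(25L, 32L, 9L, 6L, 13L, 28L, 12L))
  } else {
    n <- 30
    list(torsions = list(phi = rep(-57, n), psi = rep(-47, n), n = n),
         cys_at = 15L,
         flank_slots = c(11L, 18L, 12L, 19L, 8L))
  }
}

#' Generate a synthetic mini-protein pocket with a planted cysteine
#'
#' Builds a 30-60 residue polypeptide at ideal secondary-structure geometry
#' containing exactly one cysteine at the floor of a shallow groove, with
#' `n_flank` flanking residues of the requested family whose side chains
#' are aimed (by deterministic chi-grid search) to lie within 5 A of the
#' cysteine sulfur. Remaining positions carry a seed-dependent filler
#' sequence of small residues. The structure round-trips through
#' [write_complex()] / [read_structure()].
#'
#' @param spec an [pocket_spec()].
#' @return an [acr_structure()] with attribute `pocket_info` (cysteine
#'   location, flank positions and types).
#' @export
generate_pocket <- function(spec) {
  stopifnot(inherits(spec, "acr_pocket_spec"))
  geom <- pocket_geometry(spec)
  tt <- geom$torsions
  n <- tt$n
  bb <- build_backbone(tt$phi, tt$psi)

  with_seed(spec$seed, {
    # apolar filler with enough bulk that the helix faces present side
    # chains rather than bare backbone, as real helix surfaces do
    filler <- sample(c("LEU", "VAL", "ALA"), n, replace = TRUE,
                     prob = c(0.45, 0.3, 0.25))
    seqs <- filler
    seqs[geom$cys_at] <- "CYS"
    if (spec$n_flank > length(geom$flank_slots))
      stop("infeasible planted geometry: only ", length(geom$flank_slots),
           " flank slots available on this scaffold")
    pool <- flank_residue_pool[[spec$flank_type]]

    # cysteine side chain: aim into the groove (towards the scaffold centre)
    centre <- colMeans(bb$CA)
    cys_target <- bb$CA[geom$cys_at, ] +
      2.8 * unitv(centre - bb$CA[geom$cys_at, ])
    # Cbeta positions are fixed by the backbone, so every residue's CB is
    # known up front and counts as an obstacle for other residues
    cb_all <- t(vapply(seq_len(n), function(i)
      place_atom(bb$C[i, ], bb$N[i, ], bb$CA[i, ], 1.53, 110.4, 122.6),
      numeric(3)))
    placed_xyz <- rbind(bb$N, bb$CA, bb$C, bb$O, cb_all)
    placed_res <- c(rep(seq_len(n), 4), seq_len(n))
    placed_bb <- c(rep(TRUE, 4 * n), rep(FALSE, n))
    placed_cb <- c(rep(FALSE, 4 * n), rep(TRUE, n))
    # a residue's own and adjacent backbone atoms (and its own CB) are
    # bonded neighbours of its side chain and must not count as clashes.
    # Fixed CB stubs count only for sequence neighbours (their residues'
    # full side chains are placed, and avoided, in turn)
    avoid_for <- function(i) {
      keep <- !placed_cb |
        (placed_res != i & abs(placed_res - i) <= 2 & placed_res > 0)
      drop <- (placed_bb & abs(placed_res - i) <= 1) | !keep
      placed_xyz[!drop, , drop = FALSE]
    }
    add_placed <- function(sc, i) {
      if (length(sc) > 0) {
        placed_xyz <<- rbind(placed_xyz, do.call(rbind, sc))
        placed_res <<- c(placed_res, rep(i, length(sc)))
        placed_bb <<- c(placed_bb, rep(FALSE, length(sc)))
        placed_cb <<- c(placed_cb, rep(FALSE, length(sc)))
      }
    }
    cys_fit <- aim_sidechain(bb, geom$cys_at, "CYS", cys_target,
                             avoid_for(geom$cys_at))
    if (is.null(cys_fit))
      stop("infeasible planted geometry: cysteine side chain cannot be placed")
    sg <- cys_fit$sc$SG

    # planned adduct geometry: the pose the covalent restraints imply,
    # extending from the sulfur towards solvent. Its volume is kept free
    # of all side chains (so the site stays dockable in every variant) and
    # donor flanks are aimed at hydrogen-bond positions beside its
    # carbonyl oxygen.
    outward <- unitv(sg - centre)
    ca_c <- bb$CA[geom$cys_at, ]
    cb_c <- cys_fit$sc$CB
    plan_chain <- function(t1, t2, t3) {
      c1 <- place_atom(ca_c, cb_c, sg, 1.8, 100, t1)
      c2 <- place_atom(cb_c, sg, c1, 1.53, 112, t2)
      c3 <- place_atom(sg, c1, c2, 1.52, 111, t3)
      o1 <- place_atom(c1, c2, c3, 1.23, 121, 0)
      n1 <- place_atom(c1, c2, c3, 1.33, 116, 180)
      rbind(c1, c2, c3, o1, n1)
    }
    best_plan <- NULL
    plan_obst <- placed_xyz[placed_res != geom$cys_at, , drop = FALSE]
    for (t1 in seq(-180, 150, by = 30)) {
      for (t2 in seq(-180, 150, by = 30)) {
        for (t3 in c(180, 60, -60)) {
          lig <- plan_chain(t1, t2, t3)
          # prefer an outward-pointing chain with clearance from the scaffold
          out_score <- sum((sweep(lig, 2, sg, "-") %*% outward))
          clear <- sqrt(min(cross_dist2(lig, plan_obst)))
          if (clear < 2.7) next
          sc <- -out_score - 2 * min(clear, 4)
          if (is.null(best_plan) || sc < best_plan$sc)
            best_plan <- list(sc = sc, lig = lig)
        }
      }
    }
    if (is.null(best_plan))
      stop("infeasible planted geometry: no clash-free adduct direction")
    planned_lig <- best_plan$lig
    o1 <- planned_lig[4, ]
    # side-chain placement must respect the planned adduct volume
    placed_xyz <- rbind(placed_xyz, planned_lig)
    placed_res <- c(placed_res, rep(-999L, nrow(planned_lig)))
    placed_bb <- c(placed_bb, rep(FALSE, nrow(planned_lig)))
    placed_cb <- c(placed_cb, rep(FALSE, nrow(planned_lig)))

    # build all residues; flanks aimed at the sulfur, others at canonical
    # chi. Slots are tried in order of preference and kept when the side
    # chain's terminal atom can reach the 5 A shell without clashing.
    sides <- vector("list", n)
    sides[[geom$cys_at]] <- cys_fit$sc
    add_placed(cys_fit$sc, geom$cys_at)
    flank_pos <- integer(0)
    flank_res <- character(0)
    # the first flank aims straight at the planned carbonyl oxygen (the
    # clearance rule keeps its functional atom at hydrogen-bond distance
    # rather than on top of it); further flanks take thiolate-stabilising
    # positions beside the sulfur. All polar flank atoms must end inside
    # the 5 A microenvironment shell.
    axis_dir <- unitv(bb$CA[n, ] - bb$CA[1, ])
    side_dir <- unitv(vcross(outward, axis_dir))
    role <- switch(spec$flank_type, positive = "donor", neutral = "ala",
                   "acceptor")
    polar_sc <- c("NZ", "NH1", "NH2", "NE", "ND1", "NE2", "OD1", "OD2",
                  "OE1", "OE2")
    for (slot in geom$flank_slots) {
      if (length(flank_pos) >= spec$n_flank) break
      k_fl <- length(flank_pos)
      side_sign <- if (k_fl %% 2 == 1) 1 else -1
      # donors: the first sits between the carbonyl oxygen and the sulfur
      # (close enough to hydrogen-bond the former inside the latter's 5 A
      # shell), later ones take thiolate-stabilising spots beside the
      # sulfur. Proton acceptors always target the thiol region, which is
      # where they act in the reaction. Ala just lines the wall.
      target <- if (role == "donor" && k_fl == 0) {
        o1 + 1.2 * unitv(sg - o1)
      } else {
        sg + 1.0 * outward + 2.8 * side_dir * side_sign
      }
      max_dist <- if (role == "donor" && k_fl == 0) 3.4 else 3.2
      fits <- lapply(pool, function(rn)
        aim_sidechain(bb, slot, rn, target, avoid_for(slot),
                      chi1_grid = seq(-180, 165, by = 15),
                      chi2_grid = seq(-180, 165, by = 15)))
      ok <- which(vapply(seq_along(fits), function(k) {
        f <- fits[[k]]
        if (is.null(f)) return(FALSE)
        if (role == "ala")
          return(vlen(f$sc$CB - sg) <= 6.5)  # Ala lines the groove wall
        # the functional (polar) part of the side chain must sit in the
        # 5 A microenvironment shell
        pol <- f$sc[names(f$sc) %in% polar_sc]
        dpol <- min(vapply(pol, function(p) vlen(p - sg), 0))
        f$dist <= max_dist && dpol <= 5.0
      }, TRUE))
      if (length(ok) == 0) next
      best <- ok[which.min(vapply(fits[ok], `[[`, 0, "dist"))]
      seqs[slot] <- pool[best]
      sides[[slot]] <- fits[[best]]$sc
      add_placed(fits[[best]]$sc, slot)
      flank_pos <- c(flank_pos, slot)
      flank_res <- c(flank_res, pool[best])
    }
    if (length(flank_pos) < spec$n_flank)
      stop("infeasible planted geometry: only ", length(flank_pos), " of ",
           spec$n_flank, " flank residues can reach within 5 A of the ",
           "cysteine sulfur on this scaffold")
    for (i in setdiff(seq_len(n), c(geom$cys_at, flank_pos))) {
      best <- NULL
      av <- avoid_for(i)
      for (c1 in seq(-180, 150, by = 30)) {
        for (c2 in c(180, 60, -60)) {
          sc <- build_sidechain(bb, i, seqs[i], chi = c(c1, c2))
          xyz <- do.call(rbind, sc)
          dmin <- if (length(sc) > 0) sqrt(min(cross_dist2(xyz, av))) else Inf
          # prefer rotamer-like chi1 wells among clash-free placements
          score <- min(dmin, 4) + 0.1 * (c1 %in% c(-60, 60, 180))
          if (is.null(best) || score > best$score)
            best <- list(sc = sc, dmin = dmin, score = score)
        }
      }
      sides[[i]] <- best$sc
      add_placed(best$sc, i)
    }

    rows <- list()
    for (i in seq_len(n)) {
      nm <- c("N", "CA", "C", "O", names(sides[[i]]))
      xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ],
                   do.call(rbind, sides[[i]]))
      rows[[i]] <- data.frame(
        name = nm, element = substr(nm, 1, 1), resname = seqs[i],
        chain = "A", resno = i, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        hetero = FALSE, water = FALSE, stringsAsFactors = FALSE)
    }
    s <- acr_structure(do.call(rbind, rows), source = "synthetic pocket")
    attr(s, "pocket_info") <- list(
      cys = list(chain = "A", resno = geom$cys_at),
      flank_resno = flank_pos, flank_res = flank_res,
      flank_type = spec$flank_type, spec = spec)
    s
  })
}

#' Generate a pocket plus a planted adduct pose with known interactions
#'
#' Places the propionamide adduct on the pocket cysteine with both covalent
#' restraints satisfied exactly (reactive carbon at 1.8 A from Sgamma,
#' adjacent carbon at 2.8 A from Cbeta) and, if `spec$planted_hbond` is
#' given, the carbonyl oxygen positioned at the requested donor-acceptor
#' distance from the donor flank residue with the donor-H-acceptor angle at
#' least the requested value. Ligand torsions are chosen by deterministic
#' grid search with clash and spurious-contact penalties, so the planted
#' hydrogen bond is the only side-chain H-bond of the complex.
#'
#' @param spec a [pocket_spec()] (its `planted_hbond` entry is used).
#' @return list with `structure` (pocket with hydrogens and parameters),
#'   `pose` (an `acr_pose`), `template`, and `ground_truth` (data frame of
#'   the planted interaction, empty when no H-bond was requested).
#' @export
generate_known_complex <- function(spec) {
  s <- generate_pocket(spec)
  info <- attr(s, "pocket_info")
  s <- add_polar_hydrogens(s)
  s <- assign_parameters(s)
  template <- build_adduct_template()
  at <- s$atoms
  cys <- info$cys
  sg <- as.numeric(at[atom_index(s, cys$chain, cys$resno, "SG"), c("x", "y", "z")])
  cb <- as.numeric(at[atom_index(s, cys$chain, cys$resno, "CB"), c("x", "y", "z")])
  ca <- as.numeric(at[atom_index(s, cys$chain, cys$resno, "CA"), c("x", "y", "z")])

  hb <- spec$planted_hbond
  donor_xyz <- NULL
  donor_res <- NULL
  if (!is.null(hb)) {
    donor_res <- info$flank_resno[hb$donor_flank]
    drows <- residue_atoms(s, cys$chain, donor_res)
    dn <- drows[at$element[drows] %in% c("N", "O") &
                  !(at$name[drows] %in% backbone_names)]
    dn <- dn[vapply(dn, function(i) any(at$h_parent == i, na.rm = TRUE), TRUE)]
    if (length(dn) == 0)
      stop("infeasible planted geometry: donor flank has no polar hydrogen")
    donor_idx <- dn[1]
    donor_xyz <- as.numeric(at[donor_idx, c("x", "y", "z")])
    donor_h <- which(at$h_parent == donor_idx)
  }

  heavy_pro <- which(at$element != "H")
  pro_xyz <- as.matrix(at[heavy_pro, c("x", "y", "z")])

  place_ligand <- function(t1, t2, t3, t4) {
    c1 <- place_atom(ca, cb, sg, 1.8, 100, t1)
    c2 <- place_atom(cb, sg, c1, 1.53, 112, t2)
    c3 <- place_atom(sg, c1, c2, 1.52, 111, t3)
    o1 <- place_atom(c1, c2, c3, 1.23, 121, t4)
    n1 <- place_atom(c1, c2, c3, 1.33, 116, t4 + 180)
    h11 <- place_atom(c2, c3, n1, 1.01, 120, 0)
    h12 <- place_atom(c2, c3, n1, 1.01, 120, 180)
    rbind(c1, c2, c3, o1, n1, h11, h12)
  }
  # solve t2 so that |CB - C2| = 2.8 exactly (bisection on the grid interval)
  solve_t2 <- function(t1) {
    f <- function(t2) vlen(place_ligand(t1, t2, 180, 0)[2, ] - cb) - 2.8
    grid <- seq(-180, 180, by = 5)
    vals <- vapply(grid, f, 0)
    sgn <- which(diff(sign(vals)) != 0)
    if (length(sgn) == 0) return(grid[which.min(abs(vals))])
    lo <- grid[sgn[1]]; hi <- grid[sgn[1] + 1]
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  objective <- function(xyz) {
    pen <- 0
    heavy <- xyz[1:5, , drop = FALSE]
    dmin <- sqrt(cross_dist2(heavy, pro_xyz))
    # exclude the anchoring SG/CB contacts from the clash check
    near_anchor <- which(at$name[heavy_pro] %in% c("SG", "CB") &
                           at$resno[heavy_pro] == cys$resno)
    dmin[, near_anchor] <- Inf
    pen <- pen + sum(pmax(0, 2.9 - dmin)^2) * 10
    if (!is.null(donor_xyz)) {
      dda <- vlen(xyz[4, ] - donor_xyz)
      pen <- pen + 30 * (dda - hb$distance)^2
      ang <- max(vapply(donor_h, function(h) {
        bond_angle(donor_xyz, as.numeric(at[h, c("x", "y", "z")]), xyz[4, ])
      }, 0))
      pen <- pen + 0.02 * max(0, hb$angle - ang)^2
      # keep the polar ligand atoms away from everything except the donor
      polar <- which(at$element[heavy_pro] %in% c("N", "O"))
      polar <- polar[!(heavy_pro[polar] %in% c(donor_idx))]
      dpol <- sqrt(cross_dist2(xyz[4:5, , drop = FALSE],
                               pro_xyz[polar, , drop = FALSE]))
      pen <- pen + sum(pmax(0, 4.4 - dpol)^2) * 0.5
    } else {
      # negative-control / plain placements: keep polar atoms unbonded
      polar <- which(at$element[heavy_pro] %in% c("N", "O"))
      dpol <- sqrt(cross_dist2(xyz[4:5, , drop = FALSE],
                               pro_xyz[polar, , drop = FALSE]))
      pen <- pen + sum(pmax(0, 4.4 - dpol)^2) * 0.5
    }
    pen
  }

  best <- NULL
  for (t1 in seq(-180, 150, by = 30)) {
    t2 <- solve_t2(t1)
    for (t3 in seq(-180, 150, by = 30)) {
      for (t4 in seq(-180, 120, by = 60)) {
        xyz <- place_ligand(t1, t2, t3, t4)
        sc <- objective(xyz)
        if (is.null(best) || sc < best$sc)
          best <- list(sc = sc, par = c(t1, t3, t4), t2 = t2)
      }
    }
  }
  fit <- stats::optim(best$par, function(p) {
    objective(place_ligand(p[1], solve_t2(p[1]), p[2], p[3]))
  }, method = "Nelder-Mead", control = list(maxit = 200))
  xyz <- place_ligand(fit$par[1], solve_t2(fit$par[1]), fit$par[2], fit$par[3])

  if (!is.null(hb)) {
    dda <- vlen(xyz[4, ] - donor_xyz)
    if (abs(dda - hb$distance) > 0.25)
      stop("infeasible planted geometry: requested donor-acceptor distance ",
           hb$distance, " A not achievable (best ", round(dda, 2), " A)")
  }
  pose <- acr_pose(xyz, index = 1L)
  gt <- if (is.null(hb)) {
    data.frame(donor_resno = integer(0), ligand_group = character(0),
               distance = numeric(0))
  } else {
    data.frame(donor_resno = donor_res, ligand_group = "carbonyl",
               distance = vlen(xyz[4, ] - donor_xyz))
  }
  list(structure = s, pose = pose, template = template, ground_truth = gt,
       cys = cys)
}

#' Fixture with two free cysteines sharing one groove
#'
#' A helix-pair pocket carrying a second cysteine across the groove, with a
#' Calpha-Calpha separation of 7.1 +/- 0.3 A — the geometry in which two
#' adducts can compete for one pocket and multibody docking applies.
#'
#' @param seed integer seed.
#' @return an [acr_structure()]; attribute `pocket_info$cys2` names the
#'   second cysteine.
#' @export
make_paired_site_fixture <- function(seed = 1) {
  spec <- pocket_spec("helix-pair", "neutral", n_flank = 0, seed = seed)
  s <- generate_pocket(spec)
  info <- attr(s, "pocket_info")
  # second cysteine: the scaffold position across the groove whose CA sits
  # closest to 7.1 A from the first cysteine's CA
  ca1 <- as.numeric(s$atoms[atom_index(s, "A", info$cys$resno, "CA"),
                            c("x", "y", "z")])
  cand <- setdiff(seq_len(max(s$atoms$resno)), info$cys$resno)
  dd <- vapply(cand, function(i) {
    vlen(as.numeric(s$atoms[atom_index(s, "A", i, "CA"), c("x", "y", "z")]) - ca1)
  }, 0)
  pick <- cand[which.min(abs(dd - 7.1))]
  if (abs(dd[which.min(abs(dd - 7.1))] - 7.1) > 0.3)
    stop("no scaffold position with CA-CA distance within 7.1 +/- 0.3 A")
  # rebuild the chosen residue as CYS aimed at the first sulfur
  sg1 <- as.numeric(s$atoms[atom_index(s, "A", info$cys$resno, "SG"),
                            c("x", "y", "z")])
  geom <- pocket_geometry(spec)
  tt <- geom$torsions
  bb <- build_backbone(tt$phi, tt$psi)
  keep <- !(s$atoms$resno == pick & !(s$atoms$name %in% c("N", "CA", "C", "O")))
  at <- s$atoms[keep, , drop = FALSE]
  avoid <- as.matrix(at[abs(at$resno - pick) > 1, c("x", "y", "z")])
  fit <- aim_sidechain(bb, pick, "CYS", sg1 + c(0, 0, 0), avoid)
  if (is.null(fit)) stop("second cysteine side chain cannot be placed")
  sc <- fit$sc
  newrows <- data.frame(
    name = names(sc), element = substr(names(sc), 1, 1), resname = "CYS",
    chain = "A", resno = pick,
    x = vapply(sc, `[`, 0, 1), y = vapply(sc, `[`, 0, 2),
    z = vapply(sc, `[`, 0, 3),
    hetero = FALSE, water = FALSE, stringsAsFactors = FALSE)
  at$resname[at$resno == pick] <- "CYS"
  for (col in setdiff(names(at), names(newrows))) newrows[[col]] <- NA
  at <- rbind(at, newrows[, names(at)])
  at <- at[order(at$resno, match(at$name, c("N", "CA", "C", "O", "CB", "SG",
                                            "OG", "OG1", "CG", "CG1", "CG2",
                                            "CD", "CD1", "CD2"))), ]
  out <- acr_structure(at, source = "synthetic paired-site pocket")
  info$cys2 <- list(chain = "A", resno = pick)
  attr(out, "pocket_info") <- info
  out
}

#' Planted-site discrimination experiment
#'
#' Docks the adduct onto geometrically identical pockets differing only in
#' the planted flank family (Lys/Arg-lined vs Ala-lined) across several
#' seeds, returning the analysed-cluster score of each. A scoring function
#' sensitive to the electrostatic stabilisation of the adduct should score
#' the positively lined pocket better (more negative) in nearly every run.
#'
#' @param seeds integer vector of seeds (one docking pair per seed).
#' @param config docking configuration.
#' @param flank_types the two flank families to compare.
#' @return data frame with one row per seed and the two analysed-cluster
#'   scores.
#' @export
planted_site_discrimination <- function(seeds = 1:10,
                                        config = dock_config(),
                                        flank_types = c("positive",
                                                        "neutral")) {
  out <- lapply(seeds, function(sd) {
    scores <- vapply(flank_types, function(ft) {
      s <- generate_pocket(pocket_spec("helix-pair", ft, n_flank = 2,
                                       seed = sd))
      cfg <- config
      cfg$seed <- sd
      res <- dock_site(s, attr(s, "pocket_info")$cys, cfg)
      res$clusters[[1]]$score
    }, 0)
    data.frame(seed = sd, score_a = scores[1], score_b = scores[2])
  })
  out <- do.call(rbind, out)
  names(out) <- c("seed", paste0("score_", flank_types))
  out
}
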