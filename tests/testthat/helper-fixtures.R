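# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are built once per test run and cached in this
# environment.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# --- minimal text fixtures --------------------------------------------------

pdb_line <- function(serial, name, resname, chain, resno, xyz, occ = 1,
                     alt = "", element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0, element)
}

# three-residue Ala peptide as raw PDB text
tiny_pdb_text <- function() {
  bb <- acrydock:::build_backbone(rep(-57, 3), rep(-47, 3))
  lines <- character(0)
  serial <- 0
  for (i in 1:3) {
    for (nm in c("N", "CA", "C", "O")) {
      serial <- serial + 1
      lines <- c(lines, pdb_line(serial, nm, "ALA", "A", i, bb[[nm]][i, ]))
    }
  }
  c(lines, "END")
}

# the same three residues as a minimal mmCIF
tiny_cif_text <- function() {
  bb <- acrydock:::build_backbone(rep(-57, 3), rep(-47, 3))
  hdr <- c("data_tiny", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  rows <- character(0)
  serial <- 0
  for (i in 1:3) {
    for (nm in c("N", "CA", "C", "O")) {
      serial <- serial + 1
      x <- bb[[nm]][i, ]
      rows <- c(rows, sprintf(
        "ATOM %d %s %s . ALA A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d ALA A %s 1",
        serial, substr(nm, 1, 1), nm, i, x[1], x[2], x[3], i, nm))
    }
  }
  c(hdr, rows, "#")
}

write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# --- prepared synthetic structures (cached) ---------------------------------

pocket_positive <- function() cached("pocket_positive", {
  generate_pocket(pocket_spec("helix-pair", "positive", n_flank = 2, seed = 1))
})

pocket_prepared <- function() cached("pocket_prepared", {
  assign_parameters(add_polar_hydrogens(pocket_positive()))
})

tiny_dock_config <- function(seed = 7) {
  dock_config(n_initial = 40, n_selected = 12, anneal_steps = c(30, 30),
              rigid_min_iter = 35, local_min_iter = 30, seed = seed)
}

dock_result_small <- function() cached("dock_result_small", {
  s <- pocket_positive()
  dock_site(s, attr(s, "pocket_info")$cys, tiny_dock_config())
})

# pocket with a single planted lysine donating to the adduct carbonyl at
# known geometry (and a negative-control variant beyond the cutoff)
known_complex <- function() cached("known_complex", {
  generate_known_complex(pocket_spec("helix-pair", "positive", n_flank = 1,
                                     seed = 4,
                                     planted_hbond = list(donor_flank = 1,
                                                          distance = 2.9,
                                                          angle = 140)))
})

known_complex_far <- function() cached("known_complex_far", {
  generate_known_complex(pocket_spec("helix-pair", "positive", n_flank = 1,
                                     seed = 4,
                                     planted_hbond = list(donor_flank = 1,
                                                          distance = 4.2,
                                                          angle = 140)))
})

# --- independent oracles ----------------------------------------------------

# Monte-Carlo surface integration: random points on each expanded sphere,
# kept if outside every neighbouring expanded sphere
mc_sasa <- function(xyz, radii, probe = 1.4, n_mc = 20000) {
  expanded <- radii + probe
  out <- numeric(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    u <- matrix(stats::rnorm(3 * n_mc), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * expanded[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_mc)
    for (j in seq_len(nrow(xyz))[-i]) {
      d2 <- rowSums(sweep(pts, 2, xyz[j, ], "-")^2)
      free <- free & d2 > expanded[j]^2
    }
    out[i] <- 4 * pi * expanded[i]^2 * mean(free)
  }
  out
}

# brute-force H-bond enumeration over every donor-H/acceptor combination,
# written against the published geometric definitions only
brute_hbonds <- function(atoms, dist_cutoff = 4.1, angle_cutoff = 100) {
  idx <- seq_len(nrow(atoms))
  has_h <- idx %in% atoms$h_parent
  hs <- idx[atoms$element == "H" & !is.na(atoms$h_parent) & !atoms$water]
  acc <- idx[!atoms$water &
               (atoms$element %in% c("O", "S") |
                  (atoms$element == "N" & !has_h & atoms$name != "N"))]
  hits <- list()
  for (h in hs) {
    d <- atoms$h_parent[h]
    for (a in acc) {
      if (a == d || a == h) next
      dv <- as.numeric(atoms[d, c("x", "y", "z")])
      hv <- as.numeric(atoms[h, c("x", "y", "z")])
      av <- as.numeric(atoms[a, c("x", "y", "z")])
      dda <- sqrt(sum((dv - av)^2))
      if (dda > dist_cutoff) next
      v1 <- dv - hv; v2 <- av - hv
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= angle_cutoff)
        hits[[length(hits) + 1]] <- c(donor = d, hydrogen = h, acceptor = a)
    }
  }
  if (length(hits) == 0)
    return(matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("donor", "hydrogen", "acceptor"))))
  do.call(rbind, hits)
}

# brute-force hydrophobic contact enumeration
brute_hydrophobic <- function(atoms, lig_idx, lig_carbons,
                              dist_cutoff = 4.0, charge_thresh = 0.15) {
  pro_c <- setdiff(which(atoms$element == "C" & !atoms$water &
                           abs(atoms$charge) < charge_thresh), lig_idx)
  hits <- list()
  for (lc in lig_carbons) {
    for (pc in pro_c) {
      d <- sqrt(sum((as.numeric(atoms[lc, c("x", "y", "z")]) -
                       as.numeric(atoms[pc, c("x", "y", "z")]))^2))
      if (d <= dist_cutoff)
        hits[[length(hits) + 1]] <- c(lig = lc, pro = pc)
    }
  }
  if (length(hits) == 0)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("lig", "pro"))))
  do.call(rbind, hits)
}

# random protein-fragment + adduct-pose complex for detector oracle tests
random_complex <- function(seed) {
  set.seed(seed)
  tpl <- build_adduct_template()
  n_pro <- sample(6:14, 1)
  resnames <- sample(c("ALA", "SER", "LYS", "ASP", "LEU"), n_pro, replace = TRUE)
  names_pool <- list(C = c("CB", "CG", "C"), N = c("N", "ND2", "NZ"),
                     O = c("O", "OG", "OD1"))
  rows <- list()
  for (i in seq_len(n_pro)) {
    el <- sample(c("C", "N", "O"), 1, prob = c(0.5, 0.25, 0.25))
    nm <- sample(names_pool[[el]], 1)
    rows[[i]] <- data.frame(
      name = nm, element = el, resname = resnames[i], chain = "A",
      resno = i, x = runif(1, -6, 6), y = runif(1, -6, 6),
      z = runif(1, -6, 6), hetero = FALSE, water = FALSE,
      charge = round(runif(1, -0.6, 0.6), 2), rmin = 1.9, eps = 0.1,
      sigma_solv = 0, is_polar_h = FALSE, h_parent = NA_integer_,
      stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  # attach hydrogens to some N/O heavy atoms
  polar <- which(at$element %in% c("N", "O"))
  for (p in polar[runif(length(polar)) < 0.6]) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    at <- rbind(at, data.frame(
      name = paste0("H", at$name[p]), element = "H", resname = at$resname[p],
      chain = "A", resno = at$resno[p],
      x = at$x[p] + u[1], y = at$y[p] + u[2], z = at$z[p] + u[3],
      hetero = FALSE, water = FALSE, charge = 0.3, rmin = 0.2245, eps = 0.046,
      sigma_solv = 0, is_polar_h = TRUE, h_parent = p,
      stringsAsFactors = FALSE))
  }
  s <- acr_structure(at, source = "random fixture")
  attr(s, "hydrogens_added") <- TRUE
  attr(s, "parameters_assigned") <- TRUE
  R <- acrydock:::random_rotation()
  xyz <- acrydock:::template_xyz(tpl) %*% t(R)
  xyz <- sweep(xyz, 2, runif(3, -3, 3), "+")
  pose <- acrydock:::acr_pose(xyz, index = 1L)
  list(s = s, pose = pose, template = tpl)
}
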