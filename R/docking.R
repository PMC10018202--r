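# Restraint-based covalent docking of the propionamide adduct: rigid-body
# pose generation around the reactive sulfur, selection, Metropolis
# Monte-Carlo annealing over ligand rigid-body/torsional and protein
# side-chain degrees of freedom, local minimisation, and scoring.

#' Docking configuration
#'
#' @param n_initial rigid-body poses generated in stage 1.
#' @param n_selected best-scored poses carried into refinement.
#' @param cluster_cutoff interface-ligand RMSD clustering cutoff (Angstrom).
#' @param restraint_k covalent-restraint force constant (kcal/mol/A^2).
#' @param anneal list of two `c(T_start, T_end)` temperature ramps (K): a
#'   hot stage and a cooler stage, mirroring a two-step annealing schedule.
#' @param anneal_steps Monte-Carlo steps per stage.
#' @param rigid_min_iter,local_min_iter Nelder-Mead iterations for the
#'   rigid-body minimisation of initial poses and the post-annealing local
#'   minimisation.
#' @param elec_cutoff nonbonded cutoff (Angstrom) for LJ and Coulomb terms.
#' @param vdw_ceiling per-pair LJ cap for overlapping atoms (kcal/mol).
#' @param sasa_points_dock sphere-sampling density for the desolvation term
#'   during docking.
#' @param probe_radius solvent probe radius (Angstrom).
#' @param flip_fraction fraction of initial poses additionally rotated 180
#'   degrees about the S-C axis (the symmetry-flip orientation class).
#' @param donor_bias_fraction fraction of initial poses spun about the S-C
#'   axis so the carbonyl oxygen faces a randomly chosen nearby polar
#'   hydrogen (hydrogen-bond-biased orientation class).
#' @param flexible_radius protein residues with side-chain atoms within
#'   this distance of the ligand become torsionally flexible (Angstrom).
#' @param score_window secondary sites must score within this window of the
#'   primary site (a.u.); used by [rank_sites()].
#' @param seed integer seed; every random draw of a docking run derives
#'   from it, making results bit-reproducible.
#' @return list of class `acr_dock_config`.
#' @export
dock_config <- function(n_initial = 1000, n_selected = 200,
                        cluster_cutoff = 1.0, restraint_k = 50,
                        anneal = list(c(500, 50), c(300, 50)),
                        anneal_steps = c(100, 100),
                        rigid_min_iter = 60, local_min_iter = 40,
                        elec_cutoff = 8.5, vdw_ceiling = 1000,
                        sasa_points_dock = 120, probe_radius = 1.4,
                        flip_fraction = 0.5, donor_bias_fraction = 0.5,
                        flexible_radius = 5,
                        score_window = 5, seed = 1) {
  structure(as.list(environment()), class = "acr_dock_config")
}

#' A docked pose
#' @noRd
acr_pose <- function(xyz, index, ncopy = 1L, moved_protein = NULL,
                     energy = NULL, violations = NULL) {
  structure(list(xyz = xyz, index = index, ncopy = ncopy,
                 moved_protein = moved_protein, energy = energy,
                 violations = violations),
            class = "acr_pose")
}

n_ligand_copies <- function(pose) pose$ncopy

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# ---------------------------------------------------------------------------
# docking context: precomputed arrays for one protein + one or two sites

greek_rank <- function(name) {
  pos <- substr(gsub("[0-9]", "", name), 2, 2)
  m <- c(A = 0, B = 1, G = 2, D = 3, E = 4, Z = 5, H = 6)
  r <- unname(m[pos])
  r[is.na(r)] <- 0
  r
}

prepare_for_docking <- function(s) {
  if (!isTRUE(attr(s, "hydrogens_added"))) s <- add_polar_hydrogens(s)
  if (!isTRUE(attr(s, "parameters_assigned"))) s <- assign_parameters(s)
  s
}

dock_context <- function(s, sites, template, config) {
  s <- prepare_for_docking(s)
  keys <- vapply(sites, function(x) paste(x$chain, x$resno, sep = ":"), "")
  if (anyDuplicated(keys))
    stop("the same cysteine was passed twice: ", keys[duplicated(keys)][1])
  dep <- deprotonated_keys(s)
  for (k in seq_along(sites)) {
    if (!(keys[k] %in% dep))
      stop("cysteine ", keys[k], " is not modelled as deprotonated; ",
           "run add_polar_hydrogens() with it listed in `deprotonate`")
    s <- scale_sulfur_vdw(s, sites[[k]]$chain, sites[[k]]$resno)
  }

  rows <- which(!s$atoms$water)
  at <- s$atoms[rows, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])

  sg <- vapply(sites, function(x)
    match(atom_index(s, x$chain, x$resno, "SG"), rows), 0L)
  cb <- vapply(sites, function(x)
    match(atom_index(s, x$chain, x$resno, "CB"), rows), 0L)

  restraints <- do.call(rbind, lapply(seq_along(sites), function(k) {
    r <- make_covalent_restraints(s, sites[[k]]$chain, sites[[k]]$resno,
                                  template, config$restraint_k, copy = k)
    r$protein_atom <- match(r$protein_atom, rows)
    r
  }))

  # protein atoms that can interact with any ligand placement
  reach <- config$elec_cutoff + 7
  d2 <- cross_dist2(xyz, xyz[sg, , drop = FALSE])
  near <- which(sqrt(do.call(pmin, as.data.frame(d2))) <= reach)

  lt <- template$atoms
  nat <- nrow(lt)
  ncopy <- length(sites)
  np <- config$sasa_points_dock
  lig_sasa0 <- sasa_points(template_xyz(template), lt$rmin,
                           config$probe_radius, np)

  # the restrained Sgamma/Cbeta form the covalent attachment of their
  # ligand copy: like any bonded pair they are excluded from nonbonded
  # terms with that copy (the restraints represent the bond)
  excl <- lapply(seq_along(sites), function(k) c(sg[k], cb[k]))

  list(
    s = s, rows = rows, at = at, xyz = xyz,
    q = at$charge, rmin = at$rmin, eps = at$eps, sigma = at$sigma_solv,
    sasa0 = sasa_points(xyz, at$rmin, config$probe_radius, np),
    near = near, sg = sg, cb = cb, excl = excl,
    site_keys = keys, sites = sites,
    template = template, nat = nat, ncopy = ncopy,
    lq = rep(lt$charge, ncopy), lrmin = rep(lt$rmin, ncopy),
    leps = rep(lt$eps, ncopy), lsigma = rep(lt$sigma_solv, ncopy),
    lig_sasa0 = rep(lig_sasa0, ncopy),
    lig_heavy = rep(lt$element != "H", ncopy),
    restraints = restraints, config = config
  )
}

copy_rows <- function(ctx, k) (k - 1) * ctx$nat + seq_len(ctx$nat)

# cheap objective used by minimisation and Monte-Carlo moves: LJ + weighted
# Coulomb + full-strength restraint energy (+ side-chain clash guard)
protein_ligand_pairs <- function(ctx, lig_xyz, pro_xyz) {
  evdw <- 0; eelec <- 0; capped <- FALSE
  for (k in seq_len(ctx$ncopy)) {
    nr <- setdiff(ctx$near, ctx$excl[[k]])
    rk <- copy_rows(ctx, k)
    pe <- pair_energies(lig_xyz[rk, , drop = FALSE], ctx$lq[rk],
                        ctx$lrmin[rk], ctx$leps[rk],
                        pro_xyz[nr, , drop = FALSE], ctx$q[nr], ctx$rmin[nr],
                        ctx$eps[nr], cutoff = ctx$config$elec_cutoff,
                        vdw_ceiling = ctx$config$vdw_ceiling)
    evdw <- evdw + pe$evdw
    eelec <- eelec + pe$eelec
    capped <- capped || pe$capped
  }
  list(evdw = evdw, eelec = eelec, capped = capped)
}

cheap_energy <- function(ctx, lig_xyz, pro_xyz = ctx$xyz,
                         clash_rows = NULL, restraints = ctx$restraints) {
  pe <- protein_ligand_pairs(ctx, lig_xyz, pro_xyz)
  e <- pe$evdw + 0.1 * pe$eelec
  if (ctx$ncopy > 1) {
    r1 <- copy_rows(ctx, 1); r2 <- copy_rows(ctx, 2)
    ll <- pair_energies(lig_xyz[r1, ], ctx$lq[r1], ctx$lrmin[r1], ctx$leps[r1],
                        lig_xyz[r2, ], ctx$lq[r2], ctx$lrmin[r2], ctx$leps[r2],
                        cutoff = ctx$config$elec_cutoff,
                        vdw_ceiling = ctx$config$vdw_ceiling)
    e <- e + ll$evdw + 0.1 * ll$eelec
  }
  e <- e + restraint_energy(restraints, pro_xyz, lig_xyz)
  if (!is.null(clash_rows) && length(clash_rows) > 0)
    e <- e + clash_penalty(ctx, pro_xyz, clash_rows)
  e
}

# soft steric guard for moved side-chain atoms against the rest of the protein
clash_penalty <- function(ctx, pro_xyz, moved_rows) {
  other <- setdiff(ctx$near, moved_rows)
  own <- residue_key(ctx$at[moved_rows, , drop = FALSE])
  pen <- 0
  d <- sqrt(cross_dist2(pro_xyz[moved_rows, , drop = FALSE],
                        pro_xyz[other, , drop = FALSE]))
  lim <- 0.7 * outer(ctx$rmin[moved_rows], ctx$rmin[other], "+")
  same <- outer(own, residue_key(ctx$at[other, , drop = FALSE]), "==")
  bad <- d < lim & !same
  if (any(bad)) pen <- sum(10 * (lim[bad] - d[bad])^2)
  pen
}

# full scored breakdown (adds the SASA desolvation term)
full_breakdown <- function(ctx, lig_xyz, pro_xyz = ctx$xyz) {
  pe <- protein_ligand_pairs(ctx, lig_xyz, pro_xyz)
  evdw <- pe$evdw; eelec <- pe$eelec; capped <- pe$capped
  ll_evdw <- 0
  if (ctx$ncopy > 1) {
    r1 <- copy_rows(ctx, 1); r2 <- copy_rows(ctx, 2)
    ll <- pair_energies(lig_xyz[r1, ], ctx$lq[r1], ctx$lrmin[r1], ctx$leps[r1],
                        lig_xyz[r2, ], ctx$lq[r2], ctx$lrmin[r2], ctx$leps[r2],
                        cutoff = ctx$config$elec_cutoff,
                        vdw_ceiling = ctx$config$vdw_ceiling)
    evdw <- evdw + ll$evdw
    eelec <- eelec + ll$eelec
    ll_evdw <- ll$evdw
    capped <- capped || ll$capped
  }
  edesol <- desolvation_energy(pro_xyz, ctx$rmin, ctx$sigma, ctx$sasa0,
                               lig_xyz, ctx$lrmin, ctx$lsigma, ctx$lig_sasa0,
                               probe = ctx$config$probe_radius,
                               n_points = ctx$config$sasa_points_dock)
  eair <- restraint_energy(ctx$restraints, pro_xyz, lig_xyz)
  eb <- energy_breakdown(evdw, eelec, edesol, eair, vdw_capped = capped)
  eb$ligand_ligand_evdw <- ll_evdw
  eb
}

#' Score a docked pose
#'
#' Computes the four energy components — intermolecular 12-6 Lennard-Jones,
#' Coulomb electrostatics in a distance-dependent dielectric with an 8.5 A
#' cutoff, SASA-based desolvation, and flat-bottom restraint energy — and
#' the weighted composite.
#'
#' @param s prepared structure (or the structure used to build `pose`).
#' @param pose an `acr_pose`.
#' @param restraints restraint table from [make_covalent_restraints()];
#'   used to (re)build the context when `sites` are not given.
#' @param sites list of site specifications `list(chain =, resno =)`.
#' @param template adduct template.
#' @param config docking configuration.
#' @return an [energy_breakdown()].
#' @export
score_pose <- function(s, pose, restraints = NULL, sites = NULL,
                       template = build_adduct_template(),
                       config = dock_config()) {
  if (is.null(sites)) {
    if (is.null(restraints)) stop("either `sites` or `restraints` required")
    sgrow <- restraints$protein_atom[restraints$target == 1.8]
    sites <- lapply(sgrow, function(i)
      list(chain = s$atoms$chain[i], resno = s$atoms$resno[i]))
  }
  ctx <- dock_context(s, sites, template, config)
  pro <- ctx$xyz
  if (!is.null(pose$moved_protein)) {
    m <- match(pose$moved_protein$index, ctx$rows)
    pro[m, ] <- pose$moved_protein$xyz
  }
  full_breakdown(ctx, pose$xyz, pro)
}

# ---------------------------------------------------------------------------
# stage 1: rigid-body generation

apply_rigid <- function(xyz, p, center) {
  ang <- sqrt(sum(p[4:6]^2))
  out <- if (ang > 1e-9)
    rotate_about(xyz, center, p[4:6], rad2deg(ang)) else xyz
  sweep(out, 2, p[1:3], "+")
}

gen_poses_ctx <- function(ctx, n) {
  cfg <- ctx$config
  center <- colMeans(ctx$xyz)
  poses <- vector("list", n)
  base <- sweep(template_xyz(ctx$template), 2,
                template_xyz(ctx$template)[ctx$template$reactive_carbon, ], "-")
  for (i in seq_len(n)) {
    lig <- matrix(0, ctx$nat * ctx$ncopy, 3)
    for (k in seq_len(ctx$ncopy)) {
      sgx <- ctx$xyz[ctx$sg[k], ]
      outdir <- unitv(sgx - center)
      u <- unitv(outdir + 0.9 * stats::rnorm(3))
      c1 <- sgx + 1.8 * u
      xyz <- sweep(base %*% t(random_rotation()), 2, c1, "+")
      if (stats::runif(1) < cfg$flip_fraction)
        xyz <- rotate_about(xyz, c1, u, 180)
      # donor-biased orientation class: part of the poses spin about the
      # S-C axis so the carbonyl oxygen faces a nearby polar hydrogen
      if (stats::runif(1) < cfg$donor_bias_fraction) {
        ph <- which(ctx$at$is_polar_h)
        if (length(ph) > 0) {
          dd <- sqrt(rowSums(sweep(ctx$xyz[ph, , drop = FALSE], 2, sgx,
                                   "-")^2))
          cand <- ph[dd <= 7]
          if (length(cand) > 0) {
            hx <- ctx$xyz[cand[sample.int(length(cand), 1)], ]
            o_idx <- ctx$template$carbonyl_oxygen
            spin <- seq(0, 345, by = 15)
            dbest <- vapply(spin, function(a)
              vlen(rotate_about(xyz, c1, u, a)[o_idx, ] - hx), 0)
            xyz <- rotate_about(xyz, c1, u, spin[which.min(dbest)])
          }
        }
      }
      # rigid-body minimisation of this copy against the protein
      rsub <- ctx$restraints[ctx$restraints$ligand_atom %in% copy_rows(ctx, k), ]
      rsub$ligand_atom <- rsub$ligand_atom - (k - 1) * ctx$nat
      nr <- setdiff(ctx$near, ctx$excl[[k]])
      rk <- copy_rows(ctx, k)
      obj <- function(p) {
        moved <- apply_rigid(xyz, p, c1)
        pe <- pair_energies(moved, ctx$lq[rk], ctx$lrmin[rk], ctx$leps[rk],
                            ctx$xyz[nr, , drop = FALSE],
                            ctx$q[nr], ctx$rmin[nr],
                            ctx$eps[nr], cutoff = cfg$elec_cutoff,
                            vdw_ceiling = cfg$vdw_ceiling)
        pe$evdw + 0.1 * pe$eelec +
          restraint_energy(rsub, ctx$xyz, moved)
      }
      fit <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                          control = list(maxit = cfg$rigid_min_iter))
      lig[copy_rows(ctx, k), ] <- apply_rigid(xyz, fit$par, c1)
    }
    p <- acr_pose(lig, index = i, ncopy = ctx$ncopy)
    p$energy <- full_breakdown(ctx, lig)
    p$violations <- restraint_violations(ctx$restraints, ctx$xyz, lig)
    poses[[i]] <- p
  }
  if (!any(vapply(poses, function(p) p$energy$eair < 10, TRUE)))
    warning("no pose satisfies the covalent restraints well; ",
            "the sulfur may be sterically inaccessible")
  poses
}

#' Generate rigid-body starting poses around a reactive cysteine
#'
#' Places the adduct's reactive carbon on the restraint-satisfying shell
#' around Sgamma with random orientations (including a 180-degree flipped
#' orientation class) and rigid-body minimises each placement against the
#' protein. Deterministic for a fixed seed.
#'
#' @param s structure (prepared automatically if needed).
#' @param cys site specification `list(chain =, resno =)`.
#' @param template adduct template.
#' @param n number of poses.
#' @param seed RNG seed.
#' @param config docking configuration.
#' @return list of `acr_pose` objects, scored.
#' @export
generate_rigid_poses <- function(s, cys, template = build_adduct_template(),
                                 n = 1000, seed = 1,
                                 config = dock_config()) {
  ctx <- dock_context(s, list(cys), template, config)
  with_seed(seed, gen_poses_ctx(ctx, n))
}

#' Select the best-scored poses
#'
#' @param poses scored pose list.
#' @param k number to keep (by composite score, ties broken by pose index).
#' @return the `k` best poses.
#' @export
select_top <- function(poses, k = 200) {
  if (k > length(poses)) {
    warning("k exceeds the number of poses; returning all")
    k <- length(poses)
  }
  sc <- vapply(poses, function(p) p$energy$composite, 0)
  idx <- vapply(poses, function(p) p$index, 0L)
  poses[order(sc, idx)[seq_len(k)]]
}

# ---------------------------------------------------------------------------
# stage 2: Metropolis annealing + local minimisation

flexible_residues <- function(ctx, lig_xyz) {
  cfg <- ctx$config
  at <- ctx$at
  side <- which(!(at$name %in% backbone_names) & at$element != "H" &
                  !at$hetero)
  if (length(side) == 0) return(list())
  d <- sqrt(do.call(pmin, as.data.frame(
    cross_dist2(ctx$xyz[side, , drop = FALSE], lig_xyz))))
  keys <- residue_key(at[side, , drop = FALSE])
  hit <- unique(keys[d <= cfg$flexible_radius])
  hit <- setdiff(hit, ctx$site_keys)
  out <- list()
  allkeys <- residue_key(at)
  for (k in hit) {
    rows <- which(allkeys == k)
    sc <- rows[!(at$name[rows] %in% backbone_names)]
    ranks <- greek_rank(at$name[sc])
    heavy <- sc[at$element[sc] != "H"]
    if (sum(greek_rank(at$name[heavy]) > 1) == 0) next  # nothing beyond CB
    ca <- rows[at$name[rows] == "CA"]
    cb <- sc[at$name[sc] == "CB" & at$element[sc] != "H"]
    cg <- sc[greek_rank(at$name[sc]) == 2 & at$element[sc] != "H"]
    axes <- list(list(from = ca[1], to = cb[1],
                      moving = sc[ranks > 1]))
    if (length(cg) == 1 && sum(greek_rank(at$name[heavy]) > 2) > 0)
      axes <- c(axes, list(list(from = cb[1], to = cg[1],
                                moving = sc[ranks > 2])))
    out[[k]] <- list(key = k, rows = sc, axes = axes)
  }
  out
}

anneal_pose <- function(ctx, pose) {
  cfg <- ctx$config
  lig <- pose$xyz
  pro <- ctx$xyz
  flex <- flexible_residues(ctx, lig)
  moved_rows <- unique(unlist(lapply(flex, `[[`, "rows")))

  e_cheap <- cheap_energy(ctx, lig, pro, moved_rows)
  best <- list(lig = lig, pro = pro,
               full = full_breakdown(ctx, lig, pro))

  temps <- unlist(lapply(seq_along(cfg$anneal), function(st) {
    seq(cfg$anneal[[st]][1], cfg$anneal[[st]][2],
        length.out = cfg$anneal_steps[st])
  }))
  stage_end <- cumsum(cfg$anneal_steps)

  n_move_types <- if (length(flex) > 0) 4 else 3
  for (step in seq_along(temps)) {
    kt <- BOLTZMANN_KCAL * temps[step]
    mt <- sample.int(n_move_types, 1)
    k <- if (ctx$ncopy > 1) sample.int(ctx$ncopy, 1) else 1L
    rows_k <- copy_rows(ctx, k)
    lig2 <- lig; pro2 <- pro
    if (mt == 1) {
      lig2[rows_k, ] <- sweep(lig[rows_k, , drop = FALSE], 2,
                              stats::rnorm(3, sd = 0.25), "+")
    } else if (mt == 2) {
      cen <- colMeans(lig[rows_k, , drop = FALSE])
      lig2[rows_k, ] <- rotate_about(lig[rows_k, , drop = FALSE], cen,
                                     stats::rnorm(3), stats::rnorm(1, sd = 12))
    } else if (mt == 3) {
      tor <- ctx$template$rotatable_torsions[[
        sample.int(length(ctx$template$rotatable_torsions), 1)]]
      a <- lig[rows_k[tor$axis[1]], ]
      b <- lig[rows_k[tor$axis[2]], ]
      mv <- rows_k[tor$moving]
      lig2[mv, ] <- rotate_about(lig[mv, , drop = FALSE], a, b - a,
                                 stats::rnorm(1, sd = 30))
    } else {
      fr <- flex[[sample.int(length(flex), 1)]]
      ax <- fr$axes[[sample.int(length(fr$axes), 1)]]
      a <- pro[ax$from, ]
      b <- pro[ax$to, ]
      pro2[ax$moving, ] <- rotate_about(pro[ax$moving, , drop = FALSE], a,
                                        b - a, stats::rnorm(1, sd = 30))
    }
    e2 <- cheap_energy(ctx, lig2, pro2, moved_rows)
    if (e2 <= e_cheap || stats::runif(1) < exp(-(e2 - e_cheap) / kt)) {
      lig <- lig2; pro <- pro2; e_cheap <- e2
    }
    if (step %in% stage_end) {
      fb <- full_breakdown(ctx, lig, pro)
      if (fb$composite < best$full$composite)
        best <- list(lig = lig, pro = pro, full = fb)
    }
  }

  # local rigid + torsion minimisation (side chains held)
  for (k in seq_len(ctx$ncopy)) {
    rows_k <- copy_rows(ctx, k)
    cen <- colMeans(lig[rows_k, , drop = FALSE])
    obj <- function(p) {
      l2 <- lig
      block <- apply_rigid(lig[rows_k, , drop = FALSE], p[1:6], cen)
      for (ti in seq_along(ctx$template$rotatable_torsions)) {
        tor <- ctx$template$rotatable_torsions[[ti]]
        a <- block[tor$axis[1], ]; b <- block[tor$axis[2], ]
        block[tor$moving, ] <- rotate_about(
          block[tor$moving, , drop = FALSE], a, b - a, p[6 + ti])
      }
      l2[rows_k, ] <- block
      cheap_energy(ctx, l2, pro, moved_rows)
    }
    np <- 6 + length(ctx$template$rotatable_torsions)
    fit <- stats::optim(rep(0, np), obj, method = "Nelder-Mead",
                        control = list(maxit = cfg$local_min_iter))
    block <- apply_rigid(lig[rows_k, , drop = FALSE], fit$par[1:6], cen)
    for (ti in seq_along(ctx$template$rotatable_torsions)) {
      tor <- ctx$template$rotatable_torsions[[ti]]
      a <- block[tor$axis[1], ]; b <- block[tor$axis[2], ]
      block[tor$moving, ] <- rotate_about(block[tor$moving, , drop = FALSE],
                                          a, b - a, fit$par[6 + ti])
    }
    lig[rows_k, ] <- block
  }
  fb <- full_breakdown(ctx, lig, pro)
  if (fb$composite < best$full$composite)
    best <- list(lig = lig, pro = pro, full = fb)

  moved <- best$pro
  changed <- which(rowSums(abs(moved - ctx$xyz)) > 1e-12)
  out <- acr_pose(best$lig, index = pose$index, ncopy = ctx$ncopy)
  out$energy <- best$full
  out$violations <- restraint_violations(ctx$restraints, moved, best$lig)
  if (length(changed) > 0)
    out$moved_protein <- list(index = ctx$rows[changed],
                              xyz = moved[changed, , drop = FALSE])
  out
}

#' Refine poses by simulated annealing in torsion/rigid-body space
#'
#' Per pose: Metropolis Monte-Carlo over ligand rigid-body motion, ligand
#' torsions and side-chain torsions of protein residues within the
#' flexibility radius of the ligand (the backbone stays fixed), over a hot
#' and a cool temperature ramp, followed by local minimisation. The
#' best-scored configuration encountered (by full composite score) is kept,
#' so a refined pose never scores worse than its start.
#'
#' @param s structure.
#' @param poses pose list (typically from [select_top()]).
#' @param cys site specification; `sites` for multibody refinement.
#' @param template adduct template.
#' @param seed RNG seed.
#' @param config docking configuration (the `anneal` / `anneal_steps`
#'   entries are the schedule).
#' @return list of refined poses.
#' @export
refine_poses <- function(s, poses, cys, template = build_adduct_template(),
                         seed = 1, config = dock_config()) {
  sites <- if (!is.null(cys$chain)) list(cys) else cys
  ctx <- dock_context(s, sites, template, config)
  with_seed(seed, lapply(poses, function(p) anneal_pose(ctx, p)))
}

# ---------------------------------------------------------------------------
# full pipeline

#' Dock the acrylamide adduct onto one cysteine
#'
#' Runs the full pipeline: rigid-body generation, selection of the
#' best-scored poses, Monte-Carlo refinement, clustering by
#' interface-ligand RMSD, and cluster scoring as the mean of each cluster's
#' four best members. Clusters whose score lies within the standard
#' deviation of the top cluster (computed over the top cluster's four best
#' member scores) are marked for interaction analysis.
#'
#' @param s structure; hydrogens/parameters are added automatically, with
#'   free cysteines modelled deprotonated.
#' @param cys site specification `list(chain =, resno =)`.
#' @param config docking configuration ([dock_config()]); `config$seed`
#'   drives all randomness.
#' @param template adduct template.
#' @return object of class `acr_docking_result`: site, ordered
#'   `clusters`, indices of `analyzed` clusters, the seed and config, the
#'   prepared structure and the template.
#' @export
dock_site <- function(s, cys, config = dock_config(),
                      template = build_adduct_template()) {
  dock_core(s, list(cys), config, template)
}

#' Dock two adducts simultaneously onto two nearby cysteines
#'
#' Multibody mode: one ligand copy per site, each with its own covalent
#' restraints; the interaction matrix covers protein-ligand-1,
#' protein-ligand-2 and ligand-1-ligand-2 pairs, so steric competition
#' between the two adducts shows up as positive ligand-ligand vdW energy.
#' With a single site this reduces exactly to [dock_site()].
#'
#' @param s structure.
#' @param sites list of site specifications (typically two).
#' @param config docking configuration.
#' @param template adduct template.
#' @return an `acr_docking_result` whose poses hold both ligand copies.
#' @export
dock_multibody <- function(s, sites, config = dock_config(),
                           template = build_adduct_template()) {
  dock_core(s, sites, config, template)
}

dock_core <- function(s, sites, config, template) {
  s <- prepare_for_docking(s)
  ctx <- dock_context(s, sites, template, config)
  result <- with_seed(config$seed, {
    poses <- gen_poses_ctx(ctx, config$n_initial)
    sel <- select_top(poses, min(config$n_selected, length(poses)))
    refined <- lapply(sel, function(p) anneal_pose(ctx, p))
    refined
  })
  clusters <- cluster_poses(result, cutoff = config$cluster_cutoff,
                            s = ctx$s, template = template)
  if (length(clusters) == 0) stop("clustering produced zero clusters")
  scores <- vapply(clusters, `[[`, 0, "score")
  top_sd <- clusters[[1]]$sd_top
  analyzed <- which(scores <= scores[1] + top_sd + 1e-9)
  structure(list(
    site = ctx$site_keys,
    sites = sites,
    clusters = clusters,
    analyzed = analyzed,
    seed = config$seed,
    config = config,
    structure = ctx$s,
    template = template,
    n_refined = length(result)
  ), class = "acr_docking_result")
}

#' @export
print.acr_docking_result <- function(x, ...) {
  cat("Covalent docking result for", paste(x$site, collapse = " + "), "\n")
  cat(sprintf("  %d refined poses in %d cluster(s); %d analyzed\n",
              x$n_refined, length(x$clusters), length(x$analyzed)))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: score %8.2f a.u. (sd %.2f), size %d%s\n",
                i, cl$score, cl$sd_top, cl$size,
                if (i %in% x$analyzed) " *" else ""))
  }
  invisible(x)
}

#' Best-scored pose of the top cluster
#' @param result an `acr_docking_result`.
#' @return an `acr_pose`.
#' @export
representative_pose <- function(result) {
  result$clusters[[1]]$representative
}
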