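test_that("covalent restraints encode the S-C bond and its angular guide", {
  s <- pocket_prepared()
  tpl <- build_adduct_template()
  r <- make_covalent_restraints(s, "A", 29, tpl)
  expect_equal(nrow(r), 2)
  expect_equal(r$target, c(1.8, 2.8))
  expect_equal(r$tolerance, c(0.1, 0.1))
  # geometry satisfying both targets has zero violations
  sg <- as.numeric(s$atoms[r$protein_atom[1], c("x", "y", "z")])
  cb <- as.numeric(s$atoms[r$protein_atom[2], c("x", "y", "z")])
  lig <- acrydock:::template_xyz(tpl)
  lig <- sweep(lig, 2, lig[1, ], "-")
  dir <- unitv(sg - cb)
  lig1 <- sweep(lig, 2, sg + 1.8 * dir, "+")
  v <- restraint_violations(r, coords(s), lig1)
  expect_equal(v[1], 0)
  # S-C at 2.0 A violates the band by exactly 0.1
  lig2 <- sweep(lig, 2, sg + 2.0 * dir, "+")
  expect_equal(restraint_violations(r, coords(s), lig2)[1], 0.1,
               tolerance = 1e-9)
})

test_that("sulfur vdW scaling is 10-fold, site-scoped and idempotent", {
  s <- pocket_prepared()
  sg <- acrydock:::atom_index(s, "A", 29, "SG")
  r0 <- s$atoms$rmin[sg]
  s1 <- scale_sulfur_vdw(s, "A", 29)
  expect_equal(s1$atoms$rmin[sg], r0 / 10)
  other <- setdiff(seq_len(nrow(s$atoms)), sg)
  expect_equal(s1$atoms$rmin[other], s$atoms$rmin[other])
  s2 <- scale_sulfur_vdw(s1, "A", 29)
  expect_equal(s2$atoms$rmin[sg], r0 / 10)
})

test_that("the composite score reproduces the weighted sum exactly", {
  expect_equal(composite_score(-10, -20, -5, 2), -16.8)
  eb <- energy_breakdown(-10, -20, -5, 2)
  expect_equal(eb$composite, -16.8)
})

test_that("the Lennard-Jones term has its minimum of -eps at contact", {
  pe <- acrydock:::pair_energies(
    matrix(c(0, 0, 0), 1), 0, 1.9, 0.12,
    matrix(c(3.8, 0, 0), 1), 0, 1.9, 0.12)
  expect_equal(pe$evdw, -0.12, tolerance = 1e-9)
  expect_equal(pe$eelec, 0)
  # overlap is capped and flagged
  pe2 <- acrydock:::pair_energies(
    matrix(c(0, 0, 0), 1), 0, 1.9, 0.12,
    matrix(c(0.05, 0, 0), 1), 0, 1.9, 0.12, vdw_ceiling = 1000)
  expect_equal(pe2$evdw, 1000)
  expect_true(pe2$capped)
})

test_that("electrostatics follow the distance-dependent dielectric with cutoff", {
  pe <- acrydock:::pair_energies(
    matrix(c(0, 0, 0), 1), 0.5, 0.1, 0,
    matrix(c(4, 0, 0), 1), -0.4, 0.1, 0)
  expect_equal(pe$eelec, 332.0636 * 0.5 * -0.4 / 16, tolerance = 1e-9)
  far <- acrydock:::pair_energies(
    matrix(c(0, 0, 0), 1), 0.5, 0.1, 0,
    matrix(c(9, 0, 0), 1), -0.4, 0.1, 0)
  expect_equal(far$eelec, 0)
})

test_that("a ligand far from the protein has zero interaction terms", {
  s <- pocket_prepared()
  tpl <- build_adduct_template()
  far <- sweep(acrydock:::template_xyz(tpl), 2, c(500, 500, 500), "+")
  pose <- acrydock:::acr_pose(far, 1L)
  eb <- score_pose(s, pose, sites = list(list(chain = "A", resno = 29)))
  expect_equal(eb$evdw, 0)
  expect_equal(eb$eelec, 0)
  expect_equal(eb$edesol, 0, tolerance = 0.2)
  expect_gt(eb$eair, 0)  # restraints are of course violated out there
})

test_that("rigid pose generation is seed-deterministic and restraint-guided", {
  s <- pocket_positive()
  cfg <- tiny_dock_config()
  p1 <- generate_rigid_poses(s, list(chain = "A", resno = 29), n = 8,
                             seed = 5, config = cfg)
  p2 <- generate_rigid_poses(s, list(chain = "A", resno = 29), n = 8,
                             seed = 5, config = cfg)
  expect_equal(length(p1), 8)
  expect_identical(lapply(p1, `[[`, "xyz"), lapply(p2, `[[`, "xyz"))
  sprep <- acrydock:::prepare_for_docking(s)
  sg <- as.numeric(sprep$atoms[acrydock:::atom_index(sprep, "A", 29, "SG"),
                               c("x", "y", "z")])
  for (p in p1) {
    d <- vlen(p$xyz[1, ] - sg)
    expect_lt(d, 3)
  }
})

test_that("selection keeps the best scores with stable tie-breaking", {
  mk <- function(score, idx) {
    p <- acrydock:::acr_pose(matrix(0, 1, 3), idx)
    p$energy <- energy_breakdown(score, 0, 0, 0)
    p
  }
  poses <- list(mk(-3, 1L), mk(-1, 2L), mk(-2, 3L))
  top2 <- select_top(poses, 2)
  expect_equal(vapply(top2, function(p) p$energy$composite, 0), c(-3, -2))
  expect_warning(all3 <- select_top(poses, 5), "exceeds")
  expect_equal(length(all3), 3)
  expect_equal(length(select_top(poses, 3)), 3)
})

test_that("refinement never worsens the composite and respects the flexibility scope", {
  res <- dock_result_small()
  s <- res$structure
  cfg <- res$config
  ctx <- acrydock:::dock_context(pocket_positive(),
                                 list(list(chain = "A", resno = 29)),
                                 res$template, cfg)
  initial <- acrydock:::with_seed(3, acrydock:::gen_poses_ctx(ctx, 10))
  refined <- acrydock:::with_seed(4,
    lapply(initial, function(p) acrydock:::anneal_pose(ctx, p)))
  before <- vapply(initial, function(p) p$energy$composite, 0)
  after <- vapply(refined, function(p) p$energy$composite, 0)
  expect_true(all(after <= before + 1e-9))
  # protein movement confined to side chains within the flexibility radius
  for (p in refined) {
    if (is.null(p$moved_protein)) next
    moved <- s$atoms[p$moved_protein$index, ]
    expect_true(all(!(moved$name %in% c("N", "CA", "C", "O"))))
    lig0 <- initial[[which(vapply(initial, `[[`, 0L, "index") == p$index)]]$xyz
    dmin <- sqrt(apply(acrydock:::cross_dist2(
      as.matrix(moved[, c("x", "y", "z")]), lig0), 1, min))
    expect_true(all(dmin <= cfg$flexible_radius + 4))  # within a side-chain arm
  }
  # median restraint violation does not increase
  med_v <- function(ps) stats::median(vapply(ps, function(p) sum(p$violations), 0))
  expect_lte(med_v(refined), med_v(initial) + 1e-9)
})

test_that("clustering partitions poses and scores clusters by their top four", {
  s <- pocket_prepared()
  tpl <- build_adduct_template()
  mkpose <- function(offset, idx, score) {
    xyz <- sweep(acrydock:::template_xyz(tpl), 2, offset, "+")
    p <- acrydock:::acr_pose(xyz, idx)
    p$energy <- energy_breakdown(score, 0, 0, 0)
    p
  }
  # five identical poses form one cluster whose score is the pose score
  same <- lapply(1:5, function(i) mkpose(c(0, 0, 0), i, -2))
  cl <- cluster_poses(same, 1.0, s, tpl)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 5)
  expect_equal(cl[[1]]$score, -2)
  # two groups 5 A apart form two clusters
  grp <- c(lapply(1:3, function(i) mkpose(c(0, 0, 0), i, -1)),
           lapply(4:5, function(i) mkpose(c(5, 0, 0), i, -3)))
  cl2 <- cluster_poses(grp, 1.0, s, tpl)
  expect_length(cl2, 2)
  expect_equal(sum(vapply(cl2, `[[`, 0L, "size")), 5)
  expect_equal(cl2[[1]]$score, -3)  # best-scored cluster first
  # top-four averaging on a five-member cluster
  five <- lapply(1:5, function(i) mkpose(c(0, 0, 0), i, -i))
  cl3 <- cluster_poses(five, 1.0, s, tpl)
  expect_equal(cl3[[1]]$score, mean(c(-5, -4, -3, -2)))
})

test_that("a full docking run is bit-reproducible and carries its seed", {
  res <- dock_result_small()
  expect_s3_class(res, "acr_docking_result")
  expect_gte(length(res$clusters), 1)
  expect_equal(res$seed, tiny_dock_config()$seed)
  expect_equal(sum(vapply(res$clusters, `[[`, 0L, "size")), res$n_refined)
  s <- pocket_positive()
  res2 <- dock_site(s, attr(s, "pocket_info")$cys, tiny_dock_config())
  expect_identical(representative_pose(res)$xyz, representative_pose(res2)$xyz)
  expect_identical(vapply(res$clusters, `[[`, 0, "score"),
                   vapply(res2$clusters, `[[`, 0, "score"))
})

test_that("analysed clusters are the top cluster plus those within its spread", {
  res <- dock_result_small()
  scores <- vapply(res$clusters, `[[`, 0, "score")
  sd_top <- res$clusters[[1]]$sd_top
  expect_true(1 %in% res$analyzed)
  expect_setequal(res$analyzed, which(scores <= scores[1] + sd_top + 1e-9))
})

test_that("top-cluster poses satisfy the covalent restraints within 3x tolerance", {
  res <- dock_result_small()
  for (p in res$clusters[[1]]$poses) {
    expect_true(all(p$violations <= 2 * 0.1 + 1e-6))
  }
  expect_true(covalent_bond_formed(res))
})

test_that("multibody docking rejects a duplicated site and reduces to single-site", {
  s <- make_paired_site_fixture(1)
  info <- attr(s, "pocket_info")
  expect_error(dock_multibody(s, list(info$cys, info$cys), tiny_dock_config()),
               "twice")
  # one site through the multibody entry point equals dock_site
  r1 <- dock_site(pocket_positive(), list(chain = "A", resno = 29),
                  tiny_dock_config())
  r2 <- dock_multibody(pocket_positive(), list(list(chain = "A", resno = 29)),
                       tiny_dock_config())
  expect_equal(vapply(r1$clusters, `[[`, 0, "score"),
               vapply(r2$clusters, `[[`, 0, "score"))
})

test_that("multibody scoring is additive for well-separated sites", {
  # two copies of the same pocket translated far apart cannot interact:
  # the joint score of the combined pose equals the sum of the parts
  s <- pocket_prepared()
  tpl <- build_adduct_template()
  res <- dock_result_small()
  rep1 <- representative_pose(res)

  shift <- c(60, 0, 0)
  s2 <- s
  n1 <- nrow(s$atoms)
  moved <- s$atoms
  moved$x <- moved$x + shift[1]
  moved$resno <- moved$resno + 100L
  s2$atoms <- rbind(s$atoms, moved)
  attr(s2, "deprotonated") <- c("A:29", "A:129")
  attr(s2, "hydrogens_added") <- TRUE
  s2 <- assign_parameters(s2)

  pose1 <- rep1$xyz
  if (!is.null(rep1$moved_protein)) {
    s2$atoms[rep1$moved_protein$index, c("x", "y", "z")] <- rep1$moved_protein$xyz
    mp2 <- rep1$moved_protein$xyz
    mp2[, 1] <- mp2[, 1] + shift[1]
    s2$atoms[rep1$moved_protein$index + n1, c("x", "y", "z")] <- mp2
  }
  joint <- acrydock:::acr_pose(rbind(pose1, sweep(pose1, 2, shift, "+")),
                               1L, ncopy = 2L)
  eb2 <- score_pose(s2, joint,
                    sites = list(list(chain = "A", resno = 29),
                                 list(chain = "A", resno = 129)))
  single <- rep1
  single$moved_protein <- NULL
  eb1 <- score_pose(s2, single, sites = list(list(chain = "A", resno = 29)))
  expect_equal(eb2$composite, 2 * eb1$composite, tolerance = 0.15)
  expect_equal(eb2$ligand_ligand_evdw, 0)
})

test_that("adduct-adduct overlap is reported as ligand-ligand vdW energy", {
  s <- make_paired_site_fixture(1)
  info <- attr(s, "pocket_info")
  res <- cached("multibody_paired", {
    dock_multibody(s, list(info$cys, info$cys2), tiny_dock_config())
  })
  expect_gte(length(res$clusters), 1)
  # force the two copies into the same volume: the steric cost must show
  # up in the ligand-ligand vdW term
  rep <- representative_pose(res)
  nat <- nrow(res$template$atoms)
  overlap <- rep
  overlap$moved_protein <- NULL
  overlap$xyz[nat + seq_len(nat), ] <-
    sweep(rep$xyz[seq_len(nat), , drop = FALSE], 2, c(0.7, 0, 0), "+")
  eb <- score_pose(res$structure, overlap, sites = list(info$cys, info$cys2))
  expect_gt(eb$ligand_ligand_evdw, 0)
})

test_that("two sites sharing a groove compete: the joint docking scores worse than the parts", {
  s <- make_paired_site_fixture(1)
  info <- attr(s, "pocket_info")
  res <- cached("multibody_paired", {
    dock_multibody(s, list(info$cys, info$cys2), tiny_dock_config())
  })
  r1 <- cached("paired_single1", dock_site(s, info$cys, tiny_dock_config()))
  r2 <- cached("paired_single2", dock_site(s, info$cys2, tiny_dock_config()))
  expect_gt(res$clusters[[1]]$score,
            r1$clusters[[1]]$score + r2$clusters[[1]]$score)
})
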