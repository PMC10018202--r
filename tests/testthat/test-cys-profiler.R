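single_atom_structure <- function(r = 1.9) {
  at <- data.frame(name = "CB", element = "C", resname = "ALA", chain = "A",
                   resno = 1, x = 0, y = 0, z = 0, hetero = FALSE,
                   water = FALSE, charge = 0, rmin = r, eps = 0.1,
                   sigma_solv = 0.012, stringsAsFactors = FALSE)
  acr_structure(at)
}

test_that("an isolated sphere matches the closed-form surface area", {
  for (r in c(1.5, 1.9, 2.2)) {
    s <- single_atom_structure(r)
    sasa <- compute_sasa(s, n_points = 960)
    expect_equal(sasa$atom[1], 4 * pi * (r + 1.4)^2, tolerance = 0.01)
  }
})

test_that("an atom caged by neighbours has zero accessible surface", {
  pts <- rbind(diag(3) * 2.2, -diag(3) * 2.2,
               acrydock:::sphere_points(20) * 2.2)
  at <- data.frame(name = "CB", element = "C", resname = "ALA", chain = "A",
                   resno = seq_len(nrow(pts) + 1),
                   x = c(0, pts[, 1]), y = c(0, pts[, 2]), z = c(0, pts[, 3]),
                   hetero = FALSE, water = FALSE, charge = 0, rmin = 1.9,
                   eps = 0.1, sigma_solv = 0.012, stringsAsFactors = FALSE)
  sasa <- compute_sasa(acr_structure(at), n_points = 500)
  expect_equal(sasa$atom[1], 0)
})

test_that("two-atom surfaces agree with Monte-Carlo integration", {
  set.seed(11)
  for (sep in c(1.5, 2.5, 3.5, 5.0)) {
    xyz <- rbind(c(0, 0, 0), c(sep, 0, 0))
    radii <- c(1.9, 1.7)
    sr <- acrydock:::sasa_points(xyz, radii, 1.4, 960)
    mc <- mc_sasa(xyz, radii, 1.4, 40000)
    expect_equal(sr, mc, tolerance = 0.02)
  }
})

test_that("sampling density below the accuracy floor is rejected", {
  expect_error(compute_sasa(single_atom_structure(), n_points = 10),
               "n_points")
})

test_that("per-residue SASA is the exact sum over residue atoms", {
  s <- pocket_prepared()
  sasa <- compute_sasa(s, n_points = 96)
  key <- paste(s$atoms$chain, s$atoms$resno, sep = ":")
  for (k in sample(unique(key), 5)) {
    rows <- which(key == k & !s$atoms$water)
    rk <- paste(sasa$residue$chain, sasa$residue$resno, sep = ":")
    expect_equal(sum(sasa$atom[rows]), sasa$residue$sasa[match(k, rk)])
  }
})

test_that("adding atoms can only bury surface, never expose it", {
  base <- rbind(c(0, 0, 0), c(3, 0, 0))
  grown <- rbind(base, c(1.5, 2.5, 0), c(1.5, -2.5, 0))
  s0 <- acrydock:::sasa_points(base, rep(1.9, 2), 1.4, 480)
  s1 <- acrydock:::sasa_points(grown, rep(1.9, 4), 1.4, 480)
  expect_true(all(s1[1:2] <= s0 + 1e-9))
})

test_that("deprotonation penalty follows the thermodynamic formula", {
  expect_equal(deprotonation_penalty(7, ph = 7), 0)
  expect_equal(deprotonation_penalty(8.6, 7, 298.15), 2.183, tolerance = 0.005)
  expect_lt(deprotonation_penalty(5.5, ph = 7), 0)
  # linear in (pKa - pH) and in T
  expect_equal(deprotonation_penalty(9, 7), 2 * deprotonation_penalty(8, 7))
  expect_equal(deprotonation_penalty(8, 7, 400),
               deprotonation_penalty(8, 7, 200) * 2)
})

test_that("annotated pKa values rank cysteines most-acidic first", {
  s <- pocket_prepared()
  prof <- profile_cysteines(s, n_points = 96)
  prof2 <- rbind(prof, prof)  # pretend a second cysteine
  prof2$resno[2] <- 99L
  tab <- data.frame(chain = "A", resnum = c(29, 99), pka = c(11.0, 9.0))
  ranked <- rank_cys_acidity(s, prof2, tab)
  expect_equal(ranked$resno[1], 99)
  expect_equal(attr(ranked, "acidity_mode"), "annotated")
  bad <- data.frame(chain = "A", resnum = 123, pka = 8)
  expect_error(rank_cys_acidity(s, prof2, bad), "123")
})

test_that("the heuristic prefers positively surrounded cysteines and breaks ties by number", {
  base <- data.frame(chain = "A", resno = c(10L, 20L), disulfide = FALSE,
                     sasa = c(20, 20), pka = NA_real_,
                     n_positive = c(2L, 0L), n_hbond_to_s = 0L)
  r <- rank_cys_acidity(NULL, base)
  expect_equal(r$resno[1], 10)
  expect_equal(attr(r, "acidity_mode"), "heuristic")
  tie <- base
  tie$n_positive <- 1L
  r2 <- rank_cys_acidity(NULL, tie)
  expect_equal(r2$resno, c(10, 20))
})

test_that("acidity heuristic is invariant to rotation and translation", {
  s <- pocket_prepared()
  p1 <- rank_cys_acidity(s, profile_cysteines(s, n_points = 96))
  s2 <- s
  R <- acrydock:::rotation_matrix(c(1, 2, 3), 65)
  coords(s2) <- sweep(coords(s) %*% t(R), 2, c(5, -3, 8), "+")
  p2 <- rank_cys_acidity(s2, profile_cysteines(s2, n_points = 96))
  expect_equal(p1$acidity_score, p2$acidity_score, tolerance = 0.02)
})

test_that("microenvironment classification sees planted residues and nothing else", {
  s <- pocket_positive()
  cys <- attr(s, "pocket_info")$cys
  me <- analyze_microenvironment(s, cys$chain, cys$resno)
  expect_equal(nrow(me$positive_residues), 2)
  expect_equal(nrow(me$proton_acceptors), 0)
  sn <- generate_pocket(pocket_spec("helix-pair", "neutral", n_flank = 2,
                                    seed = 1))
  men <- analyze_microenvironment(sn, cys$chain, cys$resno)
  expect_equal(nrow(men$positive_residues), 0)
  expect_equal(nrow(men$proton_acceptors), 0)
  sa <- generate_pocket(pocket_spec("helix-pair", "acceptor", n_flank = 2,
                                    seed = 1))
  mea <- analyze_microenvironment(sa, cys$chain, cys$resno)
  expect_equal(nrow(mea$proton_acceptors), 2)
})

test_that("candidate prioritisation filters buried and disulfide cysteines", {
  prof <- data.frame(chain = "A", resno = c(1L, 2L, 3L),
                     disulfide = c(FALSE, TRUE, FALSE),
                     sasa = c(0, 15, 22), pka = NA_real_,
                     n_positive = 0L, n_hbond_to_s = 0L,
                     functional_flags = "")
  ranked <- rank_cys_acidity(NULL, prof)
  strict <- prioritize_candidates(ranked, "strict")
  expect_equal(strict$resno, 3)
  kept <- prioritize_candidates(ranked, "keep_disulfide")
  expect_setequal(kept$resno, c(2, 3))
  expect_match(kept$functional_flags[kept$resno == 2], "redox-shift")
  allburied <- ranked[ranked$resno == 1, ]
  expect_warning(out <- prioritize_candidates(allburied, "strict"),
                 "no candidate")
  expect_equal(nrow(out), 0)
})
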