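test_that("a planted hydrogen bond is detected and is the only side-chain H-bond", {
  kc <- known_complex()
  expect_equal(restraint_violations(
    make_covalent_restraints(kc$structure, kc$cys$chain, kc$cys$resno,
                             kc$template),
    coords(kc$structure), kc$pose$xyz), c(0, 0), tolerance = 1e-6)
  hb <- detect_hbonds(kc$structure, kc$pose, kc$template)
  sc <- hb[hb$sidechain & hb$ligand_group == "carbonyl", ]
  expect_equal(sort(unique(sc$partner_resno)), kc$ground_truth$donor_resno)
  expect_equal(kc$ground_truth$distance, 2.9, tolerance = 0.25)
})

test_that("a donor beyond the distance cutoff is not reported", {
  kc <- known_complex_far()
  hb <- detect_hbonds(kc$structure, kc$pose, kc$template)
  sc <- hb[hb$sidechain & hb$ligand_group == "carbonyl", ]
  expect_false(kc$ground_truth$donor_resno %in% sc$partner_resno)
})

test_that("detectors agree with brute-force enumeration on random fixtures", {
  for (seed in 1:40) {
    rc <- random_complex(seed)
    cx <- complex_structure(rc$s, rc$pose, rc$template)
    atoms <- cx$atoms
    lig_idx <- attr(cx, "ligand_index")

    hb <- detect_hbonds(rc$s, rc$pose, rc$template)
    bf <- brute_hbonds(atoms)
    inter <- bf[xor(bf[, "donor"] %in% lig_idx,
                    bf[, "acceptor"] %in% lig_idx), , drop = FALSE]
    got <- as.matrix(hb[order(hb$donor, hb$acceptor),
                        c("donor", "hydrogen", "acceptor")])
    want <- inter[order(inter[, "donor"], inter[, "acceptor"]), ,
                  drop = FALSE]
    storage.mode(got) <- "double"
    storage.mode(want) <- "double"
    expect_equal(unname(got), unname(want),
                 label = paste("hbond fixture", seed))

    hc <- detect_hydrophobic_contacts(rc$s, rc$pose, rc$template)
    lig_c <- lig_idx[rc$template$hydrophobic_carbons]
    bfc <- brute_hydrophobic(atoms, lig_idx, lig_c)
    expect_equal(nrow(hc), nrow(bfc), label = paste("contact fixture", seed))
    if (nrow(hc) > 0) {
      gotc <- sort(paste(hc$partner_resno, hc$partner_atom, round(hc$distance, 6)))
      wantc <- sort(paste(atoms$resno[bfc[, "pro"]], atoms$name[bfc[, "pro"]],
                          round(sqrt(rowSums((as.matrix(atoms[bfc[, "lig"], c("x", "y", "z")]) -
                                                as.matrix(atoms[bfc[, "pro"], c("x", "y", "z")]))^2)), 6)))
      expect_equal(gotc, wantc)
    }
  }
})

test_that("hydrophobic contacts respect the charge and distance rules", {
  tpl <- build_adduct_template()
  mkatom <- function(name, el, resname, resno, x, q) {
    data.frame(name = name, element = el, resname = resname, chain = "A",
               resno = resno, x = x, y = 0, z = 0, hetero = FALSE,
               water = FALSE, charge = q, rmin = 2, eps = 0.1,
               sigma_solv = 0.012, is_polar_h = FALSE,
               h_parent = NA_integer_, stringsAsFactors = FALSE)
  }
  # ligand C1 sits at origin; partners along +x
  at <- rbind(mkatom("CD1", "C", "LEU", 1, -3.5, 0.0),
              mkatom("C", "C", "ALA", 2, -3.3, 0.51),
              mkatom("CB", "C", "ALA", 3, -4.05, 0.0))
  s <- acr_structure(at)
  attr(s, "parameters_assigned") <- TRUE
  pose <- acrydock:::acr_pose(acrydock:::template_xyz(tpl), 1L)
  hc <- detect_hydrophobic_contacts(s, pose, tpl)
  expect_equal(hc$partner_restype, "LEU")  # apolar carbon at 3.5 A only
  expect_equal(hc$ligand_atom, "C1")
  expect_true(hc$sidechain)
})

test_that("interaction frequencies weight clusters by their size", {
  expect_equal(weighted_frequency(70, 10), 70)
  expect_equal(weighted_frequency(c(100, 0), c(69, 63)), 69 / 132 * 100,
               tolerance = 1e-9)
  expect_equal(round(weighted_frequency(c(100, 0), c(69, 63)), 1), 52.3)
  # bounded by the per-cluster extrema
  set.seed(2)
  for (i in 1:20) {
    f <- runif(3, 0, 100)
    w <- sample(1:50, 3)
    wf <- weighted_frequency(f, w)
    expect_gte(wf, min(f) - 1e-9)
    expect_lte(wf, max(f) + 1e-9)
  }
})

test_that("fingerprints pool analysed clusters and are pose-order invariant", {
  res <- dock_result_small()
  fp <- fingerprint_result(res)
  expect_s3_class(fp, "acr_fingerprint")
  expect_true(all(fp$frequency >= 0 & fp$frequency <= 100))
  expect_equal(attr(fp, "cluster_sizes"),
               vapply(res$clusters[res$analyzed], `[[`, 0L, "size"))
  # permuting member poses does not change frequencies
  res2 <- res
  for (ci in res2$analyzed) {
    n <- length(res2$clusters[[ci]]$poses)
    res2$clusters[[ci]]$poses <- res2$clusters[[ci]]$poses[rev(seq_len(n))]
  }
  fp2 <- fingerprint_result(res2)
  key <- function(t) paste(t$partner_resno, t$type, t$ligand_group)
  m <- match(key(fp), key(fp2))
  expect_false(any(is.na(m)))
  expect_equal(fp$frequency, fp2$frequency[m])
})

test_that("residue-type summary reproduces grouped donor shares", {
  counts <- data.frame(
    ligand_group = "carbonyl",
    restype = c("LYS", "ARG", "ASN", "SER", "TYR"),
    count = c(6, 3, 1, 1, 1))
  out <- summarize_partner_counts(counts)
  per <- out$per_residue
  expect_equal(per$share_pct[per$restype == "LYS"], 50.0)
  expect_equal(per$share_pct[per$restype == "ARG"], 25.0)
  expect_equal(per$share_pct[per$restype == "ASN"], 8.3)
  grp <- out$grouped
  expect_equal(grp$share_pct[grp$class == "positive"], 75.0)
  # grouped shares sum to 100 within the ligand group (up to rounding)
  expect_equal(sum(grp$share_pct), 100, tolerance = 0.2)
  # single partner trivially owns its group
  one <- summarize_partner_counts(data.frame(ligand_group = "amino",
                                             restype = "SER", count = 3))
  expect_equal(one$per_residue$share_pct, 100)
})

test_that("the pooling threshold filters fingerprint rows", {
  mk_fp <- function(restype, freq, group = "carbonyl") {
    t <- data.frame(partner_chain = "A", partner_resno = 10,
                    partner_restype = restype, type = "hbond",
                    ligand_group = group, sidechain = TRUE, frequency = freq)
    class(t) <- c("acr_fingerprint", class(t))
    t
  }
  tabs <- list(mk_fp("LYS", 90), mk_fp("SER", 45), mk_fp("ARG", 61))
  out <- summarize_by_residue_type(tabs, threshold = 60)
  expect_setequal(out$counts$restype, c("LYS", "ARG"))
  empty <- summarize_by_residue_type(tabs, threshold = 101)
  expect_equal(nrow(empty$per_residue), 0)
})

test_that("reaction-context annotation joins docking and pre-reaction roles", {
  res <- dock_result_small()
  me <- analyze_microenvironment(res$structure, "A", 29)
  ctxt <- annotate_reaction_context(res, me, threshold = 0)
  expect_s3_class(ctxt, "acr_reaction_context")
  # every planted lysine within the shell is reported as positive
  pinfo <- attr(pocket_positive(), "pocket_info")
  for (fr in pinfo$flank_resno)
    expect_true(paste("A", fr, sep = ":") %in%
                  ctxt$residue[ctxt$positive])
  # mismatched site is refused
  me_bad <- me
  me_bad$cys <- "A:999"
  expect_error(annotate_reaction_context(res, me_bad, threshold = 0),
               "does not match")
})
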