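test_that("a minimal PDB file parses into residues and atoms", {
  f <- write_tmp(tiny_pdb_text(), ".pdb")
  s <- read_structure(f)
  expect_s3_class(s, "acr_structure")
  expect_equal(length(unique(s$atoms$resno)), 3)
  expect_equal(nrow(s$atoms), 12)
  expect_true(all(s$atoms$resname == "ALA"))
})

test_that("PDB and mmCIF readings of the same model agree", {
  fp <- write_tmp(tiny_pdb_text(), ".pdb")
  fc <- write_tmp(tiny_cif_text(), ".cif")
  sp <- read_structure(fp)
  sc <- read_structure(fc, format = "mmcif")
  expect_equal(nrow(sp$atoms), nrow(sc$atoms))
  expect_equal(coords(sp), coords(sc), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  lines <- tiny_pdb_text()
  # duplicate the first CA with two altlocs
  ca <- lines[2]
  a <- pdb_line(2, "CA", "ALA", "A", 1, c(1.458, 0, 0), occ = 0.6, alt = "A")
  b <- pdb_line(2, "CA", "ALA", "A", 1, c(9.999, 0, 0), occ = 0.4, alt = "B")
  lines <- c(lines[1], a, b, lines[3:length(lines)])
  s <- read_structure(write_tmp(lines, ".pdb"))
  ca_rows <- which(s$atoms$name == "CA" & s$atoms$resno == 1)
  expect_length(ca_rows, 1)
  expect_equal(s$atoms$x[ca_rows], 1.458, tolerance = 1e-3)
})

test_that("unreadable input and empty models raise errors", {
  expect_error(read_structure(tempfile()), "not found")
  f <- write_tmp(c("REMARK nothing here", "END"), ".pdb")
  expect_error(read_structure(f))
})

test_that("write/read round trip preserves coordinates to PDB precision", {
  s <- pocket_prepared()
  f <- tempfile(fileext = ".pdb")
  write_complex(s, NULL, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_lt(max(abs(coords(s) - coords(s2))), 1e-3 + 1e-8)
})

test_that("a written complex carries the adduct as its own HETATM residue", {
  kc <- known_complex()
  f <- tempfile(fileext = ".pdb")
  write_complex(kc$structure, kc$pose, f, kc$template)
  s2 <- read_structure(f)
  lig <- s2$atoms[s2$atoms$resname == "PRD", ]
  expect_equal(nrow(lig), nrow(kc$template$atoms))
  expect_true(all(lig$hetero))
  expect_equal(length(unique(paste(lig$chain, lig$resno))), 1)
  # ligand coordinates survive the round trip too
  expect_lt(max(abs(as.matrix(lig[, c("x", "y", "z")]) - kc$pose$xyz)), 1e-3 + 1e-8)
})

test_that("disulfide detection is symmetric and distance-based", {
  # two cysteines with SG atoms 2.05 A apart, one isolated
  bb <- acrydock:::build_backbone(rep(-120, 3), rep(130, 3))
  mk <- function(resno, sgpos) {
    data.frame(name = c("N", "CA", "C", "O", "CB", "SG"), element = c("N", "C", "C", "O", "C", "S"),
               resname = "CYS", chain = "A", resno = resno,
               x = c(bb$N[resno, 1], bb$CA[resno, 1], bb$C[resno, 1], bb$O[resno, 1], sgpos[1] - 1.8, sgpos[1]),
               y = c(bb$N[resno, 2], bb$CA[resno, 2], bb$C[resno, 2], bb$O[resno, 2], sgpos[2], sgpos[2]),
               z = c(bb$N[resno, 3], bb$CA[resno, 3], bb$C[resno, 3], bb$O[resno, 3], sgpos[3], sgpos[3]),
               hetero = FALSE, water = FALSE, stringsAsFactors = FALSE)
  }
  at <- rbind(mk(1, c(20, 0, 0)), mk(2, c(22.05, 0, 0)), mk(3, c(40, 0, 0)))
  s <- acr_structure(at)
  cys <- enumerate_cysteines(s)
  expect_equal(cys$disulfide, c(TRUE, TRUE, FALSE))
  expect_equal(cys$candidate, c(FALSE, FALSE, TRUE))
  expect_equal(cys$partner[1], "A:2")
  expect_equal(cys$partner[2], "A:1")
})

test_that("parameter assignment distinguishes polar and apolar carbons", {
  s <- assign_parameters(pocket_positive())
  at <- s$atoms
  bbC <- at$charge[at$name == "C"]
  expect_true(all(abs(bbC) >= 0.15))
  alaCB <- at$charge[at$name == "CB" & at$resname == "ALA"]
  expect_true(all(abs(alaCB) < 0.15))
  expect_true(all(at$rmin > 0))
})

test_that("atoms missing from the charge table default to zero with a warning", {
  s <- pocket_positive()
  s$atoms$name[s$atoms$name == "CB"][1] <- "XX9"
  expect_warning(s2 <- assign_parameters(s), "charge table")
  expect_equal(s2$atoms$charge[s2$atoms$name == "XX9"], 0)
})

test_that("polar hydrogen placement follows ideal geometry and valence", {
  s <- pocket_prepared()
  at <- s$atoms
  # every hydrogen sits within 1.2 A of exactly one heavy atom
  hs <- which(at$element == "H")
  expect_true(length(hs) > 0)
  heavy <- which(at$element != "H")
  for (h in hs) {
    d <- sqrt(rowSums(sweep(as.matrix(at[heavy, c("x", "y", "z")]), 2,
                            as.numeric(at[h, c("x", "y", "z")]), "-")^2))
    expect_equal(sum(d <= 1.2), 1)
    expect_equal(heavy[which.min(d)], at$h_parent[h])
  }
  # non-terminal residues carry exactly one backbone amide H
  mid <- at[at$resno == 10, ]
  expect_equal(sum(mid$name == "H"), 1)
  # the reactive cysteine is deprotonated: no thiol hydrogen
  cysrows <- at[at$resno == attr(pocket_positive(), "pocket_info")$cys$resno, ]
  expect_false(any(cysrows$element == "H" & cysrows$name == "HG"))
  expect_true("A:29" %in% attr(s, "deprotonated"))
})

test_that("serine hydroxyl hydrogens sit at the ideal O-H bond length", {
  bb <- acrydock:::build_backbone(rep(-57, 3), rep(-47, 3))
  rows <- list()
  for (i in 1:3) {
    nm <- c("N", "CA", "C", "O")
    xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    resname <- if (i == 2) "SER" else "ALA"
    sc <- acrydock:::build_sidechain(bb, i, resname)
    nm <- c(nm, names(sc))
    xyz <- rbind(xyz, do.call(rbind, sc))
    rows[[i]] <- data.frame(name = nm, element = substr(nm, 1, 1),
                            resname = resname, chain = "A", resno = i,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            hetero = FALSE, water = FALSE,
                            stringsAsFactors = FALSE)
  }
  s <- add_polar_hydrogens(acr_structure(do.call(rbind, rows)))
  hg <- atom_index(s, "A", 2, "HG")
  og <- atom_index(s, "A", 2, "OG")
  expect_false(is.na(hg))
  d <- vlen(as.numeric(s$atoms[hg, c("x", "y", "z")]) -
              as.numeric(s$atoms[og, c("x", "y", "z")]))
  expect_equal(d, 0.96, tolerance = 0.01)
})

test_that("the adduct template has propionamide topology", {
  tpl <- build_adduct_template()
  expect_equal(sum(tpl$atoms$element != "H"), 5)
  expect_setequal(tpl$atoms$element[tpl$atoms$element != "H"],
                  c("C", "C", "C", "O", "N"))
  # reactive and adjacent carbons are bonded at single-bond distance
  d <- vlen(as.numeric(tpl$atoms[tpl$reactive_carbon, c("x", "y", "z")]) -
              as.numeric(tpl$atoms[tpl$adjacent_carbon, c("x", "y", "z")]))
  expect_equal(d, 1.53, tolerance = 0.01)
  expect_true(tpl$reactive_carbon != tpl$adjacent_carbon)
  # carbonyl oxygen bonded to the chain carbon adjacent to the amide N
  dco <- vlen(as.numeric(tpl$atoms[tpl$carbonyl_carbon, c("x", "y", "z")]) -
                as.numeric(tpl$atoms[tpl$carbonyl_oxygen, c("x", "y", "z")]))
  expect_lt(dco, 1.3)
  # amide nitrogen carries two polar hydrogens
  expect_equal(sum(tpl$atoms$h_parent %in% tpl$amide_nitrogen, na.rm = TRUE), 2)
})
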