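# Per-cysteine physicochemical profiling: solvent exposure, relative
# acidity, deprotonation penalty and the 5 A microenvironment around the
# thiol sulfur.

BOLTZMANN_KCAL <- 0.0019872041  # kcal/mol/K

#' Free-energy cost of deprotonating a cysteine thiol
#'
#' `ln(10) * kT * (pKa - pH)` in kcal/mol. The docking protocol models
#' reactive cysteines as already deprotonated, so this cost is reported
#' alongside docking scores but never added to them.
#'
#' @param pka cysteine pKa (dimensionless).
#' @param ph solution pH (default 7).
#' @param temperature absolute temperature in Kelvin.
#' @return energy in kcal/mol (negative when pKa < pH).
#' @examples
#' deprotonation_penalty(8.6)  # intrinsic Cys pKa at pH 7: ~2.18 kcal/mol
#' @export
deprotonation_penalty <- function(pka, ph = 7, temperature = 298.15) {
  log(10) * BOLTZMANN_KCAL * temperature * (pka - ph)
}

#' Classify the microenvironment around a cysteine sulfur
#'
#' Residues with any side-chain heavy atom within `radius` of the Sgamma
#' atom are collected and classified: His/Asp/Glu as potential proton
#' acceptors (they can deprotonate the thiol), Lys/Arg as positive residues
#' (they stabilise the thiolate and the enolate-type intermediate of the
#' Michael addition). Hydrogen-bond partners of the sulfur are found with
#' the same geometric criterion as [detect_hbonds()].
#'
#' @param s structure (hydrogens added for the H-bond search to see donors).
#' @param chain,resno the cysteine.
#' @param radius shell radius in Angstrom.
#' @return object of class `acr_microenv`: list with data frames
#'   `proton_acceptors`, `positive_residues` (residue, type, minimum
#'   distance) and `hbond_partners` (donors to the sulfur), and
#'   `radius_used`.
#' @export
analyze_microenvironment <- function(s, chain, resno, radius = 5.0) {
  at <- s$atoms
  sg <- atom_index(s, chain, resno, "SG")
  if (is.na(sg)) stop("residue ", chain, ":", resno, " has no SG atom")
  sg_xyz <- as.numeric(at[sg, c("x", "y", "z")])

  side <- which(!at$water & !at$hetero & !(at$name %in% backbone_names) &
                  at$element != "H" &
                  !(at$chain == chain & at$resno == resno))
  near <- data.frame(residue = character(0), restype = character(0),
                     distance = numeric(0), stringsAsFactors = FALSE)
  if (length(side) > 0) {
    d <- sqrt(rowSums(sweep(as.matrix(at[side, c("x", "y", "z")]), 2,
                            sg_xyz, "-")^2))
    hit <- side[d <= radius]
    if (length(hit) > 0) {
      df <- data.frame(residue = residue_key(at[hit, ]),
                       restype = at$resname[hit], distance = d[d <= radius],
                       stringsAsFactors = FALSE)
      near <- do.call(rbind, lapply(split(df, df$residue), function(g) {
        g[which.min(g$distance), ]
      }))
      near <- near[order(near$distance), ]
      rownames(near) <- NULL
    }
  }
  acceptors <- near[near$restype %in% c("HIS", "ASP", "GLU"), ]
  positives <- near[near$restype %in% c("LYS", "ARG"), ]

  # hydrogen-bond donors to the sulfur
  hs <- which(at$element == "H" & !is.na(at$h_parent) &
                !(at$chain == chain & at$resno == resno))
  hb <- find_hbonds(at, hs, sg)
  partners <- if (nrow(hb) == 0) {
    data.frame(residue = character(0), restype = character(0),
               donor_atom = character(0), distance = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(residue = residue_key(at[hb$donor, ]),
               restype = at$resname[hb$donor],
               donor_atom = at$name[hb$donor], distance = hb$distance,
               stringsAsFactors = FALSE)
  }
  structure(list(proton_acceptors = acceptors, positive_residues = positives,
                 hbond_partners = partners, radius_used = radius,
                 cys = paste(chain, resno, sep = ":")),
            class = "acr_microenv")
}

#' @export
print.acr_microenv <- function(x, ...) {
  cat("Microenvironment of Cys", x$cys, "within", x$radius_used, "A:\n")
  cat("  positive residues:", nrow(x$positive_residues),
      " proton acceptors:", nrow(x$proton_acceptors),
      " H-bond donors to S:", nrow(x$hbond_partners), "\n")
  invisible(x)
}

#' Read a per-cysteine annotation table
#'
#' Plain-text TSV with columns `chain`, `resnum`, `pka` and optionally
#' `flags` (free-text functional annotations carried through to reports).
#' @param path TSV file path.
#' @return data frame.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("chain", "resnum", "pka")
  miss <- setdiff(needed, names(tab))
  if (length(miss) > 0)
    stop("annotation table is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(tab$flags)) tab$flags <- ""
  tab
}

#' Profile every cysteine of a structure
#'
#' Combines [enumerate_cysteines()], [compute_sasa()] (whole-residue and
#' Sgamma-only values are both reported), the acidity measure and the
#' microenvironment census into one candidate table.
#'
#' @param s structure with parameters assigned and hydrogens added.
#' @param annotation optional annotation data frame ([read_annotation()]).
#' @param ph,temperature conditions for the deprotonation penalty.
#' @param radius microenvironment radius (Angstrom).
#' @param n_points SASA sphere sampling density.
#' @return data frame of class `acr_cys_profile`, one row per cysteine.
#' @export
profile_cysteines <- function(s, annotation = NULL, ph = 7,
                              temperature = 298.15, radius = 5.0,
                              n_points = 960) {
  cys <- enumerate_cysteines(s)
  if (nrow(cys) == 0) return(cys)
  sasa <- compute_sasa(s, n_points = n_points)
  key <- paste(cys$chain, cys$resno, sep = ":")
  rkey <- paste(sasa$residue$chain, sasa$residue$resno, sep = ":")
  cys$sasa <- sasa$residue$sasa[match(key, rkey)]
  cys$sasa_sg <- sasa$atom[cys$sg_index]

  cys$pka <- NA_real_
  cys$functional_flags <- ""
  if (!is.null(annotation)) {
    akey <- paste(annotation$chain, annotation$resnum, sep = ":")
    bad <- setdiff(akey, key)
    if (length(bad) > 0)
      stop("annotation references unknown cysteine(s): ",
           paste(bad, collapse = ", "))
    m <- match(key, akey)
    cys$pka <- annotation$pka[m]
    cys$functional_flags <- ifelse(is.na(m), "", annotation$flags[m])
  }

  cys$n_positive <- NA_integer_
  cys$n_acceptors <- NA_integer_
  cys$n_hbond_to_s <- NA_integer_
  for (i in seq_len(nrow(cys))) {
    me <- analyze_microenvironment(s, cys$chain[i], cys$resno[i], radius)
    cys$n_positive[i] <- nrow(me$positive_residues)
    cys$n_acceptors[i] <- nrow(me$proton_acceptors)
    cys$n_hbond_to_s[i] <- nrow(me$hbond_partners)
  }
  cys$deprotonation_penalty <-
    ifelse(is.na(cys$pka), NA_real_,
           deprotonation_penalty(cys$pka, ph, temperature))
  class(cys) <- c("acr_cys_profile", class(cys))
  cys
}

#' Rank cysteines by relative acidity
#'
#' With an annotation table, candidates are ordered by ascending annotated
#' pKa (most acidic first). Without one, an internal heuristic preserves the
#' ordering semantics: score = (positive side chains within 5 A of Sgamma) +
#' (H-bond donors to Sgamma) - 0.05 * max(0, 10 - SASA), higher meaning more
#' acidic; positive neighbours and H-bonding lower a thiol pKa while burial
#' raises it. Absolute pKa prediction is out of scope. Ties break by residue
#' number.
#'
#' @param s structure (used to compute the heuristic when needed).
#' @param candidates profile table from [profile_cysteines()].
#' @param pka_table optional annotation (data frame or TSV path); when the
#'   profile already carries annotated pKa values those are used.
#' @return `candidates` ordered most-acidic first, with columns
#'   `acidity_score` and `acidity_rank`; the ranking mode is recorded in
#'   attribute `acidity_mode` (`"annotated"` or `"heuristic"`).
#' @export
rank_cys_acidity <- function(s, candidates, pka_table = NULL) {
  if (is.character(pka_table)) pka_table <- read_annotation(pka_table)
  if (!is.null(pka_table)) {
    akey <- paste(pka_table$chain, pka_table$resnum, sep = ":")
    key <- paste(candidates$chain, candidates$resno, sep = ":")
    bad <- setdiff(akey, key)
    if (length(bad) > 0)
      stop("pKa table references unknown cysteine(s): ",
           paste(bad, collapse = ", "))
    candidates$pka <- pka_table$pka[match(key, akey)]
  }
  mode <- if (all(!is.na(candidates$pka))) "annotated" else "heuristic"
  if (mode == "annotated") {
    candidates$acidity_score <- -candidates$pka
  } else {
    candidates$acidity_score <- candidates$n_positive + candidates$n_hbond_to_s -
      0.05 * pmax(0, 10 - candidates$sasa)
  }
  ord <- order(-candidates$acidity_score, candidates$resno)
  candidates <- candidates[ord, ]
  candidates$acidity_rank <- seq_len(nrow(candidates))
  rownames(candidates) <- NULL
  attr(candidates, "acidity_mode") <- mode
  candidates
}

#' Filter and order candidate cysteines for docking
#'
#' Excludes disulfide-bonded cysteines (kept with a redox-shift note under
#' `policy = "keep_disulfide"`: modification would require a free-thiol
#' subpopulation) and fully buried ones (SASA = 0), then orders by acidity
#' rank with SASA (descending) as tie-break.
#'
#' @param candidates ranked profile from [rank_cys_acidity()].
#' @param policy `"strict"` or `"keep_disulfide"`.
#' @return filtered, ordered candidate table.
#' @export
prioritize_candidates <- function(candidates,
                                  policy = c("strict", "keep_disulfide")) {
  policy <- match.arg(policy)
  if (is.null(candidates$acidity_rank))
    stop("run rank_cys_acidity() first")
  out <- candidates
  if (policy == "strict") {
    out <- out[!out$disulfide, , drop = FALSE]
  } else {
    note <- "redox-shift: disulfide-bonded; requires free-thiol population"
    out$functional_flags[out$disulfide] <-
      trimws(paste(out$functional_flags[out$disulfide], note, sep = "; "))
  }
  out <- out[out$sasa > 0, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no candidate cysteines remain after filtering")
    return(out)
  }
  out <- out[order(out$acidity_rank, -out$sasa), , drop = FALSE]
  rownames(out) <- NULL
  out
}
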