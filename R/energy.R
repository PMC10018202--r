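# Scoring terms. Functional forms: 12-6 Lennard-Jones (rmin/eps
# combination rules: additive radii, geometric-mean well depths), Coulomb
# in a distance-dependent dielectric eps(r) = r with an 8.5 A cutoff, a
# SASA-based desolvation term, and flat-bottom quadratic distance
# restraints. The composite weighs them 1.0/0.1/1.0/0.1.

COULOMB_KCAL <- 332.0636  # kcal*A/(mol*e^2)

#' Weighted composite docking score
#'
#' `composite = 1.0 * evdw + 0.1 * eelec + 1.0 * edesol + 0.1 * eair`,
#' the weighting recommended for protein/small-molecule complexes. Scores
#' are in arbitrary units and comparable only within one protein and one
#' configuration.
#'
#' @param evdw,eelec,edesol,eair energy components (kcal/mol).
#' @return numeric composite score (a.u.).
#' @export
composite_score <- function(evdw, eelec, edesol, eair) {
  1.0 * evdw + 0.1 * eelec + 1.0 * edesol + 0.1 * eair
}

#' Energy breakdown of a pose
#'
#' @param evdw,eelec,edesol,eair components in kcal/mol.
#' @param vdw_capped whether any atom pair hit the overlap ceiling.
#' @return list of class `acr_energy` with the components and `composite`.
#' @export
energy_breakdown <- function(evdw, eelec, edesol, eair, vdw_capped = FALSE) {
  structure(list(evdw = evdw, eelec = eelec, edesol = edesol, eair = eair,
                 composite = composite_score(evdw, eelec, edesol, eair),
                 vdw_capped = vdw_capped),
            class = "acr_energy")
}

#' @export
print.acr_energy <- function(x, ...) {
  cat(sprintf("Evdw %8.2f  Eelec %8.2f  Edesol %8.2f  Eair %8.2f  -> %8.2f a.u.%s\n",
              x$evdw, x$eelec, x$edesol, x$eair, x$composite,
              if (isTRUE(x$vdw_capped)) " [vdw capped]" else ""))
  invisible(x)
}

#' Pairwise LJ + Coulomb between two atom sets
#'
#' Returns summed evdw and eelec over all cross pairs within `cutoff`.
#' Pairs closer than 0.1 A have their LJ term capped at `vdw_ceiling`
#' (overlap guard) and set the `capped` flag.
#' @noRd
pair_energies <- function(xyz1, q1, rmin1, eps1, xyz2, q2, rmin2, eps2,
                          cutoff = 8.5, vdw_ceiling = 1000) {
  d2 <- cross_dist2(xyz1, xyz2)
  within <- d2 <= cutoff^2
  if (!any(within)) return(list(evdw = 0, eelec = 0, capped = FALSE))
  d2w <- d2[within]
  overlap <- d2w < 0.1^2
  d2w[overlap] <- 0.1^2
  rminm <- outer(rmin1, rmin2, "+")[within]
  epsm <- sqrt(outer(eps1, eps2))[within]
  s6 <- (rminm^2 / d2w)^3
  lj <- epsm * (s6^2 - 2 * s6)
  lj <- pmin(lj, vdw_ceiling)
  qq <- outer(q1, q2)[within]
  # eps(r) = r  =>  E = k q1 q2 / r^2
  elec <- COULOMB_KCAL * qq / d2w
  list(evdw = sum(lj), eelec = sum(elec), capped = any(overlap))
}

#' Desolvation energy of binding from SASA differences
#'
#' E = sum over atoms of sigma_i * (SASA_bound - SASA_unbound). Only atoms
#' whose accessibility can change (the ligand plus protein atoms within
#' `margin` of it) are recomputed; all other contributions cancel.
#' @noRd
desolvation_energy <- function(pro_xyz, pro_radii, pro_sigma, pro_sasa0,
                               lig_xyz, lig_radii, lig_sigma, lig_sasa0,
                               probe = 1.4, n_points = 120, margin = 8.0) {
  near <- which(sqrt(do.call(pmin, as.data.frame(
    cross_dist2(pro_xyz, lig_xyz)))) <= margin)
  all_xyz <- rbind(pro_xyz, lig_xyz)
  all_rad <- c(pro_radii, lig_radii)
  np <- nrow(pro_xyz)
  subset <- c(near, np + seq_len(nrow(lig_xyz)))
  bound <- sasa_points(all_xyz, all_rad, probe, n_points, subset = subset)
  unbound <- c(pro_sasa0[near], lig_sasa0)
  sum(c(pro_sigma[near], lig_sigma) * (bound - unbound))
}
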