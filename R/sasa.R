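#' Solvent-accessible surface area by Shrake-Rupley sphere sampling
#'
#' Each atom is expanded by the probe radius and sampled with a
#' deterministic Fibonacci-spiral point set; the accessible fraction is the
#' share of points not buried inside any neighbouring expanded sphere.
#' Waters are excluded from both the surface and the occluding set.
#'
#' @param s structure with vdW radii assigned ([assign_parameters()]).
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_points sphere sample points per atom. The default of 960 keeps
#'   the isolated-sphere error below 1%.
#' @return list with `atom` (numeric vector, per-atom SASA in A^2, `NA` for
#'   waters) and `residue` (data frame `chain`, `resno`, `resname`, `sasa`
#'   where the residue value is the exact sum over its atoms).
#' @export
compute_sasa <- function(s, probe_radius = 1.4, n_points = 960) {
  if (n_points < 20)
    stop("n_points must be at least 20 for a usable surface estimate")
  at <- s$atoms
  if (all(is.na(at$rmin))) stop("vdW radii missing: run assign_parameters()")
  use <- !at$water
  xyz <- as.matrix(at[use, c("x", "y", "z")])
  radii <- at$rmin[use]
  per_use <- sasa_points(xyz, radii, probe_radius, n_points)
  atom_sasa <- rep(NA_real_, nrow(at))
  atom_sasa[use] <- per_use

  keys <- residue_key(at[use, ])
  res_sum <- rowsum(per_use, keys, reorder = FALSE)
  uk <- unique(keys)
  first <- match(uk, keys)
  residue <- data.frame(
    chain = at$chain[use][first], resno = at$resno[use][first],
    resname = at$resname[use][first],
    sasa = as.numeric(res_sum[match(uk, rownames(res_sum)), 1]),
    stringsAsFactors = FALSE
  )
  list(atom = atom_sasa, residue = residue)
}

#' Core Shrake-Rupley routine on bare coordinates
#'
#' @param xyz n x 3 coordinates; `radii` vdW radii; atoms in `subset`
#'   (default all) get a SASA value while all atoms occlude.
#' @return numeric vector of length `length(subset)`.
#' @noRd
sasa_points <- function(xyz, radii, probe_radius = 1.4, n_points = 960,
                        subset = seq_len(nrow(xyz))) {
  pts <- sphere_points(n_points)
  expanded <- radii + probe_radius
  out <- numeric(length(subset))
  for (k in seq_along(subset)) {
    i <- subset[k]
    ri <- expanded[i]
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ], "-")^2)
    nb <- which(d2 < (ri + expanded)^2 & d2 > 1e-12)
    if (length(nb) == 0) {
      out[k] <- 4 * pi * ri^2
      next
    }
    sp <- sweep(pts * ri, 2, xyz[i, ], "+")
    pd2 <- cross_dist2(sp, xyz[nb, , drop = FALSE])
    buried <- rowSums(pd2 < matrix(expanded[nb]^2, nrow(sp), length(nb),
                                   byrow = TRUE)) > 0
    out[k] <- 4 * pi * ri^2 * mean(!buried)
  }
  out
}
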