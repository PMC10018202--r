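# Greedy pose clustering on the interface-ligand RMSD (iL-RMSD): ligand
# heavy-atom RMSD after least-squares superposition on the interface
# protein backbone (backbone atoms within 10 A of the ligand in the
# reference pose).

il_rmsd_matrix <- function(poses, s, template, interface_radius = 10) {
  at <- s$atoms
  n <- length(poses)
  nat <- nrow(template$atoms)
  ncopy <- n_ligand_copies(poses[[1]])
  heavy <- rep(template$atoms$element != "H", ncopy)
  bb <- which(at$name %in% c("N", "CA", "C", "O") & !at$hetero & !at$water)
  bb_xyz <- as.matrix(at[bb, c("x", "y", "z")])
  lig <- lapply(poses, function(p) p$xyz[heavy, , drop = FALSE])

  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    ref <- lig[[i]]
    d <- sqrt(do.call(pmin, as.data.frame(cross_dist2(bb_xyz, ref))))
    iface <- which(d <= interface_radius)
    if (length(iface) < 3) iface <- seq_along(bb)
    fx <- bb_xyz[iface, , drop = FALSE]
    for (j in (i + 1):n) {
      # the backbone is rigid during refinement, so the superposition of
      # pose j's interface onto pose i's is computed on identical
      # coordinates; kept explicit for generality
      fit <- kabsch(fx, fx)
      lj <- apply_kabsch(lig[[j]], fit)
      m[i, j] <- m[j, i] <- rmsd_xyz(ref, lj)
    }
  }
  m
}

#' Cluster refined poses by interface-ligand RMSD
#'
#' Greedy neighbour clustering: the pose with the most neighbours within
#' `cutoff` seeds a cluster together with those neighbours; assigned poses
#' are removed and the procedure repeats, so the clusters partition the
#' pose set. Each cluster is scored as the mean composite of its (up to)
#' four best members and clusters are returned best-first.
#'
#' @param poses list of refined, scored poses.
#' @param cutoff iL-RMSD cutoff in Angstrom.
#' @param s the structure the poses were docked on.
#' @param template adduct template.
#' @return list of `acr_pose_cluster` objects, ordered by score.
#' @export
cluster_poses <- function(poses, cutoff = 1.0, s, template) {
  if (length(poses) == 0) stop("no poses to cluster")
  scores <- vapply(poses, function(p) p$energy$composite, 0)
  m <- il_rmsd_matrix(poses, s, template)
  nbr <- m <= cutoff
  diag(nbr) <- TRUE
  unassigned <- seq_along(poses)
  clusters <- list()
  while (length(unassigned) > 0) {
    counts <- rowSums(nbr[unassigned, unassigned, drop = FALSE])
    seedi <- unassigned[which.max(counts)]  # ties: lowest pose position
    members <- unassigned[nbr[seedi, unassigned]]
    msc <- sort(scores[members])
    top <- msc[seq_len(min(4, length(msc)))]
    rep_i <- members[which.min(scores[members])]
    clusters[[length(clusters) + 1]] <- structure(list(
      members = members,
      poses = poses[members],
      representative = poses[[rep_i]],
      score = mean(top),
      sd_top = if (length(top) > 1) stats::sd(top) else 0,
      size = length(members)
    ), class = "acr_pose_cluster")
    unassigned <- setdiff(unassigned, members)
  }
  ord <- order(vapply(clusters, `[[`, 0, "score"))
  clusters[ord]
}
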