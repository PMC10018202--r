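# Cluster-size-weighted interaction fingerprints. Frequencies are the
# percentage of member poses of each analysed cluster exhibiting an
# interaction; when several clusters are analysed the overall frequency is
# their weighted average with weights proportional to cluster size.

interaction_rows <- function(result, pose) {
  s <- result$structure
  tpl <- result$template
  hb <- detect_hbonds(s, pose, tpl)
  hc <- detect_hydrophobic_contacts(s, pose, tpl)
  rows <- list()
  if (nrow(hb) > 0) {
    rows[[1]] <- unique(data.frame(
      partner_chain = hb$partner_chain, partner_resno = hb$partner_resno,
      partner_restype = hb$partner_restype, type = "hbond",
      ligand_group = hb$ligand_group, sidechain = hb$sidechain,
      stringsAsFactors = FALSE))
  }
  if (nrow(hc) > 0) {
    rows[[2]] <- unique(data.frame(
      partner_chain = hc$partner_chain, partner_resno = hc$partner_resno,
      partner_restype = hc$partner_restype, type = "hydrophobic",
      ligand_group = "none", sidechain = hc$sidechain,
      stringsAsFactors = FALSE))
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Interaction-frequency table of a docking result
#'
#' For every analysed cluster, each (partner residue, interaction type,
#' ligand group) is scored as the percentage of member poses exhibiting it;
#' the overall frequency is the cluster-size-weighted average. H-bonds are
#' split by the adduct group involved (carbonyl oxygen as acceptor, amide
#' group as donor).
#'
#' @param result an `acr_docking_result`.
#' @return data frame of class `acr_fingerprint` with per-cluster and
#'   weighted frequencies (percent); analysed cluster sizes are stored in
#'   attribute `cluster_sizes`.
#' @export
fingerprint_result <- function(result) {
  if (length(result$analyzed) == 0) stop("no analysed clusters")
  sizes <- integer(0)
  percl <- list()
  for (ci in result$analyzed) {
    cl <- result$clusters[[ci]]
    sizes <- c(sizes, cl$size)
    tabs <- lapply(cl$poses, function(p) interaction_rows(result, p))
    tabs <- tabs[!vapply(tabs, is.null, TRUE)]
    if (length(tabs) == 0) {
      percl[[as.character(ci)]] <- NULL
      next
    }
    pool <- do.call(rbind, tabs)
    key <- do.call(paste, c(pool, sep = "|"))
    cnt <- table(key)
    first <- pool[match(names(cnt), key), , drop = FALSE]
    first$freq <- as.numeric(cnt) / cl$size * 100
    first$cluster <- ci
    percl[[as.character(ci)]] <- first
  }
  if (length(percl) == 0) {
    out <- data.frame(partner_chain = character(0),
                      partner_resno = integer(0),
                      partner_restype = character(0), type = character(0),
                      ligand_group = character(0), sidechain = logical(0),
                      frequency = numeric(0))
  } else {
    allrows <- do.call(rbind, percl)
    ids <- c("partner_chain", "partner_resno", "partner_restype", "type",
             "ligand_group", "sidechain")
    key <- do.call(paste, c(allrows[ids], sep = "|"))
    uk <- unique(key)
    wtot <- sum(sizes)
    cl_size <- stats::setNames(sizes, as.character(result$analyzed))
    out <- allrows[match(uk, key), ids, drop = FALSE]
    out$frequency <- vapply(uk, function(k) {
      rows <- allrows[key == k, , drop = FALSE]
      sum(rows$freq * cl_size[as.character(rows$cluster)]) / wtot
    }, 0)
    out <- out[order(-out$frequency, out$partner_resno), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "cluster_sizes") <- sizes
  attr(out, "clusters_used") <- result$analyzed
  attr(out, "site") <- result$site
  class(out) <- c("acr_fingerprint", class(out))
  out
}

#' Weighted average of per-cluster frequencies
#'
#' `sum(size_c * freq_c) / sum(size_c)`; exposed because the same weighting
#' underlies every reported frequency.
#'
#' @param freqs per-cluster frequencies (percent).
#' @param sizes cluster sizes.
#' @return weighted frequency (percent).
#' @export
weighted_frequency <- function(freqs, sizes) {
  stopifnot(length(freqs) == length(sizes))
  sum(freqs * sizes) / sum(sizes)
}

hbond_residue_groups <- list(
  positive = c("LYS", "ARG"),
  negative = c("ASP", "GLU"),
  polar = c("SER", "THR", "ASN", "GLN", "TYR", "HIS", "TRP", "CYS")
)

#' Shares of H-bond partner residue types from pooled counts
#'
#' Given counts of side-chain hydrogen-bond partners per residue type and
#' adduct group, computes the percentage share of each residue type within
#' its group and the combined shares of chemically similar classes
#' (positive = Lys + Arg, negative = Asp + Glu, polar = Ser/Thr/Asn/Gln/
#' Tyr/His/Trp/Cys, apolar = rest).
#'
#' @param counts data frame with columns `ligand_group`, `restype`, `count`.
#' @return list with `per_residue` and `grouped` data frames (shares in
#'   percent, 1 decimal).
#' @export
summarize_partner_counts <- function(counts) {
  counts <- counts[!is.na(counts$count) & counts$count > 0, , drop = FALSE]
  per <- do.call(rbind, lapply(split(counts, counts$ligand_group), function(g) {
    g$share_pct <- round(g$count / sum(g$count) * 100, 1)
    g[order(-g$count, g$restype), ]
  }))
  rownames(per) <- NULL
  grp_of <- function(rt) {
    for (g in names(hbond_residue_groups))
      if (rt %in% hbond_residue_groups[[g]]) return(g)
    "apolar"
  }
  per$class <- vapply(per$restype, grp_of, "")
  grouped <- do.call(rbind, lapply(split(per, per$ligand_group), function(g) {
    agg <- rowsum(g$count, g$class)
    data.frame(ligand_group = g$ligand_group[1], class = rownames(agg),
               count = as.numeric(agg),
               share_pct = round(as.numeric(agg) / sum(g$count) * 100, 1),
               stringsAsFactors = FALSE)
  }))
  rownames(grouped) <- NULL
  list(per_residue = per, grouped = grouped)
}

#' Pool fingerprints and summarise H-bond partners by residue type
#'
#' Side-chain hydrogen bonds with frequency above `threshold` percent are
#' pooled across dockings (one count per docking and partner residue) and
#' tallied by residue type, separately for the adduct's carbonyl and amino
#' groups.
#'
#' @param tables list of [fingerprint_result()] tables.
#' @param threshold display/pooling frequency threshold in percent.
#' @return as [summarize_partner_counts()], plus the pooled counts.
#' @export
summarize_by_residue_type <- function(tables, threshold = 60) {
  if (length(tables) == 0) stop("at least one fingerprint table required")
  if (inherits(tables, "acr_fingerprint")) tables <- list(tables)
  rows <- list()
  for (tb in tables) {
    q <- tb[tb$type == "hbond" & tb$sidechain &
              tb$ligand_group %in% c("carbonyl", "amino") &
              tb$frequency > threshold, , drop = FALSE]
    if (nrow(q) > 0)
      rows[[length(rows) + 1]] <- q[, c("ligand_group", "partner_restype")]
  }
  if (length(rows) == 0) {
    counts <- data.frame(ligand_group = character(0), restype = character(0),
                         count = numeric(0))
    return(list(per_residue = counts, grouped = counts, counts = counts))
  }
  pool <- do.call(rbind, rows)
  tab <- as.data.frame(table(pool$ligand_group, pool$partner_restype),
                       stringsAsFactors = FALSE)
  names(tab) <- c("ligand_group", "restype", "count")
  tab <- tab[tab$count > 0, , drop = FALSE]
  out <- summarize_partner_counts(tab)
  out$counts <- tab
  out
}

#' Join adduct H-bond partners with the pre-reaction microenvironment
#'
#' Produces the per-site narrative table: residues hydrogen-bonded to the
#' adduct (with frequency), nearby proton-acceptor candidates (His/Asp/Glu,
#' which may deprotonate the thiol) and positive residues (Lys/Arg, which
#' can stabilise the thiolate and the enolate-type intermediate), with
#' residues playing both roles flagged.
#'
#' @param result docking result (or its [fingerprint_result()]).
#' @param microenv [analyze_microenvironment()] of the same site.
#' @param threshold H-bond display threshold (percent).
#' @return data frame of class `acr_reaction_context`, one row per residue.
#' @export
annotate_reaction_context <- function(result, microenv, threshold = 60) {
  fp <- if (inherits(result, "acr_fingerprint")) result
  else fingerprint_result(result)
  site <- attr(fp, "site")
  if (!is.null(site) && !(microenv$cys %in% site))
    stop("microenvironment site ", microenv$cys,
         " does not match docking site ", paste(site, collapse = "+"))
  hb <- fp[fp$type == "hbond" & fp$frequency > threshold, , drop = FALSE]
  res <- unique(c(
    if (nrow(hb) > 0) paste(hb$partner_chain, hb$partner_resno, sep = ":"),
    microenv$proton_acceptors$residue,
    microenv$positive_residues$residue,
    microenv$hbond_partners$residue))
  if (length(res) == 0) {
    out <- data.frame(residue = character(0), restype = character(0),
                      hbond_to_adduct = logical(0), ligand_group = character(0),
                      frequency = numeric(0), proton_acceptor = logical(0),
                      positive = logical(0), hbond_to_s = logical(0))
    class(out) <- c("acr_reaction_context", class(out))
    return(out)
  }
  hbkey <- if (nrow(hb) > 0)
    paste(hb$partner_chain, hb$partner_resno, sep = ":") else character(0)
  restype_of <- function(r) {
    i <- match(r, hbkey)
    if (!is.na(i)) return(hb$partner_restype[i])
    for (tb in list(microenv$proton_acceptors, microenv$positive_residues,
                    microenv$hbond_partners)) {
      j <- match(r, tb$residue)
      if (!is.na(j)) return(tb$restype[j])
    }
    NA_character_
  }
  out <- data.frame(
    residue = res,
    restype = vapply(res, restype_of, ""),
    hbond_to_adduct = res %in% hbkey,
    ligand_group = vapply(res, function(r) {
      i <- match(r, hbkey)
      if (is.na(i)) NA_character_ else hb$ligand_group[i]
    }, ""),
    frequency = vapply(res, function(r) {
      i <- match(r, hbkey)
      if (is.na(i)) NA_real_ else hb$frequency[i]
    }, 0),
    proton_acceptor = res %in% microenv$proton_acceptors$residue,
    positive = res %in% microenv$positive_residues$residue,
    hbond_to_s = res %in% microenv$hbond_partners$residue,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("acr_reaction_context", class(out))
  out
}
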