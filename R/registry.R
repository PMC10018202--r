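#' Registry of reported acrylamide target proteins and candidate cysteines
#'
#' Published covalent-docking outcomes for acrylamide protein targets with
#' experimentally known reactive cysteines: per candidate site the
#' analysed-cluster composite score (a.u.), the top-cluster size (out of
#' 200 refined poses), whether the covalent bond was properly formed in the
#' top cluster, whether the site is the experimentally established primary
#' modification site, and — where reported — a second analysed cluster.
#' Transporter entries carry the conformational `state` (inward/outward)
#' of the structure docked. Scores are engine-specific arbitrary units and
#' comparable only within one protein; they serve as worked-example inputs
#' for the ranking stage.
#'
#' @return data frame, one row per (protein, state, site).
#' @export
acr_target_registry <- function() {
  utils::read.delim(system.file("extdata", "acr_targets.tsv",
                                package = "acrydock"),
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Reported side-chain H-bond partner tallies of the acrylamide adduct
#'
#' Pooled counts of protein residue types forming high-frequency (> 60%)
#' side-chain hydrogen bonds with the adduct, split by the adduct group
#' involved (carbonyl oxygen as acceptor vs amide group as donor). Carbonyl
#' rows carry raw counts; amino-group rows only the reported percentage
#' shares.
#'
#' @return data frame with columns `ligand_group`, `restype`, `count`,
#'   `share_pct`.
#' @export
acr_hbond_partner_registry <- function() {
  utils::read.delim(system.file("extdata", "acr_hbond_partners.tsv",
                                package = "acrydock"),
                    stringsAsFactors = FALSE, na.strings = "NA")
}
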