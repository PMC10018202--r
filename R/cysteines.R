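#' Enumerate cysteines and flag disulfide bridges
#'
#' Lists every cysteine residue of the structure. A cysteine is flagged
#' `disulfide` when its Sgamma lies within 2.3 Angstrom of another cysteine
#' Sgamma (the upper bound of an S-S bond) or when the pair appears in an
#' SSBOND record of the source PDB file. Free cysteines are candidates for
#' covalent modification.
#'
#' @param s an [acr_structure()].
#' @param ss_cutoff Sgamma-Sgamma distance (Angstrom) below which two
#'   cysteines are considered disulfide-bonded.
#' @return data frame with columns `chain`, `resno`, `sg_index` (row of the
#'   Sgamma atom), `disulfide`, `partner` (residue key of the S-S partner or
#'   `NA`) and `candidate` (`TRUE` for free cysteines).
#' @export
enumerate_cysteines <- function(s, ss_cutoff = 2.3) {
  at <- s$atoms
  idx <- which(at$resname == "CYS" & at$name == "SG" & !at$hetero)
  if (length(idx) == 0) {
    return(data.frame(chain = character(0), resno = integer(0),
                      sg_index = integer(0), disulfide = logical(0),
                      partner = character(0), candidate = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(chain = at$chain[idx], resno = at$resno[idx],
                    sg_index = idx, disulfide = FALSE,
                    partner = NA_character_, stringsAsFactors = FALSE)
  if (length(idx) > 1) {
    xyz <- as.matrix(at[idx, c("x", "y", "z")])
    d2 <- cross_dist2(xyz, xyz)
    diag(d2) <- Inf
    for (i in seq_along(idx)) {
      j <- which.min(d2[i, ])
      if (d2[i, j] <= ss_cutoff^2) {
        out$disulfide[i] <- TRUE
        out$partner[i] <- paste(out$chain[j], out$resno[j], sep = ":")
      }
    }
  }
  ss <- attr(s, "ssbond")
  if (!is.null(ss) && nrow(ss) > 0) {
    for (r in seq_len(nrow(ss))) {
      a <- which(out$chain == ss$chain1[r] & out$resno == ss$resno1[r])
      b <- which(out$chain == ss$chain2[r] & out$resno == ss$resno2[r])
      if (length(a) == 1 && length(b) == 1) {
        out$disulfide[c(a, b)] <- TRUE
        out$partner[a] <- paste(out$chain[b], out$resno[b], sep = ":")
        out$partner[b] <- paste(out$chain[a], out$resno[a], sep = ":")
      }
    }
  }
  out$candidate <- !out$disulfide
  out
}
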