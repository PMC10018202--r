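# Within-protein comparison of candidate modification sites. Composite
# scores are not normalised across proteins, so ranking is only ever done
# among cysteines of one protein docked with one configuration.

#' Did the top cluster form the covalent bond?
#'
#' The top cluster's representative must satisfy both covalent restraints
#' within three times their tolerance (|d - target| <= 3 * tolerance);
#' otherwise the site is flagged "no covalent bond formed" and excluded
#' from primary-site designation.
#'
#' @param result an `acr_docking_result`.
#' @return logical.
#' @export
covalent_bond_formed <- function(result) {
  rep <- representative_pose(result)
  tol <- 0.1
  all(rep$violations <= 2 * tol + 1e-9)  # violation = |d-t|-tol
}

site_table_from_results <- function(results) {
  cfgs <- lapply(results, function(r) {
    c <- r$config; c$seed <- NULL; c
  })
  if (length(results) > 1) {
    for (i in 2:length(results))
      if (!identical(cfgs[[1]], cfgs[[i]]))
        stop("results were produced with different configurations")
  }
  data.frame(
    site = vapply(results, function(r) paste(r$site, collapse = "+"), ""),
    score = vapply(results, function(r) r$clusters[[1]]$score, 0),
    size = vapply(results, function(r) r$clusters[[1]]$size, 0L),
    covalent = vapply(results, covalent_bond_formed, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Rank candidate cysteines of one protein by docking score
#'
#' Sites are ordered by ascending analysed-cluster score (more negative is
#' more favourable). Sites whose top cluster did not form the covalent bond
#' are flagged and excluded from primary designation. The primary site is
#' the best-scored covalent site; secondary sites are the remaining
#' covalent sites within `score_window` of it.
#'
#' @param results either a list of `acr_docking_result` objects from one
#'   protein (configurations must match) or a data frame with columns
#'   `site`, `score`, `size` and optionally `covalent` (default `TRUE`) and
#'   extra descriptor columns carried through.
#' @param protein protein identifier for the report.
#' @param score_window width (a.u.) of the secondary-site window.
#' @return object of class `acr_site_report`: the per-site table with
#'   `covalent` and `role` columns (`primary`/`secondary`/`other`/
#'   `"no covalent bond formed"`), `primary_site` and `secondary_sites`.
#' @export
rank_sites <- function(results, protein = NA_character_, score_window = 5) {
  tab <- if (is.data.frame(results)) {
    t <- results
    if (is.null(t$covalent)) t$covalent <- TRUE
    t
  } else site_table_from_results(results)
  if (nrow(tab) == 0) stop("no sites to rank")
  tab <- tab[order(tab$score, tab$site), , drop = FALSE]
  rownames(tab) <- NULL
  tab$role <- "other"
  tab$role[!tab$covalent] <- "no covalent bond formed"
  cov <- which(tab$covalent)
  primary <- NA_character_
  secondary <- character(0)
  if (length(cov) > 0) {
    primary <- tab$site[cov[1]]
    tab$role[cov[1]] <- "primary"
    sec <- cov[-1][tab$score[cov[-1]] <= tab$score[cov[1]] + score_window]
    if (length(sec) > 0) {
      tab$role[sec] <- "secondary"
      secondary <- tab$site[sec]
    }
  }
  structure(list(protein = protein, table = tab, primary_site = primary,
                 secondary_sites = secondary, score_window = score_window),
            class = "acr_site_report")
}

#' @export
print.acr_site_report <- function(x, ...) {
  cat("Site ranking", if (!is.na(x$protein)) paste0("(", x$protein, ")"), "\n")
  print(x$table[, c("site", "score", "size", "covalent", "role")],
        row.names = FALSE)
  invisible(x)
}

#' Compare docking of one cysteine across conformational states
#'
#' For proteins whose accessibility changes during the functional cycle
#' (e.g. inward- vs outward-facing transporter states), the same cysteine
#' is docked in each state's structure and the state with the more
#' favourable score is reported together with the score gap.
#'
#' @param results named list of `acr_docking_result` objects (one per
#'   state) or a named numeric vector of analysed-cluster scores.
#' @return list of class `acr_state_comparison`: ordered `table`
#'   (state, score), `preferred` state, `gap` to the runner-up and a `tie`
#'   flag.
#' @export
compare_states <- function(results) {
  scores <- if (is.numeric(results)) results
  else vapply(results, function(r) r$clusters[[1]]$score, 0)
  if (length(scores) < 2)
    stop("state comparison needs results for at least two states")
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("states must be named")
  ord <- order(scores, names(scores))
  tab <- data.frame(state = names(scores)[ord], score = unname(scores[ord]),
                    stringsAsFactors = FALSE)
  gap <- tab$score[2] - tab$score[1]
  structure(list(table = tab, preferred = tab$state[1], gap = gap,
                 tie = gap == 0), class = "acr_state_comparison")
}

#' @export
print.acr_state_comparison <- function(x, ...) {
  if (x$tie) cat("States tie at", x$table$score[1], "a.u.\n")
  else cat(sprintf("Preferred state: %s (gap %.1f a.u.)\n", x$preferred, x$gap))
  print(x$table, row.names = FALSE)
  invisible(x)
}

report_payload <- function(reports, fingerprints) {
  if (inherits(reports, "acr_site_report")) reports <- list(reports)
  payload <- lapply(reports, function(r) {
    list(protein = r$protein, primary_site = r$primary_site,
         secondary_sites = r$secondary_sites,
         score_window = r$score_window, sites = r$table)
  })
  fps <- NULL
  if (!is.null(fingerprints)) {
    if (inherits(fingerprints, "acr_fingerprint"))
      fingerprints <- list(fingerprints)
    fps <- lapply(fingerprints, function(fp) {
      df <- as.data.frame(fp)
      list(site = paste(attr(fp, "site"), collapse = "+"),
           cluster_sizes = attr(fp, "cluster_sizes"),
           interactions = df)
    })
  }
  list(reports = payload, fingerprints = fps)
}

#' Render site-ranking reports to TSV, JSON or Markdown
#'
#' Output is deterministic: rendering the same inputs twice yields
#' byte-identical files.
#'
#' @param reports one `acr_site_report` or a list of them.
#' @param fingerprints optional fingerprint table(s) to append.
#' @param format `"tsv"`, `"json"` or `"markdown"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
render_report <- function(reports, fingerprints = NULL,
                          format = c("tsv", "json", "markdown"), path) {
  format <- match.arg(format)
  payload <- report_payload(reports, fingerprints)
  if (format == "json") {
    json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, dataframe = "rows")
    writeLines(json, path)
    return(invisible(path))
  }
  lines <- character(0)
  for (r in payload$reports) {
    tab <- r$sites
    if (format == "tsv") {
      lines <- c(lines, paste0("# protein\t", r$protein),
                 paste(names(tab), collapse = "\t"),
                 vapply(seq_len(nrow(tab)), function(i)
                   paste(vapply(tab[i, ], as.character, ""), collapse = "\t"),
                   ""))
    } else {
      lines <- c(lines, paste("##", r$protein), "",
                 paste("|", paste(names(tab), collapse = " | "), "|"),
                 paste("|", paste(rep("---", ncol(tab)), collapse = " | "), "|"),
                 vapply(seq_len(nrow(tab)), function(i)
                   paste("|", paste(vapply(tab[i, ], as.character, ""),
                                    collapse = " | "), "|"), ""),
                 "",
                 paste0("Primary site: ", r$primary_site,
                        if (length(r$secondary_sites) > 0)
                          paste0("; secondary: ",
                                 paste(r$secondary_sites, collapse = ", "))
                        else "; no secondary sites"),
                 "")
    }
  }
  if (!is.null(payload$fingerprints)) {
    for (fp in payload$fingerprints) {
      tab <- fp$interactions
      hdr <- paste0(if (format == "tsv") "# fingerprint\t" else "## fingerprint ",
                    fp$site)
      lines <- c(lines, hdr)
      if (nrow(tab) == 0) {
        lines <- c(lines, if (format == "tsv") paste(names(tab), collapse = "\t")
                   else "(no interactions)")
        next
      }
      tab$frequency <- sprintf("%.1f", tab$frequency)
      if (format == "tsv") {
        lines <- c(lines, paste(names(tab), collapse = "\t"),
                   vapply(seq_len(nrow(tab)), function(i)
                     paste(vapply(tab[i, ], as.character, ""), collapse = "\t"),
                     ""))
      } else {
        lines <- c(lines,
                   paste("|", paste(names(tab), collapse = " | "), "|"),
                   paste("|", paste(rep("---", ncol(tab)), collapse = " | "), "|"),
                   vapply(seq_len(nrow(tab)), function(i)
                     paste("|", paste(vapply(tab[i, ], as.character, ""),
                                      collapse = " | "), "|"), ""), "")
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
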