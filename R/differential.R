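#' @include AllClasses.R quantify.R
NULL

#' Two-sample pooled-variance t-test for one cysteine site
#'
#' Student's two-sample t-test with pooled variance, two-tailed p-value from
#' the t distribution on \code{n1 + n2 - 2} degrees of freedom, applied to a
#' site's oxidation percentages. Degenerate inputs follow fixed conventions:
#' with zero pooled variance the p-value is 1 when the group means are equal
#' and 0 when they differ; the relative increase is \code{+Inf} when the
#' control mean is 0 and the depleted mean positive, and 0 when both are 0.
#'
#' @param control,depleted numeric vectors of oxidation percentages (each of
#'   length >= 2).
#' @return a list with \code{delta_abs} (depleted mean minus control mean,
#'   percentage points), \code{rel_increase} (\code{delta_abs / mean_control},
#'   dimensionless), \code{p_value}, plus the group means and the t
#'   statistic.
#' @examples
#' testSite(c(10, 11, 12), c(13, 14, 15))
#' @export
testSite <- function(control, depleted) {
  control <- as.numeric(control)
  depleted <- as.numeric(depleted)
  if (length(control) < 2L || length(depleted) < 2L)
    stop("insufficient replicates: each group needs >= 2 values")
  n1 <- length(control); n2 <- length(depleted)
  m1 <- mean(control); m2 <- mean(depleted)
  deltaAbs <- m2 - m1
  relIncrease <- if (m1 == 0) {
    if (m2 > 0) Inf else if (m2 < 0) -Inf else 0
  } else deltaAbs / m1
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * stats::var(control) +
          (n2 - 1L) * stats::var(depleted)) / df
  if (sp2 == 0) {
    tStat <- if (deltaAbs == 0) 0 else sign(deltaAbs) * Inf
    p <- if (deltaAbs == 0) 1 else 0
  } else {
    tStat <- deltaAbs / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tStat), df)
  }
  list(mean_control = m1, mean_depleted = m2, delta_abs = deltaAbs,
       rel_increase = relIncrease, t = tStat, p_value = p)
}

#' Call cysteines with significantly increased oxidation
#'
#' Tests every site with the pooled-variance t-test and applies the
#' three-part composite rule for an "increased oxidation" call: the raw
#' p-value below \code{alpha}, a relative oxidation increase of at least
#' \code{relMin}, and membership in the top \code{topFrac} of all tested
#' sites ranked by the absolute increase (descending, ties broken by site id
#' so the boundary is deterministic). The top set contains
#' \code{ceiling(topFrac * N)} sites computed over all tested sites, not
#' only nominally significant ones. Raw p-values gate the calls; a
#' Benjamini-Hochberg FDR column is emitted for reference but never used in
#' the rule. Sites with decreased oxidation are reported (negative
#' \code{delta_abs}) but never called.
#'
#' @param profile a (typically filtered) \linkS4class{OxidationProfile}.
#' @param alpha p-value cutoff (default 0.05).
#' @param relMin minimum relative increase (default 0.25, i.e. 25\%).
#' @param topFrac top fraction by absolute increase (default 0.15).
#' @return a data.frame (one row per tested site, input order) with columns
#'   \code{site_id}, \code{protein_accession}, \code{site_position},
#'   \code{n_control}, \code{n_depleted}, \code{mean_control},
#'   \code{mean_depleted}, \code{delta_abs}, \code{rel_increase},
#'   \code{p_value}, \code{bh_fdr}, \code{rank_delta} (1 = largest absolute
#'   increase), \code{in_top}, \code{called}; the fraction of sites called
#'   is attached as attribute \code{fraction_called}.
#' @export
callIncreasedOxidation <- function(profile, alpha = 0.05, relMin = 0.25,
                                   topFrac = 0.15) {
  stopifnot(is(profile, "OxidationProfile"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (topFrac <= 0 || topFrac > 1) stop("topFrac must lie in (0, 1]")
  if (nrow(profile) == 0L) stop("no tested sites: empty oxidation profile")
  pct <- oxidationPercent(profile)
  grp <- SummarizedExperiment::colData(profile)$group
  rd <- SummarizedExperiment::rowData(profile)
  n <- nrow(pct)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    ctrl <- pct[i, grp == "control"]
    dep <- pct[i, grp == "depleted"]
    res[[i]] <- testSite(ctrl[!is.na(ctrl)], dep[!is.na(dep)])
  }
  out <- data.frame(
    site_id = rownames(pct),
    protein_accession = rd$protein_accession,
    site_position = rd$site_position,
    n_control = rd$n_quant_control,
    n_depleted = rd$n_quant_depleted,
    mean_control = vapply(res, `[[`, numeric(1), "mean_control"),
    mean_depleted = vapply(res, `[[`, numeric(1), "mean_depleted"),
    delta_abs = vapply(res, `[[`, numeric(1), "delta_abs"),
    rel_increase = vapply(res, `[[`, numeric(1), "rel_increase"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  out$bh_fdr <- stats::p.adjust(out$p_value, method = "BH")
  ord <- order(-out$delta_abs, out$site_id)
  rankDelta <- integer(n)
  rankDelta[ord] <- seq_len(n)
  out$rank_delta <- rankDelta
  nTop <- as.integer(ceiling(topFrac * n))
  out$in_top <- rankDelta <= nTop
  out$called <- out$p_value < alpha & out$rel_increase >= relMin & out$in_top
  attr(out, "fraction_called") <- mean(out$called)
  attr(out, "n_top") <- nTop
  out
}

#' Rank proteins by number of called cysteine sites
#'
#' Groups called sites by protein accession and ranks proteins by the count
#' of cysteines with increased oxidation, descending, ties broken by
#' accession (ascending) for determinism. The top of this ranking is the
#' oxidation "hotspot" candidate.
#'
#' @param results data.frame from [callIncreasedOxidation()].
#' @return data.frame with \code{protein_accession}, \code{n_called_sites},
#'   \code{rank} (1 = most called sites); zero rows if nothing is called.
#' @export
rankProteins <- function(results) {
  called <- results[results$called, , drop = FALSE]
  if (!nrow(called))
    return(data.frame(protein_accession = character(0),
                      n_called_sites = integer(0), rank = integer(0)))
  tab <- table(called$protein_accession)
  out <- data.frame(protein_accession = names(tab),
                    n_called_sites = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_called_sites, out$protein_accession), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Map called sites onto protein domains
#'
#' Assigns each called site the unique annotated domain interval containing
#' its position (1-based, inclusive ends: a site at the last residue of a
#' domain is inside it), or \code{"unannotated"} when no interval covers it.
#'
#' @param results data.frame from [callIncreasedOxidation()]; only called
#'   sites are mapped.
#' @param annot validated domain annotation data.frame (see
#'   [readDomainAnnotation()]).
#' @return a list with \code{map} (site_id, protein_accession,
#'   site_position, domain_label) and \code{counts} (domain_label, n_sites).
#' @export
mapSitesToDomains <- function(results, annot) {
  annot <- validateDomainAnnotation(annot)
  called <- results[results$called, , drop = FALSE]
  lab <- rep("unannotated", nrow(called))
  if (nrow(called) && nrow(annot)) {
    for (acc in unique(called$protein_accession)) {
      ai <- annot[annot$protein_accession == acc, , drop = FALSE]
      if (!nrow(ai)) next
      rows <- which(called$protein_accession == acc)
      hit <- IRanges::findOverlaps(
        IRanges::IRanges(called$site_position[rows], width = 1L),
        IRanges::IRanges(ai$start, ai$end), select = "first")
      ok <- !is.na(hit)
      lab[rows[ok]] <- ai$domain_label[hit[ok]]
    }
  }
  map <- data.frame(site_id = called$site_id,
                    protein_accession = called$protein_accession,
                    site_position = called$site_position,
                    domain_label = lab, stringsAsFactors = FALSE)
  counts <- as.data.frame(table(domain_label = lab),
                          stringsAsFactors = FALSE)
  names(counts)[2L] <- "n_sites"
  counts <- counts[order(-counts$n_sites, counts$domain_label), , drop = FALSE]
  rownames(counts) <- NULL
  list(map = map, counts = counts)
}
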