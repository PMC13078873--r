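#' @include AllClasses.R io.R
NULL

.countCys <- function(pep) {
  nchar(pep) - nchar(gsub("C", "", pep, fixed = TRUE))
}

#' Aggregate PSM reporter values to cysteine sites
#'
#' Rolls peptide-level reporter signal-to-noise up to sites: for each site
#' (protein accession + 1-based cysteine position) and channel, the site
#' value is the sum of that channel's S/N over all contributing PSMs (sums
#' preserve linearity and are the conventional isobaric-label roll-up).
#' PSMs whose peptide contains more than one cysteine are excluded — the
#' label cannot be localized to a single site — and counted in the exclusion
#' report (\code{metadata(x)$n_excluded_multi_cys}). Channel values are then
#' mapped to (sample, fraction) through the plex design.
#'
#' An optional per-channel median-centering normalization (each channel of a
#' plex scaled so its median S/N equals the plex grand median) is available
#' but off by default: the oxidized/total ratio is taken within one sample,
#' so loading differences largely cancel.
#'
#' @param psms validated PSM data.frame (see [readPsmTable()]).
#' @param design a \linkS4class{PlexDesign} covering every plex and channel
#'   the PSMs reference.
#' @param normalize logical; apply per-channel median centering (default
#'   \code{FALSE}).
#' @return a \linkS4class{SiteQuant} (rows: sites, columns: biological
#'   samples, assays \code{oxidized} and \code{total}).
#' @examples
#' pd <- plexDesign(data.frame(
#'   channel_id = c("126", "127N"), sample_id = "m1",
#'   group = "control", fraction = c("oxidized", "total")))
#' psms <- data.frame(peptide_sequence = "ACK", protein_accession = "P1",
#'                    site_position = 2, plex_id = "plex1",
#'                    "126" = 10, "127N" = 40, check.names = FALSE)
#' sq <- aggregatePsmsToSites(psms, pd)
#' oxidizedSN(sq)
#' @export
aggregatePsmsToSites <- function(psms, design, normalize = FALSE) {
  stopifnot(is(design, "PlexDesign"))
  dtab <- designTable(design)
  chan <- setdiff(names(psms), PSM_FIXED_COLS)
  if (!length(chan)) stop("PSM table has no channel columns")

  multi <- .countCys(psms$peptide_sequence) > 1L
  nExcluded <- sum(multi)
  excludedPeptides <- unique(psms$peptide_sequence[multi])
  psms <- psms[!multi, , drop = FALSE]

  ## any channel actually quantified in a plex must exist in the design
  for (px in unique(psms$plex_id)) {
    if (!px %in% dtab$plex_id)
      stop(sprintf("plex '%s' in PSM table absent from design", px))
    sub <- psms[psms$plex_id == px, chan, drop = FALSE]
    used <- chan[colSums(!is.na(sub)) > 0L]
    bad <- setdiff(used, dtab$channel_id[dtab$plex_id == px])
    if (length(bad))
      stop(sprintf("channel(s) %s quantified in plex '%s' but absent from design",
                   paste(bad, collapse = ", "), px))
  }

  if (normalize) {
    for (px in unique(psms$plex_id)) {
      rows <- psms$plex_id == px
      meds <- vapply(chan, function(cc)
        stats::median(psms[[cc]][rows], na.rm = TRUE), numeric(1))
      grand <- stats::median(meds, na.rm = TRUE)
      for (cc in chan) {
        if (is.finite(meds[[cc]]) && meds[[cc]] > 0)
          psms[[cc]][rows] <- psms[[cc]][rows] * (grand / meds[[cc]])
      }
    }
  }

  siteId <- paste0(psms$protein_accession, ":", psms$site_position)
  if (!nrow(psms))
    stop("no PSMs left after multi-cysteine exclusion")
  sites <- unique(siteId)
  siteF <- factor(siteId, levels = sites)

  sampleTab <- unique(dtab[, c("sample_id", "group")])
  samples <- sampleTab$sample_id
  ox <- matrix(NA_real_, length(sites), length(samples),
               dimnames = list(sites, samples))
  tot <- ox
  sumAbsent <- function(v, f) {
    s <- rowsum(ifelse(is.na(v), 0, v), f)[, 1L]
    n <- rowsum(as.numeric(!is.na(v)), f)[, 1L]
    s[n == 0] <- NA_real_
    s
  }
  for (r in seq_len(nrow(dtab))) {
    rows <- psms$plex_id == dtab$plex_id[r]
    if (!any(rows)) next
    v <- psms[[dtab$channel_id[r]]][rows]
    agg <- sumAbsent(v, siteF[rows])
    target <- if (dtab$fraction[r] == "oxidized") "ox" else "tot"
    m <- get(target)
    keep <- !is.na(agg)
    m[names(agg)[keep], dtab$sample_id[r]] <- agg[keep]
    assign(target, m)
  }

  nPsm <- as.integer(table(siteF))
  firstIdx <- match(sites, siteId)
  rd <- S4Vectors::DataFrame(
    protein_accession = psms$protein_accession[firstIdx],
    site_position = psms$site_position[firstIdx],
    n_psm = nPsm, row.names = sites)
  cd <- S4Vectors::DataFrame(sample_id = samples, group = sampleTab$group,
                             row.names = samples)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(oxidized = ox, total = tot), rowData = rd, colData = cd,
    metadata = list(n_excluded_multi_cys = nExcluded,
                    excluded_peptides = excludedPeptides,
                    normalized = normalize))
  new("SiteQuant", se)
}

#' Compute per-site, per-sample oxidation percentages
#'
#' The core site statistic: \code{100 * oxidized_SN / total_SN} for each site
#' in each biological sample, i.e. the reversibly oxidized share of that
#' cysteine's total signal. Cells where either parent value is absent or the
#' total signal is zero are \code{NA}. Values above 100\% are kept, not
#' clamped (clamping would bias the downstream t-test); their count is
#' recorded in \code{metadata(x)$n_over_100} for QC.
#'
#' @param sites a \linkS4class{SiteQuant}.
#' @return an \linkS4class{OxidationProfile} with assay
#'   \code{oxidation_percent} and per-group quantified-replicate counts in
#'   \code{rowData}.
#' @export
computeOxidationPercent <- function(sites) {
  stopifnot(is(sites, "SiteQuant"))
  ox <- oxidizedSN(sites)
  tot <- totalSN(sites)
  pct <- 100 * ox / tot
  pct[!is.na(tot) & tot == 0] <- NA_real_
  pct[is.na(ox) | is.na(tot)] <- NA_real_
  grp <- SummarizedExperiment::colData(sites)$group
  rd <- SummarizedExperiment::rowData(sites)
  rd$n_quant_control <- rowSums(!is.na(pct[, grp == "control", drop = FALSE]))
  rd$n_quant_depleted <- rowSums(!is.na(pct[, grp == "depleted", drop = FALSE]))
  md <- S4Vectors::metadata(sites)
  md$n_over_100 <- sum(pct > 100, na.rm = TRUE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(oxidation_percent = pct), rowData = rd,
    colData = SummarizedExperiment::colData(sites), metadata = md)
  new("OxidationProfile", se)
}

#' Filter sites by quantification completeness
#'
#' Retains sites with at least \code{minReps} non-absent oxidation
#' percentages in each group, so every retained site supports the two-sample
#' t-test. Row order is preserved.
#'
#' @param profile an \linkS4class{OxidationProfile}.
#' @param minReps minimum quantified replicates per group (>= 2).
#' @return the filtered \linkS4class{OxidationProfile}.
#' @export
filterQuantifiedSites <- function(profile, minReps = 2) {
  stopifnot(is(profile, "OxidationProfile"))
  if (minReps < 2)
    stop("minReps must be >= 2: the per-site t-test needs two replicates per group")
  rd <- SummarizedExperiment::rowData(profile)
  keep <- rd$n_quant_control >= minReps & rd$n_quant_depleted >= minReps
  profile[keep, ]
}
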