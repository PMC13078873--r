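#' @import methods
#' @importFrom S4Vectors metadata DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

## Standard 20-letter amino-acid alphabet (alphabetical); 'X' marks an
## unknown residue or a window position beyond the protein terminus.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GROUP_LEVELS    <- c("control", "depleted")
FRACTION_LEVELS <- c("oxidized", "total")

#' PlexDesign: channel-to-sample mapping of a multiplexed experiment
#'
#' Maps every multiplex reporter channel to a biological sample, an
#' experimental group (\code{control} or \code{depleted}) and a half-sample
#' fraction (\code{oxidized}, the oxidized-cysteine-enriched aliquot, or
#' \code{total}, the total-cysteine aliquot). The design is the pairing
#' backbone of the whole analysis: the per-site oxidation percentage is the
#' ratio of a sample's oxidized-fraction channel to its total-fraction
#' channel, so every sample must carry both fractions.
#'
#' @slot design a \code{data.frame} with columns \code{plex_id},
#'   \code{channel_id}, \code{sample_id}, \code{group}, \code{fraction}.
#'
#' @section Validity:
#' Within each plex, channel ids are unique, every (sample, fraction) pair
#' occurs exactly once, and every sample occurs with both fractions (a sample
#' split across plexes would have no within-run pairing and is rejected).
#'
#' @seealso [plexDesign()], [readPlexDesign()]
#' @export
setClass("PlexDesign", representation(design = "data.frame"))

setValidity("PlexDesign", function(object) {
  d <- object@design
  need <- c("plex_id", "channel_id", "sample_id", "group", "fraction")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(sprintf("missing design column(s): %s", paste(miss, collapse = ", ")))
  if (!all(d$group %in% GROUP_LEVELS))
    return(sprintf("unknown group token(s): %s",
                   paste(unique(setdiff(d$group, GROUP_LEVELS)), collapse = ", ")))
  if (!all(d$fraction %in% FRACTION_LEVELS))
    return(sprintf("unknown fraction token(s): %s",
                   paste(unique(setdiff(d$fraction, FRACTION_LEVELS)), collapse = ", ")))
  for (px in unique(d$plex_id)) {
    dp <- d[d$plex_id == px, ]
    dup <- dp$channel_id[duplicated(dp$channel_id)]
    if (length(dup))
      return(sprintf("duplicate channel_id within plex '%s': %s",
                     px, paste(unique(dup), collapse = ", ")))
    key <- paste(dp$sample_id, dp$fraction)
    if (anyDuplicated(key))
      return(sprintf("duplicated (sample, fraction) pair within plex '%s': %s",
                     px, paste(unique(key[duplicated(key)]), collapse = ", ")))
    tab <- table(dp$sample_id)
    lone <- names(tab)[tab != 2L]
    if (length(lone))
      return(sprintf("sample(s) without both fractions in plex '%s': %s",
                     px, paste(lone, collapse = ", ")))
  }
  ## same sample in two plexes would duplicate its (sample, fraction) pairing
  if (anyDuplicated(unique(d[, c("plex_id", "sample_id")])$sample_id))
    return("a sample_id may not span multiple plexes")
  gr <- unique(d[, c("sample_id", "group")])
  if (anyDuplicated(gr$sample_id))
    return("a sample_id is assigned to more than one group")
  TRUE
})

#' SimConfig: parameters of the synthetic redoxome generator
#'
#' Holds every knob of the synthetic-experiment generator: replicate counts,
#' number of cysteine sites, the fraction of sites that carry a planted
#' oxidation increase, the baseline-oxidation Beta distribution, the additive
#' effect size on the oxidation-fraction scale, reporter-noise level,
#' hotspot-protein site count, flanking-motif bias and the RNG seed.
#'
#' @slot nPerGroup integer, biological replicates per group.
#' @slot nSites integer, total cysteine sites simulated.
#' @slot fracPlanted numeric in [0, 1], fraction of sites with a planted
#'   oxidation increase in the depleted group.
#' @slot betaShape1,betaShape2 shape parameters of the Beta distribution the
#'   control-group true oxidation fraction is drawn from.
#' @slot delta additive increase of the true oxidation fraction at planted
#'   sites (depleted group), clamped so the fraction stays below 0.99.
#' @slot abundanceSigma log-normal sdlog of per-site total abundance.
#' @slot noiseCv multiplicative coefficient of variation of reporter
#'   signal-to-noise; 0 gives noise-free channels.
#' @slot hotspotSites number of planted sites concentrated on the single
#'   designated hotspot protein.
#' @slot motifBias probability that a planted site's flank carries K or R at
#'   positions -5 and -6.
#' @slot seed integer RNG seed.
#'
#' @seealso [simConfig()], [generateExperiment()]
#' @export
setClass("SimConfig", representation(
  nPerGroup      = "integer",
  nSites         = "integer",
  fracPlanted    = "numeric",
  betaShape1     = "numeric",
  betaShape2     = "numeric",
  delta          = "numeric",
  abundanceSigma = "numeric",
  noiseCv        = "numeric",
  hotspotSites   = "integer",
  motifBias      = "numeric",
  seed           = "integer"
))

setValidity("SimConfig", function(object) {
  if (object@nPerGroup < 2L)
    return("nPerGroup must be >= 2 (the t-test needs two replicates per group)")
  if (object@nSites < 1L) return("nSites must be >= 1")
  if (object@fracPlanted < 0 || object@fracPlanted > 1)
    return("fracPlanted must lie in [0, 1]")
  if (object@betaShape1 <= 0 || object@betaShape2 <= 0)
    return("Beta shape parameters must be positive")
  if (object@delta < 0 || object@delta >= 1)
    return("delta must lie in [0, 1)")
  if (object@abundanceSigma < 0) return("abundanceSigma must be >= 0")
  if (object@noiseCv < 0) return("noiseCv must be >= 0")
  if (object@hotspotSites < 0L) return("hotspotSites must be >= 0")
  if (object@motifBias < 0 || object@motifBias > 1)
    return("motifBias must lie in [0, 1]")
  TRUE
})

#' SiteQuant: site-by-sample reporter quantification
#'
#' A \linkS4class{SummarizedExperiment} with one row per cysteine site and one
#' column per biological sample, carrying two assays: \code{oxidized} (summed
#' reporter signal-to-noise of the sample's oxidized-fraction channel) and
#' \code{total} (same for the total-fraction channel). Row data record the
#' protein accession, 1-based site position and contributing PSM count;
#' metadata record how many PSMs were excluded for carrying more than one
#' cysteine.
#'
#' @seealso [aggregatePsmsToSites()], [oxidizedSN()], [totalSN()]
#' @export
setClass("SiteQuant", contains = "SummarizedExperiment")

setValidity("SiteQuant", function(object) {
  if (!all(c("oxidized", "total") %in% SummarizedExperiment::assayNames(object)))
    return("assays 'oxidized' and 'total' are required")
  if (anyDuplicated(rownames(object)))
    return("site ids (rownames) must be unique")
  for (a in c("oxidized", "total")) {
    v <- SummarizedExperiment::assay(object, a)
    if (any(v < 0, na.rm = TRUE))
      return(sprintf("assay '%s' contains negative values", a))
  }
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    return("colData must carry a 'group' column")
  TRUE
})

#' OxidationProfile: per-site, per-sample oxidation percentage
#'
#' A \linkS4class{SummarizedExperiment} with assay \code{oxidation_percent},
#' the core statistic of the analysis: 100 times the ratio of a site's
#' oxidized-fraction signal to its total-fraction signal in one biological
#' sample. Values above 100 are retained (reporter noise can push the ratio
#' past 1); cells where either parent signal is absent, or the total signal is
#' zero, are \code{NA}.
#'
#' @seealso [computeOxidationPercent()], [oxidationPercent()]
#' @export
setClass("OxidationProfile", contains = "SummarizedExperiment")

setValidity("OxidationProfile", function(object) {
  if (!"oxidation_percent" %in% SummarizedExperiment::assayNames(object))
    return("assay 'oxidation_percent' is required")
  v <- SummarizedExperiment::assay(object, "oxidation_percent")
  if (any(v < 0, na.rm = TRUE))
    return("oxidation percentages must be >= 0")
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    return("colData must carry a 'group' column")
  TRUE
})

#' FlankSet: fixed-width sequence windows around cysteine sites
#'
#' Sequences of length \code{2w + 1} centered on a cysteine (position 0);
#' positions are indexed -w..-1, +1..+w and the center is excluded from motif
#' testing. Window positions beyond a protein terminus are padded with 'X',
#' which is excluded from both foreground counts and per-position denominators
#' downstream.
#'
#' @slot w integer window half-width.
#' @slot sequences character vector of 2w+1-mers with 'C' at the center.
#'
#' @seealso [extractFlanks()], [buildMotifResult()]
#' @export
setClass("FlankSet", representation(w = "integer", sequences = "character"))

setValidity("FlankSet", function(object) {
  if (object@w < 1L) return("w must be >= 1")
  len <- 2L * object@w + 1L
  if (length(object@sequences) && !all(nchar(object@sequences) == len))
    return(sprintf("all sequences must have length 2w+1 = %d", len))
  if (length(object@sequences)) {
    ctr <- substr(object@sequences, object@w + 1L, object@w + 1L)
    if (!all(ctr == "C"))
      return("center residue (position 0) must be 'C' for every sequence")
    if (!all(strsplit(paste(object@sequences, collapse = ""), "")[[1]] %in%
             c(AA20, "X")))
      return("sequences may only contain the 20 standard residues and 'X'")
  }
  TRUE
})

#' MotifResult: binomial log-odds motif statistics
#'
#' Per (position, residue) cell: the foreground count \code{k}, the number of
#' foreground sequences with a real (non-'X') residue at that position
#' \code{n}, the background frequency \code{p0}, and the signed binomial
#' log-odds \code{score} (positive = overrepresented, negative =
#' underrepresented). Cells with \code{|score|} at or above the
#' Bonferroni-corrected \code{threshold} are flagged significant. The
#' position weight matrix \code{pwm} holds per-position foreground residue
#' frequencies (columns sum to 1 over real residues).
#'
#' @slot cells data.frame with columns position, residue, k, n, p0, score,
#'   significant.
#' @slot pwm 20 x (2w+1) numeric matrix of foreground residue frequencies.
#' @slot threshold significance cutoff on |score|.
#' @slot alpha nominal family-wise error rate behind the threshold.
#' @slot w window half-width.
#' @slot nForeground,nBackground sequence counts.
#'
#' @seealso [buildMotifResult()], [significanceThreshold()]
#' @export
setClass("MotifResult", representation(
  cells       = "data.frame",
  pwm         = "matrix",
  threshold   = "numeric",
  alpha       = "numeric",
  w           = "integer",
  nForeground = "integer",
  nBackground = "integer"
))

setValidity("MotifResult", function(object) {
  need <- c("position", "residue", "k", "n", "p0", "score", "significant")
  if (!all(need %in% names(object@cells)))
    return("cells must have columns position, residue, k, n, p0, score, significant")
  if (object@threshold <= 0) return("threshold must be positive")
  cl <- object@cells
  if (any(cl$k < 0 | cl$k > cl$n)) return("0 <= k <= n violated")
  if (any(cl$p0 < 0 | cl$p0 > 1, na.rm = TRUE)) return("p0 must lie in [0, 1]")
  TRUE
})
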