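#' @include AllClasses.R io.R
NULL

TMT16_CHANNELS <- c("126", "127N", "127C", "128N", "128C", "129N", "129C",
                    "130N", "130C", "131N", "131C", "132N", "132C", "133N",
                    "133C", "134N")

## Each simulated cysteine site occupies one 15-residue block of its protein,
## with the Cys at block offset 8; blocks are concatenated, so sites on one
## protein are spaced 15 residues apart and each yields a single-Cys peptide.
BLOCK_LEN <- 15L
CYS_OFF   <- 8L

#' Construct a synthetic-experiment configuration
#'
#' Defaults describe the study conditions the generator emulates: two groups
#' (control vs glutathione-depleted) of 7 biological replicates, 10,000
#' cysteine sites of which 1.8\% carry a planted oxidation increase of +0.15
#' on the fraction scale, baseline oxidation drawn from Beta(2, 18) (mean
#' 0.10), 10 of the planted sites concentrated on a single hotspot protein,
#' 10\% multiplicative reporter noise, and an 80\% chance that a planted
#' site's flank carries K or R at positions -5 and -6.
#'
#' @param nPerGroup replicates per group (>= 2).
#' @param nSites total cysteine sites.
#' @param fracPlanted fraction of sites with a planted increase.
#' @param betaShape1,betaShape2 Beta parameters of the control oxidation
#'   fraction.
#' @param delta additive oxidation-fraction increase at planted sites
#'   (clamped so the depleted fraction stays <= 0.99).
#' @param abundanceSigma log-normal sdlog of per-site total abundance.
#' @param noiseCv multiplicative coefficient of variation of reporter
#'   signal-to-noise (0 = noise-free).
#' @param hotspotSites planted sites placed on the designated hotspot
#'   protein (capped at the total planted count).
#' @param motifBias probability a planted site's flank carries K or R at
#'   positions -5 and -6.
#' @param seed integer RNG seed; identical seeds give byte-identical output.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' simConfig(nSites = 500, seed = 7)
#' @export
simConfig <- function(nPerGroup = 7, nSites = 10000, fracPlanted = 0.018,
                      betaShape1 = 2, betaShape2 = 18, delta = 0.15,
                      abundanceSigma = 1, noiseCv = 0.1, hotspotSites = 10,
                      motifBias = 0.8, seed = 1) {
  new("SimConfig",
      nPerGroup = as.integer(nPerGroup), nSites = as.integer(nSites),
      fracPlanted = as.numeric(fracPlanted),
      betaShape1 = as.numeric(betaShape1), betaShape2 = as.numeric(betaShape2),
      delta = as.numeric(delta), abundanceSigma = as.numeric(abundanceSigma),
      noiseCv = as.numeric(noiseCv), hotspotSites = as.integer(hotspotSites),
      motifBias = as.numeric(motifBias), seed = as.integer(seed))
}

## Site-to-protein layout: hotspot protein first (all its sites planted),
## then "carrier" proteins holding at most 2 planted sites each (plus
## unplanted filler), then background proteins of up to 5 sites. Guarantees
## by construction that no protein other than the hotspot can yield more
## than 2 true-positive calls.
.siteLayout <- function(nSites, nPlanted, hotspotSites) {
  h <- min(hotspotSites, nPlanted)
  acc <- character(nSites)
  within <- integer(nSites)
  planted <- logical(nSites)
  hotspotAcc <- NA_character_
  i <- 1L; prot <- 0L
  if (h > 0L) {
    hotspotAcc <- "SYNHOT1"
    acc[i:(i + h - 1L)] <- hotspotAcc
    within[i:(i + h - 1L)] <- seq_len(h)
    planted[i:(i + h - 1L)] <- TRUE
    i <- i + h
  }
  m <- nPlanted - h
  while (m > 0L && i <= nSites) {
    prot <- prot + 1L
    pl <- min(2L, m)
    size <- min(5L, nSites - i + 1L)
    if (size < pl) size <- pl  # cannot happen: m <= sites left
    idx <- i:(i + size - 1L)
    acc[idx] <- sprintf("SYNP%04d", prot)
    within[idx] <- seq_len(size)
    planted[idx[seq_len(pl)]] <- TRUE
    m <- m - pl
    i <- i + size
  }
  while (i <= nSites) {
    prot <- prot + 1L
    size <- min(5L, nSites - i + 1L)
    idx <- i:(i + size - 1L)
    acc[idx] <- sprintf("SYNP%04d", prot)
    within[idx] <- seq_len(size)
    i <- i + size
  }
  list(accession = acc, within = within, planted = planted,
       hotspot = hotspotAcc)
}

## Trim each 15-mer block to the maximal single-Cys peptide around the
## central cysteine (a stray Cys drawn in the flanks starts/ends the peptide
## one residue away, mimicking a tryptic peptide covering only this site).
.blockPeptides <- function(charMat) {
  isC <- charMat == "C"
  left <- rep(0L, nrow(charMat))
  right <- rep(BLOCK_LEN + 1L, nrow(charMat))
  for (j in seq_len(CYS_OFF - 1L)) left[isC[, j]] <- j
  for (j in BLOCK_LEN:(CYS_OFF + 1L)) right[isC[, j]] <- j
  blocks <- do.call(paste0, lapply(seq_len(BLOCK_LEN), function(j) charMat[, j]))
  substr(blocks, left + 1L, right - 1L)
}

.plexLayout <- function(nPerGroup) {
  ctrl <- sprintf("ctrl_%02d", seq_len(nPerGroup))
  depl <- sprintf("depl_%02d", seq_len(nPerGroup))
  samples <- as.vector(rbind(ctrl, depl))   # interleave groups across plexes
  groups <- rep(c("control", "depleted"), nPerGroup)
  perPlex <- length(TMT16_CHANNELS) %/% 2L  # both fractions stay in one plex
  plexOf <- (seq_along(samples) - 1L) %/% perPlex + 1L
  rows <- lapply(seq_along(samples), function(k) {
    slot <- (k - 1L) %% perPlex
    data.frame(plex_id = sprintf("plex%d", plexOf[k]),
               channel_id = TMT16_CHANNELS[c(2L * slot + 1L, 2L * slot + 2L)],
               sample_id = samples[k], group = groups[k],
               fraction = c("oxidized", "total"),
               stringsAsFactors = FALSE)
  })
  plexDesign(do.call(rbind, rows))
}

.generate <- function(cfg, null) {
  validObject(cfg)
  set.seed(cfg@seed)
  nSites <- cfg@nSites
  nPlanted <- if (null) 0L else as.integer(round(cfg@fracPlanted * nSites))
  lay <- .siteLayout(nSites, nPlanted, cfg@hotspotSites)

  f0 <- stats::rbeta(nSites, cfg@betaShape1, cfg@betaShape2)
  f0 <- pmin(pmax(f0, 1e-6), 0.985)
  fdep <- ifelse(lay$planted, pmin(f0 + cfg@delta, 0.99), f0)
  abundance <- stats::rlnorm(nSites, meanlog = log(100),
                             sdlog = cfg@abundanceSigma)

  charMat <- matrix(sample(AA20, nSites * BLOCK_LEN, replace = TRUE),
                    nrow = nSites, ncol = BLOCK_LEN)
  charMat[, CYS_OFF] <- "C"
  pIdx <- which(lay$planted)
  if (length(pIdx)) {
    biased <- pIdx[stats::runif(length(pIdx)) < cfg@motifBias]
    if (length(biased)) {
      ## block offsets 2 and 3 are flank positions -6 and -5
      charMat[biased, CYS_OFF - 6L] <- sample(c("K", "R"), length(biased),
                                              replace = TRUE)
      charMat[biased, CYS_OFF - 5L] <- sample(c("K", "R"), length(biased),
                                              replace = TRUE)
    }
  }
  peptides <- .blockPeptides(charMat)
  blocks <- do.call(paste0,
                    lapply(seq_len(BLOCK_LEN), function(j) charMat[, j]))
  accF <- factor(lay$accession, levels = unique(lay$accession))
  protSeq <- vapply(split(blocks, accF), paste, character(1), collapse = "")
  proteins <- Biostrings::AAStringSet(protSeq)
  names(proteins) <- levels(accF)

  sitePos <- (lay$within - 1L) * BLOCK_LEN + CYS_OFF
  siteId <- paste0(lay$accession, ":", sitePos)

  design <- .plexLayout(cfg@nPerGroup)
  dtab <- designTable(design)
  sampleGroup <- unique(dtab[, c("sample_id", "group")])
  fMat <- cbind(control = f0, depleted = fdep)

  sigma <- if (cfg@noiseCv > 0) sqrt(log(1 + cfg@noiseCv^2)) else 0
  psmList <- vector("list", length(unique(dtab$plex_id)))
  allChannels <- unique(dtab$channel_id)
  for (pi in seq_along(unique(dtab$plex_id))) {
    px <- unique(dtab$plex_id)[pi]
    dp <- dtab[dtab$plex_id == px, , drop = FALSE]
    vals <- matrix(NA_real_, nrow = nSites, ncol = length(allChannels),
                   dimnames = list(NULL, allChannels))
    for (r in seq_len(nrow(dp))) {
      grp <- dp$group[r]
      expect <- if (dp$fraction[r] == "oxidized")
        fMat[, grp] * abundance else abundance
      if (sigma > 0)
        expect <- expect * stats::rlnorm(nSites, -sigma^2 / 2, sigma)
      vals[, dp$channel_id[r]] <- expect
    }
    psmList[[pi]] <- data.frame(
      peptide_sequence = peptides, protein_accession = lay$accession,
      site_position = sitePos, plex_id = px,
      vals, check.names = FALSE, stringsAsFactors = FALSE)
  }
  psms <- do.call(rbind, psmList)
  rownames(psms) <- NULL

  padded <- paste0(strrep("X", 6L), protSeq[lay$accession], strrep("X", 6L))
  truth <- data.frame(
    site_id = siteId, protein_accession = lay$accession,
    site_position = sitePos, planted = lay$planted,
    f_control = f0, f_depleted = fdep,
    flank = substr(padded, sitePos, sitePos + 12L),
    stringsAsFactors = FALSE)

  list(proteins = proteins, design = design, psms = psms, truth = truth,
       hotspot_accession = lay$hotspot, config = cfg)
}

#' Generate a synthetic redoxome experiment
#'
#' Simulates a full paired half-sample multiplex experiment: a synthetic
#' proteome, a plex design (oxidized-enriched and total channels for every
#' biological sample, split across 16-channel plexes when the sample count
#' requires it), and a PSM quantification table. For each site and sample
#' the oxidized-fraction channel has expected signal-to-noise \eqn{f A} and
#' the total channel \eqn{A}, where \eqn{A} is the site's abundance draw and
#' \eqn{f} its true oxidation fraction; independent multiplicative
#' log-normal noise with the configured CV is applied per channel. Planted
#' sites gain \code{delta} on the fraction scale in the depleted group and
#' carry the configured basic-residue bias at flank positions -5/-6.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return a list with elements \code{proteins} (named
#'   \code{AAStringSet}), \code{design} (\linkS4class{PlexDesign}),
#'   \code{psms} (PSM data.frame consumable by [aggregatePsmsToSites()]),
#'   \code{truth} (data.frame: site_id, planted, f_control, f_depleted,
#'   flank), \code{hotspot_accession}, and \code{config}.
#' @examples
#' ex <- generateExperiment(simConfig(nSites = 50, nPerGroup = 3, seed = 1))
#' head(ex$truth)
#' @export
generateExperiment <- function(cfg) .generate(cfg, null = FALSE)

#' Generate a null synthetic experiment (no group effect)
#'
#' Identical to [generateExperiment()] except that no site carries an
#' oxidation increase (\code{delta} is ignored and the planted set is
#' empty); used to check the type-I error of downstream calling.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return as [generateExperiment()]; \code{truth$planted} is all
#'   \code{FALSE}.
#' @export
generateNullExperiment <- function(cfg) .generate(cfg, null = TRUE)

#' Write a generated experiment to disk
#'
#' Emits exactly the formats the readers consume: \code{proteins.fasta},
#' \code{plex_design.tsv}, \code{psm_table.tsv} and \code{truth.tsv}.
#'
#' @param ex list from [generateExperiment()].
#' @param out_dir output directory.
#' @return named character vector of file paths, invisibly.
#' @export
writeExperiment <- function(ex, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(proteins = file.path(out_dir, "proteins.fasta"),
             plex_design = file.path(out_dir, "plex_design.tsv"),
             psm_table = file.path(out_dir, "psm_table.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  writeFasta(ex$proteins, paths[["proteins"]])
  writeTsv(designTable(ex$design), paths[["plex_design"]])
  writeTsv(ex$psms, paths[["psm_table"]])
  writeTsv(ex$truth, paths[["truth"]])
  invisible(paths)
}
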