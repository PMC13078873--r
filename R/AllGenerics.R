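#' @include AllClasses.R
NULL

#' Accessors for redoxQuant classes
#'
#' Small accessor layer over the S4 containers: \code{designTable} returns the
#' channel-to-sample mapping of a \linkS4class{PlexDesign}; \code{plexIds} and
#' \code{sampleIds} list its plexes and biological samples; \code{oxidizedSN}
#' and \code{totalSN} return the two assays of a \linkS4class{SiteQuant};
#' \code{oxidationPercent} returns the percentage matrix of an
#' \linkS4class{OxidationProfile}; \code{siteIds} returns row identifiers
#' ("accession:position"); \code{flankWidth} and \code{flankSequences} expose
#' a \linkS4class{FlankSet}; \code{motifCells}, \code{motifThreshold} and
#' \code{motifPwm} expose a \linkS4class{MotifResult}.
#'
#' @param x the object.
#' @return The extracted component (a data.frame, matrix, or vector).
#' @examples
#' pd <- plexDesign(data.frame(
#'   channel_id = c("126", "127N"), sample_id = "m1",
#'   group = "control", fraction = c("oxidized", "total")))
#' designTable(pd)
#' sampleIds(pd)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))
#' @rdname accessors
#' @export
setGeneric("plexIds", function(x) standardGeneric("plexIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))
#' @rdname accessors
#' @export
setGeneric("oxidizedSN", function(x) standardGeneric("oxidizedSN"))
#' @rdname accessors
#' @export
setGeneric("totalSN", function(x) standardGeneric("totalSN"))
#' @rdname accessors
#' @export
setGeneric("oxidationPercent", function(x) standardGeneric("oxidationPercent"))
#' @rdname accessors
#' @export
setGeneric("flankWidth", function(x) standardGeneric("flankWidth"))
#' @rdname accessors
#' @export
setGeneric("flankSequences", function(x) standardGeneric("flankSequences"))
#' @rdname accessors
#' @export
setGeneric("motifCells", function(x) standardGeneric("motifCells"))
#' @rdname accessors
#' @export
setGeneric("motifThreshold", function(x) standardGeneric("motifThreshold"))
#' @rdname accessors
#' @export
setGeneric("motifPwm", function(x) standardGeneric("motifPwm"))

#' @rdname accessors
setMethod("designTable", "PlexDesign", function(x) x@design)
#' @rdname accessors
setMethod("plexIds", "PlexDesign", function(x) unique(x@design$plex_id))
#' @rdname accessors
setMethod("sampleIds", "PlexDesign", function(x) unique(x@design$sample_id))

#' @rdname accessors
setMethod("siteIds", "SummarizedExperiment", function(x) rownames(x))

#' @rdname accessors
setMethod("oxidizedSN", "SiteQuant", function(x)
  SummarizedExperiment::assay(x, "oxidized"))
#' @rdname accessors
setMethod("totalSN", "SiteQuant", function(x)
  SummarizedExperiment::assay(x, "total"))

#' @rdname accessors
setMethod("oxidationPercent", "OxidationProfile", function(x)
  SummarizedExperiment::assay(x, "oxidation_percent"))

#' @rdname accessors
setMethod("flankWidth", "FlankSet", function(x) x@w)
#' @rdname accessors
setMethod("flankSequences", "FlankSet", function(x) x@sequences)

#' @rdname accessors
setMethod("motifCells", "MotifResult", function(x) x@cells)
#' @rdname accessors
setMethod("motifThreshold", "MotifResult", function(x) x@threshold)
#' @rdname accessors
setMethod("motifPwm", "MotifResult", function(x) x@pwm)

#' @rdname accessors
setMethod("length", "FlankSet", function(x) length(x@sequences))

setMethod("show", "PlexDesign", function(object) {
  d <- object@design
  cat(sprintf("PlexDesign: %d channel(s), %d sample(s), %d plex(es)\n",
              nrow(d), length(unique(d$sample_id)),
              length(unique(d$plex_id))))
  tab <- table(unique(d[, c("sample_id", "group")])$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  sites: %d (planted fraction %.4g, hotspot sites %d)\n",
              object@nSites, object@fracPlanted, object@hotspotSites))
  cat(sprintf("  replicates/group: %d; baseline f0 ~ Beta(%g, %g); delta %.3g\n",
              object@nPerGroup, object@betaShape1, object@betaShape2,
              object@delta))
  cat(sprintf("  noise CV %.3g; abundance sdlog %.3g; motif bias %.2g; seed %d\n",
              object@noiseCv, object@abundanceSigma, object@motifBias,
              object@seed))
})

setMethod("show", "FlankSet", function(object) {
  cat(sprintf("FlankSet: %d sequence(s), window +/-%d (width %d)\n",
              length(object@sequences), object@w, 2L * object@w + 1L))
  if (length(object@sequences))
    cat("  first:", object@sequences[1L], "\n")
})

setMethod("show", "MotifResult", function(object) {
  cat(sprintf("MotifResult: %d foreground / %d background flank(s), window +/-%d\n",
              object@nForeground, object@nBackground, object@w))
  cat(sprintf("  |score| threshold %.2f (alpha %.3g, %d residues x %d positions)\n",
              object@threshold, object@alpha, length(AA20), 2L * object@w))
  sig <- object@cells[object@cells$significant, , drop = FALSE]
  sig <- sig[order(-abs(sig$score)), , drop = FALSE]
  cat(sprintf("  %d significant cell(s)\n", nrow(sig)))
  if (nrow(sig)) {
    top <- utils::head(sig, 5L)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %s at %+d: score %.2f (k=%d/%d, p0=%.3f)\n",
                  top$residue[i], top$position[i], top$score[i],
                  top$k[i], top$n[i], top$p0[i]))
  }
})
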