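#' @include AllClasses.R io.R synthetic.R quantify.R differential.R motif.R
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

.defaultRunConfig <- list(
  mode = "simulate", seed = 1, sim = list(),
  alpha = 0.05, rel_min = 0.25, top_frac = 0.15, min_reps = 2,
  window = 6, normalize = FALSE, background = "detected",
  paths = list(), out_dir = NULL)

#' Assemble a pipeline run configuration
#'
#' Either build the configuration in code (pass a list / named arguments) or
#' load it from a YAML file; explicit arguments override file values, which
#' override defaults. In \code{mode = "simulate"} the \code{sim} block holds
#' [simConfig()] arguments; in \code{mode = "files"} the \code{paths} block
#' must name \code{fasta}, \code{plex_design} and \code{psm_table} (and may
#' name \code{domains}).
#'
#' @param file optional YAML configuration file.
#' @param ... configuration fields overriding file/defaults: \code{mode},
#'   \code{seed}, \code{sim}, \code{paths}, \code{alpha}, \code{rel_min},
#'   \code{top_frac}, \code{min_reps}, \code{window}, \code{normalize},
#'   \code{background} ("detected" or "proteome"), \code{out_dir}.
#' @return a validated configuration list.
#' @export
runConfig <- function(file = NULL, ...) {
  cfg <- .defaultRunConfig
  if (!is.null(file)) {
    if (!file.exists(file)) stop(sprintf("config file not found: %s", file))
    cfg <- utils::modifyList(cfg, yaml::read_yaml(file))
  }
  cfg <- utils::modifyList(cfg, list(...))
  if (!cfg$mode %in% c("simulate", "files"))
    stop("mode must be 'simulate' or 'files'")
  if (!cfg$background %in% c("detected", "proteome"))
    stop("background must be 'detected' or 'proteome'")
  if (is.null(cfg$out_dir)) stop("out_dir is required")
  if (cfg$mode == "files") {
    need <- c("fasta", "plex_design", "psm_table")
    miss <- setdiff(need, names(cfg$paths))
    if (length(miss))
      stop(sprintf("config error: missing input path(s): %s",
                   paste(miss, collapse = ", ")))
    for (p in unlist(cfg$paths))
      if (!file.exists(p)) stop(sprintf("config error: input path not found: %s", p))
  }
  cfg
}

#' Run the full redoxome analysis pipeline
#'
#' Orchestrates simulate/load, PSM-to-site aggregation, oxidation
#' percentages, completeness filtering, differential calling, protein
#' ranking, optional domain mapping, and motif analysis; writes every result
#' table (TSV) plus a machine-readable run log (JSON) recording the
#' effective configuration and per-stage counts. All computation happens
#' before any file is written, so a failing stage leaves no partial output.
#' Given the same configuration and seed, reruns are byte-identical.
#'
#' @param config a configuration from [runConfig()] (or a YAML file path, or
#'   a list of [runConfig()] arguments).
#' @return the run report, invisibly: a list with stage counts
#'   (\code{n_psms}, \code{n_excluded_multi_cys}, \code{n_sites_quantified},
#'   \code{n_sites_tested}, \code{n_sites_called}, \code{fraction_called},
#'   \code{n_p_below_alpha}), \code{top_proteins} (up to 10),
#'   \code{n_motif_significant}, the output \code{manifest}, and the result
#'   tables themselves.
#' @examples
#' \donttest{
#' rep <- runPipeline(runConfig(
#'   mode = "simulate", sim = list(nSites = 200, nPerGroup = 3, seed = 7),
#'   out_dir = tempfile("run")))
#' rep$n_sites_called
#' }
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- runConfig(file = config)
  if (is.null(config$out_dir) || !config$mode %in% c("simulate", "files"))
    config <- do.call(runConfig, config)

  if (config$mode == "simulate") {
    ex <- .stage("simulate", {
      simArgs <- config$sim
      if (!is.null(config$seed) && is.null(simArgs$seed))
        simArgs$seed <- config$seed
      generateExperiment(do.call(simConfig, simArgs))
    })
    db <- ex$proteins; design <- ex$design; psms <- ex$psms
    annot <- NULL
  } else {
    db <- .stage("read_fasta", readFasta(config$paths$fasta))
    design <- .stage("read_design", readPlexDesign(config$paths$plex_design))
    psms <- .stage("read_psms", readPsmTable(config$paths$psm_table, db))
    annot <- if (!is.null(config$paths$domains))
      .stage("read_domains", readDomainAnnotation(config$paths$domains, db))
    else NULL
    ex <- NULL
  }

  sq <- .stage("aggregate",
               aggregatePsmsToSites(psms, design, normalize = config$normalize))
  profile <- .stage("oxidation_percent", computeOxidationPercent(sq))
  tested <- .stage("filter",
                   filterQuantifiedSites(profile, minReps = config$min_reps))
  diffRes <- .stage("differential",
                    callIncreasedOxidation(tested, alpha = config$alpha,
                                           relMin = config$rel_min,
                                           topFrac = config$top_frac))
  ranks <- .stage("rank_proteins", rankProteins(diffRes))
  domains <- if (!is.null(annot))
    .stage("domain_map", mapSitesToDomains(diffRes, annot)) else NULL

  calledIds <- diffRes$site_id[diffRes$called]
  motif <- NULL
  if (length(calledIds) > 0L) {
    motif <- .stage("motif", {
      fg <- extractFlanks(calledIds, db, w = config$window)
      bgIds <- if (config$background == "detected") {
        siteIds(profile)
      } else {
        .allCysteineSiteIds(db)
      }
      bg <- extractFlanks(bgIds, db, w = config$window)
      buildMotifResult(fg, bg, alpha = config$alpha)
    })
  }

  ## ---- write everything ----
  outDir <- config$out_dir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  tables <- list()
  if (!is.null(ex)) {
    writeExperiment(ex, outDir)
  }
  tables$site_quant <- .siteQuantTable(sq)
  tables$oxidation_profile <- .profileTable(profile)
  tables$differential <- diffRes
  tables$protein_ranks <- ranks
  if (!is.null(domains)) {
    tables$domain_map <- domains$map
    tables$domain_counts <- domains$counts
  }
  if (!is.null(motif)) {
    tables$motif_cells <- motifCells(motif)
    tables$motif_pwm <- .pwmTable(motifPwm(motif))
  }
  manifest <- basename(writeResults(tables, outDir))
  if (!is.null(ex))
    manifest <- c("proteins.fasta", "plex_design.tsv", "psm_table.tsv",
                  "truth.tsv", manifest)

  report <- list(
    config = config[setdiff(names(config), "out_dir")],
    n_psms = nrow(psms),
    n_excluded_multi_cys = S4Vectors::metadata(sq)$n_excluded_multi_cys,
    n_sites_quantified = nrow(sq),
    n_sites_tested = nrow(tested),
    n_sites_called = length(calledIds),
    fraction_called = attr(diffRes, "fraction_called"),
    n_p_below_alpha = sum(diffRes$p_value < config$alpha),
    n_over_100_percent = S4Vectors::metadata(profile)$n_over_100,
    top_proteins = utils::head(ranks, 10L),
    n_motif_significant = if (is.null(motif)) 0L
                          else sum(motifCells(motif)$significant),
    motif_threshold = if (is.null(motif)) NA_real_ else motifThreshold(motif),
    manifest = manifest)
  logObj <- report[setdiff(names(report), "top_proteins")]
  logObj$top_proteins <- if (nrow(ranks)) utils::head(ranks, 10L) else NULL
  jsonlite::write_json(logObj, file.path(outDir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  report$tables <- tables
  invisible(report)
}

.allCysteineSiteIds <- function(db) {
  seqs <- .dbAsCharacter(db)
  ids <- lapply(names(seqs), function(acc) {
    pos <- gregexpr("C", seqs[[acc]], fixed = TRUE)[[1L]]
    if (pos[1L] == -1L) return(character(0))
    paste0(acc, ":", pos)
  })
  unlist(ids, use.names = FALSE)
}

.siteQuantTable <- function(sq) {
  rd <- SummarizedExperiment::rowData(sq)
  ox <- oxidizedSN(sq); tot <- totalSN(sq)
  colnames(ox) <- paste0("oxidized_", colnames(ox))
  colnames(tot) <- paste0("total_", colnames(tot))
  data.frame(site_id = rownames(sq),
             protein_accession = rd$protein_accession,
             site_position = rd$site_position, n_psm = rd$n_psm,
             ox, tot, check.names = FALSE, stringsAsFactors = FALSE)
}

.profileTable <- function(profile) {
  rd <- SummarizedExperiment::rowData(profile)
  data.frame(site_id = rownames(profile),
             protein_accession = rd$protein_accession,
             site_position = rd$site_position,
             n_quant_control = rd$n_quant_control,
             n_quant_depleted = rd$n_quant_depleted,
             oxidationPercent(profile), check.names = FALSE,
             stringsAsFactors = FALSE)
}

.pwmTable <- function(pwm) {
  data.frame(residue = rownames(pwm), pwm, check.names = FALSE,
             stringsAsFactors = FALSE)
}
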