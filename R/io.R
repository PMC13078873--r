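#' @include AllClasses.R
NULL

PSM_FIXED_COLS <- c("peptide_sequence", "protein_accession", "site_position",
                    "plex_id")

.readTsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "",
                    colClasses = NA, comment.char = "")
}

#' Write a results table as TSV
#'
#' All tabular output is tab-separated UTF-8 with a header row, '.' decimal
#' point and empty cells for missing values ("absent", which is distinct from
#' a zero signal). Numbers are written at full double precision so a
#' write/read round trip preserves values.
#'
#' @param x a data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' Write a set of result tables to a directory
#'
#' @param tables named list of data.frames; each is written to
#'   \code{<out_dir>/<name>.tsv}.
#' @param out_dir output directory, created if needed.
#' @return character vector of the files written, invisibly.
#' @export
writeResults <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, paste0(names(tables), ".tsv"))
  for (i in seq_along(tables)) writeTsv(tables[[i]], paths[i])
  invisible(paths)
}

#' Construct a PlexDesign
#'
#' @param entries data.frame with columns \code{channel_id},
#'   \code{sample_id}, \code{group}, \code{fraction} and optionally
#'   \code{plex_id} (defaults to \code{plex_id} argument).
#' @param plex_id default plex label used when \code{entries} carries no
#'   \code{plex_id} column.
#' @return a validated \linkS4class{PlexDesign}.
#' @examples
#' plexDesign(data.frame(
#'   channel_id = c("126", "127N"), sample_id = "m1",
#'   group = "control", fraction = c("oxidized", "total")))
#' @export
plexDesign <- function(entries, plex_id = "plex1") {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!"plex_id" %in% names(entries)) entries$plex_id <- plex_id
  need <- c("channel_id", "sample_id", "group", "fraction")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop(sprintf("plex design is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  for (col in c("plex_id", need))
    entries[[col]] <- as.character(entries[[col]])
  entries <- entries[, c("plex_id", need)]
  new("PlexDesign", design = entries)
}

#' Read a plex design table
#'
#' Expects a TSV with header columns \code{channel_id}, \code{sample_id},
#' \code{group} (one of control/depleted), \code{fraction} (one of
#' oxidized/total) and optionally \code{plex_id}. Every sample must appear
#' with both fractions; violations are reported naming the offending sample
#' or channel, never silently dropped.
#'
#' @param path TSV file path.
#' @return a validated \linkS4class{PlexDesign}.
#' @export
readPlexDesign <- function(path) {
  d <- .readTsv(path)
  need <- c("channel_id", "sample_id", "group", "fraction")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("plex design '%s' is missing column(s): %s",
                 path, paste(miss, collapse = ", ")))
  plexDesign(d)
}

#' Read a protein FASTA into a named sequence set
#'
#' The accession of each record is the first whitespace-delimited token of
#' its header line (standard UniProt practice, e.g.
#' \code{>sp|P19096|FAS_MOUSE description} yields
#' \code{sp|P19096|FAS_MOUSE}); the rule is fixed so accessions join
#' bit-stably against quantification tables. Sequences are uppercased and
#' must be non-empty, drawn from the 20-letter alphabet plus 'X'.
#'
#' @param path FASTA file path.
#' @return a named \code{\link[Biostrings]{AAStringSet}}.
#' @export
readFasta <- function(path) {
  db <- Biostrings::readAAStringSet(path)
  if (length(db) == 0L) stop(sprintf("no FASTA records in %s", path))
  acc <- vapply(strsplit(names(db), "[[:space:]]+"), `[`, character(1), 1L)
  names(db) <- acc
  if (anyDuplicated(acc))
    stop(sprintf("duplicate accession(s) in FASTA: %s",
                 paste(unique(acc[duplicated(acc)]), collapse = ", ")))
  if (any(Biostrings::width(db) == 0L))
    stop(sprintf("empty sequence(s) in FASTA: %s",
                 paste(acc[Biostrings::width(db) == 0L], collapse = ", ")))
  db <- Biostrings::AAStringSet(toupper(as.character(db)))
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", as.character(db))
  if (any(bad))
    stop(sprintf("non-standard residue(s) in sequence(s): %s",
                 paste(names(db)[bad], collapse = ", ")))
  db
}

#' Write a named sequence set as FASTA
#'
#' @param db named \code{AAStringSet} or named character vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(db, path) {
  if (!methods::is(db, "XStringSet")) db <- Biostrings::AAStringSet(db)
  Biostrings::writeXStringSet(db, path)
  invisible(path)
}

.dbAsCharacter <- function(db) {
  if (methods::is(db, "XStringSet")) {
    s <- as.character(db)
    names(s) <- names(db)
    s
  } else if (is.character(db) && !is.null(names(db))) {
    db
  } else stop("protein db must be a named AAStringSet or named character vector")
}

#' Read and validate a peptide-to-site quantification table
#'
#' Expects a TSV with columns \code{peptide_sequence},
#' \code{protein_accession}, \code{site_position} (1-based index of the
#' quantified cysteine in the protein), \code{plex_id}, followed by one
#' column per reporter channel. Empty channel cells are read as absent
#' (\code{NA}), which is distinct from a zero signal-to-noise. Every row is
#' validated against the protein database: the accession must exist and the
#' residue at \code{site_position} must be a cysteine.
#'
#' @param path TSV file path.
#' @param db protein database from [readFasta()].
#' @return a data.frame of validated PSM records (fixed columns then channel
#'   columns).
#' @export
readPsmTable <- function(path, db) {
  x <- .readTsv(path)
  miss <- setdiff(PSM_FIXED_COLS, names(x))
  if (length(miss))
    stop(sprintf("PSM table '%s' is missing column(s): %s",
                 path, paste(miss, collapse = ", ")))
  chan <- setdiff(names(x), PSM_FIXED_COLS)
  if (!length(chan)) stop(sprintf("PSM table '%s' has no channel columns", path))
  x$peptide_sequence  <- toupper(as.character(x$peptide_sequence))
  x$protein_accession <- as.character(x$protein_accession)
  x$plex_id           <- as.character(x$plex_id)
  x$site_position     <- as.integer(x$site_position)
  for (cc in chan) x[[cc]] <- as.numeric(x[[cc]])
  validatePsmTable(x, db)
}

#' Validate a PSM quantification table against a protein database
#'
#' @param x data.frame with the PSM-table columns (see [readPsmTable()]).
#' @param db protein database.
#' @return \code{x}, unchanged, if every record validates.
#' @export
validatePsmTable <- function(x, db) {
  seqs <- .dbAsCharacter(db)
  chan <- setdiff(names(x), PSM_FIXED_COLS)
  bad <- !x$protein_accession %in% names(seqs)
  if (any(bad))
    stop(sprintf("accession(s) absent from protein db: %s",
                 paste(unique(x$protein_accession[bad]), collapse = ", ")))
  if (any(!grepl("C", x$peptide_sequence, fixed = TRUE)))
    stop("peptide(s) without any cysteine in PSM table")
  plen <- nchar(seqs[x$protein_accession])
  if (any(x$site_position < 1L | x$site_position > plen))
    stop("site_position outside protein sequence")
  res <- substr(seqs[x$protein_accession], x$site_position, x$site_position)
  if (any(res != "C")) {
    off <- which(res != "C")[1L]
    stop(sprintf("residue at site %s:%d is '%s', not 'C'",
                 x$protein_accession[off], x$site_position[off], res[off]))
  }
  for (cc in chan) {
    if (any(x[[cc]] < 0, na.rm = TRUE))
      stop(sprintf("negative reporter value(s) in channel '%s'", cc))
  }
  x
}

#' Read and validate a protein domain annotation table
#'
#' Expects a TSV with columns \code{protein_accession}, \code{domain_label},
#' \code{start}, \code{end} (1-based, inclusive). Intervals of one protein
#' may not overlap; each must lie within the protein sequence when a database
#' is supplied.
#'
#' @param path TSV file path.
#' @param db optional protein database for length validation.
#' @return a validated data.frame.
#' @export
readDomainAnnotation <- function(path, db = NULL) {
  x <- .readTsv(path)
  need <- c("protein_accession", "domain_label", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(sprintf("domain annotation '%s' is missing column(s): %s",
                 path, paste(miss, collapse = ", ")))
  x$start <- as.integer(x$start)
  x$end   <- as.integer(x$end)
  validateDomainAnnotation(x, db)
}

#' @rdname readDomainAnnotation
#' @param x data.frame with the domain-annotation columns.
#' @export
validateDomainAnnotation <- function(x, db = NULL) {
  if (any(x$start < 1L)) stop("domain start positions must be >= 1")
  if (any(x$start > x$end)) stop("domain intervals must satisfy start <= end")
  if (!is.null(db)) {
    seqs <- .dbAsCharacter(db)
    bad <- !x$protein_accession %in% names(seqs)
    if (any(bad))
      stop(sprintf("domain accession(s) absent from protein db: %s",
                   paste(unique(x$protein_accession[bad]), collapse = ", ")))
    if (any(x$end > nchar(seqs[x$protein_accession])))
      stop("domain interval extends past protein end")
  }
  for (acc in unique(x$protein_accession)) {
    xi <- x[x$protein_accession == acc, , drop = FALSE]
    ir <- IRanges::IRanges(start = xi$start, end = xi$end)
    ov <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov))
      stop(sprintf("overlapping domain intervals on protein '%s'", acc))
  }
  x
}
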