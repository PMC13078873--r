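#' @include AllClasses.R io.R
NULL

#' Extract fixed-width flanking windows around cysteine sites
#'
#' For each site id ("accession:position", 1-based) the window of
#' \code{2w + 1} residues centered on the cysteine is extracted from the
#' protein; positions beyond either terminus are padded with 'X'. The
#' central residue must be a cysteine.
#'
#' @param siteIds character vector of "accession:position" site ids.
#' @param db protein database ([readFasta()] result or named character).
#' @param w window half-width (default 6, the probability-logo convention).
#' @return a \linkS4class{FlankSet}.
#' @examples
#' db <- c(P1 = "MKTAYCRGDLKWVNP")
#' flankSequences(extractFlanks("P1:6", db, w = 3))
#' @export
extractFlanks <- function(siteIds, db, w = 6) {
  w <- as.integer(w)
  if (w < 1L) stop("w must be >= 1")
  seqs <- .dbAsCharacter(db)
  parts <- regmatches(siteIds, regexec("^(.*):([0-9]+)$", siteIds))
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop(sprintf("malformed site id(s): %s",
                 paste(siteIds[bad], collapse = ", ")))
  acc <- vapply(parts, `[`, character(1), 2L)
  pos <- as.integer(vapply(parts, `[`, character(1), 3L))
  miss <- !acc %in% names(seqs)
  if (any(miss))
    stop(sprintf("accession(s) absent from protein db: %s",
                 paste(unique(acc[miss]), collapse = ", ")))
  plen <- nchar(seqs[acc])
  if (any(pos < 1L | pos > plen))
    stop("site position outside protein sequence")
  ctr <- substr(seqs[acc], pos, pos)
  if (any(ctr != "C")) {
    off <- which(ctr != "C")[1L]
    stop(sprintf("residue at site %s:%d is '%s', not 'C'",
                 acc[off], pos[off], ctr[off]))
  }
  padded <- paste0(strrep("X", w), seqs[acc], strrep("X", w))
  flanks <- substr(padded, pos, pos + 2L * w)
  new("FlankSet", w = w, sequences = unname(flanks))
}

#' Signed binomial log-odds of a residue count
#'
#' The probability-logo statistic for one (position, residue) cell: with
#' foreground count \code{k} out of \code{n} real residues and background
#' frequency \code{p0}, overrepresentation (\code{k/n >= p0}, ties scored as
#' over) gives \code{-log10 P[X >= k]} and underrepresentation gives
#' \code{log10 P[X <= k]} (negative magnitude), with
#' \code{X ~ Binomial(n, p0)} and exact tail probabilities. A tail
#' probability of 1 (certain event, e.g. \code{p0 = 1} with \code{k = n})
#' gives score 0. Vectorized over \code{k}, \code{n}, \code{p0}.
#'
#' @param k foreground count(s), \code{0 <= k <= n}.
#' @param n number(s) of foreground sequences with a real residue at the
#'   position.
#' @param p0 background frequency(ies) in [0, 1].
#' @return numeric score(s); positive = overrepresented.
#' @examples
#' binomialLogOdds(5, 10, 0.5)   # tie -> over tail
#' binomialLogOdds(0, 10, 0.05)  # under: log10(0.95^10)
#' @export
binomialLogOdds <- function(k, n, p0) {
  m <- max(length(k), length(n), length(p0))
  k <- rep_len(as.numeric(k), m)
  n <- rep_len(as.numeric(n), m)
  p0 <- rep_len(as.numeric(p0), m)
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n")
  if (any(p0 < 0 | p0 > 1)) stop("p0 must lie in [0, 1]")
  score <- numeric(m)
  zero <- n == 0
  phat <- ifelse(zero, p0, k / pmax(n, 1))
  over <- !zero & phat >= p0
  if (any(over))
    score[over] <- -log10(stats::pbinom(k[over] - 1, n[over], p0[over],
                                        lower.tail = FALSE))
  under <- !zero & !over
  if (any(under))
    score[under] <- log10(stats::pbinom(k[under], n[under], p0[under]))
  score[score == 0] <- 0   # normalize -0 from log10(1)
  score
}

#' Bonferroni-corrected significance threshold for motif log-odds
#'
#' The family of tests is every residue at every variable flanking position:
#' \code{R} residues times \code{W} positions. A cell is significant at
#' family-wise level \code{alpha} when its tail probability is below
#' \code{alpha / (R W)}, i.e. when \code{|score|} reaches
#' \code{-log10(alpha / (R W))}. For the conventional \code{+/-6} window
#' (\code{W = 12}) at \code{alpha = 0.05} this is
#' \code{-log10(0.05/240) = 3.68} (two decimals).
#'
#' @param alpha family-wise error rate in (0, 1) (default 0.05).
#' @param R alphabet size (default 20).
#' @param W number of tested positions (2w for a half-width-w window).
#' @return the threshold on \code{|score|}, full precision.
#' @examples
#' significanceThreshold(0.05, 20, 12)  # 3.6812...
#' @export
significanceThreshold <- function(alpha = 0.05, R = 20, W) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (R < 1 || W < 1) stop("R and W must be >= 1")
  -log10(alpha / (R * W))
}

#' Binomial log-odds motif statistics for a foreground flank set
#'
#' For every variable position (-w..-1, +1..+w; the fixed central cysteine
#' is excluded) and each of the 20 residues, counts the residue in the
#' foreground (\code{k} of \code{n} real residues at that position), takes
#' the background frequency \code{p0} from the background flank set, and
#' scores the cell with the signed exact binomial log-odds. 'X' padding is
#' excluded from counts and denominators on both sides. Cells with
#' \code{|score|} at or above the Bonferroni threshold are flagged. The
#' position weight matrix holds per-position foreground residue frequencies
#' over all \code{2w + 1} positions.
#'
#' @param fg foreground \linkS4class{FlankSet} (e.g. called sites);
#'   must be non-empty.
#' @param bg background \linkS4class{FlankSet} with the same window (e.g.
#'   all detected sites).
#' @param alpha family-wise error rate for the threshold (default 0.05).
#' @return a \linkS4class{MotifResult}.
#' @export
buildMotifResult <- function(fg, bg, alpha = 0.05) {
  stopifnot(is(fg, "FlankSet"), is(bg, "FlankSet"))
  if (length(fg) == 0L) stop("empty foreground flank set")
  if (length(bg) == 0L) stop("empty background flank set")
  if (fg@w != bg@w) stop("foreground and background windows differ")
  w <- fg@w
  width <- 2L * w + 1L
  positions <- setdiff(seq.int(-w, w), 0L)

  fgM <- matrix(unlist(strsplit(fg@sequences, ""), use.names = FALSE),
                nrow = length(fg), ncol = width, byrow = TRUE)
  bgM <- matrix(unlist(strsplit(bg@sequences, ""), use.names = FALSE),
                nrow = length(bg), ncol = width, byrow = TRUE)

  countCol <- function(colChars) {
    real <- colChars[colChars != "X"]
    cnt <- table(factor(real, levels = AA20))
    list(k = as.integer(cnt), n = length(real))
  }

  cells <- vector("list", length(positions))
  for (j in seq_along(positions)) {
    idx <- positions[j] + w + 1L
    fgC <- countCol(fgM[, idx])
    bgC <- countCol(bgM[, idx])
    p0 <- if (bgC$n > 0) bgC$k / bgC$n else rep(NA_real_, length(AA20))
    score <- if (bgC$n > 0)
      binomialLogOdds(fgC$k, fgC$n, p0) else rep(0, length(AA20))
    cells[[j]] <- data.frame(position = positions[j], residue = AA20,
                             k = fgC$k, n = fgC$n, p0 = p0, score = score,
                             stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells)
  threshold <- significanceThreshold(alpha, length(AA20), length(positions))
  cells$significant <- !is.na(cells$score) & abs(cells$score) >= threshold

  pwm <- matrix(0, nrow = length(AA20), ncol = width,
                dimnames = list(AA20, as.character(seq.int(-w, w))))
  for (idx in seq_len(width)) {
    cc <- countCol(fgM[, idx])
    if (cc$n > 0) pwm[, idx] <- cc$k / cc$n
  }

  new("MotifResult", cells = cells, pwm = pwm, threshold = threshold,
      alpha = alpha, w = w, nForeground = length(fg), nBackground = length(bg))
}

#' Significant motif cells, strongest first
#'
#' @param x a \linkS4class{MotifResult}.
#' @return the significant rows of [motifCells()] sorted by decreasing
#'   \code{|score|}.
#' @export
significantCells <- function(x) {
  stopifnot(is(x, "MotifResult"))
  sig <- x@cells[x@cells$significant, , drop = FALSE]
  sig <- sig[order(-abs(sig$score), sig$position, sig$residue), , drop = FALSE]
  rownames(sig) <- NULL
  sig
}
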