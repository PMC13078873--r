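# Tiny hand-built fixtures; everything is constructed in code at test time.

tinyDb <- function() {
  c(P1 = "MKTAYCRGDLKWVNPQCESTHILMAFWYVG",
    P2 = "AAAACAAAAAAAAAAAAAAC",
    `sp|P19096|FAS_MOUSE` = "MEEVVIAGMSGKLPESENLQEFWDNLIGGVDMVTDDDRRWKAGLYGC")
}

tinyDesignDf <- function(n_samples = 2) {
  samples <- sprintf("m%d", seq_len(n_samples))
  groups <- rep(c("control", "depleted"), length.out = n_samples)
  do.call(rbind, lapply(seq_len(n_samples), function(i) {
    data.frame(plex_id = "plex1",
               channel_id = sprintf("ch%d", c(2 * i - 1, 2 * i)),
               sample_id = samples[i], group = groups[i],
               fraction = c("oxidized", "total"),
               stringsAsFactors = FALSE)
  }))
}

tinyPsmDf <- function() {
  data.frame(peptide_sequence = c("TAYCR", "TAYCR", "NPQCEST"),
             protein_accession = c("P1", "P1", "P1"),
             site_position = c(6L, 6L, 17L),
             plex_id = "plex1",
             ch1 = c(10, 20, 5), ch2 = c(100, 100, 50),
             ch3 = c(12, 24, 6), ch4 = c(80, 120, 40),
             stringsAsFactors = FALSE)
}

writeTempTsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

writeTempFasta <- function(db) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(db)), unname(db))), path)
  path
}

# Profile built directly from matrices, bypassing the PSM layer.
profileFromMatrix <- function(pct, groups) {
  samples <- colnames(pct)
  acc <- sub(":.*$", "", rownames(pct))
  pos <- as.integer(sub("^.*:", "", rownames(pct)))
  rd <- S4Vectors::DataFrame(
    protein_accession = acc, site_position = pos,
    n_psm = 1L,
    n_quant_control = rowSums(!is.na(pct[, groups == "control", drop = FALSE])),
    n_quant_depleted = rowSums(!is.na(pct[, groups == "depleted", drop = FALSE])),
    row.names = rownames(pct))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(oxidation_percent = pct), rowData = rd,
    colData = S4Vectors::DataFrame(sample_id = samples, group = groups,
                                   row.names = samples))
  new("OxidationProfile", se)
}

# Independent brute-force binomial tail via log-factorials (no pbinom/dbinom).
bruteTailGE <- function(k, n, p) {
  if (k <= 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  j <- k:n
  sum(exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)))
}
bruteTailLE <- function(k, n, p) {
  if (k >= n) return(1)
  if (p == 0) return(1)
  if (p == 1) return(0)
  j <- 0:k
  sum(exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)))
}
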