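test_that("flank windows are centered, padded, and validated", {
  db <- c(P1 = "MKTAYCRGDLKWVNPQCESTHILMAFWYVC")
  # interior site: full 13-mer, no padding
  fl <- flankSequences(extractFlanks("P1:17", db, w = 6))
  expect_identical(fl, "KWVNPQCESTHIL")
  # near the N terminus (1-based position 6): one 'X'
  expect_identical(flankSequences(extractFlanks("P1:6", db, w = 6)),
                   "XMKTAYCRGDLKW")
  # position 2 would leave 5 missing upstream slots, position 3 leaves 4
  db2 <- c(P2 = "ACAAAAAAAAAA", P3 = "AACAAAAAAAAA")
  expect_identical(substr(flankSequences(extractFlanks("P2:2", db2)), 1, 5),
                   "XXXXX")
  expect_identical(substr(flankSequences(extractFlanks("P3:3", db2)), 1, 5),
                   "XXXXA")
  # C-terminal site: right half padded
  fl3 <- flankSequences(extractFlanks("P1:30", db, w = 6))
  expect_identical(substr(fl3, 8, 13), "XXXXXX")
  expect_error(extractFlanks("P1:2", db), "not 'C'")
  expect_error(extractFlanks("P9:5", db), "absent")
})

test_that("binomial log-odds follow the exact tails with sign conventions", {
  # certain event: k = n with p0 = 1
  expect_identical(binomialLogOdds(10, 10, 1), 0)
  # underrepresentation: P[X <= 0] = 0.95^10
  expect_equal(binomialLogOdds(0, 10, 0.05), log10(0.95^10), tolerance = 1e-12)
  expect_equal(binomialLogOdds(0, 10, 0.05), -0.222764, tolerance = 1e-5)
  # tie k/n = p0 scored as overrepresentation
  expect_equal(binomialLogOdds(5, 10, 0.5), -log10(bruteTailGE(5, 10, 0.5)),
               tolerance = 1e-12)
  expect_gt(binomialLogOdds(5, 10, 0.5), 0)
  expect_error(binomialLogOdds(11, 10, 0.5), "k")
})

test_that("tail probabilities match brute-force summation to 1e-10 relative", {
  for (n in c(1, 2, 5, 10, 25, 50, 100, 200)) {
    for (p0 in c(0.01, 0.05, 0.25, 0.5, 0.8, 0.95)) {
      k <- 0:n
      sc <- binomialLogOdds(k, n, p0)
      over <- k / n >= p0
      pImpl <- 10^(-abs(sc))
      pOracle <- vapply(k, function(kk)
        if (kk / n >= p0) bruteTailGE(kk, n, p0) else bruteTailLE(kk, n, p0),
        numeric(1))
      expect_equal(pImpl, pOracle, tolerance = 1e-10)
    }
  }
})

test_that("scores grow monotonically with the foreground count", {
  sc <- binomialLogOdds(0:50, 50, 0.05)
  expect_true(all(diff(sc) > 0))
})

test_that("the Bonferroni threshold reproduces the +/-6-window cutoff", {
  expect_equal(round(significanceThreshold(0.05, 20, 12), 2), 3.68)
  expect_equal(significanceThreshold(0.05, 20, 12), -log10(0.05 / 240),
               tolerance = 1e-12)
  expect_equal(significanceThreshold(0.05, 20, 10), 3.60206, tolerance = 1e-5)
  expect_error(significanceThreshold(1.2, 20, 12), "alpha")
})

test_that("self-comparison of a modest foreground yields no significant cell", {
  set.seed(501)
  seqs <- vapply(1:40, function(i) {
    s <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "W", "Y"), 13, replace = TRUE)
    s[7] <- "C"; paste(s, collapse = "")
  }, character(1))
  fs <- new("FlankSet", w = 6L, sequences = seqs)
  mr <- buildMotifResult(fs, fs)
  expect_identical(nrow(significantCells(mr)), 0L)
})

test_that("a single-sequence foreground cannot reach the threshold", {
  db <- c(P1 = "MKTAYCRGDLKWVNPQCESTHILMAFWYVC")
  bgSeqs <- flankSequences(extractFlanks(c("P1:6", "P1:17", "P1:30"), db))
  fg <- new("FlankSet", w = 6L, sequences = bgSeqs[1])
  bg <- new("FlankSet", w = 6L, sequences = bgSeqs)
  mr <- buildMotifResult(fg, bg)
  # with n = 1 the largest possible |score| is -log10(p0) <= log10(3)
  expect_lt(max(abs(motifCells(mr)$score), na.rm = TRUE), 3.68)
  expect_identical(nrow(significantCells(mr)), 0L)
})

test_that("the PWM columns are proper frequency distributions", {
  ex <- generateExperiment(simConfig(nSites = 400, nPerGroup = 2,
                                     fracPlanted = 0.05, hotspotSites = 5,
                                     seed = 31))
  fg <- extractFlanks(ex$truth$site_id[ex$truth$planted], ex$proteins)
  bg <- extractFlanks(ex$truth$site_id, ex$proteins)
  mr <- buildMotifResult(fg, bg)
  cs <- colSums(motifPwm(mr))
  expect_equal(unname(cs), rep(1, 13), tolerance = 1e-9)
  # the fixed center is pure cysteine
  expect_equal(motifPwm(mr)["C", "0"], 1)
  # flank invariants: 'X' is excluded from counts and denominators
  cells <- motifCells(mr)
  expect_true(all(cells$k <= cells$n))
  expect_true(all(cells$n <= length(fg)))
})

test_that("window mismatch and empty foreground are errors", {
  db <- c(P1 = "MKTAYCRGDLKWVNPQCESTHILM")
  f6 <- extractFlanks("P1:6", db, w = 6)
  f4 <- extractFlanks("P1:6", db, w = 4)
  expect_error(buildMotifResult(f6, f4), "window")
  empty <- new("FlankSet", w = 6L, sequences = character(0))
  expect_error(buildMotifResult(empty, f6), "empty foreground")
})
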