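test_that("PSM values are summed per site and channel", {
  pd <- plexDesign(tinyDesignDf(2))
  sq <- aggregatePsmsToSites(tinyPsmDf(), pd)
  # two PSMs for P1:6 with ch1 10 and 20 -> 30 in sample m1's oxidized channel
  expect_equal(oxidizedSN(sq)["P1:6", "m1"], 30)
  expect_equal(totalSN(sq)["P1:6", "m1"], 200)
  expect_equal(oxidizedSN(sq)["P1:17", "m1"], 5)
  expect_identical(SummarizedExperiment::rowData(sq)$n_psm, c(2L, 1L))
})

test_that("multi-cysteine peptides are excluded and reported", {
  psms <- tinyPsmDf()
  psms$peptide_sequence[3] <- "ACCK"  # two cysteines: ambiguous localization
  sq <- aggregatePsmsToSites(psms, plexDesign(tinyDesignDf(2)))
  expect_identical(S4Vectors::metadata(sq)$n_excluded_multi_cys, 1L)
  expect_identical(S4Vectors::metadata(sq)$excluded_peptides, "ACCK")
  # site P1:17 was only supported by the excluded PSM -> absent from table
  expect_false("P1:17" %in% siteIds(sq))
  expect_identical(nrow(sq), 1L)
})

test_that("a PSM referencing an undesigned channel is a design error", {
  psms <- tinyPsmDf()
  names(psms)[names(psms) == "ch4"] <- "ch9"
  expect_error(aggregatePsmsToSites(psms, plexDesign(tinyDesignDf(2))), "ch9")
})

test_that("oxidation percent is the oxidized/total ratio with absence rules", {
  pd <- plexDesign(tinyDesignDf(2))
  psms <- tinyPsmDf()[1:2, ]  # single site, summed S/N ox 30 / tot 200
  psms$ch1 <- c(10, 15); psms$ch2 <- c(50, 50)   # 25 / 100 -> 25%
  psms$ch3 <- c(0, 0);   psms$ch4 <- c(60, 40)   # 0 / 100  -> 0%
  pr <- computeOxidationPercent(aggregatePsmsToSites(psms, pd))
  expect_equal(oxidationPercent(pr)["P1:6", "m1"], 25)
  expect_equal(oxidationPercent(pr)["P1:6", "m2"], 0)
})

test_that("zero totals and absent parents yield absent percentages", {
  pd <- plexDesign(tinyDesignDf(2))
  psms <- tinyPsmDf()[1, ]
  psms$ch2 <- 0           # total zero -> undefined ratio
  psms$ch3 <- NA          # oxidized absent
  pr <- computeOxidationPercent(aggregatePsmsToSites(psms, pd))
  expect_true(is.na(oxidationPercent(pr)["P1:6", "m1"]))
  expect_true(is.na(oxidationPercent(pr)["P1:6", "m2"]))
})

test_that("ratios above 100% are kept and counted, not clamped", {
  pd <- plexDesign(tinyDesignDf(2))
  psms <- tinyPsmDf()[1, ]
  psms$ch1 <- 120; psms$ch2 <- 100
  pr <- computeOxidationPercent(aggregatePsmsToSites(psms, pd))
  expect_equal(oxidationPercent(pr)["P1:6", "m1"], 120)
  expect_identical(S4Vectors::metadata(pr)$n_over_100, 1L)
})

test_that("aggregation is linear and order-invariant", {
  ex <- generateExperiment(simConfig(nSites = 40, nPerGroup = 3, seed = 21))
  pd <- ex$design
  base <- computeOxidationPercent(aggregatePsmsToSites(ex$psms, pd))
  doubled <- aggregatePsmsToSites(rbind(ex$psms, ex$psms), pd)
  expect_equal(oxidizedSN(doubled),
               2 * oxidizedSN(aggregatePsmsToSites(ex$psms, pd)))
  expect_equal(oxidationPercent(computeOxidationPercent(doubled)),
               oxidationPercent(base))
  shuffled <- ex$psms[rev(seq_len(nrow(ex$psms))), ]
  prS <- computeOxidationPercent(aggregatePsmsToSites(shuffled, pd))
  expect_equal(oxidationPercent(prS)[rownames(base), ], oxidationPercent(base))
})

test_that("completeness filtering needs minReps per group and rejects minReps < 2", {
  pct <- matrix(c(10, NA, 12, 13,  20, 21, NA, NA), nrow = 2, byrow = TRUE,
                dimnames = list(c("P1:6", "P1:17"), c("s1", "s2", "s3", "s4")))
  pr <- profileFromMatrix(pct, c("control", "control", "depleted", "depleted"))
  kept <- filterQuantifiedSites(pr, 2)
  expect_identical(siteIds(kept), character(0))  # neither site has 2+2
  pct2 <- rbind(pct, "P2:5" = c(1, 2, 3, 4))
  pr2 <- profileFromMatrix(pct2, c("control", "control", "depleted", "depleted"))
  expect_identical(siteIds(filterQuantifiedSites(pr2, 2)), "P2:5")
  expect_error(filterQuantifiedSites(pr2, 1), "minReps")
})

test_that("optional median centering equalizes channel medians", {
  ex <- generateExperiment(simConfig(nSites = 200, nPerGroup = 2,
                                     noiseCv = 0.3, seed = 23))
  sq <- aggregatePsmsToSites(ex$psms, ex$design, normalize = TRUE)
  tot <- totalSN(sq)
  meds <- apply(tot, 2, median)
  expect_lt(max(meds) / min(meds), 1.05)
  expect_true(S4Vectors::metadata(sq)$normalized)
})
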