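test_that("the pooled-variance t-test matches the independent oracle", {
  ctrl <- c(10, 11, 12); dep <- c(13, 14, 15)
  r <- testSite(ctrl, dep)
  expect_equal(r$delta_abs, 3)
  expect_equal(r$rel_increase, 3 / 11)
  # t = 3 / sqrt(1 * (1/3 + 1/3)) = 3.674 on 4 df
  expect_equal(r$t, 3 / sqrt(2 / 3), tolerance = 1e-12)
  oracle <- t.test(dep, ctrl, var.equal = TRUE)
  expect_equal(r$p_value, oracle$p.value, tolerance = 1e-12)
  expect_equal(r$p_value, 0.02131164, tolerance = 1e-6)
})

test_that("t-test agrees with t.test on 50 random sites to 1e-9", {
  set.seed(401)
  for (i in 1:50) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    ctrl <- rnorm(n1, 10, 2); dep <- rnorm(n2, 10 + runif(1, -2, 4), 2)
    r <- testSite(ctrl, dep)
    o <- t.test(dep, ctrl, var.equal = TRUE)
    expect_equal(r$p_value, o$p.value, tolerance = 1e-9)
    expect_equal(r$t, unname(o$statistic), tolerance = 1e-9)
  }
})

test_that("degenerate inputs follow the stated conventions", {
  same <- testSite(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$delta_abs, 0)
  expect_equal(same$p_value, 1)
  zeroCtrl <- testSite(c(0, 0), c(2, 4))
  expect_identical(zeroCtrl$rel_increase, Inf)
  bothZero <- testSite(c(0, 0), c(0, 0))
  expect_equal(bothZero$rel_increase, 0)
  expect_equal(bothZero$p_value, 1)
  constDiff <- testSite(c(5, 5), c(7, 7))  # zero variance, different means
  expect_equal(constDiff$p_value, 0)
  expect_error(testSite(5, c(1, 2)), "insufficient replicates")
})

test_that("the composite rule needs all three criteria", {
  set.seed(402)
  n <- 100
  pct <- matrix(rnorm(n * 6, 10, 0.5), n, 6,
                dimnames = list(sprintf("P%03d:8", 1:n), paste0("s", 1:6)))
  # site 1: strong planted increase; site 2: significant but small relative
  pct[1, 4:6] <- pct[1, 1:3] + 10
  pct[2, 1:3] <- c(100, 100.1, 99.9); pct[2, 4:6] <- pct[2, 1:3] + 12
  groups <- rep(c("control", "depleted"), each = 3)
  dr <- callIncreasedOxidation(profileFromMatrix(pct, groups))
  expect_identical(attr(dr, "n_top"), 15L)  # ceil(0.15 * 100)
  s1 <- dr[dr$site_id == "P001:8", ]
  expect_true(s1$p_value < 0.05 && s1$rel_increase >= 0.25 && s1$in_top)
  expect_true(s1$called)
  s2 <- dr[dr$site_id == "P002:8", ]
  expect_true(s2$p_value < 0.05 && s2$in_top)
  expect_lt(s2$rel_increase, 0.25)
  expect_false(s2$called)  # fails only the relative-increase criterion
})

test_that("calls match a naive reimplementation of the three criteria", {
  set.seed(403)
  n <- 50
  pct <- matrix(abs(rnorm(n * 8, 12, 3)), n, 8,
                dimnames = list(sprintf("P%03d:8", 1:n), paste0("s", 1:8)))
  idx <- sample(n, 10)
  pct[idx, 5:8] <- pct[idx, 5:8] + rexp(10 * 4, 1 / 5)
  groups <- rep(c("control", "depleted"), each = 4)
  dr <- callIncreasedOxidation(profileFromMatrix(pct, groups),
                               alpha = 0.05, relMin = 0.25, topFrac = 0.15)
  # naive route: recompute everything from the raw matrix
  naive <- lapply(seq_len(n), function(i) {
    x <- pct[i, 1:4]; y <- pct[i, 5:8]
    sp2 <- (3 * var(x) + 3 * var(y)) / 6
    tt <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / 4 + 1 / 4))
    data.frame(site_id = rownames(pct)[i], delta = mean(y) - mean(x),
               rel = (mean(y) - mean(x)) / mean(x),
               p = 2 * pt(-abs(tt), 6))
  })
  naive <- do.call(rbind, naive)
  ord <- order(-naive$delta, naive$site_id)
  topIds <- naive$site_id[ord][1:ceiling(0.15 * n)]
  naiveCalled <- naive$site_id[naive$p < 0.05 & naive$rel >= 0.25 &
                               naive$site_id %in% topIds]
  expect_setequal(dr$site_id[dr$called], naiveCalled)
  expect_gt(length(naiveCalled), 0)
  expect_equal(dr$p_value, naive$p[match(dr$site_id, naive$site_id)],
               tolerance = 1e-12)
})

test_that("relaxing any criterion never shrinks the called set", {
  set.seed(404)
  n <- 80
  pct <- matrix(abs(rnorm(n * 6, 10, 2)), n, 6,
                dimnames = list(sprintf("P%03d:8", 1:n), paste0("s", 1:6)))
  pct[1:12, 4:6] <- pct[1:12, 4:6] + 5
  pr <- profileFromMatrix(pct, rep(c("control", "depleted"), each = 3))
  base <- callIncreasedOxidation(pr, alpha = 0.05, relMin = 0.25,
                                 topFrac = 0.15)
  for (args in list(list(alpha = 0.2), list(relMin = 0.1),
                    list(topFrac = 0.5))) {
    relaxed <- do.call(callIncreasedOxidation,
                       c(list(pr), modifyList(
                         list(alpha = 0.05, relMin = 0.25, topFrac = 0.15),
                         args)))
    expect_true(all(base$site_id[base$called] %in%
                    relaxed$site_id[relaxed$called]))
  }
})

test_that("top-set boundary ties break by site id", {
  pct <- matrix(10, 10, 4, dimnames = list(sprintf("P%02d:8", 10:1),
                                           paste0("s", 1:4)))
  pct[, 3:4] <- 12  # identical delta everywhere
  dr <- callIncreasedOxidation(profileFromMatrix(
    pct, rep(c("control", "depleted"), each = 2)), topFrac = 0.2)
  top <- sort(dr$site_id[dr$in_top])
  expect_identical(top, c("P01:8", "P02:8"))  # lexicographic ascending
})

test_that("proteins rank by called-site count with accession tie-breaks", {
  res <- data.frame(
    site_id = sprintf("x:%d", 1:14),
    protein_accession = rep(c("B", "A", "C"), c(2, 10, 2)),
    site_position = 1:14, called = TRUE)
  rk <- rankProteins(res)
  expect_identical(rk$protein_accession, c("A", "B", "C"))
  expect_identical(rk$n_called_sites, c(10L, 2L, 2L))
  expect_identical(rk$rank, 1:3)
  expect_identical(nrow(rankProteins(transform(res, called = FALSE))), 0L)
})

test_that("sites map to inclusive domain intervals or 'unannotated'", {
  annot <- data.frame(protein_accession = "P1",
                      domain_label = c("KS", "TE"),
                      start = c(40L, 61L), end = c(60L, 65L))
  res <- data.frame(site_id = c("P1:50", "P1:60", "P1:70"),
                    protein_accession = "P1",
                    site_position = c(50L, 60L, 70L), called = TRUE)
  m <- mapSitesToDomains(res, annot)
  expect_identical(m$map$domain_label, c("KS", "KS", "unannotated"))
  expect_identical(m$counts$n_sites[m$counts$domain_label == "KS"], 2L)
  ov <- annot; ov$start[2] <- 55L
  expect_error(mapSitesToDomains(res, ov), "overlap")
})
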