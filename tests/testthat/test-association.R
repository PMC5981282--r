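test_that("noise-free balanced fit recovers cell means exactly", {
  cfg <- phenoSimConfig(residualSd = 1e-10, nPerCell = 4)
  ph <- simulateLitterSizes(cfg, seed = 1)
  fit <- fitLitterModel(ph)
  truth <- trueCellMeans(cfg)
  cells <- modelCells(fit)
  for (r in seq_len(nrow(cells)))
    expect_equal(cells$mean[r],
                 truth[cells$parity[r], cells$genotype[r]],
                 tolerance = 1e-6)
  expect_lt(modelMSE(fit), 1e-12)

  lsm <- lsMeans(fit, "per-parity")
  expect_equal(lsm$estimate,
               truth[cbind(lsm$parity, lsm$genotype)], tolerance = 1e-6)
  expect_true(all(lsm$se < 1e-5))
})

test_that("identical responses give zero MSE and equal LS means", {
  ph <- data.frame(ewe_id = sprintf("e%d", 1:12),
                   parity = rep(1:2, 6),
                   genotype = rep(c("AA", "AB", "BB"), each = 4),
                   litter_size = 2)
  fit <- fitLitterModel(ph)
  expect_equal(modelMSE(fit), 0)
  lsm <- lsdLetters(lsMeans(fit, "genotype-average"), fit)
  expect_equal(lsm$estimate, rep(2, 3))
  expect_true(all(lsm$letters == "a"))
})

test_that("OLS coefficients equal a normal-equations oracle", {
  ## unbalanced data: random cell sizes
  set.seed(13)
  rows <- list()
  for (i in 1:3) for (j in c("AA", "AB", "BB")) {
    n <- sample(3:12, 1)
    rows[[paste(i, j)]] <- data.frame(
      ewe_id = sprintf("e%s%s%d", i, j, seq_len(n)), parity = i,
      genotype = j, litter_size = rnorm(n, 2.4, 0.6))
  }
  ph <- do.call(rbind, rows)
  fit <- fitLitterModel(ph)

  ## oracle: build the indicator design matrix and solve X'X b = X'y
  cellKey <- paste(ph$parity, ph$genotype, sep = ":")
  lev <- sort(unique(cellKey))
  X <- sapply(lev, function(l) as.numeric(cellKey == l))
  beta <- solve(crossprod(X), crossprod(X, ph$litter_size))[, 1]
  cells <- modelCells(fit)
  got <- setNames(cells$mean, paste(cells$parity, cells$genotype,
                                    sep = ":"))
  expect_equal(got[lev], beta[lev], tolerance = 1e-10, ignore_attr = TRUE)

  ## residual MSE against the oracle too
  sse <- sum((ph$litter_size - X %*% beta)^2)
  expect_equal(modelMSE(fit), sse / (nrow(ph) - length(lev)),
               tolerance = 1e-10)
})

test_that("standard errors follow the pooled-MSE formulas", {
  cfg <- phenoSimConfig(nPerCell = 64)
  ph <- simulateLitterSizes(cfg, seed = 3)
  fit <- fitLitterModel(ph)
  lsm <- lsMeans(fit, "per-parity")
  expect_equal(lsm$se, rep(sqrt(modelMSE(fit) / 64), 9))
  av <- lsMeans(fit, "genotype-average")
  expect_equal(av$se, rep(sqrt(modelMSE(fit) * 3 / 64) / 3, 3))
  expect_equal(av$n, rep(192L, 3))
})

test_that("LS means match emmeans on the factorial fit", {
  ph <- simulateLitterSizes(phenoSimConfig(nPerCell = 10), seed = 4)
  fit <- fitLitterModel(ph)
  ref <- stats::lm(litter_size ~ factor(parity) * factor(genotype),
                   data = ph)
  em <- as.data.frame(emmeans::emmeans(ref, ~ factor(genotype) |
                                         factor(parity)))
  lsm <- lsMeans(fit, "per-parity")
  key <- paste(em[[2]], em[[1]])
  got <- setNames(lsm$estimate, paste(lsm$parity, lsm$genotype))
  gotSe <- setNames(lsm$se, paste(lsm$parity, lsm$genotype))
  expect_equal(got[key], em$emmean, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(gotSe[key], em$SE, tolerance = 1e-10, ignore_attr = TRUE)

  emAvg <- as.data.frame(emmeans::emmeans(ref, ~ factor(genotype)))
  av <- lsMeans(fit, "genotype-average")
  expect_equal(setNames(av$estimate, av$genotype)[emAvg[[1]]],
               emAvg$emmean, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("balanced genotype-average equals the simple genotype mean", {
  ph <- simulateLitterSizes(phenoSimConfig(nPerCell = 8), seed = 5)
  fit <- fitLitterModel(ph)
  av <- lsMeans(fit, "genotype-average")
  simple <- tapply(ph$litter_size, ph$genotype, mean)
  expect_equal(av$estimate, as.vector(simple[av$genotype]),
               tolerance = 1e-10)
})

test_that("LS means are invariant to record order and shift by constants", {
  ph <- simulateLitterSizes(phenoSimConfig(nPerCell = 6), seed = 6)
  fit1 <- fitLitterModel(ph)
  fit2 <- fitLitterModel(ph[sample(nrow(ph)), ])
  expect_equal(lsMeans(fit1, "per-parity"), lsMeans(fit2, "per-parity"))

  ph3 <- ph; ph3$litter_size <- ph3$litter_size + 5
  fit3 <- fitLitterModel(ph3)
  l1 <- lsdLetters(lsMeans(fit1, "per-parity"), fit1)
  l3 <- lsdLetters(lsMeans(fit3, "per-parity"), fit3)
  expect_equal(l3$estimate, l1$estimate + 5)
  expect_equal(l3$letters, l1$letters)
})

test_that("LSD letters separate exactly the significant pairs", {
  ## far-apart groups get distinct letters
  ph <- data.frame(ewe_id = sprintf("e%d", 1:20), parity = 1,
                   genotype = rep(c("AA", "AB"), each = 10),
                   litter_size = c(rnorm(10, 1, 0.05),
                                   rnorm(10, 5, 0.05)))
  fit <- fitLitterModel(ph)
  lsm <- lsdLetters(lsMeans(fit, "per-parity"), fit)
  expect_setequal(lsm$letters, c("a", "b"))
  expect_equal(lsm$letters[which.max(lsm$estimate)], "a")

  ## random 3-group configurations against the pairwise oracle:
  ## shared letter <=> pairwise p >= alpha
  for (seed in 1:10) {
    set.seed(seed)
    mus <- rnorm(3, 2.3, 0.3)
    ph <- do.call(rbind, lapply(1:3, function(j)
      data.frame(ewe_id = sprintf("e%d_%d", j, 1:12), parity = 1,
                 genotype = c("AA", "AB", "BB")[j],
                 litter_size = rnorm(12, mus[j], 0.4))))
    fit <- fitLitterModel(ph)
    lsm <- lsdLetters(lsMeans(fit, "per-parity"), fit, alpha = 0.05)
    pmat <- attr(lsm, "pairwise")[["1"]]
    for (a in 1:2) for (b in (a + 1):3) {
      shared <- length(intersect(strsplit(lsm$letters[a], "")[[1]],
                                 strsplit(lsm$letters[b], "")[[1]])) > 0
      expect_identical(shared, pmat[a, b] >= 0.05)
    }
  }
})

test_that("heterozygote advantage is recovered as the top LS mean", {
  hits <- vapply(1:20, function(seed) {
    ph <- simulateLitterSizes(phenoSimConfig(nPerCell = 80), seed = seed)
    fit <- fitLitterModel(ph)
    av <- lsMeans(fit, "genotype-average")
    av$genotype[which.max(av$estimate)] == "AB"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("degenerate designs are rejected", {
  ph <- data.frame(ewe_id = c("a", "b"), parity = 1:2,
                   genotype = "AA", litter_size = c(2, 3))
  expect_error(fitLitterModel(ph), "residual degrees of freedom")
  expect_error(fitLitterModel(data.frame(ewe_id = "a", parity = 1,
                                         genotype = "AA",
                                         litter_size = 2)),
               "2 non-empty cells")
})
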