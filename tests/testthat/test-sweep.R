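test_that("per-site FST matches its closed form and edge cases", {
  expect_equal(siteFst(0.3, 0.3), 0)
  expect_equal(siteFst(1, 0), 1)
  expect_equal(siteFst(0.9, 0.1), 0.64)
  expect_equal(siteFst(0, 0), 0)   # HT = 0 degenerate case
  expect_equal(siteFst(1, 1), 0)
})

test_that("site statistics are symmetric in groups and allele labels", {
  set.seed(1)
  pa <- runif(100); pb <- runif(100)
  expect_equal(siteFst(pa, pb), siteFst(pb, pa))
  expect_equal(siteFst(pa, pb), siteFst(1 - pa, 1 - pb))
  expect_equal(deltaAF(pa, pb), deltaAF(pb, pa))
  expect_equal(deltaAF(pa, pb), deltaAF(1 - pa, 1 - pb))
})

test_that("delta AF is the absolute frequency difference", {
  expect_equal(deltaAF(0.5, 0.5), 0)
  expect_equal(deltaAF(1, 0), 1)
  expect_equal(deltaAF(0.33, 0.76), 0.43)
})

test_that("windowed FST reduces to the site value and to zero", {
  ## identical frequencies -> every window 0
  ps <- PooledSites("c", seq(1, 1000, by = 10), pRefA = runif(100),
                    pRefB = 0, nAllelesA = 10, nAllelesB = 10)
  mcols(ps)$pRefB <- mcols(ps)$pRefA
  ws <- windowFst(ps, windowSize = 100, step = 50, minSites = 1)
  expect_true(all(windowStat(ws)[!is.na(windowStat(ws))] == 0))

  ## one site per non-overlapping window -> window value = site value
  ps2 <- PooledSites("c", c(50, 150, 250), pRefA = c(0.9, 0.5, 1),
                     pRefB = c(0.1, 0.5, 0), nAllelesA = 10,
                     nAllelesB = 10)
  ws2 <- windowFst(ps2, windowSize = 100, step = 100, minSites = 1)
  expect_equal(windowStat(ws2), siteFst(ps2))
})

test_that("windowed FST equals a brute-force interval oracle", {
  cfg <- simConfig(nSites = 500, chromLength = 200000,
                   sweepStart = 50001, sweepEnd = 70000)
  ps <- simulateDivergentPools(cfg, seed = 9)
  ws <- windowFst(ps, windowSize = 20000, step = 10000, minSites = 3)
  oracle <- bruteWindowFst(start(ps), pRefA(ps), pRefB(ps),
                           chromLength = 200000, windowSize = 20000,
                           step = 10000, minSites = 3)
  expect_equal(windowStat(ws), oracle, tolerance = 1e-12)
})

test_that("every interior site falls in windowSize/step windows", {
  ps <- simulateDivergentPools(simConfig(nSites = 300,
                                         chromLength = 100000,
                                         sweepStart = 1,
                                         sweepEnd = 10000), seed = 3)
  win <- ovisweep:::makeWindows(ps, windowSize = 20000, step = 5000)
  hits <- countOverlaps(ps, win)
  interior <- start(ps) >= 20000 & start(ps) <= 100000 - 20000
  expect_true(all(hits[interior] == 20000 / 5000))
})

test_that("pooled heterozygosity follows its formula", {
  ## all sites at p = 0.5 -> H = 0.5 by symmetry
  ps <- PooledSites("c", seq(10, 490, by = 10), pRefA = 0.5, pRefB = 0.5,
                    nAllelesA = 10, nAllelesB = 10)
  h <- pooledHeterozygosity(ps, "A", windowSize = 500, step = 500,
                            minSites = 1)
  expect_equal(windowStat(h), 0.5)

  ## fixed sites -> H = 0
  ps2 <- PooledSites("c", seq(10, 490, by = 10), pRefA = 1, pRefB = 1,
                     nAllelesA = 10, nAllelesB = 10)
  h2 <- pooledHeterozygosity(ps2, "A", windowSize = 500, step = 500,
                             minSites = 1)
  expect_equal(windowStat(h2), 0)

  ## major frequencies {0.9, 0.6}: H = 2 * 1.5 * 0.5 / 4 = 0.375
  ps3 <- PooledSites("c", c(100, 200), pRefA = c(0.9, 0.6),
                     pRefB = c(0.9, 0.6), nAllelesA = 10, nAllelesB = 10)
  h3 <- pooledHeterozygosity(ps3, "A", windowSize = 500, step = 500,
                             minSites = 1)
  expect_equal(windowStat(h3), 0.375)

  ## minor-allele orientation: p = 0.1 and p = 0.9 give the same H
  ps4 <- PooledSites("c", c(100, 200), pRefA = c(0.1, 0.4),
                     pRefB = c(0.1, 0.4), nAllelesA = 10, nAllelesB = 10)
  h4 <- pooledHeterozygosity(ps4, "A", windowSize = 500, step = 500,
                             minSites = 1)
  expect_equal(windowStat(h4), windowStat(h3))
})

test_that("Z-standardization uses the population sd of defined windows", {
  ws <- makeWindowStats(c(1, 3))
  z <- zScore(zStandardize(ws))
  expect_equal(z, c(1, 1))   # mean 2, population sd 1

  ## adding a constant to all stats leaves z unchanged
  set.seed(2)
  x <- runif(20)
  z1 <- zScore(zStandardize(makeWindowStats(x)))
  z2 <- zScore(zStandardize(makeWindowStats(x + 7)))
  expect_equal(z1, z2)

  ## zero spread -> all z = 0 with a warning
  expect_warning(z0 <- zStandardize(makeWindowStats(rep(0.4, 5))),
                 "degenerate")
  expect_equal(zScore(z0), rep(0, 5))

  ## NA windows are excluded and stay NA
  ws3 <- makeWindowStats(c(1, NA, 3))
  expect_equal(zScore(zStandardize(ws3)), c(1, NA, 1))
})

test_that("region calling merges significant windows into disjoint spans", {
  ## nothing significant -> empty
  ws <- zStandardize(makeWindowStats(c(0.1, 0.11, 0.12, 0.1)))
  expect_length(callRegions(ws, zThreshold = 5), 0L)

  ## two overlapping significant windows merge into one region
  gr <- GRanges("c", IRanges(c(1, 25001), c(50000, 75000)))
  mcols(gr)$nSites <- 5L
  mcols(gr)$stat <- c(0.9, 0.8)
  mcols(gr)$z <- c(6, 7)
  mcols(gr)$partial <- FALSE
  ws2 <- methods::new("WindowStats", gr)
  S4Vectors::metadata(ws2)$mean <- 0.1
  rg <- callRegions(ws2, zThreshold = 5)
  expect_length(rg, 1L)
  expect_equal(start(rg), 1L)
  expect_equal(end(rg), 75000L)
  expect_equal(peakZ(rg), 7)
  expect_equal(mcols(rg)$nWindows, 2L)
})

test_that("region spans equal a connected-components oracle on random z", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60
    starts <- seq(1, by = 500, length.out = n)
    gr <- GRanges("c", IRanges(starts, starts + 999))  # 1000bp, step 500
    mcols(gr)$nSites <- 5L
    mcols(gr)$stat <- runif(n)
    mcols(gr)$z <- NA_real_
    mcols(gr)$partial <- FALSE
    ws <- zStandardize(methods::new("WindowStats", gr))
    rg <- callRegions(ws, zThreshold = 1, restrictHigh = FALSE)

    ## oracle: connected components over significant-window adjacency
    sig <- which(zScore(ws) > 1)
    comp <- list()
    for (i in sig) {
      placed <- FALSE
      for (k in seq_along(comp)) {
        cc <- comp[[k]]
        if (any(starts[i] <= starts[cc] + 1000 &
                starts[cc] <= starts[i] + 1000)) {
          comp[[k]] <- c(cc, i); placed <- TRUE; break
        }
      }
      if (!placed) comp[[length(comp) + 1L]] <- i
    }
    expect_equal(length(rg), length(comp))
    expect_equal(start(rg), vapply(comp, function(cc)
      min(starts[cc]), numeric(1)))
    expect_equal(end(rg), vapply(comp, function(cc)
      max(starts[cc]) + 999, numeric(1)))
  }
})

test_that("high-side restriction drops unusually low windows", {
  x <- c(rep(0.5, 20), 0.01, 0.99)   # both tails have |z| large
  ## step > width so the two outlier windows cannot merge
  ws <- zStandardize(makeWindowStats(x, windowSize = 100, step = 200))
  rgBoth <- callRegions(ws, zThreshold = 2, restrictHigh = FALSE)
  rgHigh <- callRegions(ws, zThreshold = 2, restrictHigh = TRUE)
  expect_length(rgBoth, 2L)
  expect_length(rgHigh, 1L)
  expect_true(windowStat(ws)[22] > S4Vectors::metadata(ws)$mean)
})

test_that("gene annotation lists overlaps of at least 1 bp", {
  rg <- makeRegions("17", 1000, 2000, 6)
  genes <- GRanges("17", IRanges(c(1200, 500, 2001), c(1300, 999, 2500)),
                   name = c("inside", "before", "after"))
  ann <- annotateRegions(rg, genes)
  expect_equal(as.character(regionGenes(ann)[[1]]), "inside")

  ## boundary: a gene ending exactly at start - 1 is not listed,
  ## touching the start is
  genes2 <- GRanges("17", IRanges(c(900, 950), c(999, 1000)),
                    name = c("misses", "touches"))
  ann2 <- annotateRegions(rg, genes2)
  expect_equal(as.character(regionGenes(ann2)[[1]]), "touches")
})

test_that("gene annotation matches an all-pairs overlap oracle", {
  set.seed(8)
  rs <- cumsum(sample(6000:20000, 20))   # spaced > width, never overlap
  rg <- makeRegions("c", rs, rs + 5000, rep(6, 20))
  gs <- sample.int(1e6, 100)
  genes <- GRanges("c", IRanges(gs, gs + sample(100:3000, 100)),
                   name = sprintf("g%03d", 1:100))
  ann <- annotateRegions(rg, genes)
  for (i in seq_along(rg)) {
    hits <- mcols(genes)$name[start(genes) <= end(rg)[i] &
                                end(genes) >= start(rg)[i]]
    expect_setequal(as.character(regionGenes(ann)[[i]]), hits)
  }
})
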