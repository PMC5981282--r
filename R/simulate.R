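## Seeded generators for every input the pipeline consumes.  All are pure
## functions of (config, seed): the RNG state is localized and restored, and
## one global seed fans out to per-operation child seeds via childSeed().

#' Configuration for simulating divergent pooled frequencies
#'
#' Defines the study conditions the divergence-scan tests run under: two
#' breed groups whose per-site allele frequencies are drawn around a shared
#' ancestral frequency under the Balding-Nichols model, with a stronger
#' divergence parameter inside an implanted sweep interval.
#'
#' @param nSites number of biallelic SNP sites.
#' @param chromLength chromosome length in bp.
#' @param chrom chromosome name.
#' @param sweepStart,sweepEnd 1-based bounds of the implanted
#'   high-divergence interval.
#' @param fBackground,fSweep Balding-Nichols divergence parameters in
#'   (0, 1); `fSweep > fBackground`.
#' @param ancestralRange interval within (0, 1) the per-site ancestral
#'   frequency is drawn uniformly from.
#' @param nAllelesA,nAllelesB called allele totals recorded per group.
#' @return A validated list of class `simConfig`.
#' @seealso [simulateDivergentPools()]
#' @export
simConfig <- function(nSites = 10000L, chromLength = 5e6, chrom = "chr1",
                      sweepStart = 2450001, sweepEnd = 2550000,
                      fBackground = 0.05, fSweep = 0.5,
                      ancestralRange = c(0.05, 0.95),
                      nAllelesA = 60L, nAllelesB = 120L) {
  stopifnot(nSites >= 2, chromLength >= nSites,
            sweepStart >= 1, sweepEnd <= chromLength, sweepStart < sweepEnd,
            fBackground > 0, fBackground < 1, fSweep > 0, fSweep < 1,
            length(ancestralRange) == 2,
            ancestralRange[1] > 0, ancestralRange[2] < 1,
            ancestralRange[1] < ancestralRange[2],
            nAllelesA >= 2, nAllelesB >= 2)
  if (fSweep <= fBackground)
    stop("fSweep must exceed fBackground", call. = FALSE)
  structure(list(nSites = as.integer(nSites), chromLength = chromLength,
                 chrom = chrom, sweepStart = sweepStart, sweepEnd = sweepEnd,
                 fBackground = fBackground, fSweep = fSweep,
                 ancestralRange = ancestralRange,
                 nAllelesA = nAllelesA, nAllelesB = nAllelesB),
            class = "simConfig")
}

#' Simulate pooled allele frequencies for two divergent groups
#'
#' Site positions are drawn uniformly (without replacement) over the
#' chromosome and sorted.  Each site gets an ancestral frequency `p` from
#' `ancestralRange`; each group's frequency is then drawn from the
#' Balding-Nichols Beta distribution with mean `p` and divergence `F`
#' (`shape1 = p(1-F)/F`, `shape2 = (1-p)(1-F)/F`), using `fSweep` inside
#' the sweep interval and `fBackground` elsewhere.  The true sweep interval
#' is recorded in `metadata(x)$sweep` for downstream recovery tests.
#'
#' @param config a [simConfig()] object.
#' @param seed integer RNG seed; identical seed gives identical output.
#' @return A [PooledSites-class] object with metadata entries `sweep` (a
#'   `GRanges` of the true interval) and `config`.
#' @examples
#' ps <- simulateDivergentPools(simConfig(nSites = 500), seed = 1)
#' metadata(ps)$sweep
#' @export
simulateDivergentPools <- function(config = simConfig(), seed = 1L) {
  stopifnot(inherits(config, "simConfig"))
  withSeed(seed, {
    pos <- sort(sample.int(config$chromLength, config$nSites))
    anc <- runif(config$nSites, config$ancestralRange[1],
                 config$ancestralRange[2])
    ## guard the degenerate Beta shapes at p = 0 or 1 (cannot occur with a
    ## strictly interior range, but resample defensively)
    bad <- anc <= 0 | anc >= 1
    while (any(bad)) {
      anc[bad] <- runif(sum(bad), config$ancestralRange[1],
                        config$ancestralRange[2])
      bad <- anc <= 0 | anc >= 1
    }
    inSweep <- pos >= config$sweepStart & pos <= config$sweepEnd
    f <- ifelse(inSweep, config$fSweep, config$fBackground)
    shape1 <- anc * (1 - f) / f
    shape2 <- (1 - anc) * (1 - f) / f
    pA <- rbeta(config$nSites, shape1, shape2)
    pB <- rbeta(config$nSites, shape1, shape2)
    out <- PooledSites(chrom = config$chrom, pos = pos, pRefA = pA,
                       pRefB = pB, nAllelesA = config$nAllelesA,
                       nAllelesB = config$nAllelesB,
                       seqlengths = setNames(config$chromLength,
                                             config$chrom))
    metadata(out)$sweep <- GRanges(config$chrom,
                                   IRanges(config$sweepStart,
                                           config$sweepEnd))
    metadata(out)$config <- config
    out
  })
}

#' Simulate genotype counts at a biallelic marker
#'
#' One multinomial draw of `n` individuals over genotype probabilities
#' `(p^2 + D, 2pq - 2D, q^2 + D)`, where `D` is the Hardy-Weinberg
#' disequilibrium coefficient (`D = 0` gives exact HWE proportions).
#'
#' @param n number of individuals.
#' @param p reference-allele frequency.
#' @param D disequilibrium coefficient; must lie in
#'   `[-min(p^2, q^2), p*q]` so all three probabilities are valid.
#' @param seed integer RNG seed.
#' @return A [GenotypeCounts-class] object.
#' @export
simulateGenotypeCounts <- function(n, p, D = 0, seed = 1L) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  q <- 1 - p
  lo <- -min(p^2, q^2); hi <- p * q
  if (D < lo || D > hi)
    stop(sprintf("infeasible D = %g; feasible range is [%g, %g]", D, lo, hi),
         call. = FALSE)
  probs <- c(p^2 + D, 2 * p * q - 2 * D, q^2 + D)
  withSeed(seed, {
    draw <- rmultinom(1, size = n, prob = probs)[, 1]
    GenotypeCounts(draw[1], draw[2], draw[3])
  })
}

#' Configuration for simulating litter-size records
#'
#' Parameters of the generating model
#' `y = mu + P_i + G_j + I_PG(i, j) + e`, `e ~ Normal(0, residualSd^2)`,
#' over three parities and three marker genotypes.
#'
#' @param mu population mean litter size (lambs).
#' @param parityEffects numeric(3) fixed parity effects, parities 1-3.
#' @param genotypeEffects named numeric(3) fixed genotype effects.
#' @param interactionEffects 3 x 3 matrix of parity x genotype interaction
#'   effects (rows = parities).
#' @param residualSd residual standard deviation (> 0).
#' @param nPerCell ewes per genotype; each ewe contributes one record per
#'   parity, so every parity x genotype cell holds `nPerCell` records.
#' @return A validated list of class `phenoSimConfig`.
#' @seealso [simulateLitterSizes()]
#' @export
phenoSimConfig <- function(mu = 2.3,
                           parityEffects = c(-0.2, 0, 0.6),
                           genotypeEffects = c(AA = -0.1, AB = 0.2, BB = 0),
                           interactionEffects = matrix(0, 3, 3),
                           residualSd = 0.75, nPerCell = 64L) {
  stopifnot(length(parityEffects) == 3, length(genotypeEffects) == 3,
            identical(dim(interactionEffects), c(3L, 3L)),
            residualSd > 0, nPerCell >= 1)
  if (is.null(names(genotypeEffects)))
    names(genotypeEffects) <- c("AA", "AB", "BB")
  structure(list(mu = mu, parityEffects = parityEffects,
                 genotypeEffects = genotypeEffects,
                 interactionEffects = interactionEffects,
                 residualSd = residualSd, nPerCell = as.integer(nPerCell)),
            class = "phenoSimConfig")
}

#' Cell means implied by a phenotype simulation config
#'
#' @param config a [phenoSimConfig()] object.
#' @return A 3 x 3 matrix (parity x genotype) of true cell means.
#' @export
trueCellMeans <- function(config) {
  stopifnot(inherits(config, "phenoSimConfig"))
  m <- outer(config$parityEffects, config$genotypeEffects, `+`) +
    config$mu + config$interactionEffects
  dimnames(m) <- list(parity = as.character(1:3),
                      genotype = names(config$genotypeEffects))
  m
}

#' Simulate per-ewe litter-size records
#'
#' Generates `nPerCell` ewes per genotype, each observed at parities 1-3,
#' with responses from the additive-plus-interaction Gaussian model of
#' [phenoSimConfig()].  A ewe keeps its genotype across parities.
#'
#' @param config a [phenoSimConfig()] object.
#' @param seed integer RNG seed.
#' @return A data.frame with columns `ewe_id`, `parity`, `genotype`,
#'   `litter_size`, plus the generating config in `attr(x, "config")`.
#' @export
simulateLitterSizes <- function(config = phenoSimConfig(), seed = 1L) {
  stopifnot(inherits(config, "phenoSimConfig"))
  gts <- names(config$genotypeEffects)
  cellMeans <- trueCellMeans(config)
  withSeed(seed, {
    rows <- list()
    for (j in seq_along(gts)) {
      ids <- sprintf("ewe_%s_%03d", gts[j], seq_len(config$nPerCell))
      for (i in 1:3) {
        y <- cellMeans[i, j] + rnorm(config$nPerCell, 0, config$residualSd)
        rows[[length(rows) + 1L]] <-
          data.frame(ewe_id = ids, parity = i, genotype = gts[j],
                     litter_size = y, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "config") <- config
    out
  })
}

#' Simulate a qPCR Ct table
#'
#' Reference-gene Ct values are drawn Normal(20, sd^2); target Ct is the
#' reference Ct plus a baseline delta-Ct, a per-group shift, and Gaussian
#' noise.  A negative shift means the target amplifies earlier (higher
#' expression) in that group.
#'
#' @param tissues character vector of tissue names.
#' @param groups character vector of group names.
#' @param deltaCtShift named numeric of per-group shifts (cycles); names
#'   must cover `groups`.
#' @param baselineDeltaCt baseline target-minus-reference Ct (cycles).
#' @param sd Gaussian noise standard deviation (cycles, > 0).
#' @param nReplicates biological replicates per tissue x group.
#' @param seed integer RNG seed.
#' @return A data.frame with columns `tissue`, `group`, `replicate`,
#'   `ct_target`, `ct_reference`.
#' @export
simulateCtTable <- function(tissues = c("brain", "cerebellum",
                                        "hypothalamus", "pituitary",
                                        "ovary", "oviduct", "uterus_body",
                                        "uterine_horn"),
                            groups = c("high_fecundity", "low_fecundity"),
                            deltaCtShift = c(high_fecundity = -1.5,
                                             low_fecundity = 0),
                            baselineDeltaCt = 5, sd = 0.2,
                            nReplicates = 3L, seed = 1L) {
  stopifnot(sd > 0, nReplicates >= 1)
  if (!all(groups %in% names(deltaCtShift)))
    stop("deltaCtShift must name every group", call. = FALSE)
  grid <- expand.grid(replicate = seq_len(nReplicates), group = groups,
                      tissue = tissues, stringsAsFactors = FALSE)
  withSeed(seed, {
    ctRef <- rnorm(nrow(grid), 20, sd)
    ctTar <- ctRef + baselineDeltaCt + deltaCtShift[grid$group] +
      rnorm(nrow(grid), 0, sd)
    data.frame(tissue = grid$tissue, group = grid$group,
               replicate = grid$replicate,
               ct_target = as.numeric(ctTar),
               ct_reference = as.numeric(ctRef),
               stringsAsFactors = FALSE)
  })
}
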