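#' Pooled per-site allele frequencies for two breed groups
#'
#' A `PooledSites` object is a [GenomicRanges::GRanges] of width-1 biallelic
#' SNP positions carrying, for each of two breed groups, the reference-allele
#' frequency and the number of called alleles it was estimated from.
#' Positions are 1-based (VCF convention), sorted, and unique per chromosome.
#'
#' Required metadata columns:
#' \describe{
#'   \item{pRefA, pRefB}{reference-allele frequency in group A / B, in
#'     \[0, 1\].}
#'   \item{nAllelesA, nAllelesB}{called allele totals per group (>= 2).}
#' }
#'
#' @slot NAMES,elementMetadata,... inherited from `GRanges`.
#' @seealso [PooledSites()] to construct, [readPooledVcf()],
#'   [readSiteFrequencies()], [simulateDivergentPools()].
#' @export
setClass("PooledSites", contains = "GRanges")

setValidity("PooledSites", function(object) {
  mc <- mcols(object)
  need <- c("pRefA", "pRefB", "nAllelesA", "nAllelesB")
  miss <- setdiff(need, names(mc))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  for (col in c("pRefA", "pRefB")) {
    p <- mc[[col]]
    if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
      return(paste(col, "must be numeric in [0, 1]"))
  }
  for (col in c("nAllelesA", "nAllelesB")) {
    n <- mc[[col]]
    if (!is.numeric(n) || anyNA(n) || any(n < 2))
      return(paste(col, "must be >= 2 (a frequency needs >= 2 called alleles)"))
  }
  if (length(object)) {
    if (any(width(object) != 1L))
      return("sites must have width 1")
    if (is.unsorted(order(as.integer(seqnames(object)), start(object))) ||
        !identical(order(as.integer(seqnames(object)), start(object)),
                   seq_along(object)))
      return("sites must be sorted by (chrom, pos)")
    key <- paste(seqnames(object), start(object))
    if (anyDuplicated(key))
      return("duplicate positions within a chromosome")
  }
  TRUE
})

#' Construct a PooledSites object
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param pRefA,pRefB reference-allele frequencies per group, in \[0, 1\].
#' @param nAllelesA,nAllelesB called allele totals per group (>= 2).
#' @param seqlengths optional named vector of chromosome lengths (bp).
#' @return A [PooledSites-class] object, sorted by (chrom, pos).
#' @examples
#' ps <- PooledSites("17", c(100L, 200L), pRefA = c(0.9, 0.5),
#'                   pRefB = c(0.1, 0.5), nAllelesA = 60, nAllelesB = 120)
#' siteFst(ps)
#' @export
PooledSites <- function(chrom, pos, pRefA, pRefB, nAllelesA, nAllelesB,
                        seqlengths = NULL) {
  gr <- GRanges(chrom, IRanges(pos, width = 1L),
                pRefA = as.numeric(pRefA), pRefB = as.numeric(pRefB),
                nAllelesA = as.numeric(nAllelesA),
                nAllelesB = as.numeric(nAllelesB))
  gr <- sort(gr)
  if (!is.null(seqlengths))
    seqlengths(gr)[names(seqlengths)] <- seqlengths
  new("PooledSites", gr)
}

#' @describeIn PooledSites reference-allele frequencies in group A.
#' @param x a `PooledSites` object.
#' @export
pRefA <- function(x) mcols(x)$pRefA

#' @describeIn PooledSites reference-allele frequencies in group B.
#' @export
pRefB <- function(x) mcols(x)$pRefB

setMethod("show", "PooledSites", function(object) {
  cat("PooledSites with", length(object), "biallelic sites on",
      length(seqlevelsInUse(object)), "chromosome(s)\n")
  callNextMethod()
})

#' Windowed scan statistics
#'
#' A `WindowStats` object is a [GenomicRanges::GRanges] of sliding windows
#' with metadata columns `nSites` (SNPs falling in the window), `stat` (the
#' raw windowed statistic, FST or pooled heterozygosity H; `NA` where the
#' window holds fewer than the minimum number of sites), `z` (the absolute
#' Z-standardized value, filled by [zStandardize()]) and `partial` (`TRUE`
#' for a truncated terminal window).  `metadata(x)` records the statistic
#' name, window size and step.
#'
#' @seealso [windowFst()], [pooledHeterozygosity()], [zStandardize()],
#'   [callRegions()].
#' @export
setClass("WindowStats", contains = "GRanges")

setValidity("WindowStats", function(object) {
  mc <- mcols(object)
  need <- c("nSites", "stat", "z", "partial")
  miss <- setdiff(need, names(mc))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (any(mc$nSites < 0)) return("nSites must be >= 0")
  z <- mc$z
  if (any(!is.na(z) & z < 0)) return("z must be >= 0 (absolute standardization)")
  TRUE
})

#' @describeIn WindowStats raw windowed statistic values (`NA` = excluded).
#' @param x a `WindowStats` object.
#' @export
windowStat <- function(x) mcols(x)$stat

#' @describeIn WindowStats standardized values (`NA` until [zStandardize()]).
#' @export
zScore <- function(x) mcols(x)$z

#' @describeIn WindowStats number of sites per window.
#' @export
nSites <- function(x) mcols(x)$nSites

setMethod("show", "WindowStats", function(object) {
  md <- metadata(object)
  cat(sprintf("WindowStats (%s): %d windows of %s bp, step %s bp; %d with defined stat\n",
              if (is.null(md$statName)) "?" else md$statName,
              length(object),
              format(md$windowSize, big.mark = ","),
              format(md$step, big.mark = ","),
              sum(!is.na(mcols(object)$stat))))
  callNextMethod()
})

#' Candidate selective-sweep regions
#'
#' A `SweepRegions` object is a [GenomicRanges::GRanges] of merged runs of
#' significant windows, with metadata columns `peakZ` (maximum member window
#' Z), `nWindows` (number of merged windows) and `genes` (a `CharacterList`
#' of overlapping gene symbols, filled by [annotateRegions()]).  Regions on
#' one chromosome never overlap.
#'
#' @seealso [callRegions()], [annotateRegions()], [writeRegionsBed()].
#' @export
setClass("SweepRegions", contains = "GRanges")

setValidity("SweepRegions", function(object) {
  mc <- mcols(object)
  need <- c("peakZ", "nWindows", "genes")
  miss <- setdiff(need, names(mc))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (length(object) && !isDisjoint(object))
    return("merged regions must not overlap")
  TRUE
})

#' @describeIn SweepRegions peak standardized value per region.
#' @param x a `SweepRegions` object.
#' @export
peakZ <- function(x) mcols(x)$peakZ

#' @describeIn SweepRegions annotated gene symbols per region.
#' @export
regionGenes <- function(x) mcols(x)$genes

setMethod("show", "SweepRegions", function(object) {
  cat("SweepRegions:", length(object), "candidate region(s)\n")
  callNextMethod()
})

#' Genotype counts at one biallelic marker
#'
#' Counts of the three genotype classes at a biallelic locus in one breed:
#' reference homozygotes (`nAA`), heterozygotes (`nAa`) and alternate
#' homozygotes (`naa`).  All downstream marker statistics (allele
#' frequencies, PIC, HE, NE, the Hardy-Weinberg test) are computed from
#' these counts.
#'
#' @slot nAA,nAa,naa non-negative integer counts; total >= 1.
#' @seealso [GenotypeCounts()], [alleleFrequencies()], [markerSummary()],
#'   [hweTest()].
#' @export
setClass("GenotypeCounts",
         representation(nAA = "integer", nAa = "integer", naa = "integer"))

setValidity("GenotypeCounts", function(object) {
  n <- c(object@nAA, object@nAa, object@naa)
  if (anyNA(n) || any(n < 0)) return("counts must be non-negative")
  if (sum(n) < 1) return("total count must be >= 1")
  TRUE
})

#' Construct a GenotypeCounts object
#'
#' @param nAA,nAa,naa counts of reference homozygotes, heterozygotes and
#'   alternate homozygotes.
#' @return A [GenotypeCounts-class] object.
#' @examples
#' g <- GenotypeCounts(42, 167, 166)
#' markerSummary(g)
#' @export
GenotypeCounts <- function(nAA, nAa, naa) {
  new("GenotypeCounts", nAA = as.integer(nAA), nAa = as.integer(nAa),
      naa = as.integer(naa))
}

#' @describeIn GenotypeCounts total number of genotyped individuals.
#' @param g a `GenotypeCounts` object.
#' @export
nIndividuals <- function(g) g@nAA + g@nAa + g@naa

setMethod("show", "GenotypeCounts", function(object) {
  cat(sprintf("GenotypeCounts: AA=%d Aa=%d aa=%d (N=%d)\n",
              object@nAA, object@nAa, object@naa, nIndividuals(object)))
})

#' Two-locus linkage disequilibrium estimated by EM
#'
#' Result of [ldEM()]: maximum-likelihood haplotype frequencies for the four
#' two-locus haplotypes (order: 11, 10, 01, 00, where 1 is the reference
#' allele at each locus), the disequilibrium coefficient `D`, the normalized
#' `Dprime` and correlation `r2`, plus the EM log-likelihood trace.
#'
#' @slot hapFreq named numeric(4) of haplotype frequencies (sums to 1).
#' @slot D,Dprime,r2 disequilibrium summaries.
#' @slot iterations number of EM iterations run.
#' @slot converged logical convergence flag.
#' @slot logLik log-likelihood at each iteration (non-decreasing).
#' @seealso [ldEM()].
#' @export
setClass("LDResult",
         representation(hapFreq = "numeric", D = "numeric",
                        Dprime = "numeric", r2 = "numeric",
                        iterations = "integer", converged = "logical",
                        logLik = "numeric"))

#' @describeIn LDResult haplotype frequencies.
#' @param x an `LDResult` object.
#' @export
hapFreq <- function(x) x@hapFreq

setMethod("show", "LDResult", function(object) {
  cat("Two-locus LD (EM over unphased genotypes)\n")
  cat("  haplotype frequencies:",
      paste(sprintf("%s=%.4f", names(object@hapFreq), object@hapFreq),
            collapse = " "), "\n")
  cat(sprintf("  D = %.4f  D' = %.4f  r2 = %.4f  (%d iterations%s)\n",
              object@D, object@Dprime, object@r2, object@iterations,
              if (object@converged) "" else ", NOT converged"))
})

#' Fitted parity x genotype litter-size model
#'
#' Ordinary least squares fit of litter size on the full parity x genotype
#' cell-means parameterization (equivalent to mean + parity + genotype +
#' interaction with estimable contrasts).  Holds the underlying [stats::lm]
#' fit, the per-cell sample sizes and means, the pooled residual mean
#' square and the residual degrees of freedom.
#'
#' @slot model the underlying `lm` fit.
#' @slot cells data.frame with columns parity, genotype, n, mean.
#' @slot mse pooled residual mean square.
#' @slot dfResidual residual degrees of freedom (N - non-empty cells).
#' @slot parityLevels,genotypeLevels declared factor levels.
#' @seealso [fitLitterModel()], [lsMeans()], [lsdLetters()].
#' @export
setClass("LitterModelFit",
         representation(model = "ANY", cells = "data.frame", mse = "numeric",
                        dfResidual = "numeric", parityLevels = "character",
                        genotypeLevels = "character"))

#' @describeIn LitterModelFit pooled residual mean square.
#' @param fit a `LitterModelFit` object.
#' @export
modelMSE <- function(fit) fit@mse

#' @describeIn LitterModelFit per-cell sample sizes and means.
#' @export
modelCells <- function(fit) fit@cells

setMethod("show", "LitterModelFit", function(object) {
  cat(sprintf("Litter-size fixed-effects fit: %d x %d parity x genotype cells, MSE = %.4f, residual df = %d\n",
              length(object@parityLevels), length(object@genotypeLevels),
              object@mse, as.integer(object@dfResidual)))
  print(object@cells)
})
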