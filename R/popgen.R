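## Marker population genetics: allele and genotype frequencies, PIC,
## expected heterozygosity, effective allele number, and the Hardy-Weinberg
## chi-square test, all from genotype counts.  Statistics are computed from
## unrounded allele frequencies; round2() (half away from zero) is applied
## only when formatting for table comparison.

#' Allele frequencies from genotype counts
#'
#' `p = (2*nAA + nAa) / (2N)` for the reference allele, `q = 1 - p`.
#'
#' @param g a [GenotypeCounts-class] object.
#' @return Named numeric: `p`, `q`.
#' @examples
#' alleleFrequencies(GenotypeCounts(42, 167, 166))  # p = 0.3347
#' @export
alleleFrequencies <- function(g) {
  stopifnot(is(g, "GenotypeCounts"))
  n <- nIndividuals(g)
  p <- (2 * g@nAA + g@nAa) / (2 * n)
  c(p = p, q = 1 - p)
}

#' Marker summary statistics (PIC, HE, NE)
#'
#' For a biallelic locus with unrounded allele frequencies `p`, `q`:
#' expected heterozygosity `HE = 1 - p^2 - q^2`, polymorphic information
#' content `PIC = HE - 2*p^2*q^2`, and effective number of alleles
#' `NE = 1 / (p^2 + q^2)`.  `PIC <= HE` always, with equality iff the
#' locus is monomorphic, and `NE = 1 / (1 - HE)` exactly.
#'
#' @param g a [GenotypeCounts-class] object.
#' @return One-row data.frame: `N`, `p`, `q`, `HE`, `PIC`, `NE`.
#' @examples
#' markerSummary(GenotypeCounts(42, 167, 166))  # PIC 0.346, HE 0.445, NE 1.80
#' @export
markerSummary <- function(g) {
  fr <- alleleFrequencies(g)
  p <- fr[["p"]]; q <- fr[["q"]]
  he <- 1 - p^2 - q^2
  data.frame(N = nIndividuals(g), p = p, q = q, HE = he,
             PIC = he - 2 * p^2 * q^2, NE = 1 / (p^2 + q^2))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Compares observed genotype counts to the expectations `N*p^2`, `2*N*p*q`,
#' `N*q^2` computed from the observed allele frequency, with
#' `chi2 = sum((obs - exp)^2 / exp)` over the three genotype classes, no
#' continuity correction, and df = 1 (three classes, minus one, minus one
#' estimated allele frequency).  A monomorphic locus is not testable and
#' returns `NA` statistics with `method` noting it.  Expected counts below
#' 5 trigger a warning (the chi-square approximation weakens), not an
#' exact test.
#'
#' @param g a [GenotypeCounts-class] object.
#' @return An object of class `htest` with `statistic` (chi2), `parameter`
#'   (df = 1) and `p.value`.
#' @examples
#' hweTest(GenotypeCounts(69, 21, 6))  # chi2 ~ 5.15, p ~ 0.02
#' @export
hweTest <- function(g) {
  stopifnot(is(g, "GenotypeCounts"))
  n <- nIndividuals(g)
  fr <- alleleFrequencies(g)
  p <- fr[["p"]]; q <- fr[["q"]]
  if (p == 0 || p == 1) {
    return(structure(list(
      statistic = c(chi2 = NA_real_), parameter = c(df = 1),
      p.value = NA_real_,
      method = "Hardy-Weinberg chi-square test (not testable: monomorphic locus)",
      data.name = sprintf("AA=%d Aa=%d aa=%d", g@nAA, g@nAa, g@naa)),
      class = "htest"))
  }
  expected <- n * c(p^2, 2 * p * q, q^2)
  if (any(expected < 5))
    warning("expected genotype count below 5; chi-square approximation may be poor",
            call. = FALSE)
  observed <- c(g@nAA, g@nAa, g@naa)
  chi2 <- sum((observed - expected)^2 / expected)
  structure(list(
    statistic = c(chi2 = chi2), parameter = c(df = 1),
    p.value = pchisq(chi2, df = 1, lower.tail = FALSE),
    method = "Hardy-Weinberg chi-square test (df = 1, no continuity correction)",
    data.name = sprintf("AA=%d Aa=%d aa=%d", g@nAA, g@nAa, g@naa)),
    class = "htest")
}

#' Full marker table from genotype counts
#'
#' Applies [alleleFrequencies()], [markerSummary()] and [hweTest()] to every
#' row of a genotype-count table (see [readGenotypeTable()]), producing the
#' columns candidate-gene studies print: genotype frequencies, allele
#' frequencies, PIC, HE, NE and the HWE p-value (`NA` for monomorphic
#' loci, which are not testable).
#'
#' @param df data.frame with columns `breed`, `locus`, `n_AA`, `n_Aa`,
#'   `n_aa`.
#' @return data.frame with one row per input row and columns `breed`,
#'   `locus`, `N`, `f_AA`, `f_Aa`, `f_aa`, `p`, `q`, `PIC`, `HE`, `NE`,
#'   `chi2`, `p_value`.
#' @export
markerTable <- function(df) {
  rows <- lapply(seq_len(nrow(df)), function(i) {
    g <- GenotypeCounts(df$n_AA[i], df$n_Aa[i], df$n_aa[i])
    n <- nIndividuals(g)
    ms <- markerSummary(g)
    hw <- suppressWarnings(hweTest(g))
    data.frame(breed = df$breed[i], locus = df$locus[i], N = n,
               f_AA = g@nAA / n, f_Aa = g@nAa / n, f_aa = g@naa / n,
               p = ms$p, q = ms$q, PIC = ms$PIC, HE = ms$HE, NE = ms$NE,
               chi2 = unname(hw$statistic), p_value = hw$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
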