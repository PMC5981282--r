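## Two-locus linkage disequilibrium from unphased genotypes by EM.  Only
## double heterozygotes have ambiguous phase; the E-step splits them
## between the coupling (11/00) and repulsion (10/01) configurations by the
## current haplotype-frequency odds.

## genotype-class probabilities given haplotype frequencies f = (f11, f10,
## f01, f00); cells indexed [g1+1, g2+1] with g = copies of allele 1
genoProbs <- function(f) {
  f11 <- f[1]; f10 <- f[2]; f01 <- f[3]; f00 <- f[4]
  m <- matrix(0, 3, 3)
  m[3, 3] <- f11^2
  m[3, 2] <- 2 * f11 * f10
  m[3, 1] <- f10^2
  m[2, 3] <- 2 * f11 * f01
  m[2, 2] <- 2 * f11 * f00 + 2 * f10 * f01
  m[2, 1] <- 2 * f10 * f00
  m[1, 3] <- f01^2
  m[1, 2] <- 2 * f01 * f00
  m[1, 1] <- f00^2
  m
}

#' Two-locus LD by EM over unphased genotypes
#'
#' Estimates the four two-locus haplotype frequencies by
#' expectation-maximization from unphased genotype pairs, then derives
#' `D = f11 - p1*p2`, `D' = |D| / Dmax` and `r2 = D^2 /
#' (p1*q1*p2*q2)`.  Genotypes are coded 0/1/2 as the number of copies of
#' the reference allele at each locus; individuals with a missing call at
#' either locus are dropped.  Initialization is at linkage equilibrium;
#' iteration stops when the largest haplotype-frequency change falls below
#' `tol`.  The log-likelihood trace is recorded and is non-decreasing by
#' construction of EM.
#'
#' @param g1,g2 integer vectors (0, 1, 2 or `NA`) of genotypes at the two
#'   loci for the same individuals.
#' @param tol convergence tolerance on haplotype frequencies.
#' @param maxIter maximum EM iterations; non-convergence warns and returns
#'   the last iterate.
#' @return An [LDResult-class] object.
#' @examples
#' g1 <- c(rep(2, 50), rep(0, 50)); g2 <- g1   # complete association
#' ldEM(g1, g2)   # D' = 1, r2 = 1
#' @export
ldEM <- function(g1, g2, tol = 1e-8, maxIter = 1000L) {
  stopifnot(length(g1) == length(g2))
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- as.integer(g1[keep]); g2 <- as.integer(g2[keep])
  if (length(g1) < 2)
    stop("need at least 2 individuals with calls at both loci",
         call. = FALSE)
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2))
    stop("genotypes must be coded 0, 1, 2", call. = FALSE)
  n <- length(g1)
  p1 <- mean(g1) / 2
  p2 <- mean(g2) / 2
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1))
    stop("LD undefined: a locus is monomorphic", call. = FALSE)

  ## observed genotype-class counts, cells [g1+1, g2+1]
  cnt <- matrix(0L, 3, 3)
  for (i in seq_len(n)) cnt[g1[i] + 1L, g2[i] + 1L] <-
      cnt[g1[i] + 1L, g2[i] + 1L] + 1L

  ## phase-determined haplotype counts (everything but double hets)
  ## hap order: 11, 10, 01, 00
  base <- c(
    2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3],                 # 11
    2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1],                 # 10
    2 * cnt[1, 3] + cnt[2, 3] + cnt[1, 2],                 # 01
    2 * cnt[1, 1] + cnt[2, 1] + cnt[1, 2])                 # 00
  nDH <- cnt[2, 2]

  f <- c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
  ll <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    pm <- genoProbs(f)
    ll <- c(ll, sum(cnt[cnt > 0] * log(pm[cnt > 0])))
    ## E-step: split double heterozygotes between coupling and repulsion
    coup <- f[1] * f[4]
    rep_ <- f[2] * f[3]
    piC <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
    hap <- base + nDH * c(piC, 1 - piC, 1 - piC, piC)
    fNew <- hap / (2 * n)
    delta <- max(abs(fNew - f))
    f <- fNew
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= maxIter) {
      warning("EM did not converge in ", maxIter, " iterations",
              call. = FALSE)
      break
    }
  }
  pm <- genoProbs(f)
  ll <- c(ll, sum(cnt[cnt > 0] * log(pm[cnt > 0])))

  D <- f[1] - p1 * p2
  q1 <- 1 - p1; q2 <- 1 - p2
  dmax <- if (D >= 0) min(p1 * q2, q1 * p2) else min(p1 * p2, q1 * q2)
  dprime <- if (D == 0) 0 else abs(D) / dmax
  r2 <- D^2 / (p1 * q1 * p2 * q2)
  new("LDResult",
      hapFreq = setNames(f, c("11", "10", "01", "00")),
      D = D, Dprime = dprime, r2 = r2, iterations = iter,
      converged = converged, logLik = ll)
}
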