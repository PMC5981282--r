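## Two-group divergence scan: per-site FST and allele-frequency differences,
## windowed FST (ratio of sums) and pooled heterozygosity, absolute
## Z-standardization against the genome-wide window distribution, region
## calling by threshold or quantile, and gene annotation.

#' Per-site fixation index between two pooled groups
#'
#' Hudson/Nei-style estimator on pooled frequencies: with
#' `pbar = (pA + pB)/2`, `HT = 2*pbar*(1 - pbar)` and
#' `HS = (2*pA*(1 - pA) + 2*pB*(1 - pB))/2`, returns `(HT - HS)/HT`,
#' defined as 0 when `HT = 0` (both groups fixed for the same allele).
#' No finite-sample correction is applied; the statistic is exactly 0 under
#' equal frequencies and 1 for a fixed difference.
#'
#' @param x a [PooledSites-class] object, or a numeric vector of group-A
#'   frequencies.
#' @param pB group-B frequencies (only when `x` is numeric).
#' @return Numeric vector of per-site FST values in \[0, 1\].
#' @examples
#' siteFst(0.9, 0.1)  # 0.64
#' @export
siteFst <- function(x, pB = NULL) {
  if (is(x, "PooledSites")) {
    pA <- pRefA(x); pB <- pRefB(x)
  } else {
    pA <- x
    stopifnot(!is.null(pB), length(pA) == length(pB))
  }
  comp <- siteFstComponents(pA, pB)
  ifelse(comp$ht > 0, (comp$ht - comp$hs) / comp$ht, 0)
}

## numerator/denominator pieces shared by siteFst and windowFst
siteFstComponents <- function(pA, pB) {
  pbar <- (pA + pB) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * pA * (1 - pA) + 2 * pB * (1 - pB)) / 2
  list(ht = ht, hs = hs)
}

#' Per-site allele-frequency difference between groups
#'
#' @param x a [PooledSites-class] object, or numeric group-A frequencies.
#' @param pB group-B frequencies (only when `x` is numeric).
#' @return `|pRefA - pRefB|` per site, in \[0, 1\].
#' @export
deltaAF <- function(x, pB = NULL) {
  if (is(x, "PooledSites")) {
    pA <- pRefA(x); pB <- pRefB(x)
  } else {
    pA <- x
    stopifnot(!is.null(pB), length(pA) == length(pB))
  }
  abs(pA - pB)
}

## Sliding windows per chromosome, 1-based inclusive.  The terminal window
## is truncated to the chromosome end and flagged partial.  Chromosome
## length comes from seqlengths when set, else the last site position.
makeWindows <- function(sites, windowSize, step) {
  if (windowSize %% step != 0)
    stop("windowSize must be a multiple of step", call. = FALSE)
  chroms <- seqlevelsInUse(sites)
  grl <- lapply(chroms, function(ch) {
    len <- seqlengths(sites)[ch]
    if (is.na(len)) len <- max(start(sites[seqnames(sites) == ch]))
    starts <- seq(1, len, by = step)
    ends <- pmin(starts + windowSize - 1, len)
    GRanges(ch, IRanges(starts, ends),
            partial = (starts + windowSize - 1) > len)
  })
  win <- do.call(c, grl)
  suppressWarnings(seqlengths(win) <- seqlengths(sites)[seqlevels(win)])
  win
}

## Shared windowed aggregation: assigns sites to windows and applies
## aggregate(idx) over per-window site index vectors.
windowApply <- function(sites, windows, aggregate) {
  hits <- findOverlaps(sites, windows)
  stat <- rep(NA_real_, length(windows))
  n <- tabulate(subjectHits(hits), nbins = length(windows))
  byWin <- split(queryHits(hits), subjectHits(hits))
  idx <- as.integer(names(byWin))
  stat[idx] <- vapply(byWin, aggregate, numeric(1))
  list(stat = stat, n = n)
}

#' Windowed FST by ratio of sums
#'
#' Sliding-window FST over a [PooledSites-class] object: per window,
#' `sum(HT - HS) / sum(HT)` over the in-window sites (ratio of sums, the
#' standard aggregation for windowed FST, rather than a mean of per-site
#' ratios).  Windows holding fewer than `minSites` SNPs get `NA` and are
#' excluded from standardization and region calling.
#'
#' @param sites a [PooledSites-class] object (sorted; enforced by the
#'   class).
#' @param windowSize window width in bp (must be a multiple of `step`).
#' @param step step between window starts in bp.
#' @param minSites minimum SNPs for a window statistic to be defined.
#' @return A [WindowStats-class] object with `stat` filled and `z` empty
#'   (`NA`); pass to [zStandardize()].
#' @export
windowFst <- function(sites, windowSize = 50000, step = 25000,
                      minSites = 3L) {
  win <- makeWindows(sites, windowSize, step)
  comp <- siteFstComponents(pRefA(sites), pRefB(sites))
  agg <- function(idx) {
    den <- sum(comp$ht[idx])
    if (den > 0) sum(comp$ht[idx] - comp$hs[idx]) / den else 0
  }
  res <- windowApply(sites, win, agg)
  res$stat[res$n < minSites] <- NA_real_
  mcols(win)$nSites <- res$n
  mcols(win)$stat <- res$stat
  mcols(win)$z <- NA_real_
  mcols(win) <- mcols(win)[c("nSites", "stat", "z", "partial")]
  out <- new("WindowStats", win)
  metadata(out) <- list(statName = "FST", windowSize = windowSize,
                        step = step, minSites = minSites)
  out
}

#' Windowed pooled heterozygosity H
#'
#' Within one group, per window: `H = 2*Sp*Sq / (Sp + Sq)^2`, where `Sp` is
#' the sum of the major-allele frequencies of the in-window SNPs and `Sq`
#' the sum of the minor-allele frequencies.  Major/minor is assigned per
#' site within the group (`pmax(p, 1-p)`).  Defaults follow the
#' 20-kb/10-kb convention for this statistic.
#'
#' @param sites a [PooledSites-class] object.
#' @param group `"A"`, `"B"`, or `"pooled"` (mean of the two group
#'   frequencies per site).
#' @param windowSize,step window width and step in bp.
#' @param minSites minimum SNPs for a window to be defined.
#' @return A [WindowStats-class] object with `stat` = H and `z` empty.
#' @export
pooledHeterozygosity <- function(sites, group = c("A", "B", "pooled"),
                                 windowSize = 20000, step = 10000,
                                 minSites = 3L) {
  group <- match.arg(group)
  p <- switch(group, A = pRefA(sites), B = pRefB(sites),
              pooled = (pRefA(sites) + pRefB(sites)) / 2)
  pmaj <- pmax(p, 1 - p)
  pmin_ <- 1 - pmaj
  win <- makeWindows(sites, windowSize, step)
  agg <- function(idx) {
    sp <- sum(pmaj[idx]); sq <- sum(pmin_[idx])
    2 * sp * sq / (sp + sq)^2
  }
  res <- windowApply(sites, win, agg)
  res$stat[res$n < minSites] <- NA_real_
  mcols(win)$nSites <- res$n
  mcols(win)$stat <- res$stat
  mcols(win)$z <- NA_real_
  mcols(win) <- mcols(win)[c("nSites", "stat", "z", "partial")]
  out <- new("WindowStats", win)
  metadata(out) <- list(statName = paste0("H_", group),
                        windowSize = windowSize, step = step,
                        minSites = minSites)
  out
}

#' Absolute Z-standardization of window statistics
#'
#' Fills `z = |stat - mean| / sd` over all windows with a defined
#' statistic, genome-wide; `sd` uses the population (n) denominator.  The
#' absolute value means unusually low as well as unusually high windows get
#' large Z; [callRegions()] restricts to the high side by default.
#'
#' @param windows a [WindowStats-class] object from [windowFst()] or
#'   [pooledHeterozygosity()].
#' @return The same object with `z` filled (`NA` windows stay `NA`).  If
#'   the defined statistics have zero spread, all `z` are set to 0 with a
#'   warning (degenerate scan).
#' @export
zStandardize <- function(windows) {
  x <- windowStat(windows)
  def <- !is.na(x)
  if (sum(def) < 2)
    stop("need at least 2 defined windows to standardize", call. = FALSE)
  mu <- mean(x[def])
  sigma <- sdPop(x[def])
  z <- rep(NA_real_, length(windows))
  if (sigma == 0) {
    warning("all window statistics identical; setting z = 0 (degenerate scan)",
            call. = FALSE)
    z[def] <- 0
  } else {
    z[def] <- abs(x[def] - mu) / sigma
  }
  mcols(windows)$z <- z
  metadata(windows)$mean <- mu
  metadata(windows)$sd <- sigma
  windows
}

#' Call candidate sweep regions from standardized windows
#'
#' Windows are significant when their Z exceeds a fixed threshold
#' (`z > zThreshold`, the classical cut-off being 5) or falls in the top
#' genome-wide quantile (`z >= quantile(z, 1 - topQuantile)`).  Because the
#' standardization is absolute, calling is restricted by default to windows
#' whose raw statistic lies above the genome-wide mean (elevated
#' divergence); set `restrictHigh = FALSE` to keep the low tail too.
#' Significant windows that overlap or abut on one chromosome are merged;
#' each region records its peak Z and member-window count.
#'
#' @param windows a [WindowStats-class] object with `z` filled.
#' @param zThreshold fixed Z cut-off (used when `topQuantile` is `NULL`).
#' @param topQuantile if non-`NULL`, call the top fraction (e.g. `0.05`)
#'   of defined windows instead of using `zThreshold`.
#' @param restrictHigh only call windows with `stat` above the genome-wide
#'   mean.
#' @return A [SweepRegions-class] object (empty when nothing is
#'   significant).
#' @export
callRegions <- function(windows, zThreshold = 5, topQuantile = NULL,
                        restrictHigh = TRUE) {
  z <- zScore(windows)
  if (all(is.na(z)))
    stop("z not filled; run zStandardize() first", call. = FALSE)
  x <- windowStat(windows)
  def <- !is.na(z)
  if (is.null(topQuantile)) {
    sig <- def & z > zThreshold
  } else {
    thr <- stats::quantile(z[def], probs = 1 - topQuantile, names = FALSE)
    sig <- def & z >= thr
  }
  if (restrictHigh) {
    mu <- metadata(windows)$mean
    if (is.null(mu)) mu <- mean(x[def])
    sig <- sig & x > mu
  }
  emptyRegions <- function() {
    gr <- GRanges()
    mcols(gr)$peakZ <- numeric(0)
    mcols(gr)$nWindows <- integer(0)
    mcols(gr)$genes <- CharacterList()
    new("SweepRegions", gr)
  }
  if (!any(sig)) return(emptyRegions())
  sw <- granges(windows[sig])
  merged <- reduce(sw)           # merges overlapping and abutting windows
  hits <- findOverlaps(merged, windows[sig])
  zs <- zScore(windows[sig])
  mcols(merged)$peakZ <- unname(vapply(split(zs[subjectHits(hits)],
                                             queryHits(hits)), max,
                                       numeric(1)))
  mcols(merged)$nWindows <- tabulate(queryHits(hits), nbins = length(merged))
  mcols(merged)$genes <- CharacterList(rep(list(character(0)),
                                           length(merged)))
  new("SweepRegions", merged)
}

#' Annotate sweep regions with overlapping genes
#'
#' A gene is listed for a region iff its interval overlaps the region span
#' by at least 1 bp.
#'
#' @param regions a [SweepRegions-class] object.
#' @param genes a `GRanges` of gene intervals with a `name` metadata
#'   column (see [readGeneIntervals()]).
#' @return `regions` with the `genes` column filled.
#' @export
annotateRegions <- function(regions, genes) {
  if (is.null(mcols(genes)$name))
    stop("genes must carry a 'name' metadata column", call. = FALSE)
  hits <- findOverlaps(regions, genes, minoverlap = 1L)
  lst <- rep(list(character(0)), length(regions))
  if (length(hits)) {
    sp <- split(mcols(genes)$name[subjectHits(hits)], queryHits(hits))
    lst[as.integer(names(sp))] <- lapply(sp, unique)
  }
  mcols(regions)$genes <- CharacterList(lst)
  regions
}

#' Convert window statistics to a plain data.frame
#'
#' @param windows a [WindowStats-class] object.
#' @return data.frame with chrom, start, end, n_sites, stat, z, partial.
#' @export
windowStatsTable <- function(windows) {
  data.frame(chrom = as.character(seqnames(windows)),
             start = start(windows), end = end(windows),
             n_sites = nSites(windows), stat = windowStat(windows),
             z = zScore(windows), partial = mcols(windows)$partial,
             stringsAsFactors = FALSE)
}
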