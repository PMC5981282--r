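## Fixture builders shared across test files.  Everything is generated in
## code; no binary fixtures.

## Minimal VCF 4.2 text.  `records` is a list of lists with chrom, pos,
## ref, alt, gt (character vector, one entry per sample).
makeVcfText <- function(records, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r)
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", ".", ".", "GT", r$gt),
          collapse = "\t"), character(1))
  c(header, body)
}

writeTempVcf <- function(records, samples) {
  path <- tempfile(fileext = ".vcf")
  writeLines(makeVcfText(records, samples), path)
  path
}

## Random biallelic SNP records with occasional missing calls.
randomVcfRecords <- function(n, samples, seed) {
  set.seed(seed)
  pos <- sort(sample.int(1e6, n))
  gts <- c("0/0", "0/1", "1/0", "1/1", "./.", "0|0", "0|1", "1|1")
  lapply(seq_len(n), function(i) {
    ra <- sample(c("A", "C", "G", "T"), 2)
    list(chrom = "1", pos = pos[i], ref = ra[1], alt = ra[2],
         gt = sample(gts, length(samples), replace = TRUE))
  })
}

## Direct construction of a WindowStats object with given raw statistics.
makeWindowStats <- function(stat, chrom = "chr1", windowSize = 100,
                            step = 100) {
  n <- length(stat)
  starts <- seq(1, by = step, length.out = n)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(starts,
                                                starts + windowSize - 1))
  S4Vectors::mcols(gr)$nSites <- rep(5L, n)
  S4Vectors::mcols(gr)$stat <- stat
  S4Vectors::mcols(gr)$z <- NA_real_
  S4Vectors::mcols(gr)$partial <- rep(FALSE, n)
  methods::new("WindowStats", gr)
}

## Direct construction of a SweepRegions object.
makeRegions <- function(chrom, start, end, peakZ) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  S4Vectors::mcols(gr)$peakZ <- peakZ
  S4Vectors::mcols(gr)$nWindows <- rep(1L, length(gr))
  S4Vectors::mcols(gr)$genes <-
    IRanges::CharacterList(rep(list(character(0)), length(gr)))
  methods::new("SweepRegions", gr)
}

## Small helper: the printed genotype-count fixture shipped with the
## package (the counts a candidate-gene study reports).
table3Path <- function() {
  system.file("extdata", "table3_genotype_counts.tsv", package = "ovisweep")
}

table3Row <- function(breed, locus) {
  df <- readGenotypeTable(table3Path())
  df[df$breed == breed & df$locus == locus, ]
}

## Brute-force windowed-FST oracle: re-filters sites by interval
## membership and recomputes the ratio of sums per window, independently
## of the package's findOverlaps path.
bruteWindowFst <- function(pos, pA, pB, chromLength, windowSize, step,
                           minSites) {
  starts <- seq(1, chromLength, by = step)
  ends <- pmin(starts + windowSize - 1, chromLength)
  vapply(seq_along(starts), function(k) {
    idx <- which(pos >= starts[k] & pos <= ends[k])
    if (length(idx) < minSites) return(NA_real_)
    pbar <- (pA[idx] + pB[idx]) / 2
    ht <- 2 * pbar * (1 - pbar)
    hs <- (2 * pA[idx] * (1 - pA[idx]) + 2 * pB[idx] * (1 - pB[idx])) / 2
    den <- sum(ht)
    if (den > 0) sum(ht - hs) / den else 0
  }, numeric(1))
}
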