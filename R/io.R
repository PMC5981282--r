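## Readers and writers for the formats the pipeline touches: VCF in (via
## VariantAnnotation), site-frequency / genotype / phenotype / Ct TSVs with
## strict schema validation, BED6 out for called regions, BED/GFF in for
## gene intervals (via rtracklayer).  Internal coordinates are 1-based
## inclusive throughout; only BED output converts to 0-based half-open.

#' Read pooled reference-allele frequencies from a VCF
#'
#' Reads a VCF, keeps biallelic SNP records only, and computes the
#' reference-allele frequency of each of two breed groups from the called
#' genotypes of the named samples.  Missing genotype calls (`./.`) are
#' excluded from the allele totals, never imputed.  Multiallelic and indel
#' records are skipped and counted, as are sites with fewer than two called
#' alleles in either group; the counts are available as
#' `metadata(x)$skipped`.
#'
#' @param path path to a VCF (4.x) file.
#' @param groupA,groupB sample names per group.  Either plain character
#'   vectors (`aggregate = "pool"`: alleles of all samples in the group are
#'   pooled) or named lists of character vectors, one element per breed
#'   (`aggregate = "breed-mean"`: the group frequency is the unweighted mean
#'   of per-breed frequencies, for designs where breeds were pooled before
#'   calling).
#' @param aggregate how to combine samples into a group frequency.
#' @return A [PooledSites-class] object with `metadata(x)$skipped`, a named
#'   count of skipped records (`multiallelic`, `indel`, `lowCall`).
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c(
#'   "##fileformat=VCFv4.2",
#'   "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
#'   paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
#'         "FORMAT", "s1", "s2", "s3", sep = "\t"),
#'   paste("17", "100", ".", "G", "A", ".", ".", ".", "GT",
#'         "0/0", "0/1", "1/1", sep = "\t")), vcf)
#' ps <- readPooledVcf(vcf, groupA = c("s1", "s2"), groupB = "s3")
#' pRefA(ps)  # 0.75
#' @export
readPooledVcf <- function(path, groupA, groupB,
                          aggregate = c("pool", "breed-mean")) {
  aggregate <- match.arg(aggregate)
  asBreeds <- function(g, label) {
    if (is.list(g)) g else setNames(list(g), label)
  }
  breedsA <- asBreeds(groupA, "groupA")
  breedsB <- asBreeds(groupB, "groupB")
  allSamples <- unlist(c(breedsA, breedsB), use.names = FALSE)

  vcf <- VariantAnnotation::readVcf(path)
  have <- colnames(vcf)
  missing <- setdiff(allSamples, have)
  if (length(missing))
    stop("sample(s) not present in VCF: ", paste(missing, collapse = ", "),
         call. = FALSE)

  rr <- SummarizedExperiment::rowRanges(vcf)
  ## sortedness: chromosomes in contiguous blocks, positions non-decreasing
  chr <- as.character(seqnames(rr))
  if (length(rr)) {
    blocks <- rle(chr)$values
    if (anyDuplicated(blocks))
      stop("unsorted VCF: chromosome blocks are not contiguous", call. = FALSE)
    if (any(tapply(start(rr), factor(chr, levels = unique(chr)), is.unsorted)))
      stop("unsorted VCF: positions not sorted within a chromosome",
           call. = FALSE)
  }

  ref <- VariantAnnotation::ref(vcf)
  alt <- VariantAnnotation::alt(vcf)
  nAlt <- lengths(alt)
  multi <- nAlt > 1L
  altChar <- rep(NA_character_, length(vcf))
  altChar[nAlt == 1L] <- as.character(unlist(alt[nAlt == 1L]))
  isSnp <- !multi & width(ref) == 1L & !is.na(altChar) &
    nchar(altChar) == 1L & altChar %in% c("A", "C", "G", "T")
  indel <- !multi & !isSnp

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field", call. = FALSE)

  countAlleles <- function(gtcol) {
    ## per record: number of called REF alleles and total called alleles
    toks <- strsplit(gsub("|", "/", gtcol, fixed = TRUE), "/", fixed = TRUE)
    nref <- vapply(toks, function(a) sum(a == "0"), integer(1))
    ncall <- vapply(toks, function(a) sum(a != "." & nzchar(a)), integer(1))
    cbind(nref, ncall)
  }

  groupFreq <- function(breeds) {
    perBreed <- lapply(breeds, function(samps) {
      nref <- ncall <- numeric(nrow(gt))
      for (s in samps) {
        cc <- countAlleles(gt[, s])
        nref <- nref + cc[, 1]
        ncall <- ncall + cc[, 2]
      }
      list(nref = nref, ncall = ncall)
    })
    ncallTot <- Reduce(`+`, lapply(perBreed, `[[`, "ncall"))
    if (aggregate == "pool") {
      nrefTot <- Reduce(`+`, lapply(perBreed, `[[`, "nref"))
      p <- ifelse(ncallTot > 0, nrefTot / ncallTot, NA_real_)
    } else {
      fmat <- vapply(perBreed, function(b)
        ifelse(b$ncall > 0, b$nref / b$ncall, NA_real_),
        numeric(nrow(gt)))
      fmat <- matrix(fmat, nrow = nrow(gt))
      p <- rowMeans(fmat, na.rm = TRUE)
      p[!is.finite(p)] <- NA_real_
    }
    list(p = p, ncall = ncallTot)
  }

  fa <- groupFreq(breedsA)
  fb <- groupFreq(breedsB)
  lowCall <- isSnp & (fa$ncall < 2 | fb$ncall < 2 | is.na(fa$p) | is.na(fb$p))
  keep <- isSnp & !lowCall

  skipped <- c(multiallelic = sum(multi), indel = sum(indel),
               lowCall = sum(lowCall))
  out <- PooledSites(chrom = chr[keep], pos = start(rr)[keep],
                     pRefA = fa$p[keep], pRefB = fb$p[keep],
                     nAllelesA = fa$ncall[keep], nAllelesB = fb$ncall[keep])
  metadata(out)$skipped <- skipped
  out
}

#' Read / write pooled site frequencies as TSV
#'
#' Plain-text alternative to VCF input: a tab-separated table with columns
#' `chrom`, `pos`, `p_ref_A`, `p_ref_B`, `n_alleles_A`, `n_alleles_B`.
#'
#' @param path file path.
#' @return `readSiteFrequencies()` returns a [PooledSites-class] object;
#'   `writeSiteFrequencies()` returns `path` invisibly.
#' @export
readSiteFrequencies <- function(path) {
  df <- readTsv(path, required = c("chrom", "pos", "p_ref_A", "p_ref_B",
                                   "n_alleles_A", "n_alleles_B"))
  PooledSites(chrom = as.character(df$chrom), pos = as.integer(df$pos),
              pRefA = df$p_ref_A, pRefB = df$p_ref_B,
              nAllelesA = df$n_alleles_A, nAllelesB = df$n_alleles_B)
}

#' @rdname readSiteFrequencies
#' @param sites a [PooledSites-class] object.
#' @export
writeSiteFrequencies <- function(sites, path) {
  df <- data.frame(chrom = as.character(seqnames(sites)),
                   pos = start(sites),
                   p_ref_A = pRefA(sites), p_ref_B = pRefB(sites),
                   n_alleles_A = mcols(sites)$nAllelesA,
                   n_alleles_B = mcols(sites)$nAllelesB)
  writeTsv(df, path)
}

#' Read / write a marker genotype-count table
#'
#' Tab-separated table with header `breed`, `locus`, `n_AA`, `n_Aa`, `n_aa`
#' giving per-breed counts of reference homozygotes, heterozygotes and
#' alternate homozygotes at each locus.  Counts must be non-negative
#' integers and each row must genotype at least one individual.
#'
#' @param path file path.
#' @return `readGenotypeTable()` returns a data.frame with the five columns
#'   above (counts as integers).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("breed\tlocus\tn_AA\tn_Aa\tn_aa",
#'              "SmallTailHan\tg.71874104G>A\t42\t167\t166"), tf)
#' readGenotypeTable(tf)
#' @export
readGenotypeTable <- function(path) {
  df <- readTsv(path, required = c("breed", "locus", "n_AA", "n_Aa", "n_aa"))
  for (col in c("n_AA", "n_Aa", "n_aa")) {
    v <- df[[col]]
    bad <- which(is.na(v) | !is.numeric(v) | v < 0 | v != round(v))
    if (length(bad))
      stop("invalid count in column ", col, ", row ", bad[1],
           ": counts must be non-negative integers", call. = FALSE)
    df[[col]] <- as.integer(v)
  }
  empty <- which(df$n_AA + df$n_Aa + df$n_aa < 1)
  if (length(empty))
    stop("row ", empty[1], ": no genotyped individuals", call. = FALSE)
  df$breed <- as.character(df$breed)
  df$locus <- as.character(df$locus)
  df[c("breed", "locus", "n_AA", "n_Aa", "n_aa")]
}

#' @rdname readGenotypeTable
#' @param df a data.frame as returned by `readGenotypeTable()`.
#' @export
writeGenotypeTable <- function(df, path) {
  writeTsv(df[c("breed", "locus", "n_AA", "n_Aa", "n_aa")], path)
}

#' Write called sweep regions as BED6
#'
#' Converts 1-based inclusive region spans to BED's 0-based half-open
#' convention.  The score column carries the region's peak Z value
#' formatted to two decimals.
#'
#' @param regions a [SweepRegions-class] object (non-overlapping).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
  if (length(regions) && !isDisjoint(regions))
    stop("regions overlap after merging; upstream merging contract violated",
         call. = FALSE)
  if (!length(regions)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.",
                   as.character(seqnames(regions)),
                   start(regions) - 1L, end(regions),
                   sprintf("region_%d", seq_along(regions)),
                   sprintf("%.2f", peakZ(regions)))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene intervals from BED or GFF
#'
#' Thin wrapper over [rtracklayer::import()] that returns a `GRanges` with a
#' `name` metadata column holding the gene symbol (taken from the BED name
#' column, or from `gene_name`/`Name`/`gene_id` attributes for GFF).
#'
#' @param path a BED or GFF/GTF file.
#' @return A `GRanges` of gene intervals with a `name` column.
#' @export
readGeneIntervals <- function(path) {
  gr <- rtracklayer::import(path)
  nm <- mcols(gr)$name
  if (is.null(nm)) nm <- mcols(gr)$gene_name
  if (is.null(nm)) nm <- mcols(gr)$Name
  if (is.null(nm)) nm <- mcols(gr)$gene_id
  if (is.null(nm)) nm <- rep(NA_character_, length(gr))
  mcols(gr) <- DataFrame(name = as.character(nm))
  gr
}

#' Read / write per-ewe litter-size phenotype records
#'
#' Tab-separated table with header `ewe_id`, `parity`, `genotype`,
#' `litter_size`.  Litter sizes must be positive; values below one lamb
#' trigger a warning (they can arise in Gaussian-simulated data but not in
#' real records).
#'
#' @param path file path.
#' @return `readPhenotypeTable()` returns a data.frame with the four
#'   columns above.
#' @export
readPhenotypeTable <- function(path) {
  df <- readTsv(path, required = c("ewe_id", "parity", "genotype",
                                   "litter_size"))
  df$litter_size <- as.numeric(df$litter_size)
  if (anyNA(df$litter_size))
    stop("litter_size must be numeric and non-missing", call. = FALSE)
  if (any(df$litter_size < 1))
    warning("litter_size values below 1 lamb present; real records are ",
            ">= 1 (Gaussian-simulated data can fall below)", call. = FALSE)
  df
}

#' @rdname readPhenotypeTable
#' @param df a phenotype data.frame.
#' @export
writePhenotypeTable <- function(df, path) {
  writeTsv(df[c("ewe_id", "parity", "genotype", "litter_size")], path)
}

#' Read / write a qPCR Ct table
#'
#' Tab-separated table with header `tissue`, `group`, `replicate`,
#' `ct_target`, `ct_reference`; Ct values must be positive and finite.
#'
#' @param path file path.
#' @return `readCtTable()` returns a data.frame with the five columns above.
#' @export
readCtTable <- function(path) {
  df <- readTsv(path, required = c("tissue", "group", "replicate",
                                   "ct_target", "ct_reference"))
  for (col in c("ct_target", "ct_reference")) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]]) || any(!is.finite(df[[col]]) | df[[col]] <= 0))
      stop(col, " must be positive and finite", call. = FALSE)
  }
  df
}

#' @rdname readCtTable
#' @param df a Ct data.frame.
#' @export
writeCtTable <- function(df, path) {
  writeTsv(df[c("tissue", "group", "replicate", "ct_target",
                "ct_reference")], path)
}
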