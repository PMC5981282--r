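## Litter-size association: OLS fit of y = mu + parity + genotype +
## parity:genotype under the cell-means parameterization, least-squares
## means with pooled-MSE standard errors, and LSD pairwise letters.

#' Fit the parity x genotype litter-size model
#'
#' Ordinary least squares on the full cell-means parameterization (one
#' coefficient per non-empty parity x genotype cell), equivalent to the
#' fixed-effects model with mean, parity, genotype and interaction terms
#' under estimable contrasts.  Records are treated as independent (the
#' model carries no ewe random effect).
#'
#' @param records data.frame with columns `ewe_id`, `parity`, `genotype`,
#'   `litter_size` (see [readPhenotypeTable()], [simulateLitterSizes()]).
#' @param parityLevels,genotypeLevels optional explicit factor levels;
#'   default: sorted unique values present.
#' @return A [LitterModelFit-class] object.  Empty cells are allowed and
#'   recorded; zero residual degrees of freedom is an error.
#' @export
fitLitterModel <- function(records, parityLevels = NULL,
                           genotypeLevels = NULL) {
  need <- c("parity", "genotype", "litter_size")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(parityLevels))
    parityLevels <- sort(unique(as.character(records$parity)))
  if (is.null(genotypeLevels))
    genotypeLevels <- sort(unique(as.character(records$genotype)))
  par <- factor(as.character(records$parity), levels = parityLevels)
  gen <- factor(as.character(records$genotype), levels = genotypeLevels)
  if (anyNA(par) || anyNA(gen))
    stop("parity/genotype value outside declared levels", call. = FALSE)
  y <- records$litter_size
  cell <- interaction(par, gen, sep = ":", drop = TRUE)
  if (nlevels(cell) < 2) stop("need at least 2 non-empty cells", call. = FALSE)
  fit <- lm(y ~ 0 + cell)
  nTot <- length(y)
  k <- nlevels(cell)
  dfRes <- nTot - k
  if (dfRes <= 0)
    stop("zero residual degrees of freedom: more cells than spare records",
         call. = FALSE)
  mse <- sum(residuals(fit)^2) / dfRes
  grid <- expand.grid(parity = parityLevels, genotype = genotypeLevels,
                      stringsAsFactors = FALSE)
  key <- paste(par, gen, sep = ":")
  grid$n <- as.integer(table(factor(key, levels = paste(grid$parity,
                                                        grid$genotype,
                                                        sep = ":"))))
  cm <- coef(fit)
  names(cm) <- sub("^cell", "", names(cm))
  grid$mean <- unname(cm[paste(grid$parity, grid$genotype, sep = ":")])
  new("LitterModelFit", model = fit, cells = grid, mse = mse,
      dfResidual = dfRes, parityLevels = parityLevels,
      genotypeLevels = genotypeLevels)
}

#' Least-squares means of litter size
#'
#' `scope = "per-parity"`: the LS mean of each non-empty parity x genotype
#' cell is its cell mean, with `SE = sqrt(MSE / n_ij)` from the pooled
#' residual mean square.  `scope = "genotype-average"`: the equally
#' weighted mean of a genotype's per-parity cell means, with
#' `SE = sqrt(MSE * sum(1 / n_ij)) / k` over the `k` contributing cells
#' (`k = 3` when no cell is empty; empty cells are dropped with a warning
#' and the average flagged).
#'
#' @param fit a [LitterModelFit-class] object.
#' @param scope which marginal means to report.
#' @return data.frame with columns `parity` (or `"average"`), `genotype`,
#'   `estimate`, `se`, `n`, `flagged`; the cell-weight matrix used for each
#'   estimate is attached as `attr(x, "weights")` (rows = estimates,
#'   columns = cells) for downstream pairwise tests.
#' @export
lsMeans <- function(fit, scope = c("per-parity", "genotype-average")) {
  scope <- match.arg(scope)
  stopifnot(is(fit, "LitterModelFit"))
  cells <- fit@cells
  filled <- cells$n > 0
  cellKey <- paste(cells$parity, cells$genotype, sep = ":")
  if (scope == "per-parity") {
    sel <- which(filled)
    W <- matrix(0, length(sel), nrow(cells),
                dimnames = list(NULL, cellKey))
    for (r in seq_along(sel)) W[r, sel[r]] <- 1
    out <- data.frame(parity = cells$parity[sel],
                      genotype = cells$genotype[sel],
                      estimate = cells$mean[sel],
                      se = sqrt(fit@mse / cells$n[sel]),
                      n = cells$n[sel], flagged = FALSE,
                      stringsAsFactors = FALSE)
  } else {
    gts <- fit@genotypeLevels
    W <- matrix(0, length(gts), nrow(cells),
                dimnames = list(gts, cellKey))
    out <- data.frame(parity = "average", genotype = gts,
                      estimate = NA_real_, se = NA_real_, n = NA_integer_,
                      flagged = FALSE, stringsAsFactors = FALSE)
    for (r in seq_along(gts)) {
      idx <- which(cells$genotype == gts[r] & filled)
      if (!length(idx)) stop("genotype ", gts[r], " has no records",
                             call. = FALSE)
      if (length(idx) < length(fit@parityLevels)) {
        warning("genotype ", gts[r],
                " has empty parity cells; average over non-empty cells",
                call. = FALSE)
        out$flagged[r] <- TRUE
      }
      k <- length(idx)
      W[r, idx] <- 1 / k
      out$estimate[r] <- mean(cells$mean[idx])
      out$se[r] <- sqrt(fit@mse * sum(1 / cells$n[idx])) / k
      out$n[r] <- sum(cells$n[idx])
    }
  }
  attr(out, "weights") <- W
  attr(out, "cellN") <- setNames(cells$n, cellKey)
  out
}

#' LSD pairwise comparisons and significance letters
#'
#' For each group of LS means (the genotypes within one parity, or the
#' genotype averages), all pairwise differences are tested with
#' `t = (m1 - m2) / SE(diff)`, where the difference SE comes from the
#' pooled MSE and the cell weights of each LS mean, against the residual-df
#' t distribution, two-sided, with no multiplicity adjustment (the least
#' significant difference procedure).  Letters are assigned by
#' insert-and-absorb so that two levels share a letter iff their pairwise
#' p-value is >= `alpha`.
#'
#' @param lsm an [lsMeans()] table (with its weight attributes).
#' @param fit the [LitterModelFit-class] the table came from.
#' @param alpha significance level.
#' @return `lsm` with a `letters` column added; pairwise p-values are
#'   attached as `attr(x, "pairwise")` (a list of matrices per group).
#' @export
lsdLetters <- function(lsm, fit, alpha = 0.05) {
  stopifnot(is(fit, "LitterModelFit"))
  W <- attr(lsm, "weights")
  cellN <- attr(lsm, "cellN")
  if (is.null(W) || is.null(cellN))
    stop("lsm must come from lsMeans() (weight attributes missing)",
         call. = FALSE)
  lsm$letters <- NA_character_
  pairwiseAll <- list()
  for (grp in unique(lsm$parity)) {
    rows <- which(lsm$parity == grp)
    k <- length(rows)
    if (k < 2) { lsm$letters[rows] <- "a"; next }
    pmat <- matrix(NA_real_, k, k,
                   dimnames = list(lsm$genotype[rows], lsm$genotype[rows]))
    for (a in seq_len(k - 1)) {
      for (b in seq(a + 1, k)) {
        dw <- W[rows[a], ] - W[rows[b], ]
        use <- dw != 0
        vd <- fit@mse * sum(dw[use]^2 / cellN[use])
        tstat <- (lsm$estimate[rows[a]] - lsm$estimate[rows[b]]) / sqrt(vd)
        ## zero-variance (degenerate) fits are not testable: NA, never split
        p <- if (!is.finite(tstat)) NA_real_ else
          2 * pt(-abs(tstat), df = fit@dfResidual)
        pmat[a, b] <- pmat[b, a] <- p
      }
    }
    lsm$letters[rows] <- assignLetters(lsm$estimate[rows], pmat, alpha)
    pairwiseAll[[as.character(grp)]] <- pmat
  }
  attr(lsm, "pairwise") <- pairwiseAll
  lsm
}

#' Table of LS means with letters, one row per genotype
#'
#' Convenience wrapper running [fitLitterModel()], [lsMeans()] at both
#' scopes and [lsdLetters()], then arranging the result in the layout
#' association studies print: one row per genotype, one column block per
#' parity plus the three-parity average, each as `estimate +/- se (n)`
#' with its letter.
#'
#' @param records phenotype data.frame.
#' @param alpha LSD significance level.
#' @return list with elements `fit`, `perParity`, `average` (letter-annotated
#'   [lsMeans()] tables) and `formatted` (a character data.frame).
#' @export
associationTable <- function(records, alpha = 0.05) {
  fit <- fitLitterModel(records)
  pp <- lsdLetters(lsMeans(fit, "per-parity"), fit, alpha)
  av <- lsdLetters(lsMeans(fit, "genotype-average"), fit, alpha)
  fmt <- function(df) {
    ## omit letters in a column where no pair separates (all share "a")
    shown <- stats::ave(df$letters, df$parity,
                        FUN = function(l) if (length(unique(l)) == 1)
                          rep("", length(l)) else l)
    trimws(sprintf("%.2f +/- %.2f%s (%d)", df$estimate, df$se,
                   ifelse(shown == "", "", paste0(" ", shown)), df$n))
  }
  wide <- data.frame(genotype = fit@genotypeLevels,
                     stringsAsFactors = FALSE)
  for (p in fit@parityLevels) {
    sub <- pp[pp$parity == p, ]
    wide[[paste0("parity_", p)]] <-
      fmt(sub)[match(wide$genotype, sub$genotype)]
  }
  wide$average <- fmt(av)[match(wide$genotype, av$genotype)]
  list(fit = fit, perParity = pp, average = av, formatted = wide)
}
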