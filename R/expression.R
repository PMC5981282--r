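## Relative expression by 2^-ddCt and per-tissue group comparison with
## significance letters (lowercase at the nominal level, uppercase at the
## stringent level), mirroring how qPCR panels are reported.

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = ct_target - ct_reference` (normalization to the
#' reference gene); `ddCt = dCt - mean(dCt)` of the calibrator cell; and
#' `rel_expr = 2^-ddCt`.  By default the calibrator is a *group*, applied
#' within each tissue (so each tissue's fold changes are relative to that
#' tissue's calibrator group); a single global `(tissue, group)` calibrator
#' cell is also supported.
#'
#' @param records Ct data.frame with columns `tissue`, `group`,
#'   `replicate`, `ct_target`, `ct_reference` (see [readCtTable()],
#'   [simulateCtTable()]).
#' @param calibratorGroup group name used as per-tissue calibrator;
#'   default: the first group level in sorted order.  Ignored when
#'   `calibrator` is given.
#' @param calibrator optional `c(tissue, group)` pair naming one global
#'   calibrator cell.
#' @return `records` with columns `delta_ct`, `ddct`, `rel_expr` added.
#'   The calibrator cell's mean `ddct` is 0 by construction, so its mean
#'   fold change on the log2 scale is exactly 1.
#' @examples
#' ct <- simulateCtTable(tissues = "ovary", sd = 0.1, seed = 3)
#' relativeExpression(ct, calibratorGroup = "low_fecundity")
#' @export
relativeExpression <- function(records, calibratorGroup = NULL,
                               calibrator = NULL) {
  need <- c("tissue", "group", "ct_target", "ct_reference")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  records$delta_ct <- records$ct_target - records$ct_reference
  if (!is.null(calibrator)) {
    stopifnot(length(calibrator) == 2)
    sel <- records$tissue == calibrator[1] & records$group == calibrator[2]
    if (!any(sel))
      stop("calibrator cell not found: tissue=", calibrator[1],
           " group=", calibrator[2], call. = FALSE)
    records$ddct <- records$delta_ct - mean(records$delta_ct[sel])
  } else {
    if (is.null(calibratorGroup))
      calibratorGroup <- sort(unique(records$group))[1]
    if (!calibratorGroup %in% records$group)
      stop("calibrator group not found: ", calibratorGroup, call. = FALSE)
    records$ddct <- NA_real_
    for (ti in unique(records$tissue)) {
      inTissue <- records$tissue == ti
      cal <- inTissue & records$group == calibratorGroup
      if (!any(cal))
        stop("calibrator cell not found: tissue=", ti, " group=",
             calibratorGroup, call. = FALSE)
      records$ddct[inTissue] <- records$delta_ct[inTissue] -
        mean(records$delta_ct[cal])
    }
  }
  records$rel_expr <- 2^(-records$ddct)
  records
}

#' Per-tissue group comparison of relative expression
#'
#' Within each tissue, all group pairs are compared with two-sided pooled
#' (equal-variance) t-tests, by default on the `delta_ct` scale (Ct values
#' are log2-scale, where Gaussian errors are the natural assumption);
#' testing directly on `rel_expr` is available.  Letters are assigned per
#' alpha level with the same insert-and-absorb rule as the association
#' module: lowercase letters separate at `alphaLevels[1]`, uppercase at
#' `alphaLevels[2]`.  Tissues where any group has fewer than two
#' replicates are flagged untestable (`NA` letters).
#'
#' @param rel output of [relativeExpression()].
#' @param alphaLevels two significance levels, nominal then stringent.
#' @param on scale to test on.
#' @return data.frame with one row per tissue x group: `tissue`, `group`,
#'   `n`, `mean_fold` (geometric-style mean `2^-mean(ddct)`),
#'   `letters` (at `alphaLevels[1]`), `LETTERS` (at `alphaLevels[2]`),
#'   `testable`; per-tissue pairwise p-value matrices are attached as
#'   `attr(x, "pairwise")`.
#' @export
compareExpression <- function(rel, alphaLevels = c(0.05, 0.01),
                              on = c("delta_ct", "rel_expr")) {
  on <- match.arg(on)
  stopifnot(length(alphaLevels) == 2, "ddct" %in% names(rel))
  out <- list()
  pairwiseAll <- list()
  for (ti in unique(rel$tissue)) {
    sub <- rel[rel$tissue == ti, ]
    grps <- sort(unique(sub$group))
    ns <- vapply(grps, function(g) sum(sub$group == g), integer(1))
    res <- data.frame(tissue = ti, group = grps, n = ns,
                      mean_fold = vapply(grps, function(g)
                        2^(-mean(sub$ddct[sub$group == g])), numeric(1)),
                      letters = NA_character_, LETTERS = NA_character_,
                      testable = all(ns >= 2) && length(grps) >= 2,
                      stringsAsFactors = FALSE)
    if (res$testable[1]) {
      v <- if (on == "delta_ct") sub$delta_ct else sub$rel_expr
      k <- length(grps)
      pmat <- matrix(NA_real_, k, k, dimnames = list(grps, grps))
      for (a in seq_len(k - 1)) {
        for (b in seq(a + 1, k)) {
          xa <- v[sub$group == grps[a]]
          xb <- v[sub$group == grps[b]]
          p <- stats::t.test(xa, xb, var.equal = TRUE)$p.value
          pmat[a, b] <- pmat[b, a] <- p
        }
      }
      ## order by expression so the most-expressed group letters first
      m <- res$mean_fold
      res$letters <- assignLetters(m, pmat, alphaLevels[1], letters)
      res$LETTERS <- assignLetters(m, pmat, alphaLevels[2], LETTERS)
      pairwiseAll[[ti]] <- pmat
    }
    out[[ti]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "pairwise") <- pairwiseAll
  out
}
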