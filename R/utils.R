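## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards so simulations are pure in (config,
## seed) and do not disturb the session stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## Deterministic fan-out of one global seed into per-operation child seeds;
## kept below 2^31 - 1 so the result is always a valid integer seed.
childSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index) %% 2147483647)
}

#' Round half away from zero
#'
#' Rounding convention used by the printed marker tables this package
#' reproduces (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return `x` rounded with ties going away from zero.
#' @examples
#' round2(0.125, 2)  # 0.13, where round() gives 0.12
#' @export
round2 <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Population (n-denominator) standard deviation.
sdPop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

readTsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("missing required column(s) in ", path, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

## Significance-letter assignment by insert-and-absorb: start from one
## letter covering all levels; every significant pair splits each letter
## column containing both; subset columns are then absorbed.  Guarantees
## that two levels share a letter iff their pairwise test is
## non-significant.  `pmat` is a symmetric matrix of pairwise p-values.
assignLetters <- function(means, pmat, alpha, alphabet = letters) {
  k <- length(means)
  if (k == 1L) return("a")
  ord <- order(means, decreasing = TRUE)
  cols <- list(seq_len(k))
  for (a in seq_len(k - 1L)) {
    for (b in seq((a + 1L), k)) {
      i <- ord[a]; j <- ord[b]
      if (!is.na(pmat[i, j]) && pmat[i, j] < alpha) {
        hit <- which(vapply(cols, function(cc) i %in% cc && j %in% cc,
                            logical(1)))
        for (h in hit) {
          cc <- cols[[h]]
          cols[[h]] <- setdiff(cc, i)
          cols[[length(cols) + 1L]] <- setdiff(cc, j)
        }
        ## absorb columns wholly contained in another
        keep <- rep(TRUE, length(cols))
        for (u in seq_along(cols)) {
          for (v in seq_along(cols)) {
            if (u != v && keep[u] && keep[v] &&
                all(cols[[u]] %in% cols[[v]]))
              keep[u] <- FALSE
          }
        }
        cols <- cols[keep]
      }
    }
  }
  ## order columns by the rank of their best member so the top mean gets "a"
  rank_of <- match(seq_len(k), ord)
  colrank <- vapply(cols, function(cc) min(rank_of[cc]), numeric(1))
  cols <- cols[order(colrank)]
  out <- vapply(seq_len(k), function(i) {
    paste(alphabet[which(vapply(cols, function(cc) i %in% cc, logical(1)))],
          collapse = "")
  }, character(1))
  out
}
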