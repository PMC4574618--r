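## compact letter display by insert-and-absorb: start from one column
## containing every group; for each significantly different pair split any
## column containing both; absorb columns that are subsets of another.
.letterDisplay <- function(groups, sigPairs) {
  cols <- list(groups)
  for (k in seq_len(nrow(sigPairs))) {
    g1 <- sigPairs$a[k]; g2 <- sigPairs$b[k]
    newCols <- list()
    for (col in cols) {
      if (g1 %in% col && g2 %in% col) {
        newCols <- c(newCols, list(setdiff(col, g1)), list(setdiff(col, g2)))
      } else newCols <- c(newCols, list(col))
    }
    ## absorb subset/duplicate columns
    keep <- rep(TRUE, length(newCols))
    for (i in seq_along(newCols)) for (j in seq_along(newCols)) {
      if (i == j || !keep[i] || !keep[j]) next
      if (all(newCols[[i]] %in% newCols[[j]]) &&
          (length(newCols[[i]]) < length(newCols[[j]]) || i > j))
        keep[i] <- FALSE
    }
    cols <- newCols[keep]
  }
  letters_ <- letters[seq_along(cols)]
  out <- vapply(groups, function(g) {
    paste(letters_[vapply(cols, function(col) g %in% col, logical(1))],
          collapse = "")
  }, character(1))
  names(out) <- groups
  out
}

#' One-way ANOVA with Fisher's LSD and a compact letter display
#'
#' The replication units are the per-chromosome values of each comparison.
#' Proportions (0-1 data) can be arcsine-square-root transformed before the
#' analysis; reported means are on the original scale.  Pairwise means are
#' compared with the unprotected least-significant-difference t-test at
#' `alpha` using the pooled ANOVA error; groups sharing a letter do not
#' differ significantly.
#'
#' @param groups named list of numeric vectors (one per comparison), each
#'   of length >= 2.
#' @param transform `"none"` or `"arcsine"` (arcsin of the square root,
#'   for data in 0-1).
#' @param alpha significance level (default 0.05).
#' @return list: `means` (original scale), `letters`, `anova_p`, `lsd`
#'   (data.frame of pairwise decisions), `alpha`, `transform`.
#' @export
anovaLsd <- function(groups, transform = c("none", "arcsine"),
                     alpha = 0.05) {
  transform <- match.arg(transform)
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  if (transform == "arcsine") {
    if (any(y < 0 | y > 1))
      stop("arcsine transform requires values in [0, 1]")
    yt <- asin(sqrt(y))
  } else yt <- y
  fit <- stats::aov(yt ~ g)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  pAnova <- an[1, "Pr(>F)"]
  mt <- tapply(yt, g, mean)
  ns <- tapply(yt, g, length)
  nm <- names(groups)
  pairsIdx <- utils::combn(nm, 2)
  lsd <- data.frame(a = pairsIdx[1, ], b = pairsIdx[2, ],
                    stringsAsFactors = FALSE)
  lsd$t <- abs(mt[lsd$a] - mt[lsd$b]) /
    sqrt(mse * (1 / ns[lsd$a] + 1 / ns[lsd$b]))
  lsd$p <- 2 * stats::pt(lsd$t, dfe, lower.tail = FALSE)
  lsd$significant <- lsd$p < alpha
  ltr <- .letterDisplay(nm, lsd[lsd$significant, c("a", "b"), drop = FALSE])
  list(means = vapply(groups, mean, numeric(1)),
       letters = ltr, anova_p = pAnova, lsd = lsd, alpha = alpha,
       transform = transform)
}

#' Chi-square test for marker segregation distortion
#'
#' One-degree-of-freedom goodness-of-fit test (no continuity correction)
#' of two observed genotype counts against an expected ratio; a marker is
#' distorted when p < alpha (default 0.01).
#'
#' @param countA,countB observed counts of the two genotype classes.
#' @param expectedRatio numeric length-2 expected ratio (default 1:1).
#' @param alpha distortion threshold (default 0.01).
#' @return list(`chi2`, `p`, `distorted`).
#' @export
chiSquareSegregation <- function(countA, countB, expectedRatio = c(1, 1),
                                 alpha = 0.01) {
  n <- countA + countB
  if (n <= 0 || countA < 0 || countB < 0)
    stop("counts must be non-negative with a positive total")
  e <- n * expectedRatio / sum(expectedRatio)
  chi2 <- sum((c(countA, countB) - e)^2 / e)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p, distorted = p < alpha)
}

#' Genetic-map gap and autozygosity report
#'
#' Gaps are distances between adjacent mapped markers on each linkage
#' group; gaps exceeding `thresholdCm` are collected, totalled and
#' expressed as a percentage of the total map length.  A comparison map's
#' gaps can be rescaled (divided by `scaleFactor`) before thresholding to
#' correct for different overall linkage-group lengths.
#'
#' @param positionsByLg named list of numeric cM positions per linkage
#'   group (sorted internally, with a warning when unsorted).
#' @param thresholdCm gap threshold in cM.
#' @param totalMapCm total map length for the percentage.
#' @param scaleFactor divisor applied to each gap before thresholding
#'   (default 1).
#' @return list: `gaps` (data.frame lg, lo_cm, hi_cm, length_cm sorted
#'   descending), `n_gaps_over`, `total_gap_cm`, `pct_of_map`.
#' @export
mapGapAnalysis <- function(positionsByLg, thresholdCm, totalMapCm,
                           scaleFactor = 1) {
  rows <- list()
  for (lg in names(positionsByLg)) {
    p <- positionsByLg[[lg]]
    if (is.unsorted(p)) {
      warning("positions of ", lg, " were not sorted; sorting")
      p <- sort(p)
    }
    if (length(p) < 2L) next
    d <- diff(p) / scaleFactor
    over <- which(d > thresholdCm)
    if (length(over))
      rows[[lg]] <- data.frame(lg = lg, lo_cm = p[over],
                               hi_cm = p[over + 1L], length_cm = d[over],
                               stringsAsFactors = FALSE)
  }
  gaps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lg = character(), lo_cm = numeric(), hi_cm = numeric(),
               length_cm = numeric(), stringsAsFactors = FALSE)
  gaps <- gaps[order(-gaps$length_cm), , drop = FALSE]
  rownames(gaps) <- NULL
  total <- sum(gaps$length_cm)
  list(gaps = gaps, n_gaps_over = nrow(gaps), total_gap_cm = total,
       pct_of_map = 100 * total / totalMapCm)
}

#' Percentage reduction between two quantities
#'
#' @param before,after the quantity before and after (e.g. map length
#'   before and after removing nested contigs).
#' @return `100 * (before - after) / before`; negative values indicate
#'   growth.
#' @export
percentChange <- function(before, after) {
  if (!is.numeric(before) || before <= 0) stop("before must be positive")
  100 * (before - after) / before
}
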