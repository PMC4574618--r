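#' Select recombination anchors every `stepMb` along a chromosome
#'
#' Takes, for each multiple of `stepMb` along the physical map, the nearest
#' marker that carries a genetic position (ties go to the smaller physical
#' position); consecutive duplicates collapse.  Chromosomes shorter than
#' two steps are flagged too short for a meaningful profile.
#'
#' @param markers data.frame of one chromosome's markers (`pos_kb`, `cm`).
#' @param chromLengthMb physical length of the chromosome, Mb.
#' @param stepMb window step (default 5 Mb).
#' @return list(`anchors` data.frame(marker_id, pos_mb, cm), `too_short`).
#' @export
selectAnchors <- function(markers, chromLengthMb, stepMb = 5) {
  m <- markers[!is.na(markers$cm), , drop = FALSE]
  if (chromLengthMb < 2 * stepMb || nrow(m) < 2L)
    return(list(anchors = NULL, too_short = TRUE))
  m <- m[order(m$pos_kb, m$marker_id), , drop = FALSE]
  grid <- seq(0, chromLengthMb, by = stepMb)
  posMb <- m$pos_kb / 1000
  pick <- vapply(grid, function(g) {
    d <- abs(posMb - g)
    cand <- which(d == min(d))
    cand[which.min(posMb[cand])]
  }, integer(1))
  pick <- pick[!duplicated(pick)]
  anchors <- data.frame(marker_id = m$marker_id[pick],
                        pos_mb = posMb[pick], cm = m$cm[pick],
                        stringsAsFactors = FALSE)
  list(anchors = anchors, too_short = FALSE)
}

#' Sliding-window recombination-rate profile
#'
#' Interval rates (Delta cM / Delta Mb, clamped at zero) between successive
#' anchors are smoothed by averaging the two intervals flanking each
#' anchor.  At the chromosome ends only a single flanking interval exists;
#' the pass is therefore run in both directions and the two estimates are
#' averaged, which leaves interior anchors at the mean of their two
#' flanking intervals and end anchors at their single flanking interval.
#'
#' @param anchors data.frame from [selectAnchors()] (`pos_mb`, `cm`).
#' @param chrom chromosome label stored in the profile.
#' @return data.frame profile: `chrom`, `center_mb`, `rate_cm_per_mb`.
#' @export
windowRates <- function(anchors, chrom = NA_character_) {
  a <- anchors[order(anchors$pos_mb), , drop = FALSE]
  dup <- diff(a$pos_mb) <= 0
  if (any(dup)) {
    warning("zero-length interval(s) between anchors; collapsed")
    a <- a[c(TRUE, !dup), , drop = FALSE]
  }
  n <- nrow(a)
  if (n < 3L) stop("need at least 3 distinct anchors")
  r <- pmax(0, diff(a$cm) / diff(a$pos_mb))
  fwd <- bwd <- numeric(n)
  ## forward pass: each anchor gets the mean of its two flanking interval
  ## rates; the last step has only one window
  for (i in seq_len(n)) {
    left <- if (i > 1L) r[i - 1L] else NA_real_
    right <- if (i < n) r[i] else NA_real_
    fwd[i] <- mean(c(left, right), na.rm = TRUE)
  }
  ## backward pass, symmetric
  for (i in seq_len(n)) {
    right <- if (i < n) r[i] else NA_real_
    left <- if (i > 1L) r[i - 1L] else NA_real_
    bwd[i] <- mean(c(right, left), na.rm = TRUE)
  }
  data.frame(chrom = chrom, center_mb = a$pos_mb,
             rate_cm_per_mb = (fwd + bwd) / 2,
             stringsAsFactors = FALSE)
}

#' Extrema of a recombination profile
#'
#' @param profile data.frame from [windowRates()].
#' @return list(`global_min` = (center_mb, rate) with ties resolved to the
#'   centroid of the tied windows, `local_maxima` data.frame; terminal
#'   windows count as maxima when greater than their single neighbour).
#' @export
findExtrema <- function(profile) {
  x <- profile$center_mb
  r <- profile$rate_cm_per_mb
  n <- length(r)
  if (n < 3L) stop("profile too short")
  tied <- which(r == min(r))
  globalMin <- c(center_mb = mean(x[tied]), rate = min(r))
  isMax <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i > 1L) r[i - 1L] else -Inf
    right <- if (i < n) r[i + 1L] else -Inf
    isMax[i] <- r[i] > left && r[i] > right
  }
  list(global_min = globalMin,
       local_maxima = data.frame(center_mb = x[isMax], rate = r[isMax]))
}

#' Profile every chromosome of a marker map
#'
#' @param markers full marker map data.frame.
#' @param chromLengthsMb named numeric of chromosome lengths (Mb).
#' @param stepMb window step (default 5).
#' @return list per chromosome: `profile` (or NULL), `too_short`,
#'   `extrema`.
#' @export
recombinationProfiles <- function(markers, chromLengthsMb, stepMb = 5) {
  out <- list()
  for (ch in names(chromLengthsMb)) {
    m <- markers[markers$chrom == ch, , drop = FALSE]
    sel <- selectAnchors(m, chromLengthsMb[[ch]], stepMb)
    if (sel$too_short || nrow(sel$anchors) < 3L) {
      out[[ch]] <- list(profile = NULL, too_short = TRUE, extrema = NULL)
      next
    }
    prof <- windowRates(sel$anchors, chrom = ch)
    out[[ch]] <- list(profile = prof, too_short = FALSE,
                      extrema = findExtrema(prof))
  }
  out
}

#' Infer centromeric intervals
#'
#' A centromere call is made where the global recombination minimum of a
#' chromosome (window = centre +/- step/2) overlaps a synteny gap shared by
#' all genome comparisons.  When the minimum and the nearest gap do not
#' coincide, no call is made and both candidates are reported.
#'
#' @param profiles result of [recombinationProfiles()].
#' @param sharedGaps data.frame from [findSyntenyGaps()].
#' @param stepMb window step used for the profiles (default 5).
#' @return data.frame: `chrom`, `called`, `lo_mb`, `hi_mb`, `min_center_mb`,
#'   `min_rate`; uncalled chromosomes have `NA` interval bounds.
#' @export
inferCentromeres <- function(profiles, sharedGaps, stepMb = 5) {
  rows <- list()
  for (ch in names(profiles)) {
    p <- profiles[[ch]]
    if (is.null(p$profile)) next
    gm <- p$extrema$global_min
    wlo <- gm[["center_mb"]] - stepMb / 2
    whi <- gm[["center_mb"]] + stepMb / 2
    g <- sharedGaps[sharedGaps$chrom == ch, , drop = FALSE]
    hit <- which(g$lo_kb / 1000 <= whi & g$hi_kb / 1000 >= wlo)
    if (length(hit)) {
      g <- g[hit[1L], ]
      rows[[ch]] <- data.frame(chrom = ch, called = TRUE,
                               lo_mb = g$lo_kb / 1000, hi_mb = g$hi_kb / 1000,
                               min_center_mb = gm[["center_mb"]],
                               min_rate = gm[["rate"]],
                               stringsAsFactors = FALSE)
    } else {
      rows[[ch]] <- data.frame(chrom = ch, called = FALSE,
                               lo_mb = NA_real_, hi_mb = NA_real_,
                               min_center_mb = gm[["center_mb"]],
                               min_rate = gm[["rate"]],
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), called = logical(),
                      lo_mb = numeric(), hi_mb = numeric(),
                      min_center_mb = numeric(), min_rate = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Mean and SD of profile extrema across chromosomes
#'
#' @param profiles result of [recombinationProfiles()].
#' @return list(`maxima_mean`, `maxima_sd`, `minima_mean`, `minima_sd`,
#'   `n`); SDs are `NA` with fewer than two profiled chromosomes.
#' @export
extremaSummary <- function(profiles) {
  maxMeans <- minRates <- numeric()
  for (p in profiles) {
    if (is.null(p$profile)) next
    if (nrow(p$extrema$local_maxima))
      maxMeans <- c(maxMeans, mean(p$extrema$local_maxima$rate))
    minRates <- c(minRates, p$extrema$global_min[["rate"]])
  }
  n <- length(minRates)
  list(maxima_mean = mean(maxMeans),
       maxima_sd = if (length(maxMeans) > 1L) stats::sd(maxMeans) else NA_real_,
       minima_mean = mean(minRates),
       minima_sd = if (n > 1L) stats::sd(minRates) else NA_real_,
       n = n)
}
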