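#' Detect synteny blocks duplicated across query chromosomes
#'
#' A whole-genome duplication in the query lineage leaves the same subject
#' interval syntenic with two different query chromosomes.  Every pair of
#' blocks on different query chromosomes whose spans on the *same* subject
#' chromosome overlap by at least `dupOverlapFrac` of the shorter subject
#' span is reported; a block may take part in several pairs.  Because
#' chained blocks can run very long, two genuinely duplicated blocks may
#' overlap by far less than half of the shorter span while still sharing
#' many megabases; a pair is therefore also accepted on a large absolute
#' overlap (`dupMinOverlapMb`).
#'
#' @param sbs ranked [SyntenyBlockSet-class] of one comparison.
#' @param dupOverlapFrac overlap threshold (default 0.5 of the shorter).
#' @param dupMinOverlapMb absolute subject overlap that also qualifies a
#'   pair (default 3 Mb).
#' @return data.frame: `block_a`, `block_b`, `subject_chrom`,
#'   `overlap_lo_bp`, `overlap_hi_bp`, `qchrom_a`, `qchrom_b`.
#' @export
detectDuplicatedBlocks <- function(sbs, dupOverlapFrac = 0.5,
                                   dupMinOverlapMb = 3) {
  b <- blocks(sbs)
  empty <- data.frame(block_a = character(), block_b = character(),
                      subject_chrom = character(), overlap_lo_bp = numeric(),
                      overlap_hi_bp = numeric(), qchrom_a = character(),
                      qchrom_b = character(), stringsAsFactors = FALSE)
  if (nrow(b) < 2L) return(empty)
  out <- list()
  for (sc in unique(b$subject_chrom)) {
    sel <- which(b$subject_chrom == sc)
    if (length(sel) < 2L) next
    ir <- IRanges::IRanges(as.integer(round(b$s_lo_bp[sel])),
                           as.integer(round(pmax(b$s_hi_bp[sel],
                                                 b$s_lo_bp[sel] + 1))))
    hits <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    keep <- qh < sh
    for (k in which(keep)) {
      i <- sel[qh[k]]; j <- sel[sh[k]]
      if (b$query_chrom[i] == b$query_chrom[j]) next
      lo <- max(b$s_lo_bp[i], b$s_lo_bp[j])
      hi <- min(b$s_hi_bp[i], b$s_hi_bp[j])
      shorter <- min(b$s_hi_bp[i] - b$s_lo_bp[i],
                     b$s_hi_bp[j] - b$s_lo_bp[j])
      if (shorter <= 0) next
      ok <- (hi - lo) >= dupOverlapFrac * shorter ||
            (hi - lo) >= dupMinOverlapMb * 1e6
      if (!ok) next
      out[[length(out) + 1L]] <- data.frame(
        block_a = b$block_id[i], block_b = b$block_id[j],
        subject_chrom = sc, overlap_lo_bp = lo, overlap_hi_bp = hi,
        qchrom_a = b$query_chrom[i], qchrom_b = b$query_chrom[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## markers lying in locally supported duplicated portions: one row per
## (marker, own chromosome, duplicated-on chromosome)
.dupSupport <- function(sbs, dupPairs, supportWindowKb) {
  aa <- blockAnchors(sbs)
  empty <- data.frame(marker_id = character(), c1 = character(),
                      c2 = character(), stringsAsFactors = FALSE)
  if (!nrow(dupPairs) || !nrow(aa)) return(empty)
  aaByBlock <- split(aa, aa$block_id)
  w <- supportWindowKb * 1000
  nearAny <- function(x, ref) {
    if (!length(ref)) return(rep(FALSE, length(x)))
    ref <- sort(ref)
    i <- findInterval(x, ref)
    dLo <- ifelse(i >= 1L, x - ref[pmax(i, 1L)], Inf)
    dHi <- ifelse(i < length(ref), ref[pmin(i + 1L, length(ref))] - x, Inf)
    pmin(dLo, dHi) <= w
  }
  sup <- list()
  for (k in seq_len(nrow(dupPairs))) {
    lo <- dupPairs$overlap_lo_bp[k]; hi <- dupPairs$overlap_hi_bp[k]
    for (side in 1:2) {
      blk <- if (side == 1L) dupPairs$block_a[k] else dupPairs$block_b[k]
      oth <- if (side == 1L) dupPairs$block_b[k] else dupPairs$block_a[k]
      c1 <- if (side == 1L) dupPairs$qchrom_a[k] else dupPairs$qchrom_b[k]
      c2 <- if (side == 1L) dupPairs$qchrom_b[k] else dupPairs$qchrom_a[k]
      p <- aaByBlock[[blk]]
      po <- aaByBlock[[oth]]
      if (is.null(p) || is.null(po)) next
      inOv <- p$s_start >= lo & p$s_start <= hi
      supported <- inOv & nearAny(p$s_start, po$s_start)
      m <- unique(p$marker_id[supported])
      if (length(m))
        sup[[length(sup) + 1L]] <- data.frame(
          marker_id = m, c1 = c1, c2 = c2, stringsAsFactors = FALSE)
    }
  }
  if (!length(sup)) return(empty)
  unique(do.call(rbind, sup))
}

#' Fraction of collinear markers lying in duplicated blocks
#'
#' A marker counts as duplicated when it lies in the duplicated portion of
#' a block pair and the partner block holds an anchor within
#' `supportWindowKb` of it on the subject (the same local-support rule as
#' [homoeologueMatrix()]); membership of a very long block in some pair is
#' not by itself enough.
#'
#' @param sbs ranked [SyntenyBlockSet-class].
#' @param dupPairs data.frame from [detectDuplicatedBlocks()].
#' @param supportWindowKb local-support window on the subject (default
#'   500 Kb).
#' @return percentage (0-100) of collinear markers in locally supported
#'   duplicated regions; `NA` when there are no collinear markers.
#' @export
duplicatedFraction <- function(sbs, dupPairs, supportWindowKb = 500) {
  aa <- blockAnchors(sbs)
  denom <- length(unique(aa$marker_id))
  if (denom == 0L) return(NA_real_)
  sup <- .dupSupport(sbs, dupPairs, supportWindowKb)
  100 * length(unique(sup$marker_id)) / denom
}

#' Build the homoeology support matrix and pair the chromosomes
#'
#' `counts[c1, c2]` accumulates collinear markers on query chromosome c1
#' lying in the duplicated portion of a block whose duplicate is on c2.
#' A marker counts only when the duplication is locally supported: its
#' homologous gene must fall inside the subject-span overlap of a
#' duplicated-block pair *and* the partner block must hold an anchor
#' within `supportWindowKb` of it on the subject, so a sparse chain
#' stretched across a dense block cannot claim the dense block's whole
#' marker count.  Each marker counts once per (c1, c2) however many pairs
#' support it.  Each chromosome's partner is the column maximising the
#' row percentage (percentages neutralize chromosome-size differences); a
#' pairing is reciprocal when the partner of the partner is the
#' chromosome itself.
#'
#' @param sbs ranked [SyntenyBlockSet-class].
#' @param dupPairs data.frame from [detectDuplicatedBlocks()].
#' @param supportWindowKb local-support window on the subject (default
#'   500 Kb).
#' @return a [HomoeologyMatrix-class].
#' @export
homoeologueMatrix <- function(sbs, dupPairs, supportWindowKb = 500) {
  aa <- blockAnchors(sbs)
  b <- blocks(sbs)
  chroms <- sort(unique(b$query_chrom))
  counts <- matrix(0L, length(chroms), length(chroms),
                   dimnames = list(chroms, chroms))
  sup <- .dupSupport(sbs, dupPairs, supportWindowKb)
  if (nrow(sup)) {
    tab <- table(factor(sup$c1, levels = chroms),
                 factor(sup$c2, levels = chroms))
    counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                     dimnames = list(chroms, chroms))
  }
  rs <- rowSums(counts)
  rowPct <- counts
  rowPct[] <- ifelse(rep(rs, ncol(counts)) > 0,
                     100 * counts / pmax(rs, 1L), NA_real_)
  partner <- vapply(chroms, function(c1) {
    r <- rowPct[c1, ]
    if (all(is.na(r)) || sum(counts[c1, ]) == 0L) NA_character_
    else names(which.max(r))
  }, character(1))
  reciprocal <- vapply(chroms, function(c1) {
    p <- partner[[c1]]
    !is.na(p) && !is.na(partner[[p]]) && partner[[p]] == c1
  }, logical(1))
  new("HomoeologyMatrix", counts = counts, rowPct = rowPct,
      partner = partner, reciprocal = reciprocal)
}


#' Call a whole-genome duplication from S/P ratios
#'
#' The secondary-to-primary block-length ratio of a test comparison is
#' judged against a benchmark comparison known to carry no recent WGD; the
#' call is positive when the test ratio exceeds the benchmark by more than
#' `marginFrac`.
#'
#' @param spTest S/P ratio of the comparison under test.
#' @param spBenchmark S/P ratio of the benchmark (no recent WGD) comparison.
#' @param marginFrac required excess over the benchmark (default 0.5,
#'   i.e. the test ratio must exceed 1.5x the benchmark).
#' @return list(`wgd` logical, `margin` = spTest/spBenchmark - 1).
#' @export
wgdCall <- function(spTest, spBenchmark, marginFrac = 0.5) {
  if (!is.numeric(spBenchmark) || spBenchmark <= 0)
    stop("benchmark S/P ratio must be positive")
  list(wgd = spTest > spBenchmark * (1 + marginFrac),
       margin = spTest / spBenchmark - 1)
}

#' Best/second-best alternation along a parallel block group
#'
#' In duplicated regions the top-ranked and second-ranked homologous genes
#' alternate between the primary and secondary track when the two tracks
#' are equidistant from the query segment.  Over the query-ordered anchors
#' of one parallel group this computes the proportion of best/second
#' transitions between consecutive anchors and an exact binomial test
#' against 0.5.
#'
#' @param sbs ranked [SyntenyBlockSet-class].
#' @param groupId a `group_id` present in `blocks(sbs)`.
#' @return list(`n`, `proportion`, `p_value`, `insufficient`).
#' @export
alternationTest <- function(sbs, groupId) {
  b <- blocks(sbs)
  ids <- b$block_id[b$group_id == groupId]
  aa <- blockAnchors(sbs)
  aa <- aa[aa$block_id %in% ids, , drop = FALSE]
  aa <- aa[order(aa$pos_kb, aa$marker_id), , drop = FALSE]
  n <- nrow(aa)
  if (n < 3L)
    return(list(n = n, proportion = NA_real_, p_value = NA_real_,
                insufficient = TRUE))
  sw <- sum(aa$via[-1L] != aa$via[-n])
  bt <- stats::binom.test(sw, n - 1L, p = 0.5)
  list(n = n, proportion = sw / (n - 1L), p_value = bt$p.value,
       insufficient = FALSE)
}

## longest common subsequence of two label vectors; returns index pairs
.lcs <- function(x, y) {
  nx <- length(x); ny <- length(y)
  L <- matrix(0L, nx + 1L, ny + 1L)
  for (i in seq_len(nx)) for (j in seq_len(ny))
    L[i + 1L, j + 1L] <- if (x[i] == y[j]) L[i, j] + 1L else
      max(L[i, j + 1L], L[i + 1L, j])
  ## traceback
  i <- nx; j <- ny; ix <- integer(); iy <- integer()
  while (i > 0L && j > 0L) {
    if (x[i] == y[j] && L[i + 1L, j + 1L] == L[i, j] + 1L) {
      ix <- c(i, ix); iy <- c(j, iy); i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1L] >= L[i + 1L, j]) i <- i - 1L else j <- j - 1L
  }
  list(ix = ix, iy = iy, len = L[nx + 1L, ny + 1L])
}

#' Reconstruct the ancestral chromosome underlying a homoeologue pair
#'
#' Orders the subject-chromosome labels of the pair's synteny blocks along
#' a consensus of both homoeologues: the order is taken from the member
#' with the greater total block span, and blocks present only in the other
#' member are inserted at their flanking positions.  A block present in one
#' member and absent from every other query chromosome is tagged
#' single-copy (printed in parentheses), the signature of a post-WGD
#' deletion from the missing homoeologue.
#'
#' @param chromA,chromB the homoeologous query chromosomes.
#' @param sbs ranked [SyntenyBlockSet-class] of the reference comparison.
#' @param dupOverlapFrac overlap threshold used to match blocks between the
#'   homoeologues and genome-wide (default 0.5).
#' @return list with `sequence` (subject labels in ancestral order),
#'   `single_copy` (logical, parallel to `sequence`), `conflict` (logical),
#'   and `text` (Table-style rendering, parentheses = single copy).
#' @export
ancestralComposition <- function(chromA, chromB, sbs,
                                 dupOverlapFrac = 0.5) {
  b <- blocks(sbs)
  memb <- function(ch) {
    m <- b[b$query_chrom == ch & b$rank == "primary", , drop = FALSE]
    m[order(m$q_lo_kb), , drop = FALSE]
  }
  ba <- memb(chromA); bb <- memb(chromB)
  spanSum <- function(m) sum(m$q_hi_kb - m$q_lo_kb)
  if (spanSum(bb) > spanSum(ba)) { tmp <- ba; ba <- bb; bb <- tmp }
  la <- ba$subject_chrom; lb <- bb$subject_chrom
  cs <- .lcs(la, lb)
  conflict <- FALSE
  if (length(lb)) {
    rev_cs <- .lcs(la, rev(lb))
    if (rev_cs$len > cs$len) conflict <- TRUE
  }
  ## merge: walk the longer member; insert unmatched blocks of the shorter
  ## after the position of their preceding matched neighbour
  seqLabels <- la
  seqBlocks <- ba$block_id
  insertAfter <- rep(NA_integer_, 0)
  if (length(lb)) {
    matchedB <- cs$iy
    for (j in seq_along(lb)) {
      if (j %in% matchedB) next
      prevMatched <- matchedB[matchedB < j]
      posInA <- if (length(prevMatched))
        cs$ix[match(max(prevMatched), cs$iy)] else 0L
      seqLabels <- append(seqLabels, lb[j], after = posInA)
      seqBlocks <- append(seqBlocks, bb$block_id[j], after = posInA)
      ## shift recorded match positions in A beyond the insertion
      cs$ix[cs$ix > posInA] <- cs$ix[cs$ix > posInA] + 1L
    }
  }
  ## single-copy: block found nowhere else in the query genome
  single <- vapply(seq_along(seqBlocks), function(k) {
    id <- seqBlocks[k]
    row <- b[b$block_id == id, ]
    others <- b[b$query_chrom != row$query_chrom &
                b$subject_chrom == row$subject_chrom, , drop = FALSE]
    if (!nrow(others)) return(TRUE)
    ov <- pmin(others$s_hi_bp, row$s_hi_bp) -
          pmax(others$s_lo_bp, row$s_lo_bp)
    shorter <- pmin(others$s_hi_bp - others$s_lo_bp,
                    row$s_hi_bp - row$s_lo_bp)
    !any(ov >= dupOverlapFrac * shorter & ov > 0)
  }, logical(1))
  txt <- paste(ifelse(single, paste0("(", seqLabels, ")"), seqLabels),
               collapse = ", ")
  list(sequence = seqLabels, single_copy = single, conflict = conflict,
       text = txt)
}
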