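## Collinear chain semantics
##
## Anchor points of one (query chromosome, subject chromosome) pair are
## sorted by query position.  A chain is a subsequence whose subject gene
## starts run strictly monotonely (ascending or descending), where
##   (i)  a monotonicity violation between two points whose query positions
##        lie within jitterKb of each other is forgiven (the physical order
##        of markers is only known to one BAC length),
##   (ii) at most maxDiscordant consecutive points of the subset may lie
##        between two chain members (they are left non-collinear); the
##        count includes points claimed by previously extracted chains, so
##        sparse leftovers cannot chain across dense discordant runs, and
##  (iii) consecutive chain members must be within maxAnchorGapKb on the
##        query; an optional maxSubjectGapKb (off by default) additionally
##        terminates chains on large subject-side jumps.
## One marker contributes at most one point to a chain.  Chains are
## extracted iteratively: the longest admissible chain (ties: ascending
## orientation first) is removed and the search repeats on the remaining
## points, so parallel blocks on the same subject chromosome separate into
## successive chains.

## exact longest-chain search over one point set; dir = +1 ascending,
## -1 descending.  Returns indices of the chain (possibly length 0/1).
.chainDP <- function(pos, s, marker, dir, maxGapKb, jitterKb, maxSkip,
                     fullIdx = seq_along(pos), maxSubjectGapKb = Inf) {
  n <- length(pos)
  if (n == 0L) return(integer())
  sv <- s * dir
  L <- rep(1L, n)
  prev <- rep(0L, n)
  for (j in seq_len(n)) {
    if (j == 1L) next
    for (i in (j - 1L):1L) {
      if (fullIdx[j] - fullIdx[i] - 1L > maxSkip) break
      if (pos[j] - pos[i] > maxGapKb) break
      if (marker[i] == marker[j]) next
      if (abs(s[j] - s[i]) > maxSubjectGapKb * 1000) next
      ok <- sv[j] > sv[i] || (pos[j] - pos[i]) <= jitterKb
      if (ok && L[i] + 1L > L[j]) {
        L[j] <- L[i] + 1L
        prev[j] <- i
      }
    }
  }
  jbest <- which.max(L)
  chain <- integer(L[jbest])
  k <- L[jbest]
  while (jbest > 0L) {
    chain[k] <- jbest
    k <- k - 1L
    jbest <- prev[jbest]
  }
  chain
}

## brute-force reference search over the same semantics (exhaustive DFS).
## Kept exported for validation work; quadratic-exponential, tiny inputs only.
#' Exhaustive reference search for the longest collinear chain
#'
#' Depth-first enumeration of every admissible chain under the same
#' tolerance semantics as [callCollinearChains()]; returns the maximum
#' attainable chain length.  Intended for validating the dynamic-programming
#' chainer on small anchor sets.
#'
#' @param pos,s numeric vectors of query positions (Kb) and subject starts,
#'   sorted by `pos`.
#' @param marker character vector of marker ids.
#' @param maxGapKb,jitterKb,maxSkip tolerance parameters.
#' @param maxSubjectGapKb largest subject-side jump allowed between
#'   consecutive chain members (default `Inf`: no subject-side bound).
#' @param fullIdx positions of the points in the complete anchor subset
#'   (defaults to `seq_along(pos)`: the points are the whole subset).
#' @return integer: the longest admissible chain length over both
#'   orientations.
#' @export
bruteForceChainLength <- function(pos, s, marker, maxGapKb = 2000,
                                  jitterKb = 200, maxSkip = 2,
                                  fullIdx = seq_along(pos),
                                  maxSubjectGapKb = Inf) {
  n <- length(pos)
  if (n == 0L) return(0L)
  best <- 0L
  for (dir in c(1, -1)) {
    sv <- s * dir
    recurse <- function(last, len) {
      if (len > best) best <<- len
      from <- if (last == 0L) 1L else last + 1L
      if (from > n) return()
      for (j in from:n) {
        if (last > 0L) {
          if (fullIdx[j] - fullIdx[last] - 1L > maxSkip) break
          if (pos[j] - pos[last] > maxGapKb) break
          if (marker[j] == marker[last]) next
          if (abs(s[j] - s[last]) > maxSubjectGapKb * 1000) next
          if (!(sv[j] > sv[last] || (pos[j] - pos[last]) <= jitterKb)) next
        }
        recurse(j, len + 1L)
      }
    }
    recurse(0L, 0L)
  }
  best
}

#' Call collinear anchor chains for one genome comparison
#'
#' Flags anchors as collinear and groups them into maximal monotone chains,
#' one subject genome at a time.  Both the best and the second-best gene of
#' a marker enter as separate anchor points, so parallel (duplicated)
#' synteny tracks can be recovered from the rank-two hits.
#'
#' @param at an [AnchorTable-class].
#' @param maxAnchorGapKb chain break threshold on the query (default 2000).
#' @param maxSubjectGapKb optional chain break threshold on the subject
#'   (default `Inf`: disabled).
#' @param jitterKb marker-order uncertainty, one BAC length (default 200).
#' @param maxDiscordant consecutive non-fitting anchors that may be skipped
#'   (default 2).
#' @param minChain shortest chain retained (default 3; shorter chains can
#'   never become blocks).
#' @return list with `chains` (data.frame: chain_id, query_chrom,
#'   subject_chrom, orientation, n_anchors) and `points` (data.frame of
#'   chained anchor points: marker_id, via, gene_id, pos_kb, s_start,
#'   chain_id), plus the updated `AnchorTable` with collinearity flags.
#' @export
callCollinearChains <- function(at, maxAnchorGapKb = 2000, jitterKb = 200,
                                maxDiscordant = 2, minChain = 3L,
                                maxSubjectGapKb = Inf) {
  a <- anchors(at)
  pts <- rbind(
    data.frame(marker_id = a$marker_id, via = "best", qchrom = a$chrom,
               pos_kb = a$pos_kb, gene_id = a$best_gene,
               schrom = a$best_chrom, s_start = a$best_start,
               stringsAsFactors = FALSE),
    data.frame(marker_id = a$marker_id, via = "second", qchrom = a$chrom,
               pos_kb = a$pos_kb, gene_id = a$second_gene,
               schrom = a$second_chrom, s_start = a$second_start,
               stringsAsFactors = FALSE))
  pts <- pts[!is.na(pts$gene_id), , drop = FALSE]
  chains <- list()
  assign <- list()
  cid <- 0L
  if (nrow(pts)) {
    pts <- pts[order(pts$qchrom, pts$schrom, pts$pos_kb, pts$s_start,
                     pts$marker_id, pts$via), , drop = FALSE]
    for (sub in split(pts, list(pts$qchrom, pts$schrom), drop = TRUE)) {
      remaining <- seq_len(nrow(sub))
      while (length(remaining) >= minChain) {
        pos <- sub$pos_kb[remaining]
        s <- sub$s_start[remaining]
        mk <- sub$marker_id[remaining]
        up <- .chainDP(pos, s, mk, 1, maxAnchorGapKb, jitterKb,
                       maxDiscordant, fullIdx = remaining,
                       maxSubjectGapKb = maxSubjectGapKb)
        dn <- .chainDP(pos, s, mk, -1, maxAnchorGapKb, jitterKb,
                       maxDiscordant, fullIdx = remaining,
                       maxSubjectGapKb = maxSubjectGapKb)
        ori <- if (length(up) >= length(dn)) "+" else "-"
        ch <- if (ori == "+") up else dn
        if (length(ch) < minChain) break
        cid <- cid + 1L
        idx <- remaining[ch]
        chains[[cid]] <- data.frame(
          chain_id = cid, query_chrom = sub$qchrom[1L],
          subject_chrom = sub$schrom[1L], orientation = ori,
          n_anchors = length(idx), stringsAsFactors = FALSE)
        assign[[cid]] <- cbind(sub[idx, c("marker_id", "via", "gene_id",
                                          "pos_kb", "s_start"),
                                   drop = FALSE],
                               chain_id = cid)
        remaining <- setdiff(remaining, idx)
      }
    }
  }
  chains <- if (length(chains)) do.call(rbind, chains) else
    data.frame(chain_id = integer(), query_chrom = character(),
               subject_chrom = character(), orientation = character(),
               n_anchors = integer(), stringsAsFactors = FALSE)
  points <- if (length(assign)) do.call(rbind, assign) else
    data.frame(marker_id = character(), via = character(),
               gene_id = character(), pos_kb = numeric(),
               s_start = numeric(), chain_id = integer(),
               stringsAsFactors = FALSE)
  rownames(points) <- NULL
  a$collinear_best <- a$marker_id %in%
    points$marker_id[points$via == "best"]
  a$collinear_second <- a$marker_id %in%
    points$marker_id[points$via == "second"]
  at@anchors <- a
  list(chains = chains, points = points, anchorTable = at)
}

#' Filter chains into synteny blocks
#'
#' A chain survives as a synteny block when it contains at least `minGenes`
#' *distinct* subject genes and its query span is at least `minSpanKb` on
#' the minimum tiling path.
#'
#' @param chainResult result of [callCollinearChains()].
#' @param minGenes minimum distinct collinear genes (default 3).
#' @param minSpanKb minimum query span in Kb (default 500, i.e. ~0.5 Mb).
#' @param comparison label for the comparison, e.g. `"Jr-Vv"`.
#' @return a [SyntenyBlockSet-class] with unranked blocks.
#' @export
filterBlocks <- function(chainResult, minGenes = 3L, minSpanKb = 500,
                         comparison = NA_character_) {
  ch <- chainResult$chains
  pts <- chainResult$points
  keep <- logical(nrow(ch))
  rows <- vector("list", nrow(ch))
  ptsByChain <- split(pts, pts$chain_id)
  for (k in seq_len(nrow(ch))) {
    p <- ptsByChain[[as.character(ch$chain_id[k])]]
    span <- max(p$pos_kb) - min(p$pos_kb)
    ngene <- length(unique(p$gene_id))
    if (ngene >= minGenes && span >= minSpanKb) {
      keep[k] <- TRUE
      rows[[k]] <- data.frame(
        block_id = NA_character_, query_chrom = ch$query_chrom[k],
        q_lo_kb = min(p$pos_kb), q_hi_kb = max(p$pos_kb),
        subject_chrom = ch$subject_chrom[k],
        s_lo_bp = min(p$s_start), s_hi_bp = max(p$s_start),
        orientation = ch$orientation[k], n_collinear = nrow(p),
        n_genes = ngene, rank = NA_character_, group_id = NA_character_,
        chain_id = ch$chain_id[k], stringsAsFactors = FALSE)
    }
  }
  b <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(block_id = character(), query_chrom = character(),
               q_lo_kb = numeric(), q_hi_kb = numeric(),
               subject_chrom = character(), s_lo_bp = numeric(),
               s_hi_bp = numeric(), orientation = character(),
               n_collinear = integer(), n_genes = integer(),
               rank = character(), group_id = character(),
               chain_id = integer(), stringsAsFactors = FALSE)
  if (nrow(b)) {
    b <- b[order(b$query_chrom, b$q_lo_kb, b$q_hi_kb), , drop = FALSE]
    b$block_id <- sprintf("SB%04d", seq_len(nrow(b)))
    aa <- pts[pts$chain_id %in% b$chain_id, , drop = FALSE]
    aa$block_id <- b$block_id[match(aa$chain_id, b$chain_id)]
    aa$chain_id <- NULL
  } else {
    aa <- data.frame(marker_id = character(), via = character(),
                     gene_id = character(), pos_kb = numeric(),
                     s_start = numeric(), block_id = character(),
                     stringsAsFactors = FALSE)
  }
  b$chain_id <- NULL
  rownames(b) <- rownames(aa) <- NULL
  new("SyntenyBlockSet", blocks = b, anchorAssign = aa,
      comparison = comparison,
      params = list(minGenes = minGenes, minSpanKb = minSpanKb))
}

## union-find for transitive closure of parallel-group membership
.unionFind <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  list(find = find,
       union = function(i, j) parent[find(i)] <<- find(j),
       roots = function() vapply(seq_len(n), find, integer(1)))
}

#' Group parallel blocks and rank them primary/secondary/tertiary
#'
#' Blocks on one query chromosome whose query spans overlap by at least
#' `overlapFrac` of the shorter span belong to one parallel group
#' (transitive closure).  Within a group, blocks are ranked by descending
#' query-span length: the longest is primary, the next secondary, the
#' shortest tertiary; a fourth or later parallel block is reported as
#' tertiary with a warning.  Singleton groups are primary.  Ties in length
#' go to the smaller subject chromosome label.
#'
#' @param sbs a [SyntenyBlockSet-class] (unranked).
#' @param overlapFrac reciprocal-shorter overlap threshold (default 0.5).
#' @return the same `SyntenyBlockSet` with `rank` and `group_id` filled.
#' @export
classifyParallel <- function(sbs, overlapFrac = 0.5) {
  b <- blocks(sbs)
  if (!nrow(b)) return(sbs)
  b$group_id <- NA_character_
  b$rank <- NA_character_
  warned <- FALSE
  gcount <- 0L
  for (ch in unique(b$query_chrom)) {
    sel <- which(b$query_chrom == ch)
    uf <- .unionFind(length(sel))
    for (i in seq_along(sel)) for (j in seq_len(i - 1L)) {
      bi <- b[sel[i], ]; bj <- b[sel[j], ]
      ov <- min(bi$q_hi_kb, bj$q_hi_kb) - max(bi$q_lo_kb, bj$q_lo_kb)
      shorter <- min(bi$q_hi_kb - bi$q_lo_kb, bj$q_hi_kb - bj$q_lo_kb)
      if (ov >= overlapFrac * shorter && ov > 0) uf$union(i, j)
    }
    roots <- uf$roots()
    for (r in unique(roots)) {
      gcount <- gcount + 1L
      gid <- sprintf("%s.g%03d", ch, gcount)
      members <- sel[roots == r]
      len <- b$q_hi_kb[members] - b$q_lo_kb[members]
      ord <- members[order(-len, b$subject_chrom[members])]
      ranks <- c("primary", "secondary", "tertiary")
      for (k in seq_along(ord)) {
        b$group_id[ord[k]] <- gid
        b$rank[ord[k]] <- ranks[min(k, 3L)]
        if (k > 3L && !warned) {
          warning("parallel group with more than three blocks; ",
                  "extra blocks ranked tertiary")
          warned <- TRUE
        }
      }
    }
  }
  sbs@blocks <- b
  sbs
}

#' Synteny statistics for one ranked comparison
#'
#' Computes the block counts, the percentage of collinear markers, the mean
#' collinear markers per block, the summed primary/secondary/tertiary block
#' lengths (in Mb of query MTP), their percentages of the total map, and
#' the secondary-to-primary (S/P) length ratio used to flag whole-genome
#' duplications.
#'
#' The denominator of `pct_collinear` is the number of markers with at
#' least one passing homology hit in this comparison.
#'
#' @param sbs ranked [SyntenyBlockSet-class].
#' @param at the matching [AnchorTable-class].
#' @param totalMtpMb total query map length in Mb.
#' @param nPseudomolecules chromosome count of the subject genome.
#' @return one-row data.frame of statistics.
#' @export
syntenySummary <- function(sbs, at, totalMtpMb, nPseudomolecules) {
  if (!is.numeric(totalMtpMb) || totalMtpMb <= 0)
    stop("totalMtpMb must be positive")
  b <- blocks(sbs)
  aa <- blockAnchors(sbs)
  a <- anchors(at)
  nHit <- sum(!is.na(a$best_gene))
  nColl <- length(unique(aa$marker_id))
  lenBy <- function(r) sum(b$q_hi_kb[b$rank == r] -
                           b$q_lo_kb[b$rank == r]) / 1000
  lp <- lenBy("primary"); ls <- lenBy("secondary"); lt <- lenBy("tertiary")
  data.frame(
    comparison = comparisonLabel(sbs),
    n_blocks = nrow(b),
    n_blocks_per_pseudomolecule = if (nPseudomolecules > 0)
      nrow(b) / nPseudomolecules else NA_real_,
    n_collinear = nColl,
    n_with_hit = nHit,
    pct_collinear = if (nHit > 0) 100 * nColl / nHit else 0,
    collinear_per_block = if (nrow(b) > 0) nColl / nrow(b) else 0,
    len_primary_mb = lp, len_secondary_mb = ls, len_tertiary_mb = lt,
    pct_primary = 100 * lp / totalMtpMb,
    pct_secondary = 100 * ls / totalMtpMb,
    pct_tertiary = 100 * lt / totalMtpMb,
    sp_ratio = if (lp > 0) ls / lp else 0,
    stringsAsFactors = FALSE)
}

#' Find synteny gaps shared across genome comparisons
#'
#' A synteny gap is a maximal query-map interval of at least `gapMinKb`
#' overlapped by no block of any supplied comparison; shared gaps are devoid
#' of synteny in every comparison simultaneously, the signature used to
#' localize centromeres.
#'
#' @param blockSets list of ranked [SyntenyBlockSet-class] objects.
#' @param chromLengthsKb named numeric vector of chromosome lengths (Kb).
#' @param gapMinKb minimum reported gap length (default 1000 Kb).
#' @return data.frame: `chrom`, `lo_kb`, `hi_kb`, `comparisons_devoid`.
#' @export
findSyntenyGaps <- function(blockSets, chromLengthsKb, gapMinKb = 1000) {
  labels <- vapply(blockSets, comparisonLabel, character(1))
  out <- list()
  for (ch in names(chromLengthsKb)) {
    len <- round(chromLengthsKb[[ch]] * 1000)
    devoid <- lapply(blockSets, function(sbs) {
      b <- blocks(sbs)
      b <- b[b$query_chrom == ch, , drop = FALSE]
      if (!nrow(b))
        return(IRanges::IRanges(1L, len))
      cov <- IRanges::reduce(IRanges::IRanges(
        pmax(1L, as.integer(round(b$q_lo_kb * 1000))),
        pmin(len, as.integer(round(b$q_hi_kb * 1000)))))
      IRanges::gaps(cov, start = 1L, end = len)
    })
    shared <- Reduce(IRanges::intersect, devoid)
    shared <- shared[IRanges::width(shared) >= gapMinKb * 1000]
    if (length(shared))
      out[[ch]] <- data.frame(
        chrom = ch,
        lo_kb = (BiocGenerics::start(shared) - 1L) / 1000,
        hi_kb = BiocGenerics::end(shared) / 1000,
        comparisons_devoid = paste(labels, collapse = ","),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), lo_kb = numeric(),
                      hi_kb = numeric(), comparisons_devoid = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the anchor-to-ranked-blocks chain for one comparison
#'
#' Convenience wrapper: chains, filters, ranks, summarises.
#'
#' @param at an [AnchorTable-class].
#' @param comparison comparison label.
#' @param totalMtpMb,nPseudomolecules passed to [syntenySummary()].
#' @param maxAnchorGapKb,jitterKb,maxDiscordant chaining tolerances, see
#'   [callCollinearChains()].
#' @param minGenes,minSpanKb block filters, see [filterBlocks()].
#' @param overlapFrac parallel-group threshold, see [classifyParallel()].
#' @return list(anchorTable, blockSet, stats).
#' @export
analyzeSynteny <- function(at, comparison, totalMtpMb, nPseudomolecules,
                           maxAnchorGapKb = 2000, jitterKb = 200,
                           maxDiscordant = 2, minGenes = 3L,
                           minSpanKb = 500, overlapFrac = 0.5,
                           maxSubjectGapKb = Inf) {
  cr <- callCollinearChains(at, maxAnchorGapKb = maxAnchorGapKb,
                            jitterKb = jitterKb,
                            maxDiscordant = maxDiscordant,
                            maxSubjectGapKb = maxSubjectGapKb)
  sbs <- filterBlocks(cr, minGenes = minGenes, minSpanKb = minSpanKb,
                      comparison = comparison)
  sbs <- classifyParallel(sbs, overlapFrac = overlapFrac)
  list(anchorTable = cr$anchorTable, blockSet = sbs,
       stats = syntenySummary(sbs, cr$anchorTable, totalMtpMb,
                              nPseudomolecules))
}
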