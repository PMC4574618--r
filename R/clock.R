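## Nei-Gojobori (1986) synonymous/nonsynonymous counting.
##
## Site counting: at each codon position the three possible single-base
## changes are classified; a change is synonymous when the mutated codon is
## a sense codon for the same amino acid, otherwise (different amino acid
## or stop) nonsynonymous.  Synonymous sites per codon are the sum over
## positions of (synonymous changes)/3, averaged over the two sequences.
##
## Difference counting: codons differing at d positions are resolved over
## all d! orderings of the single-base steps; paths passing through a stop
## codon are excluded (if every path is blocked, all paths are used).
## Synonymous/nonsynonymous differences are averaged over the admitted
## paths.

.ng86env <- new.env(parent = emptyenv())

.codonTable <- function() {
  if (is.null(.ng86env$aa)) {
    gc <- Biostrings::GENETIC_CODE
    .ng86env$aa <- gc
    bases <- c("A", "C", "G", "T")
    syn <- numeric(length(gc))
    names(syn) <- names(gc)
    for (cod in names(gc)) {
      if (gc[[cod]] == "*") next
      s <- 0
      for (p in 1:3) {
        for (b in bases) {
          if (substr(cod, p, p) == b) next
          mut <- cod
          substr(mut, p, p) <- b
          if (gc[[mut]] != "*" && gc[[mut]] == gc[[cod]]) s <- s + 1 / 3
        }
      }
      syn[[cod]] <- s
    }
    .ng86env$syn <- syn
  }
  .ng86env
}

## average synonymous/nonsynonymous differences between two codons over
## all mutational pathways
.codonDiffs <- function(c1, c2, aa) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- if (d == 1L) list(pos) else {
    if (d == 2L) list(pos, rev(pos)) else {
      out <- list()
      for (i in 1:3) for (j in setdiff(1:3, i))
        out[[length(out) + 1L]] <- pos[c(i, j, setdiff(1:3, c(i, j)))]
      out
    }
  }
  score <- function(order, allowStop) {
    cur <- c1
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allowStop && aa[[nxt]] == "*") return(NULL)
      if (aa[[nxt]] == aa[[cur]] && aa[[nxt]] != "*") sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  paths <- Filter(Negate(is.null), lapply(perms, score, allowStop = FALSE))
  if (!length(paths))
    paths <- lapply(perms, score, allowStop = TRUE)
  m <- do.call(rbind, paths)
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

#' Nei-Gojobori Ks/Ka for one aligned coding-sequence pair
#'
#' Computes synonymous and nonsynonymous site counts and differences by
#' the NG86 method, with pathway averaging through non-stop intermediates,
#' and applies the Jukes-Cantor multiple-hit correction
#' \eqn{K = -\frac{3}{4}\ln(1 - \frac{4}{3} p)} (the uncorrected
#' proportions are available with `variant = "pdistance"`).  Codon columns
#' containing gaps or ambiguity codes are dropped pairwise.
#'
#' @param seqA,seqB aligned nucleotide strings of equal length, a multiple
#'   of 3.
#' @param variant `"jc"` (default) or `"pdistance"`.
#' @return list: `ks`, `ka`, `S`, `N`, `Sd`, `Nd`, `ps`, `pn`,
#'   `saturated_s`, `saturated_n`, `n_codons`.  `ks` is `NA` when
#'   \eqn{p_s \ge 3/4} (saturation).
#' @export
ng86Ks <- function(seqA, seqB, variant = c("jc", "pdistance")) {
  variant <- match.arg(variant)
  seqA <- toupper(as.character(seqA))
  seqB <- toupper(as.character(seqB))
  if (nchar(seqA) != nchar(seqB))
    stop("aligned sequences must have equal length")
  if (nchar(seqA) %% 3L != 0L)
    stop("alignment length must be a multiple of 3")
  tab <- .codonTable()
  aa <- tab$aa
  codA <- substring(seqA, seq(1, nchar(seqA), 3), seq(3, nchar(seqA), 3))
  codB <- substring(seqB, seq(1, nchar(seqB), 3), seq(3, nchar(seqB), 3))
  clean <- grepl("^[ACGT]{3}$", codA) & grepl("^[ACGT]{3}$", codB)
  codA <- codA[clean]; codB <- codB[clean]
  if (!length(codA)) stop("no analyzable codons")
  if (any(aa[codA] == "*") || any(aa[codB] == "*"))
    stop("internal stop codon in alignment")
  S <- (sum(tab$syn[codA]) + sum(tab$syn[codB])) / 2
  N <- 3 * length(codA) - S
  Sd <- Nd <- 0
  for (k in seq_along(codA)) {
    if (codA[k] == codB[k]) next
    d <- .codonDiffs(codA[k], codB[k], aa)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  if (variant == "jc") {
    ks <- jc(ps); ka <- jc(pn)
  } else {
    ks <- ps; ka <- pn
  }
  list(ks = ks, ka = ka, S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       saturated_s = ps >= 0.75, saturated_n = pn >= 0.75,
       n_codons = length(codA))
}

#' Iterative outlier removal for Ks sets
#'
#' The default rule removes the largest value whenever it exceeds the mean
#' plus 3 SD of the *remaining* values (leave-one-out, so a gross outlier
#' cannot mask itself by inflating the dispersion), repeated until stable;
#' `"iqr3"` removes values above Q3 + 3 IQR (Tukey far out), also
#' iterated.
#'
#' @param x numeric vector (>= 3 values).
#' @param rule `"mean+3sd"` (default) or `"iqr3"`.
#' @return list(`kept`, `removed`).
#' @export
removeOutliers <- function(x, rule = c("mean+3sd", "iqr3")) {
  rule <- match.arg(rule)
  if (length(x) < 3L) stop("need at least 3 values")
  kept <- x
  removed <- numeric()
  repeat {
    if (length(kept) < 4L) break
    if (rule == "mean+3sd") {
      i <- which.max(kept)
      rest <- kept[-i]
      if (kept[i] > mean(rest) + 3 * stats::sd(rest)) {
        removed <- c(removed, kept[i])
        kept <- kept[-i]
        next
      }
      break
    } else {
      q <- stats::quantile(kept, c(0.25, 0.75), names = FALSE)
      drop <- kept > q[2] + 3 * (q[2] - q[1])
      if (!any(drop)) break
      removed <- c(removed, kept[drop])
      kept <- kept[!drop]
    }
  }
  list(kept = kept, removed = removed)
}

#' Silent-site substitution rate from mean Ks
#'
#' r = Ks / (2 t): substitutions per synonymous site per year given the
#' divergence time of the pair.
#'
#' @param ksMean mean Ks (substitutions per synonymous site).
#' @param tYears divergence time in years.
#' @return the rate r.
#' @export
substitutionRate <- function(ksMean, tYears) {
  if (!is.numeric(tYears) || tYears <= 0) stop("tYears must be positive")
  if (ksMean < 0) stop("ksMean must be non-negative")
  ksMean / (2 * tYears)
}

#' Fold difference between a reference substitution rate and this one
#'
#' @param rReference published rate to compare against.
#' @param r the rate estimated here.
#' @return `rReference / r` (values > 1 mean this lineage is slower);
#'   `NA` with a warning when `r` is zero.
#' @export
rateRatio <- function(rReference, r) {
  if (r == 0) {
    warning("rate is zero; ratio undefined")
    return(NA_real_)
  }
  rReference / r
}

#' Flag syntelog pairs against the selection criteria
#'
#' A pair enters the Ks mean only when both markers are exonic, sit in
#' blocks duplicated on different query chromosomes (as a pair), are both
#' collinear with a reference-genome gene, share the same exon (aligned
#' ungapped overlap of at least `minOverlapCodons` complete codons), and
#' neither is annotated as a transposable element.  All pairs are retained
#' with their flags for audit.
#'
#' @param pairs data.frame with `pair_id`, `marker_a`, `marker_b`.
#' @param sbs ranked [SyntenyBlockSet-class] of the reference comparison.
#' @param dupPairs data.frame from [detectDuplicatedBlocks()].
#' @param alignments named list (by `pair_id`) of `list(a =, b =)` aligned
#'   sequences.
#' @param markers marker map with optional `annotation` column (used for
#'   the transposable-element flag).
#' @param minOverlapCodons same-exon threshold (default 50 codons).
#' @return `pairs` with logical columns `in_duplicated_blocks`,
#'   `both_collinear`, `same_exon`, `te_annotation`, `eligible`.
#' @export
selectSyntelogs <- function(pairs, sbs, dupPairs, alignments,
                            markers = NULL, minOverlapCodons = 50L) {
  aa <- blockAnchors(sbs)
  blockOf <- function(m) unique(aa$block_id[aa$marker_id == m])
  dupKey <- if (nrow(dupPairs))
    paste(pmin(dupPairs$block_a, dupPairs$block_b),
          pmax(dupPairs$block_a, dupPairs$block_b)) else character()
  ann <- if (!is.null(markers) && !is.null(markers$annotation))
    stats::setNames(markers$annotation, markers$marker_id) else NULL
  res <- pairs
  res$in_duplicated_blocks <- FALSE
  res$both_collinear <- FALSE
  res$same_exon <- FALSE
  res$te_annotation <- FALSE
  for (k in seq_len(nrow(res))) {
    ma <- res$marker_a[k]; mb <- res$marker_b[k]
    ba <- blockOf(ma); bb <- blockOf(mb)
    res$both_collinear[k] <- length(ba) > 0L && length(bb) > 0L
    if (length(ba) && length(bb)) {
      keys <- as.vector(outer(ba, bb, function(x, y)
        paste(pmin(x, y), pmax(x, y))))
      res$in_duplicated_blocks[k] <- any(keys %in% dupKey)
    }
    al <- alignments[[res$pair_id[k]]]
    if (!is.null(al)) {
      sa <- toupper(al$a); sb <- toupper(al$b)
      if (nchar(sa) != nchar(sb))
        stop("alignment lengths differ for pair ", res$pair_id[k])
      idx <- seq(1, nchar(sa) - nchar(sa) %% 3, by = 3)
      ca <- substring(sa, idx, idx + 2)
      cb <- substring(sb, idx, idx + 2)
      ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
      res$same_exon[k] <- sum(ok) >= minOverlapCodons
    }
    if (!is.null(ann)) {
      txt <- tolower(paste(ann[c(ma, mb)], collapse = " "))
      res$te_annotation[k] <- grepl("transpos|retroelement|\\bte\\b", txt)
    }
  }
  res$eligible <- res$in_duplicated_blocks & res$both_collinear &
    res$same_exon & !res$te_annotation
  res
}

#' Read aligned coding-sequence pairs from FASTA
#'
#' Expects an even number of records; consecutive records form a pair and
#' the pair id is the part of the first name before `"|"` (or the whole
#' name).
#'
#' @param path aligned FASTA file.
#' @return named list of `list(a =, b =)` character sequences.
#' @export
readAlignedPairs <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) %% 2L != 0L)
    stop("expected an even number of aligned sequences in ", path)
  out <- list()
  for (k in seq(1, length(x), by = 2)) {
    id <- sub("\\|.*", "", names(x)[k])
    out[[id]] <- list(a = as.character(x[[k]]), b = as.character(x[[k + 1]]))
  }
  out
}

#' Full molecular-clock estimate from a set of alignments
#'
#' Computes NG86 Ks per pair, removes outliers, and converts the mean to a
#' substitution rate with optional cross-lineage fold comparisons.
#'
#' @param alignments named list of `list(a =, b =)` aligned pairs.
#' @param tYears divergence time (years) of the pairs (the WGD age).
#' @param referenceRates optional named numeric of published rates for
#'   fold-difference reporting.
#' @param outlierRule passed to [removeOutliers()].
#' @param variant passed to [ng86Ks()].
#' @return list: `table` (per-pair Ks/Ka), `n_pairs`, `ks_mean`, `ks_sd`,
#'   `t_years`, `r`, `ratios`, `removed`.
#' @export
clockEstimate <- function(alignments, tYears, referenceRates = NULL,
                          outlierRule = "mean+3sd", variant = "jc") {
  rows <- lapply(names(alignments), function(id) {
    al <- alignments[[id]]
    res <- ng86Ks(al$a, al$b, variant = variant)
    data.frame(pair_id = id, ks = res$ks, ka = res$ka, S = res$S,
               N = res$N, saturated = res$saturated_s,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ks <- tab$ks[!is.na(tab$ks)]
  filt <- removeOutliers(ks, rule = outlierRule)
  r <- substitutionRate(mean(filt$kept), tYears)
  ratios <- if (!is.null(referenceRates))
    vapply(referenceRates, rateRatio, numeric(1), r = r) else numeric()
  list(table = tab, n_pairs = length(filt$kept),
       ks_mean = mean(filt$kept),
       ks_sd = if (length(filt$kept) > 1) stats::sd(filt$kept) else NA_real_,
       t_years = tYears, r = r, ratios = ratios, removed = filt$removed)
}
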