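## shared fixtures: one full default-scenario analysis, cached per session

.fixtures <- new.env(parent = emptyenv())

## run simulate -> anchors -> ranked blocks for one subject, cached
fullAnalysis <- function(seed = 101L, subject = "benchmark",
                         scenario = NULL) {
  key <- paste0("run_", seed, "_", subject, "_",
                if (is.null(scenario)) "default" else "custom")
  if (!is.null(.fixtures[[key]]) && is.null(scenario))
    return(.fixtures[[key]])
  scn <- if (is.null(scenario)) evolutionScenario(seed = seed) else scenario
  sim <- simulateComparison(scn, subject)
  top <- selectTopTwoHits(sim$hits, sim$genes)
  at <- buildAnchorTable(sim$markers, top, subject)
  syn <- suppressWarnings(
    analyzeSynteny(at, paste0("Q-", subject), sim$totalMtpMb,
                   sim$subjectNChrom))
  out <- list(scn = scn, sim = sim, at = syn$anchorTable,
              sbs = syn$blockSet, stats = syn$stats)
  if (is.null(scenario)) .fixtures[[key]] <- out
  out
}

## a minimal hand-built marker map file
writeTinyMarkerMap <- function(path, rows = NULL) {
  if (is.null(rows))
    rows <- data.frame(
      marker_id = c("m3", "m1", "m2"),
      chrom = c("Jr1", "Jr1", "Jr1"),
      pos_kb = c(300, 100, 200),
      contig_id = c("c1", "c1", "c1"),
      stringsAsFactors = FALSE)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## build a SyntenyBlockSet directly from a block description table
makeBlockSet <- function(blocks, anchors = NULL, comparison = "test") {
  if (is.null(anchors))
    anchors <- data.frame(marker_id = character(), via = character(),
                          gene_id = character(), pos_kb = numeric(),
                          s_start = numeric(), block_id = character(),
                          stringsAsFactors = FALSE)
  new("SyntenyBlockSet", blocks = blocks, anchorAssign = anchors,
      comparison = comparison, params = list())
}

blockRow <- function(id, qc, qlo, qhi, sc, slo, shi, rank = "primary",
                     ori = "+", n = 10L) {
  data.frame(block_id = id, query_chrom = qc, q_lo_kb = qlo, q_hi_kb = qhi,
             subject_chrom = sc, s_lo_bp = slo, s_hi_bp = shi,
             orientation = ori, n_collinear = n, n_genes = n,
             rank = rank, group_id = NA_character_,
             stringsAsFactors = FALSE)
}

## independent NG86 oracle: plain enumeration, seqinr translation tables
oracleNg86 <- function(seqA, seqB, variant = "jc") {
  splitCodons <- function(x) {
    x <- toupper(x)
    substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  }
  ca <- splitCodons(seqA); cb <- splitCodons(seqB)
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[ok]; cb <- cb[ok]
  aaOf <- function(cod)
    seqinr::translate(strsplit(cod, "")[[1]])
  synSites <- function(cod) {
    s <- 0
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      if (substr(cod, p, p) == b) next
      mut <- cod; substr(mut, p, p) <- b
      if (aaOf(mut) != "*" && aaOf(mut) == aaOf(cod)) s <- s + 1 / 3
    }
    s
  }
  pathDiffs <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    perms <- if (length(pos) == 1) matrix(pos) else
      t(apply(as.matrix(expand.grid(rep(list(seq_along(pos)),
                                        length(pos)))), 1, function(o)
        if (anyDuplicated(o)) rep(NA, length(pos)) else pos[o]))
    perms <- perms[!apply(is.na(perms), 1, any), , drop = FALSE]
    walk <- function(order, allowStop) {
      cur <- c1; sd <- nd <- 0
      for (p in order) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (!allowStop && aaOf(nxt) == "*") return(NULL)
        if (aaOf(nxt) == aaOf(cur) && aaOf(nxt) != "*") sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- Filter(Negate(is.null),
                  apply(perms, 1, walk, allowStop = FALSE, simplify = FALSE))
    if (!length(res))
      res <- apply(perms, 1, walk, allowStop = TRUE, simplify = FALSE)
    colMeans(do.call(rbind, res))
  }
  S <- (sum(vapply(ca, synSites, 1)) + sum(vapply(cb, synSites, 1))) / 2
  N <- 3 * length(ca) - S
  d <- rowSums(vapply(seq_along(ca), function(i) pathDiffs(ca[i], cb[i]),
                      numeric(2)))
  ps <- d[1] / S; pn <- d[2] / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  if (variant == "jc") list(ks = jc(ps), ka = jc(pn), S = S, N = N)
  else list(ks = ps, ka = pn, S = S, N = N)
}

## random codon pair without internal stops
randomCodingPair <- function(nCodons, pMut = 0.1) {
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  repeat {
    a <- paste0(sample(bases, nCodons * 3, replace = TRUE), collapse = "")
    ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
    if (!any(ca %in% stops)) break
  }
  repeat {
    b <- strsplit(a, "")[[1]]
    mut <- runif(length(b)) < pMut
    b[mut] <- sample(bases, sum(mut), replace = TRUE)
    b <- paste0(b, collapse = "")
    cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
    if (!any(cb %in% stops)) break
  }
  list(a = a, b = b)
}
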