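## build an AnchorTable from bare vectors, best hits only
simpleAT <- function(pos_kb, s_start, schrom = "S1", qchrom = "Jr1") {
  n <- length(pos_kb)
  a <- data.frame(
    marker_id = sprintf("m%02d", seq_len(n)), chrom = qchrom,
    pos_kb = pos_kb, contig_id = "c1", cm = NA_real_, exonic = TRUE,
    best_gene = sprintf("g%02d", seq_len(n)), best_chrom = schrom,
    best_start = s_start, second_gene = NA_character_,
    second_chrom = NA_character_, second_start = NA_real_,
    collinear_best = FALSE, collinear_second = FALSE,
    stringsAsFactors = FALSE)
  a <- a[order(a$chrom, a$pos_kb, a$marker_id), ]
  rownames(a) <- NULL
  new("AnchorTable", anchors = a, subjectGenome = "S", params = list())
}

test_that("perfectly collinear anchors form one full chain", {
  at <- simpleAT(c(100, 600, 1100, 1600, 2100),
                 c(10, 20, 30, 40, 50) * 1e6)
  cr <- callCollinearChains(at)
  expect_equal(nrow(cr$chains), 1L)
  expect_equal(cr$chains$n_anchors, 5L)
  expect_equal(cr$chains$orientation, "+")
  expect_true(all(anchors(cr$anchorTable)$collinear_best))
})

test_that("local order swaps within the jitter tolerance stay chained", {
  ## anchors 2 and 3 swapped in query order but within 150 Kb
  at <- simpleAT(c(100, 600, 750, 1600, 2100),
                 c(10, 30, 20, 40, 50) * 1e6)
  cr <- callCollinearChains(at, jitterKb = 200)
  expect_equal(cr$chains$n_anchors, 5L)
})

test_that("a wild anchor is skipped and flagged non-collinear", {
  at <- simpleAT(c(100, 600, 1100, 1600, 2100),
                 c(10, 20, 500, 30, 40) * 1e6)
  cr <- callCollinearChains(at)
  expect_equal(cr$chains$n_anchors[1], 4L)
  flg <- anchors(cr$anchorTable)
  expect_false(flg$collinear_best[flg$best_start == 500e6])
  expect_equal(sum(flg$collinear_best), 4L)
})

test_that("chains break on large query gaps and large subject jumps", {
  ## query gap > 2000 Kb between 5th and 6th anchor
  at <- simpleAT(c(100, 600, 1100, 4000, 4500, 5000),
                 c(10, 20, 30, 40, 50, 60) * 1e6)
  cr <- callCollinearChains(at)
  expect_equal(sort(cr$chains$n_anchors), c(3L, 3L))
  ## the optional subject-side bound splits chains on large subject jumps
  at2 <- simpleAT(c(100, 600, 1100, 1600, 2100, 2600),
                  c(10.0, 10.5, 11.0, 40.0, 40.5, 41.0) * 1e6)
  cr2 <- callCollinearChains(at2, maxSubjectGapKb = 2000)
  expect_equal(sort(cr2$chains$n_anchors), c(3L, 3L))
  ## by default the subject axis is unbounded and the chain stays whole
  cr3 <- callCollinearChains(at2)
  expect_equal(cr3$chains$n_anchors, 6L)
})

test_that("dynamic programming matches the exhaustive chain search", {
  set.seed(42)
  for (rep in 1:60) {
    n <- 18L
    pos <- sort(runif(n, 0, 12000))
    s <- sample(c(runif(n %/% 2, 0, 50e6),
                  sort(runif(n - n %/% 2, 0, 50e6))))
    mk <- sprintf("m%02d", seq_len(n))
    oracle <- bruteForceChainLength(pos, s, mk)
    up <- paleosyn:::.chainDP(pos, s, mk, 1, 2000, 200, 2)
    dn <- paleosyn:::.chainDP(pos, s, mk, -1, 2000, 200, 2)
    expect_equal(max(length(up), length(dn)), oracle)
  }
})

test_that("block filters enforce the gene-count and span rules", {
  mkChain <- function(pos_kb, genes) {
    pts <- data.frame(marker_id = sprintf("m%02d", seq_along(pos_kb)),
                      via = "best", gene_id = genes, pos_kb = pos_kb,
                      s_start = seq_along(pos_kb) * 1e6, chain_id = 1L,
                      stringsAsFactors = FALSE)
    list(chains = data.frame(chain_id = 1L, query_chrom = "Jr1",
                             subject_chrom = "S1", orientation = "+",
                             n_anchors = nrow(pts),
                             stringsAsFactors = FALSE),
         points = pts)
  }
  ## 2 distinct genes over 3 Mb: rejected on the gene-count rule
  two <- mkChain(c(0, 1500, 3000), c("gA", "gA", "gB"))
  expect_equal(nrow(blocks(filterBlocks(two))), 0L)
  ## 6 genes over 0.3 Mb: rejected on the span rule
  short <- mkChain(seq(0, 300, length.out = 6), sprintf("g%d", 1:6))
  expect_equal(nrow(blocks(filterBlocks(short))), 0L)
  ## 3 distinct genes over 0.6 Mb: boundary acceptance
  ok <- mkChain(c(0, 300, 600), c("gA", "gB", "gC"))
  expect_equal(nrow(blocks(filterBlocks(ok))), 1L)
})

test_that("parallel groups rank by span with the 50% overlap rule", {
  b <- rbind(blockRow("b1", "Jr1", 0, 5000, "S1", 0, 5e6),
             blockRow("b2", "Jr1", 1000, 4000, "S2", 0, 3e6))
  sbs <- classifyParallel(makeBlockSet(b))
  bb <- blocks(sbs)
  expect_equal(bb$rank[bb$block_id == "b1"], "primary")
  expect_equal(bb$rank[bb$block_id == "b2"], "secondary")
  expect_equal(length(unique(bb$group_id)), 1L)

  ## three mutually overlapping blocks rank primary/secondary/tertiary
  b3 <- rbind(b, blockRow("b3", "Jr1", 1500, 3500, "S3", 0, 2e6))
  bb3 <- blocks(classifyParallel(makeBlockSet(b3)))
  expect_equal(bb3$rank[order(bb3$block_id)],
               c("primary", "secondary", "tertiary"))

  ## 10% overlap of the shorter: two separate groups, both primary
  b10 <- rbind(blockRow("b1", "Jr1", 0, 5000, "S1", 0, 5e6),
               blockRow("b2", "Jr1", 4800, 6800, "S2", 0, 2e6))
  bb10 <- blocks(classifyParallel(makeBlockSet(b10)))
  expect_equal(unname(table(bb10$rank)["primary"]), 2L)
  expect_equal(length(unique(bb10$group_id)), 2L)
})

test_that("parallel grouping matches a direct overlap-fraction oracle", {
  set.seed(7)
  for (rep in 1:25) {
    n <- 6L
    lo <- runif(n, 0, 8000)
    hi <- lo + runif(n, 600, 4000)
    b <- do.call(rbind, lapply(seq_len(n), function(i)
      blockRow(sprintf("b%d", i), "Jr1", lo[i], hi[i],
               sprintf("S%d", i), 0, 1e6)))
    got <- blocks(suppressWarnings(classifyParallel(makeBlockSet(b))))
    ## oracle: union-find by pairwise overlap >= half the shorter span
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      ov <- min(hi[i], hi[j]) - max(lo[i], lo[j])
      if (i != j && ov > 0 && ov >= 0.5 * min(hi[i] - lo[i], hi[j] - lo[j]))
        parent[find(i)] <- find(j)
    }
    oracleGroups <- vapply(seq_len(n), find, 1L)
    gotGroups <- match(got$group_id[match(sprintf("b%d", 1:n),
                                          got$block_id)],
                       unique(got$group_id))
    expect_equal(length(unique(oracleGroups)), length(unique(gotGroups)))
    expect_true(all(outer(oracleGroups, oracleGroups, "==") ==
                    outer(gotGroups, gotGroups, "==")))
  }
})

test_that("synteny statistics reproduce the published Table 4 arithmetic", {
  t4 <- read.delim(system.file("extdata", "synteny_block_lengths.tsv",
                               package = "paleosyn"))
  total <- 736.070
  vv <- t4[t4$comparison == "Jr-Vv", ]
  expect_equal(round(100 * vv$primary_mb / total, 1), 81.5)
  expect_equal(round(100 * vv$secondary_mb / total, 1), 14.4)
  pt <- t4[t4$comparison == "Jr-Pt", ]
  expect_equal(round(pt$secondary_mb / pt$primary_mb, 2), 0.68)
  fv <- t4[t4$comparison == "Jr-Fv", ]
  expect_equal(round(fv$secondary_mb / fv$primary_mb, 2), 0.01)
})

test_that("synteny summary handles the degenerate empty case", {
  at <- simpleAT(c(100, 600), c(1e6, 2e6))
  sbs <- makeBlockSet(blockRow("b1", "Jr1", 0, 1000, "S1", 0, 1e6)[0, ])
  s <- syntenySummary(sbs, at, totalMtpMb = 10, nPseudomolecules = 5)
  expect_equal(s$n_blocks, 0L)
  expect_equal(s$sp_ratio, 0)
  expect_equal(s$pct_primary, 0)
  expect_error(syntenySummary(sbs, at, totalMtpMb = 0,
                              nPseudomolecules = 5), "positive")
})

test_that("synteny gaps respect coverage, thresholds and sharing", {
  full <- makeBlockSet(blockRow("b1", "Jr1", 0, 50000, "S1", 0, 5e7),
                       comparison = "A")
  expect_equal(nrow(findSyntenyGaps(list(full), c(Jr1 = 50000))), 0L)

  ## both comparisons leave 38.4-48.4 Mb uncovered: one shared gap there
  g1 <- makeBlockSet(rbind(blockRow("b1", "Jr1", 0, 38400, "S1", 0, 1e6),
                           blockRow("b2", "Jr1", 48400, 63400, "S2", 0, 1e6)),
                     comparison = "A")
  g2 <- makeBlockSet(rbind(blockRow("b1", "Jr1", 0, 38400, "S1", 0, 1e6),
                           blockRow("b2", "Jr1", 48400, 63400, "S2", 0, 1e6)),
                     comparison = "B")
  gaps <- findSyntenyGaps(list(g1, g2), c(Jr1 = 63400))
  expect_equal(nrow(gaps), 1L)
  expect_equal(gaps$lo_kb, 38400, tolerance = 1)
  expect_equal(gaps$hi_kb, 48400, tolerance = 1)
  expect_equal(gaps$comparisons_devoid, "A,B")

  ## a 0.8 Mb hole stays below the 1 Mb default threshold
  g3 <- makeBlockSet(rbind(blockRow("b1", "Jr1", 0, 10000, "S1", 0, 1e6),
                           blockRow("b2", "Jr1", 10800, 20000, "S2", 0, 1e6)),
                     comparison = "A")
  expect_equal(nrow(findSyntenyGaps(list(g3), c(Jr1 = 20000))), 0L)
})

test_that("chain anchors are monotone within each called block", {
  run <- fullAnalysis()
  aa <- blockAnchors(run$sbs)
  b <- blocks(run$sbs)
  jit <- run$sbs@params$jitterKb
  if (is.null(jit)) jit <- 200
  for (id in sample(b$block_id, min(25, nrow(b)))) {
    p <- aa[aa$block_id == id, ]
    p <- p[order(p$pos_kb), ]
    ori <- b$orientation[b$block_id == id]
    d <- diff(p$s_start) * (if (ori == "+") 1 else -1)
    ## violations only where query positions are within the jitter
    bad <- which(d <= 0)
    expect_true(all(diff(p$pos_kb)[bad] <= jit))
  }
})

test_that("rank order equals descending span within every parallel group", {
  run <- fullAnalysis()
  b <- blocks(run$sbs)
  for (g in unique(b$group_id)) {
    m <- b[b$group_id == g, ]
    m <- m[order(factor(m$rank, c("primary", "secondary", "tertiary")),
                 -(m$q_hi_kb - m$q_lo_kb)), ]
    spans <- m$q_hi_kb - m$q_lo_kb
    firstOfRank <- !duplicated(m$rank)
    expect_true(all(diff(spans[firstOfRank]) <= 1e-9))
  }
  expect_lte(run$stats$pct_primary, 100)
})
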