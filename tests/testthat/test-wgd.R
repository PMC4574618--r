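test_that("duplicated-block detection follows the overlap rule", {
  b <- rbind(blockRow("b1", "Jr1", 0, 10000, "Vv7", 10e6, 20e6),
             blockRow("b2", "Jr10", 0, 10000, "Vv7", 12e6, 22e6))
  d <- detectDuplicatedBlocks(makeBlockSet(b))
  expect_equal(nrow(d), 1L)
  expect_equal(d$overlap_lo_bp, 12e6)
  expect_equal(d$overlap_hi_bp, 20e6)

  ## same query chromosome: never a pair
  b2 <- b; b2$query_chrom <- "Jr1"
  expect_equal(nrow(detectDuplicatedBlocks(makeBlockSet(b2))), 0L)

  ## 20% overlap of the shorter with the 50% threshold: no pair
  b3 <- rbind(blockRow("b1", "Jr1", 0, 10000, "Vv7", 10e6, 20e6),
              blockRow("b2", "Jr10", 0, 10000, "Vv7", 18e6, 28e6))
  expect_equal(nrow(detectDuplicatedBlocks(makeBlockSet(b3))), 0L)
})

test_that("duplicated fraction counts markers in paired blocks", {
  b <- rbind(blockRow("b1", "Jr1", 0, 10000, "Vv7", 10e6, 20e6),
             blockRow("b2", "Jr10", 0, 10000, "Vv7", 10e6, 20e6),
             blockRow("b3", "Jr2", 0, 10000, "Vv1", 0, 10e6))
  aa <- data.frame(marker_id = sprintf("m%d", 1:9), via = "best",
                   gene_id = sprintf("g%d", 1:9),
                   pos_kb = rep(c(1, 2, 3), 3) * 1000,
                   s_start = rep(c(11e6, 14e6, 19e6), 3),
                   block_id = rep(c("b1", "b2", "b3"), each = 3),
                   stringsAsFactors = FALSE)
  sbs <- makeBlockSet(b, aa)
  d <- detectDuplicatedBlocks(sbs)
  expect_equal(duplicatedFraction(sbs, d), 100 * 6 / 9)
  expect_equal(duplicatedFraction(sbs, d[0, ]), 0)
  empty <- makeBlockSet(b, aa[0, ])
  expect_true(is.na(duplicatedFraction(empty, d)))
})

test_that("the homoeology matrix pairs chromosomes reciprocally", {
  ## two homoeologous chromosomes sharing one subject span, plus an
  ## unrelated chromosome
  b <- rbind(blockRow("b1", "Jr1", 0, 10000, "Vv7", 10e6, 20e6),
             blockRow("b2", "Jr10", 0, 10000, "Vv7", 10e6, 20e6),
             blockRow("b3", "Jr2", 0, 10000, "Vv1", 0, 10e6))
  aa <- data.frame(marker_id = sprintf("m%d", 1:9), via = "best",
                   gene_id = sprintf("g%d", 1:9),
                   pos_kb = rep(c(1, 2, 3), 3) * 1000,
                   s_start = rep(c(11e6, 14e6, 19e6), 3),
                   block_id = rep(c("b1", "b2", "b3"), each = 3),
                   stringsAsFactors = FALSE)
  sbs <- makeBlockSet(b, aa)
  hm <- homoeologueMatrix(sbs, detectDuplicatedBlocks(sbs))
  expect_equal(unname(hm@partner[["Jr1"]]), "Jr10")
  expect_equal(unname(hm@partner[["Jr10"]]), "Jr1")
  expect_true(hm@reciprocal[["Jr1"]])
  expect_true(is.na(hm@partner[["Jr2"]]))
  prs <- homoeologuePairs(hm)
  expect_equal(nrow(prs), 1L)

  hm0 <- homoeologueMatrix(sbs, detectDuplicatedBlocks(sbs)[0, ])
  expect_true(all(is.na(hm0@partner)))
})

test_that("WGD calls compare S/P ratios against the benchmark", {
  expect_true(wgdCall(0.68, 0.17)$wgd)
  expect_false(wgdCall(0.01, 0.17)$wgd)
  expect_false(wgdCall(0.17, 0.17)$wgd)
  expect_error(wgdCall(0.5, 0), "positive")
  expect_equal(wgdCall(0.34, 0.17)$margin, 1, tolerance = 1e-9)
})

test_that("alternation statistics behave at the extremes and under noise", {
  mkGroup <- function(vias) {
    n <- length(vias)
    b <- rbind(blockRow("p", "Jr1", 0, 10000, "Vv1", 0, 1e7, "primary"),
               blockRow("s", "Jr1", 0, 10000, "Vv2", 0, 1e7, "secondary"))
    b$group_id <- "g1"
    aa <- data.frame(marker_id = sprintf("m%02d", seq_len(n)), via = vias,
                     gene_id = sprintf("g%02d", seq_len(n)),
                     pos_kb = seq_len(n) * 100,
                     s_start = seq_len(n) * 1e5,
                     block_id = ifelse(vias == "best", "p", "s"),
                     stringsAsFactors = FALSE)
    makeBlockSet(b, aa)
  }
  perfect <- alternationTest(mkGroup(rep(c("best", "second"), 5)), "g1")
  expect_equal(perfect$proportion, 1)
  allBest <- alternationTest(mkGroup(rep("best", 8)), "g1")
  expect_equal(allBest$proportion, 0)
  tiny <- alternationTest(mkGroup(c("best", "second")), "g1")
  expect_true(tiny$insufficient)

  ## a random equal mixture has transition proportion near 1/2: compare
  ## the achieved rejection rate with the exact binomial expectation
  set.seed(11)
  props <- pvals <- numeric(200)
  for (i in 1:200) {
    r <- alternationTest(mkGroup(sample(rep(c("best", "second"), 10))), "g1")
    props[i] <- r$proportion
    pvals[i] <- r$p_value
  }
  ## a fixed 10+10 composition yields E[transitions] = 2*n1*n2/n = 10
  ## over 19 gaps, i.e. 0.526
  expect_lt(abs(mean(props) - 2 * 10 * 10 / 20 / 19), 0.03)
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("ancestral composition merges orders and tags single copies", {
  ## identical order, all shared somewhere else in the genome
  b <- rbind(blockRow("a1", "Jr1", 0, 3000, "Vv1", 0, 3e6),
             blockRow("a2", "Jr1", 3000, 6000, "Vv2", 0, 3e6),
             blockRow("a3", "Jr1", 6000, 9000, "Vv3", 0, 3e6),
             blockRow("b1", "Jr10", 0, 2000, "Vv1", 0, 3e6),
             blockRow("b2", "Jr10", 2000, 4000, "Vv2", 0, 3e6),
             blockRow("b3", "Jr10", 4000, 6000, "Vv3", 0, 3e6))
  ac <- ancestralComposition("Jr1", "Jr10", makeBlockSet(b))
  expect_equal(ac$sequence, c("Vv1", "Vv2", "Vv3"))
  expect_false(any(ac$single_copy))
  expect_false(ac$conflict)

  ## one member carries an extra block absent genome-wide: parenthesized
  bx <- rbind(b, blockRow("bx", "Jr10", 2500, 3500, "Vv9", 0, 1e6))
  acx <- ancestralComposition("Jr1", "Jr10", makeBlockSet(bx))
  expect_true("Vv9" %in% acx$sequence)
  expect_true(acx$single_copy[acx$sequence == "Vv9"])
  expect_match(acx$text, "\\(Vv9\\)")
  ## insertion lands between its flanking shared blocks
  expect_equal(which(acx$sequence == "Vv9"), 3L)
})

test_that("a simulated WGD pair recovers its ancestral block order", {
  run <- fullAnalysis()
  hm <- homoeologueMatrix(run$sbs, detectDuplicatedBlocks(run$sbs))
  truth <- run$sim$truth$homoeoPairsQuery
  pr <- truth[1, ]
  ac <- ancestralComposition(pr$chrom_a, pr$chrom_b, run$sbs)
  expect_gt(length(ac$sequence), 0)
  ## homoeologues derive from one ancestral chromosome: their block labels
  ## must overlap substantially
  b <- blocks(run$sbs)
  la <- unique(b$subject_chrom[b$query_chrom == pr$chrom_a &
                               b$rank == "primary"])
  lb <- unique(b$subject_chrom[b$query_chrom == pr$chrom_b &
                               b$rank == "primary"])
  expect_gt(length(intersect(la, lb)), 0)
})

test_that("a heavily deleted homoeologue loses reciprocity", {
  scn <- evolutionScenario(seed = 103L)
  sim <- simulateComparison(scn, "benchmark", mutateQuery = function(g)
    deleteChromSegment(g, 15L, 0.9))
  top <- selectTopTwoHits(sim$hits, sim$genes)
  at <- buildAnchorTable(sim$markers, top, "benchmark")
  syn <- suppressWarnings(
    analyzeSynteny(at, "Q-benchmark", sim$totalMtpMb, sim$subjectNChrom))
  hm <- homoeologueMatrix(syn$blockSet, detectDuplicatedBlocks(syn$blockSet))
  ## the shrunken chromosome still points at its true partner, but the
  ## partner's row is dominated by other chromosomes (non-reciprocal),
  ## mirroring the short-homoeologue anomaly
  truth <- sim$truth$homoeoPairsQuery
  small <- "Q15"
  partnerOfSmall <- c(truth$chrom_b[truth$chrom_a == small],
                      truth$chrom_a[truth$chrom_b == small])
  expect_false(isTRUE(hm@reciprocal[[partnerOfSmall]]) &&
               isTRUE(hm@reciprocal[[small]]) &&
               hm@partner[[small]] == partnerOfSmall &&
               hm@partner[[partnerOfSmall]] == small)
})
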