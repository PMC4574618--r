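test_that("scenarios validate their parameters", {
  expect_s4_class(evolutionScenario(), "EvolutionScenario")
  expect_error(evolutionScenario(bogus = 1), "unknown scenario")
  expect_error(evolutionScenario(lossRate = -1), "non-negative")
  expect_error(evolutionScenario(
    wgdEvents = data.frame(lineage = "query", time_mya = 150)),
    "older than the query branch")
  expect_error(evolutionScenario(
    wgdEvents = data.frame(lineage = "nosuch", time_mya = 10)),
    "without a split time")
})

test_that("the ancestor is deterministic and correctly structured", {
  scn <- evolutionScenario(seed = 5L, genesPerChrom = 120L)
  a1 <- simulateAncestor(scn)
  a2 <- simulateAncestor(scn)
  expect_identical(a1$chroms, a2$chroms)
  expect_equal(length(a1$chroms), 8L)
  ## one centromere per chromosome near the configured relative position
  for (df in a1$chroms) {
    expect_equal(sum(df$is_cen), 1L)
    expect_equal(which(df$is_cen) / nrow(df), 0.45, tolerance = 0.1)
  }
  ## unique gene ids genome-wide
  ids <- unlist(lapply(a1$chroms, function(d) d$gene_id[!d$is_cen]))
  expect_false(anyDuplicated(ids) > 0)
  ## ancient duplicate fraction near the configured retention (small
  ## genomes carry few retention runs, so the bound is loose)
  anc <- unlist(lapply(a1$chroms, function(d) d$anc[!d$is_cen]))
  both <- mean(table(anc) == 2)
  expect_gt(both, 0.03)
  expect_lt(both, 0.22)
})

test_that("a WGD doubles the chromosomes with exact 1:1 paralogy", {
  scn <- evolutionScenario(seed = 5L, genesPerChrom = 100L,
    lossRate = 0, duplicateLossRate = 0, transpositionRate = 0,
    inversionRate = 0, translocationRate = 0)
  anc <- simulateAncestor(scn)
  q <- evolveLineage(anc, scn, "query")
  expect_equal(length(q$chroms), 16L)
  expect_equal(nrow(q$homoeo), 8L)
  g <- finalizeGenome(q, "Q", scn)$genes
  g <- g[!g$is_cen, ]
  expect_true(all(table(paste(g$anc, g$gcopy)) == 2L))
})

test_that("gene counts reconcile exactly with the event log", {
  ## WGD at the branch start so every logged loss happens after doubling
  scn <- evolutionScenario(seed = 9L, genesPerChrom = 150L,
    wgdEvents = data.frame(lineage = "query", time_mya = 100))
  anc <- simulateAncestor(scn)
  q <- evolveLineage(anc, scn, "query")
  n0 <- sum(vapply(anc$chroms, function(d) sum(!d$is_cen), 1L))
  lost <- sum(as.integer(sub(" genes lost", "",
                             q$events$detail[q$events$type == "loss"])))
  n1 <- sum(vapply(q$chroms, function(d) sum(!d$is_cen), 1L))
  expect_equal(n1, 2L * n0 - lost)
})

test_that("dysploid fusion reduces the chromosome number by one", {
  scn <- evolutionScenario(seed = 5L, genesPerChrom = 100L,
    fusionEvents = data.frame(lineage = "benchmark", time_mya = 50))
  anc <- simulateAncestor(scn)
  s <- evolveLineage(anc, scn, "benchmark")
  expect_equal(length(s$chroms), 7L)
  expect_equal(sum(s$events$type == "fusion"), 1L)
  ## a fused chromosome keeps a single centromere
  for (df in s$chroms) expect_equal(sum(df$is_cen), 1L)
})

test_that("inversion counts follow the Poisson process", {
  scn <- evolutionScenario(seed = 1L, genesPerChrom = 40L,
    lossRate = 0, duplicateLossRate = 0, transpositionRate = 0,
    translocationRate = 0, inversionRate = 0.5,
    wgdEvents = data.frame(lineage = character(), time_mya = numeric()),
    splitTimesMya = c(benchmark = 20))
  anc <- simulateAncestor(scn)
  counts <- vapply(1:200, function(k) {
    scnK <- evolutionScenario(seed = k, genesPerChrom = 40L,
      lossRate = 0, duplicateLossRate = 0, transpositionRate = 0,
      translocationRate = 0, inversionRate = 0.5,
      wgdEvents = data.frame(lineage = character(), time_mya = numeric()),
      splitTimesMya = c(benchmark = 20))
    g <- evolveLineage(anc, scnK, "benchmark")
    sum(g$events$type == "inversion")
  }, 1L)
  lambda <- 0.5 * 20
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("identical scenario and seed reproduce identical observations", {
  scn <- evolutionScenario(seed = 31L, genesPerChrom = 300L)
  s1 <- simulateComparison(scn, "benchmark")
  s2 <- simulateComparison(scn, "benchmark")
  expect_identical(s1$markers, s2$markers)
  expect_identical(s1$hits, s2$hits)
  expect_identical(s1$truth$centromeresMb, s2$truth$centromeresMb)
})

test_that("observation model: jitter bound, exonic markers, cen exclusion", {
  run <- fullAnalysis()
  sim <- run$sim
  scn <- run$scn
  m <- sim$markers
  expect_true(all(m$exonic))
  ## markers avoid the pericentromeric zone (up to one jitter width)
  cen <- sim$truth$centromeresMb
  cenOf <- setNames(cen$cen_mb, cen$chrom)
  d <- abs(m$pos_kb / 1000 - cenOf[m$chrom])
  expect_true(all(d > scn@cenHalfwidthMb - scn@jitterKb / 1000 - 1e-9))
  ## genetic positions are monotone along each chromosome
  for (ch in unique(m$chrom)) {
    cm <- m$cm[m$chrom == ch]
    cm <- cm[!is.na(cm)]
    expect_true(!is.unsorted(cm))
  }
  ## mapped fraction near the configured value
  expect_lt(abs(mean(!is.na(m$cm)) - scn@markerMappedFrac), 0.01)
  ## density below the target only through centromere exclusion
  dens <- nrow(m) / sim$totalMtpMb
  expect_gt(dens, 0.6 * scn@markerDensityPerMb)
  expect_lt(dens, 1.1 * scn@markerDensityPerMb)
})

test_that("zero-divergence hits point at the true orthologue", {
  scn <- evolutionScenario(seed = 13L, genesPerChrom = 200L,
    lossRate = 0, duplicateLossRate = 0, transpositionRate = 0,
    inversionRate = 0, translocationRate = 0, spuriousHitRate = 0,
    ancientRetention = 0, tauOpaqueMy = Inf,
    wgdEvents = data.frame(lineage = character(), time_mya = numeric()),
    splitTimesMya = c(benchmark = 1), queryBranchMya = 1)
  sim <- simulateComparison(scn, "benchmark")
  top <- selectTopTwoHits(sim$hits, sim$genes)
  tr <- sim$truth$orthology
  best <- setNames(top$best_gene, top$marker_id)
  expect_true(all(best[tr$marker_id] == tr$gene_id, na.rm = TRUE))
})

test_that("a clean no-WGD genome yields one full primary block per chromosome", {
  scn <- evolutionScenario(seed = 17L, genesPerChrom = 400L,
    lossRate = 0, duplicateLossRate = 0, transpositionRate = 0,
    inversionRate = 0, translocationRate = 0, spuriousHitRate = 0,
    ancientRetention = 0, tauOpaqueMy = Inf, cenHalfwidthMb = 0,
    wgdEvents = data.frame(lineage = character(), time_mya = numeric()),
    splitTimesMya = c(benchmark = 5), queryBranchMya = 5)
  sim <- simulateComparison(scn, "benchmark")
  top <- selectTopTwoHits(sim$hits, sim$genes)
  at <- buildAnchorTable(sim$markers, top, "benchmark")
  syn <- analyzeSynteny(at, "clean", sim$totalMtpMb, sim$subjectNChrom)
  b <- blocks(syn$blockSet)
  prim <- b[b$rank == "primary", ]
  expect_equal(nrow(prim), length(unique(sim$markers$chrom)))
  expect_lt(syn$stats$sp_ratio, 0.05)
  ## each primary block holds at least 95% of its chromosome's markers
  aa <- blockAnchors(syn$blockSet)
  for (k in seq_len(nrow(prim))) {
    ch <- prim$query_chrom[k]
    nIn <- sum(aa$block_id == prim$block_id[k])
    expect_gte(nIn / sum(sim$markers$chrom == ch), 0.95)
  }
})

test_that("subject-lineage WGD shows parallel blocks; query WGD duplicates", {
  ## subject WGD: parallel tracks on single query chromosomes
  rt <- fullAnalysis(seed = 101L, subject = "test")
  bt <- blocks(rt$sbs)
  expect_gt(sum(bt$rank == "secondary"), 10)
  expect_gt(rt$stats$sp_ratio, 0.4)
  ## query WGD: the same subject interval hit from two query chromosomes
  rb <- fullAnalysis(seed = 101L, subject = "benchmark")
  dup <- detectDuplicatedBlocks(rb$sbs)
  expect_gt(nrow(dup), 0)
  expect_gt(duplicatedFraction(rb$sbs, dup), 70)
})

test_that("duplicated fraction falls with growing post-WGD segmental loss", {
  ## interleaved single-gene loss leaves block spans co-extensive, so the
  ## lever on the duplicated fraction is segmental deletion of the
  ## duplicate copies, increasing along the grid
  fractions <- vapply(c(0, 0.35, 0.7), function(frac) {
    scn <- evolutionScenario(seed = 23L, genesPerChrom = 500L)
    sim <- simulateComparison(scn, "benchmark", mutateQuery = function(g) {
      if (frac > 0) for (i in 9:16) g <- deleteChromSegment(g, i, frac)
      g
    })
    top <- selectTopTwoHits(sim$hits, sim$genes)
    at <- buildAnchorTable(sim$markers, top, "benchmark")
    syn <- suppressWarnings(
      analyzeSynteny(at, "x", sim$totalMtpMb, sim$subjectNChrom))
    duplicatedFraction(syn$blockSet, detectDuplicatedBlocks(syn$blockSet))
  }, 1)
  expect_true(all(diff(fractions) < 0))
  expect_lt(fractions[3], fractions[1] - 10)
})
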