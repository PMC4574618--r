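#' Construct a genome-evolution scenario
#'
#' The default scenario mirrors the walnut-style study design: an x = 8
#' ancestor of ~20,800 genes spaced one per 40 Kb, whose whole-genome
#' duplication at 60 MYA followed by duplicate-biased fractionation leaves
#' a ~736 Mb query genome of 16 chromosomes carrying ~11,500 markers
#' (20 per Mb outside the pericentromeric zones).
#' Every lineage inherits the clustered remnants of an ancient (130 MYA,
#' pre-split) duplication — the gamma-like baseline duplication state; the
#' `benchmark` subject has no later WGD (a grape-like comparison) while
#' the `test` subject carries a recent (65 MYA, post-split) WGD.  Markers
#' are sampled at ~20 per Mb with their physical order known only to one
#' BAC length (200 Kb jitter); a tenth of them carry genetic positions
#' from a centromere-suppressed recombination profile with distal and
#' pericentromeric intensities of 2.5 and 0.63 cM/Mb.
#'
#' @param seed master seed; with the scenario it determines every output.
#' @param ... any scenario slot to override (see
#'   [EvolutionScenario-class]).
#' @return an [EvolutionScenario-class] object.
#' @export
evolutionScenario <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    seed = as.integer(seed),
    nChromAncestor = 8L,
    genesPerChrom = 2150L,
    chromSizeSpread = c(0.6, 1.4),
    bpPerGene = 40000L,
    queryBranchMya = 100,
    splitTimesMya = c(benchmark = 110, test = 105),
    wgdEvents = data.frame(
      lineage = c("query", "test"),
      time_mya = c(60, 65), stringsAsFactors = FALSE),
    fusionEvents = data.frame(lineage = character(), time_mya = numeric(),
                              stringsAsFactors = FALSE),
    lossRate = 0.002,
    duplicateLossRate = 0.01,
    transpositionRate = 1e-4,
    inversionRate = 0.5,
    translocationRate = 0.005,
    invMeanGenes = 20,
    gammaMya = 130,
    ancientRetention = 0.10,
    retainedRunGenes = 25,
    rTrue = 2.29e-9,
    tauOpaqueMy = 600,
    opaqueRunGenes = 80,
    markerDensityPerMb = 20,
    markerMappedFrac = 0.1,
    jitterKb = 200,
    cenRelPos = 0.45,
    cenHalfwidthMb = 5,
    rampMb = 5,
    baseDistalCmPerMb = 2.5,
    basePericenCmPerMb = 0.63,
    spuriousHitRate = 0.02)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("unknown scenario parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(args)] <- args
  defaults$seed <- as.integer(defaults$seed)
  defaults$nChromAncestor <- as.integer(defaults$nChromAncestor)
  defaults$genesPerChrom <- as.integer(defaults$genesPerChrom)
  defaults$bpPerGene <- as.integer(defaults$bpPerGene)
  do.call(new, c(list("EvolutionScenario"), defaults))
}

## deterministic per-lineage sub-seed (kept well below 2^31)
.lineageSeed <- function(scn, lineage, salt = 0L) {
  h <- sum(utf8ToInt(lineage)) %% 1000L
  as.integer((as.numeric(scn@seed) * 7919 + h * 131 + salt) %% 2147483647)
}

#' Simulate the ancestral genome
#'
#' The ancestor is built as the fractionated remnant of an ancient
#' duplication that predates every lineage split (the baseline duplication
#' state shared by all descendants, such as the gamma event in the grape
#' comparison): `nChromAncestor/2` proto-chromosomes are duplicated and
#' then fractionated in clustered runs — segments of mean
#' `retainedRunGenes` genes keep both copies at stationary fraction
#' `ancientRetention`, the remainder keeps a single copy on one member of
#' the pair.  Every gene carries its duplication-copy tag (`gcopy`), which
#' downstream determines whether two genes are orthologues (same copy,
#' divergence = the split) or ancient paralogues (divergence = the
#' duplication age).  One centromere token sits at `cenRelPos` of each
#' chromosome.  Chromosome gene numbers spread deterministically over
#' `chromSizeSpread` times the mean so chromosomes differ in length.
#'
#' @param scn an [EvolutionScenario-class].
#' @return internal genome object (list of per-chromosome gene tables).
#' @export
simulateAncestor <- function(scn) {
  n <- scn@nChromAncestor
  if (n %% 2L != 0L)
    stop("nChromAncestor must be even (ancient duplication pairs)")
  set.seed(.lineageSeed(scn, "ancestor", salt = 3L))
  nProto <- n %/% 2L
  rA <- scn@ancientRetention
  eff <- rA + (1 - rA) / 2
  protoSizes <- round(scn@genesPerChrom / eff *
                      seq(scn@chromSizeSpread[1], scn@chromSizeSpread[2],
                          length.out = nProto))
  chroms <- list()
  nextAnc <- 1L
  addCen <- function(df, uid) {
    cenAt <- max(1L, round(scn@cenRelPos * nrow(df)))
    df <- rbind(df[seq_len(cenAt), ],
                data.frame(gene_id = paste0("cen_u", uid), anc = NA_integer_,
                           gcopy = NA_integer_, is_cen = TRUE,
                           stringsAsFactors = FALSE),
                df[-seq_len(cenAt), ])
    rownames(df) <- NULL
    df
  }
  gammaPairs <- data.frame(uid_a = integer(), uid_b = integer())
  for (p in seq_len(nProto)) {
    sz <- protoSizes[p]
    anc <- seq.int(nextAnc, nextAnc + sz - 1L)
    nextAnc <- nextAnc + sz
    ## clustered retention: alternate runs of both-copy and single-copy
    ## states; run lengths are capped for very small chromosomes so both
    ## copies always receive genes, preserving the stationary retention
    runBoth <- scn@retainedRunGenes
    runSingle <- if (rA > 1e-6) runBoth * (1 - rA) / rA else runBoth
    if (runSingle > sz / 8) {
      runSingle <- max(2, sz / 8)
      if (rA > 1e-6) runBoth <- max(1, runSingle * rA / (1 - rA))
    }
    state <- integer(0)        # 0 = both, 1 = copy-1 only, 2 = copy-2 only
    while (length(state) < sz) {
      if (rA > 1e-6) {
        lenS <- 1L + stats::rpois(1L, max(0, runSingle - 1))
        state <- c(state, rep(sample(1:2, 1L), lenS))
        lenB <- 1L + stats::rpois(1L, max(0, runBoth - 1))
        state <- c(state, rep(0L, lenB))
      } else {
        lenS <- 1L + stats::rpois(1L, max(0, runBoth - 1))
        state <- c(state, rep(sample(1:2, 1L), lenS))
      }
    }
    state <- state[seq_len(sz)]
    mk <- function(copy) {
      keep <- state == 0L | state == copy
      data.frame(gene_id = sprintf("anc_g%05d.%d", anc[keep], copy),
                 anc = anc[keep], gcopy = rep(copy, sum(keep)),
                 is_cen = rep(FALSE, sum(keep)),
                 stringsAsFactors = FALSE)
    }
    ua <- 2L * p - 1L; ub <- 2L * p
    chroms[[ua]] <- addCen(mk(1L), ua)
    chroms[[ub]] <- addCen(mk(2L), ub)
    gammaPairs <- rbind(gammaPairs, data.frame(uid_a = ua, uid_b = ub))
  }
  list(lineage = "ancestor", chroms = chroms,
       uids = seq_len(n), nextUid = n + 1L,
       homoeo = data.frame(uid_a = integer(), uid_b = integer(),
                           time_mya = numeric()),
       gammaPairs = gammaPairs,
       events = data.frame(type = character(), time_mya = numeric(),
                           detail = character(), stringsAsFactors = FALSE),
       nextGene = 1L)
}

.logEvent <- function(g, type, time, detail) {
  g$events <- rbind(g$events, data.frame(type = type, time_mya = time,
                                         detail = detail,
                                         stringsAsFactors = FALSE))
  g
}

.applyWgd <- function(g, scn, time, lineage) {
  nOld <- length(g$chroms)
  for (i in seq_len(nOld)) {
    df <- g$chroms[[i]]
    dup <- df
    ngene <- sum(!df$is_cen)
    dup$gene_id[!dup$is_cen] <- sprintf("%s_g%06d", lineage,
      seq.int(g$nextGene, g$nextGene + ngene - 1L))
    g$nextGene <- g$nextGene + ngene
    dup$gene_id[dup$is_cen] <- paste0("cen_u", g$nextUid)
    g$chroms[[nOld + i]] <- dup
    g$uids[nOld + i] <- g$nextUid
    g$homoeo <- rbind(g$homoeo,
      data.frame(uid_a = g$uids[i], uid_b = g$nextUid, time_mya = time))
    g$nextUid <- g$nextUid + 1L
  }
  .logEvent(g, "wgd", time, sprintf("%d -> %d chromosomes", nOld, 2L * nOld))
}

.applyFusion <- function(g, time) {
  if (length(g$chroms) < 2L)
    stop("fusion requested with fewer than 2 chromosomes")
  pick <- sample(length(g$chroms), 2L)
  a <- g$chroms[[pick[1]]]; b <- g$chroms[[pick[2]]]
  joined <- rbind(a, b)
  cenRows <- which(joined$is_cen)
  if (length(cenRows) > 1L) joined <- joined[-cenRows[-1L], ]
  rownames(joined) <- NULL
  g$chroms[[pick[1]]] <- joined
  g$chroms <- g$chroms[-pick[2]]
  g$uids <- g$uids[-pick[2]]
  .logEvent(g, "fusion", time, sprintf("chrom uids merged"))
}

.applyInversion <- function(g, scn, time) {
  sizes <- vapply(g$chroms, nrow, integer(1))
  ci <- sample(length(g$chroms), 1L, prob = sizes)
  n <- sizes[ci]
  len <- min(n, 1L + stats::rgeom(1L, 1 / scn@invMeanGenes))
  start <- sample(max(1L, n - len + 1L), 1L)
  idx <- start:(start + len - 1L)
  g$chroms[[ci]][idx, ] <- g$chroms[[ci]][rev(idx), ]
  .logEvent(g, "inversion", time, sprintf("uid %d: %d genes", g$uids[ci], len))
}

.applyTranslocation <- function(g, time) {
  if (length(g$chroms) < 2L) return(g)
  pick <- sample(length(g$chroms), 2L)
  a <- g$chroms[[pick[1]]]; b <- g$chroms[[pick[2]]]
  if (nrow(a) < 2L || nrow(b) < 2L) return(g)
  ## reciprocal exchange of terminal arms distal to the centromere, so
  ## each product keeps exactly one centromere
  cenA <- which(a$is_cen)[1L]
  cenB <- which(b$is_cen)[1L]
  if (is.na(cenA)) cenA <- 1L
  if (is.na(cenB)) cenB <- 1L
  if (cenA > nrow(a) - 1L || cenB > nrow(b) - 1L) return(g)
  ba <- if (cenA == nrow(a) - 1L) cenA else
    sample(cenA:(nrow(a) - 1L), 1L)
  bb <- if (cenB == nrow(b) - 1L) cenB else
    sample(cenB:(nrow(b) - 1L), 1L)
  newA <- rbind(a[seq_len(ba), ], b[-seq_len(bb), ])
  newB <- rbind(b[seq_len(bb), ], a[-seq_len(ba), ])
  rownames(newA) <- rownames(newB) <- NULL
  g$chroms[[pick[1]]] <- newA
  g$chroms[[pick[2]]] <- newB
  .logEvent(g, "translocation", time,
            sprintf("uids %d/%d tails swapped", g$uids[pick[1]],
                    g$uids[pick[2]]))
}

.applyLoss <- function(g, scn, dt, time) {
  all <- do.call(rbind, lapply(seq_along(g$chroms), function(i)
    data.frame(ci = i, ri = seq_len(nrow(g$chroms[[i]])),
               anc = g$chroms[[i]]$anc, gcopy = g$chroms[[i]]$gcopy,
               is_cen = g$chroms[[i]]$is_cen)))
  cand <- all[!all$is_cen, , drop = FALSE]
  ## fractionation acts on duplicates of lineage WGDs (same ancient-copy
  ## tag); ancient duplicate pairs that survived to the ancestor are
  ## treated as retained for good and only see the background rate
  key <- paste(cand$anc, cand$gcopy)
  copies <- table(key)
  dupGene <- copies[key] >= 2L
  rate <- scn@lossRate + ifelse(dupGene, scn@duplicateLossRate, 0)
  lost <- stats::runif(nrow(cand)) < (1 - exp(-rate * dt))
  if (!any(lost)) return(g)
  byChrom <- split(cand$ri[lost], cand$ci[lost])
  for (ci in names(byChrom)) {
    ii <- as.integer(ci)
    g$chroms[[ii]] <- g$chroms[[ii]][-byChrom[[ci]], , drop = FALSE]
    rownames(g$chroms[[ii]]) <- NULL
  }
  .logEvent(g, "loss", time, sprintf("%d genes lost", sum(lost)))
}

.applyTransposition <- function(g, time) {
  sizes <- vapply(g$chroms, nrow, integer(1))
  ci <- sample(length(g$chroms), 1L, prob = sizes)
  df <- g$chroms[[ci]]
  nc <- which(!df$is_cen)
  if (!length(nc)) return(g)
  ri <- sample(nc, 1L)
  row <- df[ri, , drop = FALSE]
  df <- df[-ri, , drop = FALSE]
  g$chroms[[ci]] <- df
  cj <- sample(length(g$chroms), 1L)
  tgt <- g$chroms[[cj]]
  at <- sample(nrow(tgt) + 1L, 1L) - 1L
  top <- if (at > 0L) tgt[seq_len(at), , drop = FALSE] else
    tgt[0L, , drop = FALSE]
  bot <- if (at < nrow(tgt)) tgt[(at + 1L):nrow(tgt), , drop = FALSE] else
    tgt[0L, , drop = FALSE]
  g$chroms[[cj]] <- rbind(top, row, bot)
  rownames(g$chroms[[cj]]) <- NULL
  .logEvent(g, "transposition", time, row$gene_id)
}

#' Evolve one lineage from the ancestor
#'
#' Rearrangements and losses are drawn as Poisson processes over the
#' branch; WGD and dysploid-fusion events happen at their scheduled times.
#' The branch is processed in time slices of at most 5 MY so that
#' duplicate-biased fractionation responds to the changing copy number of
#' each ancestral gene.  The result is deterministic given the scenario
#' seed and lineage name.
#'
#' @param ancestor genome from [simulateAncestor()].
#' @param scn the scenario.
#' @param lineage `"query"` or a name of `splitTimesMya`.
#' @return internal genome object with its event log and homoeologue
#'   truth.
#' @export
evolveLineage <- function(ancestor, scn, lineage) {
  duration <- if (lineage == "query") scn@queryBranchMya else {
    if (!lineage %in% names(scn@splitTimesMya))
      stop("unknown lineage: ", lineage)
    scn@splitTimesMya[[lineage]]
  }
  set.seed(.lineageSeed(scn, lineage))
  g <- ancestor
  g$lineage <- lineage
  pickEvents <- function(df, what) {
    df <- df[df$lineage == lineage, , drop = FALSE]
    if (!nrow(df)) return(NULL)
    cbind(df, what = what)
  }
  fixed <- rbind(pickEvents(scn@wgdEvents, "wgd"),
                 pickEvents(scn@fusionEvents, "fusion"))
  fixed <- if (is.null(fixed)) data.frame(time_mya = numeric(),
                                          what = character()) else
    fixed[order(-fixed$time_mya), , drop = FALSE]
  bounds <- sort(unique(c(duration, fixed$time_mya, 0)), decreasing = TRUE)
  for (b in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[b]; t1 <- bounds[b + 1L]
    ## fixed events scheduled at the start of this slice
    for (k in which(abs(fixed$time_mya - t0) < 1e-9)) {
      g <- if (fixed$what[k] == "wgd") .applyWgd(g, scn, t0, lineage)
           else .applyFusion(g, t0)
    }
    cuts <- seq(t0, t1, by = -min(5, t0 - t1))
    if (cuts[length(cuts)] > t1) cuts <- c(cuts, t1)
    for (s in seq_len(length(cuts) - 1L)) {
      dt <- cuts[s] - cuts[s + 1L]
      tm <- cuts[s]
      g <- .applyLoss(g, scn, dt, tm)
      nGenes <- sum(vapply(g$chroms, function(d) sum(!d$is_cen), integer(1)))
      for (dummy in seq_len(stats::rpois(1L, scn@inversionRate * dt)))
        g <- .applyInversion(g, scn, tm)
      for (dummy in seq_len(stats::rpois(1L, scn@translocationRate * dt)))
        g <- .applyTranslocation(g, tm)
      for (dummy in seq_len(stats::rpois(1L,
                                         scn@transpositionRate * nGenes * dt)))
        g <- .applyTransposition(g, tm)
    }
  }
  g
}

#' Lay a genome onto physical coordinates
#'
#' @param genome internal genome object.
#' @param prefix chromosome label prefix (e.g. `"Q"` or `"S"`).
#' @param scn the scenario (for `bpPerGene`).
#' @return list: `genes` data.frame (chrom, pos_bp, gene_id, anc, is_cen),
#'   `chromLengthsMb` named numeric, `centromeresMb` data.frame,
#'   `homoeoPairs` data.frame of final chromosome labels.
#' @export
finalizeGenome <- function(genome, prefix, scn) {
  labels <- paste0(prefix, seq_along(genome$chroms))
  names(labels) <- as.character(genome$uids)
  rows <- lapply(seq_along(genome$chroms), function(i) {
    df <- genome$chroms[[i]]
    data.frame(chrom = labels[[as.character(genome$uids[i])]],
               pos_bp = (seq_len(nrow(df)) - 1L) * as.numeric(scn@bpPerGene),
               gene_id = df$gene_id, anc = df$anc, gcopy = df$gcopy,
               is_cen = df$is_cen, stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  lens <- vapply(genome$chroms, nrow, integer(1)) *
    as.numeric(scn@bpPerGene) / 1e6
  names(lens) <- labels
  cen <- genes[genes$is_cen, c("chrom", "pos_bp")]
  cen$cen_mb <- cen$pos_bp / 1e6
  cen$lo_mb <- pmax(0, cen$cen_mb - scn@cenHalfwidthMb)
  cen$hi_mb <- pmin(lens[cen$chrom], cen$cen_mb + scn@cenHalfwidthMb)
  cen$pos_bp <- NULL
  rownames(cen) <- NULL
  hp <- genome$homoeo
  homoeoPairs <- if (nrow(hp)) {
    keep <- as.character(hp$uid_a) %in% names(labels) &
            as.character(hp$uid_b) %in% names(labels)
    data.frame(chrom_a = labels[as.character(hp$uid_a[keep])],
               chrom_b = labels[as.character(hp$uid_b[keep])],
               time_mya = hp$time_mya[keep], stringsAsFactors = FALSE)
  } else data.frame(chrom_a = character(), chrom_b = character(),
                    time_mya = numeric(), stringsAsFactors = FALSE)
  rownames(homoeoPairs) <- NULL
  list(genes = genes, chromLengthsMb = lens, centromeresMb = cen,
       homoeoPairs = homoeoPairs)
}

## cumulative integral of the piecewise-linear recombination intensity
.geneticPosition <- function(posMb, cenMb, lenMb, scn) {
  hw <- scn@cenHalfwidthMb
  ramp <- scn@rampMb
  hi <- scn@baseDistalCmPerMb
  lo <- scn@basePericenCmPerMb
  kx <- c(0, cenMb - hw - ramp, cenMb - hw, cenMb + hw, cenMb + hw + ramp,
          lenMb)
  ky <- c(hi, hi, lo, lo, hi, hi)
  dupk <- duplicated(kx)
  kx <- kx[!dupk]; ky <- ky[!dupk]
  ok <- kx >= 0 & kx <= lenMb
  kx2 <- c(0, kx[ok], lenMb)
  ky2 <- stats::approx(kx, ky, xout = kx2, rule = 2)$y
  o <- order(kx2)
  kx2 <- kx2[o]; ky2 <- ky2[o]
  keep <- !duplicated(kx2)
  kx2 <- kx2[keep]; ky2 <- ky2[keep]
  cum <- c(0, cumsum(diff(kx2) * (utils::head(ky2, -1) +
                                  utils::tail(ky2, -1)) / 2))
  iy <- stats::approx(kx2, ky2, xout = posMb, rule = 2)$y
  seg <- findInterval(posMb, kx2, rightmost.closed = TRUE)
  seg[seg < 1L] <- 1L
  x0 <- kx2[seg]; y0 <- ky2[seg]
  cum[seg] + (posMb - x0) * (y0 + iy) / 2
}

#' Simulate one full genome comparison
#'
#' Evolves the query and one subject lineage from a common ancestor and
#' emits the complete observation set the analysis pipeline consumes:
#' the ordered marker map with jittered physical positions and partial
#' genetic positions, the subject gene annotation, the homology hits with
#' rank-consistent scores, plus the ground truth (orthology, homoeologue
#' pairs, centromeres, event logs).  Markers are exonic BAC-end analogues;
#' none are sampled inside the pericentromeric zone, which is how the
#' repeat-rich centromere manifests as a synteny gap.
#'
#' @param scn an [EvolutionScenario-class].
#' @param subject name of the subject lineage (default `"benchmark"`).
#' @param mutateQuery optional function applied to the evolved query
#'   genome before observation (e.g. [deleteChromSegment()] for a
#'   shrunken-homoeologue scenario).
#' @return list: `markers`, `genes` (GRanges), `hits`, `truth`,
#'   `queryChromLengthsMb`, `subjectNChrom`, `totalMtpMb`, `scenario`,
#'   `subject`.
#' @export
simulateComparison <- function(scn, subject = "benchmark",
                               mutateQuery = NULL) {
  ancestor <- simulateAncestor(scn)
  q <- evolveLineage(ancestor, scn, "query")
  if (!is.null(mutateQuery)) q <- mutateQuery(q)
  s <- evolveLineage(ancestor, scn, subject)
  qg <- finalizeGenome(q, "Q", scn)
  sg <- finalizeGenome(s, "S", scn)
  set.seed(.lineageSeed(scn, paste0("obs_", subject), salt = 17L))
  div <- scn@queryBranchMya + scn@splitTimesMya[[subject]]

  genes <- qg$genes[!qg$genes$is_cen, , drop = FALSE]
  cen <- qg$centromeresMb
  cenOf <- stats::setNames(cen$cen_mb, cen$chrom)
  inCen <- abs(genes$pos_bp / 1e6 - cenOf[genes$chrom]) <=
    scn@cenHalfwidthMb
  pMarker <- scn@markerDensityPerMb * scn@bpPerGene / 1e6
  sel <- !inCen & stats::runif(nrow(genes)) < pMarker
  mk <- genes[sel, , drop = FALSE]
  lenKb <- qg$chromLengthsMb[mk$chrom] * 1000
  posKb <- pmin(pmax(mk$pos_bp / 1000 +
                       stats::runif(nrow(mk), -scn@jitterKb, scn@jitterKb),
                     0), lenKb)
  markers <- data.frame(
    marker_id = paste0("m.", mk$gene_id), chrom = mk$chrom,
    pos_kb = posKb,
    contig_id = paste0(mk$chrom, "_c",
                       1L + (stats::ave(seq_len(nrow(mk)), mk$chrom,
                                        FUN = seq_along) - 1L) %/% 8L),
    cm = NA_real_, exonic = TRUE, stringsAsFactors = FALSE)
  mapped <- stats::runif(nrow(markers)) < scn@markerMappedFrac
  for (ch in unique(markers$chrom)) {
    ii <- which(markers$chrom == ch & mapped)
    if (!length(ii)) next
    ## genetic position evaluated at the observed physical coordinate, so
    ## cm is monotone along the as-ordered map by construction
    markers$cm[ii] <- .geneticPosition(markers$pos_kb[ii] / 1000,
                                       cenOf[[ch]],
                                       qg$chromLengthsMb[[ch]], scn)
  }
  markers <- markers[order(markers$chrom, markers$pos_kb,
                           markers$marker_id), , drop = FALSE]
  rownames(markers) <- NULL

  sgenes <- sg$genes[!sg$genes$is_cen, , drop = FALSE]
  exp_ <- merge(data.frame(marker_id = paste0("m.", mk$gene_id),
                           anc = mk$anc, gcopy_q = mk$gcopy,
                           stringsAsFactors = FALSE),
                data.frame(anc = sgenes$anc, gene_id = sgenes$gene_id,
                           gcopy_s = sgenes$gcopy, stringsAsFactors = FALSE),
                by = "anc")
  ## clustered homology opacity: runs of query genes with no detectable
  ## homologue; the opaque fraction grows with divergence and is what
  ## erodes synteny coverage over time
  pOp <- 1 - exp(-div / scn@tauOpaqueMy)
  opaque <- logical(nrow(mk))
  if (pOp > 1e-6) {
    for (ch in unique(mk$chrom)) {
      ii <- which(mk$chrom == ch)
      st <- logical(0)
      runOn <- scn@opaqueRunGenes
      runOff <- runOn * (1 - pOp) / pOp
      while (length(st) < length(ii)) {
        st <- c(st, rep(FALSE, 1L + stats::rpois(1L, max(0, runOff - 1))),
                rep(TRUE, 1L + stats::rpois(1L, max(0, runOn - 1))))
      }
      opaque[ii] <- st[seq_along(ii)]
    }
  }
  opaqueGene <- stats::setNames(opaque, mk$gene_id)

  ## orthologues (same ancient-duplication copy) diverged at the split;
  ## ancient paralogues diverged at the duplication itself and score lower
  exp_$ortholog <- exp_$gcopy_q == exp_$gcopy_s
  qgene <- sub("^m\\.", "", exp_$marker_id)
  exp_ <- exp_[!opaqueGene[qgene], , drop = FALSE]
  pairDiv <- ifelse(exp_$ortholog, div, 2 * scn@gammaMya)
  pDet <- exp(-pairDiv / 2000)
  exp_ <- exp_[stats::runif(nrow(exp_)) < pDet, , drop = FALSE]
  pairDiv <- ifelse(exp_$ortholog, div, 2 * scn@gammaMya)
  bit <- stats::rnorm(nrow(exp_), 80 + 320 * exp(-pairDiv / 150), 12)
  hits <- data.frame(marker_id = exp_$marker_id,
                     subject_genome = subject,
                     gene_id = exp_$gene_id,
                     evalue = pmax(10^(-bit / 7), 1e-180),
                     bitscore = round(bit, 1), stringsAsFactors = FALSE)
  nSpur <- stats::rbinom(1L, nrow(markers), scn@spuriousHitRate)
  if (nSpur > 0L) {
    sb <- stats::runif(nSpur, 25, 45)
    hits <- rbind(hits, data.frame(
      marker_id = sample(markers$marker_id, nSpur),
      subject_genome = subject,
      gene_id = sample(sgenes$gene_id, nSpur, replace = TRUE),
      evalue = 10^(-sb / 7), bitscore = round(sb, 1),
      stringsAsFactors = FALSE))
  }

  gr <- GenomicRanges::GRanges(
    seqnames = sgenes$chrom,
    ranges = IRanges::IRanges(start = sgenes$pos_bp + 1L,
                              end = sgenes$pos_bp +
                                round(0.6 * scn@bpPerGene)),
    strand = sample(c("+", "-"), nrow(sgenes), replace = TRUE))
  names(gr) <- sgenes$gene_id
  S4Vectors::mcols(gr)$gene_id <- sgenes$gene_id
  S4Vectors::metadata(gr)$genome <- subject

  truth <- list(
    orthology = exp_,
    homoeoPairsQuery = qg$homoeoPairs,
    homoeoPairsSubject = sg$homoeoPairs,
    centromeresMb = cen,
    queryEvents = q$events,
    subjectEvents = s$events,
    queryGenes = qg$genes,
    subjectGenes = sg$genes)
  list(markers = markers, genes = gr, hits = hits, truth = truth,
       queryChromLengthsMb = qg$chromLengthsMb,
       subjectNChrom = length(sg$chromLengthsMb),
       totalMtpMb = sum(qg$chromLengthsMb),
       scenario = scn, subject = subject)
}

#' Aligned syntelog pairs with known silent-site divergence
#'
#' Draws homoeologous gene pairs retained on both members of a query
#' homoeologue pair, builds an ancestral coding sequence from codons with
#' fourfold-degenerate third positions, and evolves the third positions
#' independently along both post-WGD branches under Jukes-Cantor dynamics
#' at `rTrue` substitutions per silent site per year, so the expected
#' pairwise Ks is `2 * wgdAgeMya * 1e6 * rTrue`.
#'
#' @param scn the scenario.
#' @param nPairs number of syntelog pairs (default 100).
#' @param nCodons codons per sequence (default 200).
#' @param wgdAgeMya age of the query WGD (default: from the scenario).
#' @return list: `alignments` (named list of `list(a =, b =)`),
#'   `ks_true` expected Ks.
#' @export
simulateSyntelogAlignments <- function(scn, nPairs = 100L, nCodons = 200L,
                                       wgdAgeMya = NULL) {
  if (is.null(wgdAgeMya)) {
    w <- scn@wgdEvents[scn@wgdEvents$lineage == "query", , drop = FALSE]
    if (!nrow(w)) stop("scenario has no query WGD to date")
    wgdAgeMya <- w$time_mya[1L]
  }
  set.seed(.lineageSeed(scn, "syntelogs", salt = 29L))
  prefixes <- c("GC", "GG", "CC", "GT", "TC", "AC")
  bases <- c("A", "C", "G", "T")
  d <- scn@rTrue * wgdAgeMya * 1e6        # per-branch divergence
  pSame <- 0.25 + 0.75 * exp(-4 * d / 3)
  evolve <- function(third) {
    change <- stats::runif(length(third)) > pSame
    third[change] <- vapply(third[change], function(b)
      sample(setdiff(bases, b), 1L), character(1))
    third
  }
  alignments <- list()
  for (k in seq_len(nPairs)) {
    pre <- sample(prefixes, nCodons, replace = TRUE)
    third0 <- sample(bases, nCodons, replace = TRUE)
    a <- paste0(pre, evolve(third0), collapse = "")
    b <- paste0(pre, evolve(third0), collapse = "")
    alignments[[sprintf("pair%03d", k)]] <- list(a = a, b = b)
  }
  list(alignments = alignments, ks_true = 2 * d)
}

#' Delete a fraction of one chromosome's genes
#'
#' Utility for constructing shrunken-homoeologue scenarios (a chromosome
#' that lost a large block of its post-WGD content).
#'
#' @param genome internal genome object.
#' @param chromIndex index of the chromosome.
#' @param frac fraction of genes to delete (a contiguous terminal run).
#' @return the modified genome.
#' @export
deleteChromSegment <- function(genome, chromIndex, frac) {
  df <- genome$chroms[[chromIndex]]
  nc <- which(!df$is_cen)
  drop <- utils::tail(nc, round(frac * length(nc)))
  genome$chroms[[chromIndex]] <- df[-drop, , drop = FALSE]
  rownames(genome$chroms[[chromIndex]]) <- NULL
  genome
}

#' Write a simulated comparison to pipeline input files
#'
#' Emits exactly the formats the readers consume: the marker map as TSV,
#' the subject annotation as GFF3, the homology hits as 12-column BLAST
#' tabular, and the truth tables as TSVs.
#'
#' @param sim result of [simulateComparison()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
writeComparativeData <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- c(markers = file.path(dir, "markers.tsv"),
         genes = file.path(dir, "subject_genes.gff3"),
         hits = file.path(dir, "hits.blast.tsv"),
         truth_orthology = file.path(dir, "truth_orthology.tsv"),
         truth_centromeres = file.path(dir, "truth_centromeres.tsv"),
         truth_homoeologues = file.path(dir, "truth_homoeologues.tsv"))
  writeMarkerMap(sim$markers, f[["markers"]])
  gr <- sim$genes
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- names(gr)
  rtracklayer::export(gr, f[["genes"]], format = "gff3")
  h <- sim$hits
  blast <- data.frame(h$marker_id, h$gene_id, 90, 450, 30, 0, 1, 450, 1,
                      450, format(h$evalue, digits = 3), h$bitscore)
  utils::write.table(blast, f[["hits"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth$orthology, f[["truth_orthology"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$centromeresMb, f[["truth_centromeres"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$homoeoPairsQuery, f[["truth_homoeologues"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  f
}
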