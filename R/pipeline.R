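#' Export duplicated-block pairs as a Circos-style link table
#'
#' One link per duplicated-block pair: the query spans of the two blocks,
#' coloured by the subject chromosome they share.
#'
#' @param dupPairs data.frame from [detectDuplicatedBlocks()].
#' @param sbs the [SyntenyBlockSet-class] the pairs came from.
#' @param path output path (TSV, Circos link layout).
#' @return the path, invisibly.
#' @export
exportLinks <- function(dupPairs, sbs, path) {
  if (!nrow(dupPairs)) {
    file.create(path)
    return(invisible(path))
  }
  b <- blocks(sbs)
  rowOf <- match(dupPairs$block_a, b$block_id)
  rowOf2 <- match(dupPairs$block_b, b$block_id)
  links <- data.frame(
    chrom1 = b$query_chrom[rowOf],
    start1 = round(b$q_lo_kb[rowOf] * 1000),
    end1 = round(b$q_hi_kb[rowOf] * 1000),
    chrom2 = b$query_chrom[rowOf2],
    start2 = round(b$q_lo_kb[rowOf2] * 1000),
    end2 = round(b$q_hi_kb[rowOf2] * 1000),
    color = paste0("color=", dupPairs$subject_chrom),
    stringsAsFactors = FALSE)
  utils::write.table(links, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a dot-plot table of collinear anchor points
#'
#' One row per collinear anchor: query position against subject gene
#' start, grouped (coloured) by block.
#'
#' @param sbs a [SyntenyBlockSet-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
exportDotplot <- function(sbs, path) {
  aa <- blockAnchors(sbs)
  b <- blocks(sbs)
  d <- data.frame(query_chrom = b$query_chrom[match(aa$block_id, b$block_id)],
                  pos_kb = aa$pos_kb,
                  subject_chrom = b$subject_chrom[match(aa$block_id,
                                                        b$block_id)],
                  s_start = aa$s_start,
                  block_id = aa$block_id,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export blocks as a BED-like table
#'
#' @param sbs ranked [SyntenyBlockSet-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
exportBlocks <- function(sbs, path) {
  b <- blocks(sbs)
  out <- data.frame(query_chrom = b$query_chrom,
                    start_kb = b$q_lo_kb, end_kb = b$q_hi_kb,
                    block_id = b$block_id, rank = b$rank,
                    subject_chrom = b$subject_chrom,
                    subject_start = b$s_lo_bp, subject_end = b$s_hi_bp,
                    orientation = b$orientation,
                    n_collinear = b$n_collinear,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the pipeline stage by stage over a run directory
#'
#' Thin orchestration over the package functions: each stage reads its
#' inputs from `outDir`, writes its artifacts there, and fails with an
#' actionable message naming the producing stage when an upstream artifact
#' is missing.  Stage `"all"` runs simulate, anchors, synteny and wgd in
#' order.
#'
#' @param stage one of `"simulate"`, `"anchors"`, `"synteny"`, `"wgd"`,
#'   `"all"`.
#' @param config list: `scenario` (an [EvolutionScenario-class]),
#'   `subject`, and optional chaining parameters (`maxAnchorGapKb`,
#'   `jitterKb`, `maxDiscordant`, `minGenes`, `minSpanKb`).
#' @param outDir run directory.
#' @return invisibly, a list of the stage's main results.
#' @export
runPipeline <- function(stage = c("all", "simulate", "anchors", "synteny",
                                  "wgd"),
                        config = list(), outDir = tempfile("psrun")) {
  stage <- match.arg(stage)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  scn <- config$scenario
  if (is.null(scn)) scn <- evolutionScenario()
  subject <- config$subject %||na% "benchmark"
  p <- function(f) file.path(outDir, f)
  needs <- function(f, producer) {
    if (!file.exists(p(f)))
      stop("missing artifact ", f, "; run the '", producer,
           "' stage first")
  }
  res <- list()
  if (stage %in% c("simulate", "all")) {
    sim <- simulateComparison(scn, subject)
    writeComparativeData(sim, outDir)
    writeLines(paste(names(qlen <- sim$queryChromLengthsMb),
                     qlen, sep = "\t"), p("query_chrom_lengths.tsv"))
    writeLines(as.character(sim$subjectNChrom), p("subject_nchrom.txt"))
    res$sim <- sim
  }
  if (stage %in% c("anchors", "all")) {
    needs("markers.tsv", "simulate")
    needs("subject_genes.gff3", "simulate")
    needs("hits.blast.tsv", "simulate")
    markers <- readMarkerMap(p("markers.tsv"))
    genes <- readGeneAnnotation(p("subject_genes.gff3"), subject)
    hits <- readBlastTab(p("hits.blast.tsv"), subject)
    top <- selectTopTwoHits(hits, genes)
    at <- buildAnchorTable(markers, top, subject)
    writeAnchorTable(at, p("anchors.tsv"))
    res$anchorTable <- at
  }
  if (stage %in% c("synteny", "all")) {
    needs("anchors.tsv", "anchors")
    needs("query_chrom_lengths.tsv", "simulate")
    at <- readAnchorTable(p("anchors.tsv"), subject)
    lens <- utils::read.delim(p("query_chrom_lengths.tsv"), header = FALSE)
    nchr <- as.integer(readLines(p("subject_nchrom.txt"))[1])
    syn <- analyzeSynteny(
      at, comparison = paste0("query-", subject),
      totalMtpMb = sum(lens[[2]]), nPseudomolecules = nchr,
      maxAnchorGapKb = config$maxAnchorGapKb %||na% 2000,
      jitterKb = config$jitterKb %||na% 200,
      maxDiscordant = config$maxDiscordant %||na% 2,
      minGenes = config$minGenes %||na% 3L,
      minSpanKb = config$minSpanKb %||na% 500)
    exportBlocks(syn$blockSet, p("blocks.tsv"))
    utils::write.table(syn$stats, p("synteny_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$synteny <- syn
  }
  if (stage %in% c("wgd", "all")) {
    if (is.null(res$synteny)) needs("blocks.tsv", "synteny")
    syn <- res$synteny
    dup <- detectDuplicatedBlocks(syn$blockSet)
    hm <- homoeologueMatrix(syn$blockSet, dup)
    exportLinks(dup, syn$blockSet, p("links.tsv"))
    exportDotplot(syn$blockSet, p("dotplot.tsv"))
    utils::write.table(homoeologuePairs(hm), p("homoeologues.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$dupPairs <- dup
    res$homoeology <- hm
  }
  invisible(res)
}

`%||na%` <- function(a, b) if (is.null(a)) b else a
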