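#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' AnchorTable: ordered markers joined to their best and second-best
#' homologous genes in one subject genome
#'
#' One row per query marker, in map order.  The two gene slots hold the
#' subject gene with the lowest BLAST e-value and the lowest e-value among
#' hits to a *different* gene.  Collinearity flags are filled in by
#' [callCollinearChains()].
#'
#' Columns of `anchors(x)`: `marker_id`, `chrom`, `pos_kb`, `contig_id`,
#' `cm`, `exonic`, `best_gene`, `best_chrom`, `best_start`, `second_gene`,
#' `second_chrom`, `second_start`, `collinear_best`, `collinear_second`.
#'
#' @slot anchors data.frame, one row per marker, ordered by (chrom, pos_kb).
#' @slot subjectGenome single character label of the subject genome.
#' @slot params list of construction parameters (e-value cutoff etc.).
#' @exportClass AnchorTable
setClass("AnchorTable",
  representation(anchors = "data.frame",
                 subjectGenome = "character",
                 params = "list"),
  prototype(anchors = data.frame(), subjectGenome = NA_character_,
            params = list()))

setValidity("AnchorTable", function(object) {
  a <- object@anchors
  need <- c("marker_id", "chrom", "pos_kb",
            "best_gene", "best_chrom", "best_start",
            "second_gene", "second_chrom", "second_start",
            "collinear_best", "collinear_second")
  miss <- setdiff(need, names(a))
  if (length(miss))
    return(paste("missing anchor columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(a$marker_id))
    return("duplicated marker_id in anchor table")
  both <- !is.na(a$best_gene) & !is.na(a$second_gene)
  if (any(both & a$best_gene == a$second_gene))
    return("best and second gene must be distinct when both present")
  ord <- order(a$chrom, a$pos_kb, a$marker_id)
  if (!identical(ord, seq_len(nrow(a))))
    return("anchor rows must be ordered by (chrom, pos_kb)")
  TRUE
})

#' SyntenyBlockSet: called synteny blocks for one genome comparison
#'
#' `blocks(x)` holds one row per block: `block_id`, `query_chrom`,
#' `q_lo_kb`, `q_hi_kb`, `subject_chrom`, `s_lo_bp`, `s_hi_bp`,
#' `orientation`, `n_collinear`, `n_genes`, `rank`, `group_id`.
#' `blockAnchors(x)` maps collinear anchor points into blocks, one row per
#' (marker, via) pair where `via` is `"best"` or `"second"`.
#'
#' @slot blocks data.frame of blocks.
#' @slot anchorAssign data.frame (marker_id, via, gene_id, pos_kb, s_start,
#'   block_id).
#' @slot comparison character label, e.g. `"Jr-Vv"`.
#' @slot params list of chaining/filtering parameters used.
#' @exportClass SyntenyBlockSet
setClass("SyntenyBlockSet",
  representation(blocks = "data.frame",
                 anchorAssign = "data.frame",
                 comparison = "character",
                 params = "list"),
  prototype(blocks = data.frame(), anchorAssign = data.frame(),
            comparison = NA_character_, params = list()))

setValidity("SyntenyBlockSet", function(object) {
  b <- object@blocks
  if (nrow(b)) {
    if (anyDuplicated(b$block_id)) return("duplicated block_id")
    if (any(b$q_hi_kb < b$q_lo_kb)) return("query span hi < lo")
    if (any(!b$orientation %in% c("+", "-"))) return("orientation must be +/-")
    bad <- !object@anchorAssign$block_id %in% b$block_id
    if (any(bad)) return("anchor assigned to unknown block")
  }
  TRUE
})

#' HomoeologyMatrix: chromosome-by-chromosome duplication support
#'
#' `counts[c1, c2]` is the number of collinear markers on query chromosome
#' c1 lying in blocks whose duplicate copy is on chromosome c2.  Partner
#' chromosomes are row-percentage maxima; a pair is reciprocal when each
#' member is the other's partner.
#'
#' @slot counts integer matrix, query chromosomes on both axes.
#' @slot rowPct numeric matrix of row percentages.
#' @slot partner named character vector, best-supported partner per chrom.
#' @slot reciprocal named logical vector.
#' @exportClass HomoeologyMatrix
setClass("HomoeologyMatrix",
  representation(counts = "matrix", rowPct = "matrix",
                 partner = "character", reciprocal = "logical"))

#' EvolutionScenario: parameters of the genome-evolution simulator
#'
#' The scenario fixes an ancestral karyotype, per-lineage branch lengths,
#' whole-genome duplication and dysploid-fusion events, rearrangement and
#' loss rates, the silent-site substitution rate, and the observation model
#' (marker density, position jitter, centromere-suppressed recombination).
#' A scenario plus its seed fully determines every simulator output.
#'
#' Times are in million years (MYA); per-gene rates are events per gene per
#' MY; per-genome rates are events per genome per MY.
#'
#' @slot seed integer master seed.
#' @slot nChromAncestor ancestral chromosome number (x).
#' @slot genesPerChrom mean gene number per ancestral chromosome.
#' @slot chromSizeSpread relative chromosome-size range (lo, hi).
#' @slot bpPerGene physical spacing of gene starts, bp.
#' @slot queryBranchMya age of the query branch.
#' @slot splitTimesMya named numeric, subject branch lengths.
#' @slot wgdEvents data.frame(lineage, time_mya).
#' @slot fusionEvents data.frame(lineage, time_mya).
#' @slot lossRate,transpositionRate per-gene per-MY rates.
#' @slot duplicateLossRate additional per-gene per-MY loss (fractionation)
#'   applied while two or more copies of an ancestral gene coexist.
#' @slot inversionRate,translocationRate per-genome per-MY rates.
#' @slot invMeanGenes mean inversion length, genes (geometric).
#' @slot gammaMya age of the ancestral (pre-split) duplication whose
#'   fractionated remnants every lineage inherits.
#' @slot ancientRetention stationary fraction of ancestral genes retained
#'   in duplicate from that event.
#' @slot retainedRunGenes mean run length (genes) of retained-duplicate
#'   segments; retention is clustered, not independent per gene.
#' @slot rTrue silent-site substitution rate, subs/site/year.
#' @slot tauOpaqueMy divergence timescale of homology opacity: the
#'   fraction of query genes with no detectable subject homologue is
#'   `1 - exp(-divergence/tauOpaqueMy)`, modelling the regional decay of
#'   detectable homology that erodes synteny coverage.
#' @slot opaqueRunGenes mean run length (genes) of opaque regions; opacity
#'   is spatially clustered.
#' @slot markerDensityPerMb expected markers per Mb of query genome.
#' @slot markerMappedFrac fraction of markers carrying a genetic position.
#' @slot jitterKb half-width of uniform marker-position jitter.
#' @slot cenRelPos relative centromere position along each chromosome.
#' @slot cenHalfwidthMb half-width of the pericentromeric zone.
#' @slot rampMb width of the transition between distal and centromeric
#'   recombination intensity.
#' @slot baseDistalCmPerMb,basePericenCmPerMb recombination intensities.
#' @slot spuriousHitRate probability of an extra random homology hit.
#' @exportClass EvolutionScenario
setClass("EvolutionScenario",
  representation(seed = "integer",
                 nChromAncestor = "integer",
                 genesPerChrom = "integer",
                 chromSizeSpread = "numeric",
                 bpPerGene = "integer",
                 queryBranchMya = "numeric",
                 splitTimesMya = "numeric",
                 wgdEvents = "data.frame",
                 fusionEvents = "data.frame",
                 lossRate = "numeric",
                 duplicateLossRate = "numeric",
                 transpositionRate = "numeric",
                 inversionRate = "numeric",
                 translocationRate = "numeric",
                 invMeanGenes = "numeric",
                 gammaMya = "numeric",
                 ancientRetention = "numeric",
                 retainedRunGenes = "numeric",
                 rTrue = "numeric",
                 tauOpaqueMy = "numeric",
                 opaqueRunGenes = "numeric",
                 markerDensityPerMb = "numeric",
                 markerMappedFrac = "numeric",
                 jitterKb = "numeric",
                 cenRelPos = "numeric",
                 cenHalfwidthMb = "numeric",
                 rampMb = "numeric",
                 baseDistalCmPerMb = "numeric",
                 basePericenCmPerMb = "numeric",
                 spuriousHitRate = "numeric"))

setValidity("EvolutionScenario", function(object) {
  rates <- c(object@lossRate, object@transpositionRate,
             object@inversionRate, object@translocationRate)
  if (any(rates < 0)) return("event rates must be non-negative")
  if (object@nChromAncestor < 1L) return("need at least one chromosome")
  if (object@rTrue < 0) return("rTrue must be non-negative")
  if (nrow(object@wgdEvents)) {
    qw <- object@wgdEvents[object@wgdEvents$lineage == "query", , drop = FALSE]
    if (any(qw$time_mya > object@queryBranchMya))
      return("query WGD older than the query branch")
    sw <- object@wgdEvents[object@wgdEvents$lineage != "query", , drop = FALSE]
    if (nrow(sw)) {
      tmax <- object@splitTimesMya[sw$lineage]
      if (any(is.na(tmax)))
        return("WGD event on a lineage without a split time")
      if (any(sw$time_mya > tmax))
        return("subject WGD older than the lineage split")
    }
  }
  TRUE
})

setMethod("show", "AnchorTable", function(object) {
  a <- object@anchors
  cat(sprintf("AnchorTable vs %s: %d markers on %d chromosomes, %d with hits\n",
              object@subjectGenome, nrow(a),
              length(unique(a$chrom)), sum(!is.na(a$best_gene))))
})

setMethod("show", "SyntenyBlockSet", function(object) {
  b <- object@blocks
  cat(sprintf("SyntenyBlockSet %s: %d blocks (%s), %d collinear anchor points\n",
              object@comparison, nrow(b),
              if (nrow(b) && !all(is.na(b$rank)))
                paste(table(b$rank), names(table(b$rank)), collapse = ", ")
              else "unranked",
              nrow(object@anchorAssign)))
})

setMethod("show", "HomoeologyMatrix", function(object) {
  cat(sprintf("HomoeologyMatrix: %d chromosomes, %d reciprocal pairs\n",
              nrow(object@counts), sum(object@reciprocal, na.rm = TRUE) %/% 2L))
  prs <- homoeologuePairs(object)
  if (nrow(prs))
    cat(paste0("  ", prs$chrom_a, " - ", prs$chrom_b,
               ifelse(prs$reciprocal, "", " (not reciprocal)"),
               collapse = "\n"), "\n")
})

setMethod("show", "EvolutionScenario", function(object) {
  cat(sprintf(
    "EvolutionScenario (seed %d): x = %d ancestor, %d genes/chrom, query branch %g MY\n",
    object@seed, object@nChromAncestor, object@genesPerChrom,
    object@queryBranchMya))
  cat(sprintf("  subjects: %s\n",
              paste(sprintf("%s (%g MY)", names(object@splitTimesMya),
                            object@splitTimesMya), collapse = ", ")))
  if (nrow(object@wgdEvents))
    cat(sprintf("  WGD: %s\n",
                paste(sprintf("%s @ %g MYA", object@wgdEvents$lineage,
                              object@wgdEvents$time_mya), collapse = ", ")))
})

#' Accessors for the central classes
#'
#' @param x an `AnchorTable` or `SyntenyBlockSet`.
#' @return `anchors()` and `blocks()` return the underlying data.frame;
#'   `blockAnchors()` the anchor-to-block assignment; `subjectGenome()` and
#'   `comparisonLabel()` the genome labels.
#' @rdname accessors
#' @export
anchors <- function(x) x@anchors

#' @rdname accessors
#' @export
blocks <- function(x) x@blocks

#' @rdname accessors
#' @export
blockAnchors <- function(x) x@anchorAssign

#' @rdname accessors
#' @export
subjectGenome <- function(x) x@subjectGenome

#' @rdname accessors
#' @export
comparisonLabel <- function(x) x@comparison

#' @rdname accessors
#' @export
homoeologyCounts <- function(x) x@counts

#' Homoeologous chromosome pairs from a HomoeologyMatrix
#'
#' @param x a `HomoeologyMatrix`.
#' @return data.frame with columns `chrom_a`, `chrom_b`, `reciprocal`,
#'   one row per unordered partner pair.
#' @export
homoeologuePairs <- function(x) {
  p <- x@partner
  out <- data.frame(chrom_a = character(), chrom_b = character(),
                    reciprocal = logical())
  seen <- character()
  for (c1 in names(p)) {
    c2 <- p[[c1]]
    if (is.na(c2)) next
    key <- paste(sort(c(c1, c2)), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    out <- rbind(out, data.frame(chrom_a = c1, chrom_b = c2,
                                 reciprocal = isTRUE(x@reciprocal[[c1]]) &&
                                              isTRUE(x@reciprocal[[c2]])))
  }
  out
}
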