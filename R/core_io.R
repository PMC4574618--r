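#' Read an ordered marker map
#'
#' Reads a TSV of ordered query-genome marker loci (exonic BAC-end-sequence
#' markers or equivalent).  Required columns: `marker_id`, `chrom`,
#' `pos_kb`, `contig_id`; optional `cm` (genetic position) and `exonic`.
#' Positions are Kb along the minimum tiling path of each chromosome.
#'
#' @param path path to a tab-separated file with a header line.
#' @return data.frame of loci sorted by (chrom, pos_kb, marker_id), with
#'   `cm` (numeric, NA when unmapped) and `exonic` (logical) always present.
#' @export
readMarkerMap <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "pos_kb", "contig_id")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("marker map is missing columns: ", paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.numeric(d$pos_kb))
  bad <- which(is.na(pos) | pos < 0)
  if (length(bad))
    stop("malformed pos_kb at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  d$pos_kb <- pos
  dup <- unique(d$marker_id[duplicated(d$marker_id)])
  if (length(dup))
    stop("duplicated marker_id: ", paste(utils::head(dup, 5), collapse = ", "))
  if (is.null(d$cm)) d$cm <- NA_real_ else
    d$cm <- suppressWarnings(as.numeric(d$cm))
  if (is.null(d$exonic)) d$exonic <- TRUE else
    d$exonic <- as.logical(d$exonic)
  d <- d[order(d$chrom, d$pos_kb, d$marker_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Write a marker map as TSV
#'
#' @param markers data.frame as returned by [readMarkerMap()].
#' @param path output path.
#' @export
writeMarkerMap <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read subject-genome gene models from GFF3 or BED
#'
#' Gene models are returned as a `GRanges` (1-based, closed intervals, the
#' Bioconductor convention); `rtracklayer` performs the GFF3/BED coordinate
#' conversions.  For GFF3 only `gene` (or, lacking genes, `mRNA`) features
#' are kept; gene identifiers come from the `ID`/`Name` attribute or the
#' BED name column.
#'
#' @param path path to a `.gff`/`.gff3` or `.bed` file.
#' @param genomeLabel label stored in the result's metadata.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return `GRanges` named by gene_id with metadata column `gene_id`.
#' @export
readGeneAnnotation <- function(path, genomeLabel = NA_character_,
                               format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, gff = "gff3", gff3 = "gff3", bed = "bed",
                     stop("unknown annotation format: .", ext))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop("failed to parse ", format, " file ", path,
                             ": ", conditionMessage(e)))
  if (format == "gff3") {
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      keep <- gr[gr$type == "gene"]
      if (!length(keep)) keep <- gr[gr$type == "mRNA"]
      if (length(keep)) gr <- keep
    }
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  } else {
    ids <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("g", seq_along(gr))
  }
  if (any(is.na(ids)))
    stop("annotation features without an identifier in ", path)
  if (any(BiocGenerics::end(gr) < BiocGenerics::start(gr)))
    stop("gene with end < start in ", path)
  if (anyDuplicated(ids))
    stop("duplicated gene_id in ", path)
  names(gr) <- ids
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = ids)
  S4Vectors::metadata(gr)$genome <- genomeLabel
  gr
}

#' Read BLAST tabular homology hits (outfmt 6)
#'
#' Standard 12-column tabular output: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore.
#'
#' @param path path to the tabular file (no header).
#' @param subjectGenome label attached to every hit.
#' @return data.frame with `marker_id`, `subject_genome`, `gene_id`,
#'   `evalue`, `bitscore`.
#' @export
readBlastTab <- function(path, subjectGenome = NA_character_) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 12L)
    stop("expected 12 tab-separated columns (outfmt 6) in ", path)
  data.frame(marker_id = as.character(d[[1]]),
             subject_genome = subjectGenome,
             gene_id = as.character(d[[2]]),
             evalue = as.numeric(d[[11]]),
             bitscore = as.numeric(d[[12]]),
             stringsAsFactors = FALSE)
}

#' Select the best and second-best homologous gene per marker
#'
#' Hits are filtered at the e-value cutoff; per marker the best gene is the
#' hit with the lowest e-value (ties broken by higher bitscore, then
#' lexicographic gene_id) and the second-best is the lowest e-value among
#' hits to a *different* gene, so multiple HSPs on one gene never occupy
#' both slots.
#'
#' @param hits data.frame as from [readBlastTab()] (one subject genome).
#' @param genes `GRanges` from [readGeneAnnotation()] for the same genome.
#' @param evalueCutoff significance cutoff (default `1e-5`).
#' @return data.frame, one row per marker appearing in `hits`, with
#'   best/second gene ids, subject chromosomes and start positions (bp,
#'   0-based starts used for ordering only); markers with no passing hit
#'   are absent.
#' @export
selectTopTwoHits <- function(hits, genes, evalueCutoff = 1e-5) {
  h <- hits[hits$evalue <= evalueCutoff, , drop = FALSE]
  if (!nrow(h))
    return(data.frame(marker_id = character(), best_gene = character(),
                      best_chrom = character(), best_start = numeric(),
                      second_gene = character(), second_chrom = character(),
                      second_start = numeric(), stringsAsFactors = FALSE))
  unknown <- setdiff(unique(h$gene_id), names(genes))
  if (length(unknown))
    stop("hits reference gene_id(s) absent from the annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  gchrom <- stats::setNames(as.character(GenomicRanges::seqnames(genes)),
                            names(genes))
  gstart <- stats::setNames(BiocGenerics::start(genes) - 1, names(genes))
  h <- h[order(h$marker_id, h$evalue, -h$bitscore, h$gene_id), , drop = FALSE]
  best <- h[!duplicated(h$marker_id), , drop = FALSE]
  bestGeneOf <- stats::setNames(best$gene_id, best$marker_id)
  h2 <- h[h$gene_id != bestGeneOf[h$marker_id], , drop = FALSE]
  second <- h2[!duplicated(h2$marker_id), , drop = FALSE]
  si <- match(best$marker_id, second$marker_id)
  out <- data.frame(
    marker_id = best$marker_id,
    best_gene = best$gene_id,
    best_chrom = unname(gchrom[best$gene_id]),
    best_start = unname(gstart[best$gene_id]),
    second_gene = second$gene_id[si],
    second_chrom = unname(gchrom[second$gene_id[si]]),
    second_start = unname(gstart[second$gene_id[si]]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the anchor table for one genome comparison
#'
#' Joins the ordered marker map with the per-marker best/second-best gene
#' positions, yielding the marker-row-by-genome-column layout used for all
#' collinearity work.  Collinearity flags start out `FALSE`.
#'
#' @param markers data.frame from [readMarkerMap()].
#' @param topHits data.frame from [selectTopTwoHits()].
#' @param subjectGenome subject genome label.
#' @param params list of provenance parameters kept with the table.
#' @return an [AnchorTable-class] object.
#' @export
buildAnchorTable <- function(markers, topHits, subjectGenome = NA_character_,
                             params = list()) {
  a <- markers[order(markers$chrom, markers$pos_kb, markers$marker_id),
               c("marker_id", "chrom", "pos_kb", "contig_id", "cm", "exonic"),
               drop = FALSE]
  idx <- match(a$marker_id, topHits$marker_id)
  for (col in c("best_gene", "best_chrom", "second_gene", "second_chrom"))
    a[[col]] <- ifelse(is.na(idx), NA_character_,
                       as.character(topHits[[col]][idx]))
  for (col in c("best_start", "second_start"))
    a[[col]] <- ifelse(is.na(idx), NA_real_, topHits[[col]][idx])
  a$collinear_best <- FALSE
  a$collinear_second <- FALSE
  rownames(a) <- NULL
  new("AnchorTable", anchors = a, subjectGenome = subjectGenome,
      params = params)
}

#' Export / import an anchor table as TSV
#'
#' The layout mirrors a marker-rows-by-gene-columns synteny spreadsheet;
#' `readAnchorTable()` reverses it exactly, so write-then-read round-trips.
#'
#' @param at an `AnchorTable`.
#' @param path file path.
#' @rdname anchorTableIO
#' @export
writeAnchorTable <- function(at, path) {
  utils::write.table(anchors(at), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param subjectGenome genome label to attach on read.
#' @rdname anchorTableIO
#' @export
readAnchorTable <- function(path, subjectGenome = NA_character_) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("best_gene", "best_chrom", "second_gene", "second_chrom"))
    a[[col]] <- as.character(a[[col]])
  new("AnchorTable", anchors = a, subjectGenome = subjectGenome,
      params = list())
}

#' Summarise a marker map chromosome by chromosome
#'
#' @param markers data.frame from [readMarkerMap()].
#' @return data.frame with one row per chromosome plus a `Total` row:
#'   `chrom`, `n_markers`, `n_mapped`, `genetic_length_cm`, `mtp_length_mb`,
#'   `n_contigs`.
#' @export
chromosomeSummary <- function(markers) {
  sp <- split(markers, markers$chrom)
  rows <- lapply(names(sp), function(ch) {
    m <- sp[[ch]]
    cm <- m$cm[!is.na(m$cm)]
    data.frame(chrom = ch,
               n_markers = nrow(m),
               n_mapped = length(cm),
               genetic_length_cm = if (length(cm)) max(cm) - min(cm) else 0,
               mtp_length_mb = max(m$pos_kb) / 1000,
               n_contigs = length(unique(m$contig_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot <- data.frame(chrom = "Total",
                    n_markers = sum(out$n_markers),
                    n_mapped = sum(out$n_mapped),
                    genetic_length_cm = sum(out$genetic_length_cm),
                    mtp_length_mb = sum(out$mtp_length_mb),
                    n_contigs = sum(out$n_contigs),
                    stringsAsFactors = FALSE)
  rbind(out, tot)
}
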