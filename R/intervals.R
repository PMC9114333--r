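## Interval arithmetic on GRanges: BED I/O, fractional overlap, consensus
## merging at reciprocal overlap, TAD containment, nearest-gene lookup.
##
## BED files are 0-based half-open; GRanges are 1-based closed. Converters:
## GRanges start = BED start + 1, GRanges end = BED end. Regenerated feature
## ids use BED coordinates ("chr1:100-250" covers BED [100, 250)).

#' Read a BED3/BED4 file into a GRanges
#'
#' Coordinates are converted from BED (0-based half-open) to the GRanges
#' convention; the optional 4th column becomes the element names, the
#' optional 6th column the strand.
#'
#' @param path path to an uncompressed BED file.
#' @return A [GenomicRanges::GRanges] with names when a name column exists.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               quote = "", comment.char = "#", colClasses = "character"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(NULL)
      stop("failed to read BED file ", path, ": ", conditionMessage(e))
    })
  if (is.null(tab)) return(GenomicRanges::GRanges())
  if (ncol(tab) < 3) stop("BED file must have at least 3 columns: ", path)
  start0 <- suppressWarnings(as.numeric(tab[[2]]))
  end0 <- suppressWarnings(as.numeric(tab[[3]]))
  badNum <- which(is.na(start0) | is.na(end0))
  if (length(badNum) > 0)
    stop("non-numeric coordinate at line ", badNum[1], " of ", path)
  badOrd <- which(start0 >= end0)
  if (length(badOrd) > 0)
    stop("start >= end at line ", badOrd[1], " of ", path)
  if (any(start0 < 0))
    stop("negative start at line ", which(start0 < 0)[1], " of ", path)
  strand <- if (ncol(tab) >= 6) tab[[6]] else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = tab[[1]],
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand)
  if (ncol(tab) >= 4) names(gr) <- tab[[4]]
  gr
}

#' Write a GRanges as BED
#'
#' Inverse of [readBed()]: coordinates are emitted 0-based half-open, the
#' names (if any) as the 4th column, and the strand as columns 5-6 when any
#' element is stranded. Round-tripping preserves coordinates bit-exactly.
#'
#' @param gr a [GenomicRanges::GRanges].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  strands <- as.character(GenomicRanges::strand(gr))
  if (!is.null(names(gr))) out$name <- names(gr)
  if (any(strands != "*")) {
    if (is.null(out$name)) out$name <- "."
    out$score <- 0
    out$strand <- ifelse(strands == "*", ".", strands)
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export peaks as GTF for read counting
#'
#' Writes one GTF record per peak with the literal value `"peak"` in the
#' source (2nd) and feature (3rd) columns, and `gene_id`/`peak_id`
#' attributes, the layout expected by feature-counting tools when counting
#' reads under consensus peaks.
#'
#' @param peaks named [GenomicRanges::GRanges] of peaks.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportPeaksGTF <- function(peaks, path) {
  ids <- if (is.null(names(peaks))) peakIDsFromCoords(peaks) else names(peaks)
  lines <- sprintf(
    "%s\tpeak\tpeak\t%d\t%d\t.\t.\t.\tgene_id \"%s\"; peak_id \"%s\";",
    as.character(GenomicRanges::seqnames(peaks)),
    GenomicRanges::start(peaks), GenomicRanges::end(peaks), ids, ids)
  writeLines(lines, path)
  invisible(path)
}

## Deterministic peak ids from BED-convention coordinates.
peakIDsFromCoords <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr) - 1, GenomicRanges::end(gr))
}

#' Fractional overlap between two interval vectors, element-wise
#'
#' For each pair `(a[i], b[i])`, the overlap length divided by the length
#' of each interval. Intervals on different chromosomes overlap by 0.
#'
#' @param a,b parallel [GenomicRanges::GRanges] of equal length.
#' @return data.frame with columns `fracA` and `fracB` in `[0, 1]`.
#' @export
fractionalOverlap <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  sameChrom <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  ov <- pmax(0, pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
                pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1)
  ov[!sameChrom] <- 0
  data.frame(fracA = ov / GenomicRanges::width(a),
             fracB = ov / GenomicRanges::width(b))
}

#' Merge per-sample peak sets into a consensus set
#'
#' Any two peaks whose reciprocal overlap -- the overlap length as a
#' fraction of the *shorter* of the two peaks -- is at least `minFraction`
#' are replaced by their union (the spanning interval). Merging is applied
#' transitively and iterated to a fixed point, so the result is independent
#' of the order of the input sets. Output is sorted with deterministic
#' `chrom:start-end` identifiers (BED coordinates).
#'
#' @param peakSets a list of [GenomicRanges::GRanges] (one per sample), or
#'   a single GRanges.
#' @param minFraction reciprocal-overlap threshold in `(0, 1]`; default 0.5.
#' @return A named, sorted [GenomicRanges::GRanges] of consensus peaks.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250))
#' mergeConsensus(list(a, b))  # one peak spanning chr1:100-250 (BED)
#' @export
mergeConsensus <- function(peakSets, minFraction = 0.5) {
  if (!is.numeric(minFraction) || length(minFraction) != 1 ||
      minFraction <= 0 || minFraction > 1)
    stop("minFraction must be a single value in (0, 1]")
  if (methods::is(peakSets, "GRanges")) peakSets <- list(peakSets)
  gr <- suppressWarnings(do.call(c, lapply(peakSets, function(g) {
    names(g) <- NULL
    GenomicRanges::granges(g)
  })))
  GenomicRanges::strand(gr) <- "*"
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  gr <- GenomicRanges::sort(gr)
  repeat {
    if (length(gr) < 2) break
    hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    keep <- qh < sh
    qh <- qh[keep]; sh <- sh[keep]
    if (length(qh) > 0) {
      ov <- pmin(GenomicRanges::end(gr)[qh], GenomicRanges::end(gr)[sh]) -
        pmax(GenomicRanges::start(gr)[qh], GenomicRanges::start(gr)[sh]) + 1
      shorter <- pmin(GenomicRanges::width(gr)[qh],
                      GenomicRanges::width(gr)[sh])
      qualify <- (ov / shorter) >= minFraction
      qh <- qh[qualify]; sh <- sh[qualify]
    }
    if (length(qh) == 0) break
    ## union-find over qualifying pairs, then span each component
    comp <- seq_len(length(gr))
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (k in seq_along(qh)) {
      ri <- find(qh[k]); rj <- find(sh[k])
      if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
    }
    root <- vapply(seq_len(length(gr)), find, 1L)
    starts <- tapply(GenomicRanges::start(gr), root, min)
    ends <- tapply(GenomicRanges::end(gr), root, max)
    chroms <- tapply(as.character(GenomicRanges::seqnames(gr)), root,
                     function(x) x[1])
    gr <- GenomicRanges::GRanges(
      seqnames = as.character(chroms),
      ranges = IRanges::IRanges(start = as.numeric(starts),
                                end = as.numeric(ends)))
    gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
    gr <- unique(gr)
  }
  names(gr) <- peakIDsFromCoords(gr)
  gr
}

#' Drop peaks on excluded chromosomes
#'
#' By default removes the sex chromosomes and mitochondrial DNA, the
#' standard exclusion for accessibility analysis of mixed-gender cohorts.
#'
#' @param peaks a [GenomicRanges::GRanges].
#' @param exclude character vector of chromosome names to drop.
#' @return The retained peaks, input order preserved.
#' @export
filterChromosomes <- function(peaks, exclude = c("chrX", "chrY", "chrM")) {
  peaks[!as.character(GenomicRanges::seqnames(peaks)) %in% exclude]
}

#' Assign peaks to topologically associating domains
#'
#' A peak is assigned to the TAD covering at least `minFraction` of the
#' peak's length. When several TADs qualify (peaks spanning a boundary can
#' qualify for at most one at fractions > 0.5, but lower settings permit
#' several), the TAD with the largest overlap wins; ties go to the TAD with
#' the smaller start coordinate. Peaks with no qualifying TAD are absent
#' from the result.
#'
#' @param peaks named [GenomicRanges::GRanges] of peaks.
#' @param tads named [GenomicRanges::GRanges] of TADs.
#' @param minFraction minimum fraction of the peak contained in the TAD;
#'   default 0.9.
#' @return Named character vector mapping peak id to TAD id.
#' @export
assignToTAD <- function(peaks, tads, minFraction = 0.9) {
  if (is.null(names(peaks))) names(peaks) <- peakIDsFromCoords(peaks)
  if (is.null(names(tads)))
    stop("TADs must carry identifiers as names")
  if (length(peaks) == 0 || length(tads) == 0)
    return(setNames(character(0), character(0)))
  hits <- GenomicRanges::findOverlaps(peaks, tads, ignore.strand = TRUE)
  if (length(hits) == 0) return(setNames(character(0), character(0)))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(GenomicRanges::end(peaks)[qh], GenomicRanges::end(tads)[sh]) -
    pmax(GenomicRanges::start(peaks)[qh], GenomicRanges::start(tads)[sh]) + 1
  frac <- ov / GenomicRanges::width(peaks)[qh]
  keep <- frac >= minFraction
  qh <- qh[keep]; sh <- sh[keep]; ov <- ov[keep]
  if (length(qh) == 0) return(setNames(character(0), character(0)))
  ## best TAD per peak: largest overlap, ties to smaller TAD start
  ord <- order(qh, -ov, GenomicRanges::start(tads)[sh])
  qh <- qh[ord]; sh <- sh[ord]
  first <- !duplicated(qh)
  setNames(names(tads)[sh[first]], names(peaks)[qh[first]])
}

#' Transcription start sites of a gene set
#'
#' The TSS is the start of the gene body for `+` or unstranded genes and
#' the end for `-` genes.
#'
#' @param genes a [GenomicRanges::GRanges] of gene bodies.
#' @return Integer vector of TSS coordinates (1-based).
#' @export
geneTSS <- function(genes) {
  strands <- as.character(GenomicRanges::strand(genes))
  ifelse(strands == "-", GenomicRanges::end(genes), GenomicRanges::start(genes))
}

#' Nearest gene by TSS distance for each peak
#'
#' For each peak, finds the gene on the same chromosome whose TSS is
#' closest to the peak midpoint (`floor((start + end) / 2)` in BED
#' coordinates). Equidistant genes are resolved to the lexicographically
#' smaller gene id. Peaks on chromosomes with no gene get `NA`.
#'
#' @param peaks named [GenomicRanges::GRanges] of peaks.
#' @param genes named [GenomicRanges::GRanges] of genes (strand sets the
#'   TSS side).
#' @return data.frame with columns `peak_id`, `gene_id`, `distance` (bp).
#' @export
nearestGeneTSS <- function(peaks, genes) {
  if (length(genes) == 0) stop("gene set must be non-empty")
  if (is.null(names(peaks))) names(peaks) <- peakIDsFromCoords(peaks)
  if (is.null(names(genes))) stop("genes must carry identifiers as names")
  ## midpoint in BED coordinates: floor((start0 + end0) / 2); convert back
  mid0 <- floor((GenomicRanges::start(peaks) - 1 + GenomicRanges::end(peaks)) / 2)
  tss0 <- geneTSS(genes) - 1
  peakChrom <- as.character(GenomicRanges::seqnames(peaks))
  geneChrom <- as.character(GenomicRanges::seqnames(genes))
  out <- data.frame(peak_id = names(peaks), gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (chrom in unique(peakChrom)) {
    pi <- which(peakChrom == chrom)
    gi <- which(geneChrom == chrom)
    if (length(gi) == 0) next
    ## order genes by id so equidistant ties resolve to the smaller gene_id
    gi <- gi[order(names(genes)[gi])]
    for (block in split(pi, ceiling(seq_along(pi) / 512))) {
      d <- abs(outer(mid0[block], tss0[gi], "-"))
      best <- max.col(-d, ties.method = "first")
      out$gene_id[block] <- names(genes)[gi[best]]
      out$distance[block] <- d[cbind(seq_along(block), best)]
    }
  }
  out
}
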