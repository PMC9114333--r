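## Independent brute-force oracles and small fixture builders, used to
## check the interval arithmetic against exhaustive all-pairs evaluation.
## These work on plain BED-convention data.frames (chrom, start0, end0,
## half-open) with nested loops -- deliberately not sharing code with the
## package implementation.

bedDF <- function(chrom, start0, end0) {
  data.frame(chrom = chrom, start0 = start0, end0 = end0,
             stringsAsFactors = FALSE)
}

bedToGRanges <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(start = df$start0 + 1,
                                                end = df$end0))
  if (!is.null(df$name)) names(gr) <- df$name
  gr
}

grToBed <- function(gr) {
  bedDF(as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr) - 1, GenomicRanges::end(gr))
}

## overlap length of two half-open intervals, 0 if different chromosomes
oracleOverlap <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0)
  max(0, min(e1, e2) - max(s1, s2))
}

## Consensus merging oracle: build the graph of interval pairs whose
## overlap covers >= minFrac of the shorter interval, merge each connected
## component to its spanning interval, and repeat until no pair qualifies.
oracleMergeConsensus <- function(df, minFrac = 0.5) {
  repeat {
    n <- nrow(df)
    if (n < 2) break
    adj <- diag(TRUE, n)
    any_edge <- FALSE
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      ov <- oracleOverlap(df$chrom[i], df$start0[i], df$end0[i],
                          df$chrom[j], df$start0[j], df$end0[j])
      shorter <- min(df$end0[i] - df$start0[i], df$end0[j] - df$start0[j])
      if (ov / shorter >= minFrac) { adj[i, j] <- adj[j, i] <- TRUE; any_edge <- TRUE }
    }
    if (!any_edge) break
    ## transitive closure by repeated boolean multiplication
    repeat {
      nxt <- (adj %*% adj) > 0
      if (identical(nxt, adj)) break
      adj <- nxt
    }
    comp <- integer(n); c0 <- 0
    for (i in seq_len(n)) if (comp[i] == 0) {
      c0 <- c0 + 1
      comp[adj[i, ]] <- c0
    }
    df <- do.call(rbind, lapply(seq_len(c0), function(k) {
      rows <- df[comp == k, ]
      bedDF(rows$chrom[1], min(rows$start0), max(rows$end0))
    }))
  }
  df <- df[order(df$chrom, df$start0, df$end0), ]
  rownames(df) <- NULL
  df
}

## TAD-assignment oracle: exhaustive all-pairs overlap fractions, best
## qualifying TAD per peak (largest overlap, ties to smaller TAD start).
oracleAssignToTAD <- function(peakDF, tadDF, minFrac = 0.9) {
  out <- character(0)
  for (i in seq_len(nrow(peakDF))) {
    len <- peakDF$end0[i] - peakDF$start0[i]
    bestTad <- NA_character_; bestOv <- -1; bestStart <- Inf
    for (j in seq_len(nrow(tadDF))) {
      ov <- oracleOverlap(peakDF$chrom[i], peakDF$start0[i], peakDF$end0[i],
                          tadDF$chrom[j], tadDF$start0[j], tadDF$end0[j])
      if (ov / len >= minFrac &&
          (ov > bestOv || (ov == bestOv && tadDF$start0[j] < bestStart))) {
        bestTad <- tadDF$name[j]; bestOv <- ov; bestStart <- tadDF$start0[j]
      }
    }
    if (!is.na(bestTad)) out[peakDF$name[i]] <- bestTad
  }
  out
}

randomIntervalSet <- function(n, chroms = c("chr1", "chr2"),
                              span = 5000, maxWidth = 300) {
  start0 <- sample.int(span, n, replace = TRUE) - 1
  w <- sample.int(maxWidth - 9, n, replace = TRUE) + 9
  bedDF(sample(chroms, n, replace = TRUE), start0, start0 + w)
}

table1Path <- function() {
  system.file("extdata", "table1_cohort.tsv", package = "atacmap")
}
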