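test_that("the simulated genome tiles TADs and places features inside them", {
  cfg <- simulationConfig(seed = 30, nTads = 10, peaksPerTad = 5,
                          genesPerTad = 3, straddleFraction = 0)
  g <- simulateGenome(cfg)
  expect_equal(length(g$tads), 10L)
  expect_equal(length(g$peaks), 50L)
  expect_equal(length(g$genes), 30L)
  ## TADs tile without overlap
  expect_equal(sum(GenomicRanges::countOverlaps(g$tads, g$tads,
                                                minoverlap = 2) > 1), 0L)
  ## with no straddlers every peak passes the 90% gate
  expect_equal(length(assignToTAD(g$peaks, g$tads, 0.9)), 50L)
})

test_that("boundary-straddling peaks fail the containment gate", {
  cfg <- simulationConfig(seed = 31, nTads = 20, peaksPerTad = 5,
                          straddleFraction = 0.1)
  g <- simulateGenome(cfg)
  expect_equal(length(g$straddlers), 10L)  # 0.1 of 100 peaks
  assigned <- assignToTAD(g$peaks, g$tads, 0.9)
  expect_false(any(g$straddlers %in% names(assigned)))
  expect_equal(length(assigned), 90L)
})

test_that("simulation output is a pure function of the configuration", {
  cfg <- simulationConfig(seed = 32, nTads = 8, peaksPerTad = 4,
                          genesPerTad = 3, nPlantedLinks = 5,
                          nSurvivalDrivers = 2, nDifferentialPerGroup = 2)
  g1 <- simulateGenome(cfg); g2 <- simulateGenome(cfg)
  expect_identical(g1, g2)
  c1 <- simulateCohort(cfg); c2 <- simulateCohort(cfg)
  expect_identical(records(c1), records(c2))
  s1 <- simulateCounts(g1, c1, cfg); s2 <- simulateCounts(g2, c2, cfg)
  expect_identical(s1, s2)
  r1 <- simulateRadiationPairs(g1, cfg); r2 <- simulateRadiationPairs(g2, cfg)
  expect_identical(r1, r2)
})

test_that("infeasible genome configurations are rejected", {
  expect_error(simulateGenome(simulationConfig(seed = 1, tadLength = 3000)),
               "infeasible")
})

test_that("the default cohort reproduces the study's group structure", {
  cohort <- simulateCohort(simulationConfig(seed = 33))
  s <- summarizeCohort(cohort)
  expect_equal(s@nByGradeStage[c("II.primary", "III.primary",
                                 "IV.primary", "IV.recurrent")],
               c(II.primary = 7L, III.primary = 9L,
                 IV.primary = 9L, IV.recurrent = 13L))
  expect_equal(s@nTotal, 38L)
  expect_equal(s@nRNAseq, 16L)
  expect_equal(s@nPairedPatients, 3L)
})

test_that("grade-dependent survival locations order the group medians", {
  cfg <- simulationConfig(
    seed = 34,
    nSamplesPerGroup = c("II.primary" = 300, "IV.recurrent" = 300),
    survivalMeanlog = c("II.primary" = 4.1, "IV.recurrent" = 1.9),
    nPairedPatients = 0)
  rec <- records(simulateCohort(cfg))
  medII <- median(rec$survival[rec$grade == "II"])
  medIVr <- median(rec$survival[rec$stage == "recurrent"])
  expect_gt(medII, medIVr)
  ## lognormal medians: exp(meanlog)
  expect_equal(medII, exp(4.1), tolerance = 0.15)
  expect_equal(medIVr, exp(1.9), tolerance = 0.15)
})

test_that("counts are non-negative integers with coherent ground truth", {
  cfg <- simulationConfig(seed = 35, nTads = 20, peaksPerTad = 5,
                          genesPerTad = 4, nPlantedLinks = 10,
                          nSurvivalDrivers = 3, nDifferentialPerGroup = 3)
  g <- simulateGenome(cfg)
  coh <- simulateCohort(cfg)
  sim <- simulateCounts(g, coh, cfg)
  expect_true(is.integer(sim$peakCounts) && all(sim$peakCounts >= 0))
  expect_true(is.integer(sim$geneCounts) && all(sim$geneCounts >= 0))
  tr <- sim$groundTruth
  expect_true(all(tr$plantedLinks$peak_id %in% names(g$peaks)))
  expect_true(all(tr$plantedLinks$gene_id %in% names(g$genes)))
  expect_false(any(duplicated(tr$plantedLinks$gene_id)))
  expect_true(all(tr$survivalDrivers$peak_id %in% names(g$peaks)))
  expect_true(all(unlist(tr$droppedPeaks) %in% names(g$peaks)))
  ## linked pairs share a TAD
  expect_equal(unname(tr$peakTads[tr$plantedLinks$peak_id]),
               unname(tr$geneTads[tr$plantedLinks$gene_id]))
})

test_that("planted link correlations are calibrated to the configured effect", {
  rs <- unlist(lapply(1:10, function(s) {
    cfg <- simulationConfig(seed = 500 + s, nTads = 50, peaksPerTad = 4,
                            genesPerTad = 6, nPlantedLinks = 40,
                            nRNAseq = 38)
    g <- simulateGenome(cfg)
    coh <- simulateCohort(cfg)
    sim <- simulateCounts(g, coh, cfg)
    pn <- logNormalize(sim$peakCounts)
    gn <- logNormalize(sim$geneCounts)
    tl <- sim$groundTruth$plantedLinks
    mapply(function(p, gi) cor(normValues(pn)[p, ], normValues(gn)[gi, ]),
           tl$peak_id, tl$gene_id)
  }))
  expect_lt(abs(mean(abs(rs)) - 0.9), 0.05)
  ## signs follow the planted signs in the vast majority of links
  expect_gt(mean(rs > 0), 0.8)
})

test_that("survival drivers correlate with survival in the planted direction", {
  cfg <- simulationConfig(seed = 36, nTads = 30, peaksPerTad = 5,
                          genesPerTad = 2, nSurvivalDrivers = 6,
                          fracPositiveDrivers = 1)
  g <- simulateGenome(cfg); coh <- simulateCohort(cfg)
  sim <- simulateCounts(g, coh, cfg)
  pn <- logNormalize(sim$peakCounts)
  sc <- peakSurvivalCorrelations(pn, survivalVector(coh, colnames(normValues(pn))))
  dr <- sc$r[match(sim$groundTruth$survivalDrivers$peak_id, sc$peak_id)]
  expect_true(all(dr > 0.5))
})

test_that("recurrent dropout lowers open-peak totals in recurrent samples", {
  cfg <- simulationConfig(seed = 37)
  g <- simulateGenome(cfg); coh <- simulateCohort(cfg)
  sim <- simulateCounts(g, coh, cfg)
  tpm <- tpmNormalize(sim$peakCounts, g$peaks)
  open <- totalOpenPeaks(tpm)
  rec <- records(coh)
  expect_lt(mean(open[rec$stage == "recurrent"]),
            mean(open[rec$stage == "primary"]))
})

test_that("radiation pairs lose peaks after treatment, and only then", {
  cfg <- simulationConfig(seed = 38, radiationDropoutFrac = 0.4)
  g <- simulateGenome(cfg)
  rad <- simulateRadiationPairs(g, cfg, nLines = 3)
  expect_equal(nrow(rad$pairs), 3L)
  expect_equal(ncol(rad$counts), 6L)
  open <- totalOpenPeaks(tpmNormalize(rad$counts, g$peaks))
  deltas <- open[rad$pairs$post] - open[rad$pairs$pre]
  expect_true(all(deltas < 0))
  expect_equal(unique(rad$pairs$condition), "9 Gy in three fractions")

  ## without dropout there is no systematic post-treatment loss
  deltas0 <- unlist(lapply(1:6, function(s) {
    cfg0 <- simulationConfig(seed = 600 + s, radiationDropoutFrac = 0)
    g0 <- simulateGenome(cfg0)
    r0 <- simulateRadiationPairs(g0, cfg0, nLines = 3)
    o <- totalOpenPeaks(tpmNormalize(r0$counts, g0$peaks))
    o[r0$pairs$post] - o[r0$pairs$pre]
  }))
  expect_false(all(deltas0 < 0))
  expect_lt(abs(mean(deltas0)), 5)
})

test_that("ground truth serializes to JSON", {
  cfg <- simulationConfig(seed = 39, nTads = 8, peaksPerTad = 4,
                          genesPerTad = 3, nPlantedLinks = 4,
                          nSurvivalDrivers = 2, nDifferentialPerGroup = 1)
  g <- simulateGenome(cfg); coh <- simulateCohort(cfg)
  sim <- simulateCounts(g, coh, cfg)
  tmp <- tempfile(fileext = ".json")
  writeGroundTruth(sim$groundTruth, tmp)
  back <- jsonlite::read_json(tmp)
  expect_equal(length(back$plantedLinks), 4L)  # one record per link
})
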