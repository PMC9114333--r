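## Synthetic multi-omic cohort generator: TAD-partitioned genome,
## negative-binomial counts over latent log2 accessibility, planted
## peak-gene links, survival-driver peaks, group-specific differential
## peaks, recurrence/radiation peak dropout -- with exported ground truth.

#' Build and validate a simulation configuration
#'
#' Returns the full parameter set of the generator, with defaults chosen
#' to emulate a 38-sample mixed-grade glioma accessibility cohort: group
#' sizes 7/9/9/13 over (II, III, IV primary, IV recurrent), lognormal
#' survival with grade-dependent location, negative-binomial counts with
#' lognormal library sizes, mostly positive planted peak-gene links and
#' survival drivers, and global peak dropout in recurrent and
#' post-radiation samples. Every random quantity is a pure function of
#' `seed`.
#'
#' @param seed integer seed fixing all randomness.
#' @param nSamplesPerGroup named integer vector of samples per
#'   `"<grade>.<stage>"` group.
#' @param nTads,tadLength,tadsPerChromosome genome layout: TADs tile each
#'   synthetic chromosome contiguously.
#' @param genesPerTad,peaksPerTad features placed per TAD.
#' @param straddleFraction fraction of peaks deliberately placed across a
#'   TAD boundary so that no TAD contains 90% of them.
#' @param nPlantedLinks number of planted peak-gene regulatory links.
#' @param linkEffect target Pearson correlation of a planted link, on the
#'   normalized scale, in `(0, 1]`.
#' @param linkLatentSd across-sample latent sd (log2) of linked peaks.
#' @param fracPositiveLinks fraction of links with positive sign.
#' @param fracNearestGeneLinks fraction of links planted on the peak's
#'   nearest gene (the remainder are distal same-TAD genes).
#' @param nSurvivalDrivers number of peaks whose accessibility tracks
#'   survival.
#' @param survivalEffect target |Pearson correlation| of a driver peak
#'   with survival.
#' @param fracPositiveDrivers fraction of drivers with positive sign.
#' @param survivalMeanlog,survivalSdlog lognormal survival model (months)
#'   per group.
#' @param nDifferentialPerGroup,differentialEffect group-specific
#'   accessibility shifts (log2 units) planted per (grade, stage) group.
#' @param nbDispersion negative-binomial dispersion (1/size).
#' @param librarySizeMeanlog,librarySizeSdlog lognormal per-sample library
#'   size factors.
#' @param peakBaselineLogRange,geneBaselineLogRange uniform ranges of
#'   baseline log2 abundance.
#' @param latentSd latent log2 noise sd of unplanted features.
#' @param recurrentDropoutFrac fraction of peaks silenced (mean scaled to
#'   near zero) per recurrent sample.
#' @param radiationDropoutFrac fraction of peaks silenced after in-vitro
#'   radiation.
#' @param radiationLabel free-text condition tag for post-radiation
#'   columns.
#' @param nPairedPatients number of patients contributing a primary and a
#'   recurrent specimen.
#' @param nRNAseq number of samples with expression data.
#' @param idh1MutantProbByGrade,idh1UnknownProb IDH1 assignment model.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             nSamplesPerGroup = c("II.primary" = 7,
                                                  "III.primary" = 9,
                                                  "IV.primary" = 9,
                                                  "IV.recurrent" = 13),
                             nTads = 40, tadLength = 1e6,
                             tadsPerChromosome = 10,
                             genesPerTad = 6, peaksPerTad = 10,
                             straddleFraction = 0.05,
                             nPlantedLinks = 50, linkEffect = 0.9,
                             linkLatentSd = 1.8,
                             fracPositiveLinks = 0.9,
                             fracNearestGeneLinks = 0.1,
                             nSurvivalDrivers = 6, survivalEffect = 0.9,
                             fracPositiveDrivers = 0.9,
                             survivalMeanlog = c("II.primary" = 4.1,
                                                 "III.primary" = 3.9,
                                                 "IV.primary" = 2.6,
                                                 "IV.recurrent" = 1.9),
                             survivalSdlog = 0.5,
                             nDifferentialPerGroup = 20,
                             differentialEffect = 1.0,
                             nbDispersion = 0.1,
                             librarySizeMeanlog = 0,
                             librarySizeSdlog = 0.3,
                             peakBaselineLogRange = c(5, 9),
                             geneBaselineLogRange = c(5, 10),
                             latentSd = 0.7,
                             recurrentDropoutFrac = 0.3,
                             radiationDropoutFrac = 0.3,
                             radiationLabel = "9 Gy in three fractions",
                             nPairedPatients = 3, nRNAseq = 16,
                             idh1MutantProbByGrade = c(II = 0.9, III = 0.8,
                                                       IV = 0.3),
                             idh1UnknownProb = 0.1) {
  cfg <- as.list(environment())
  fracs <- c(straddleFraction, fracPositiveLinks, fracNearestGeneLinks,
             fracPositiveDrivers, idh1UnknownProb)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (recurrentDropoutFrac < 0 || recurrentDropoutFrac >= 1 ||
      radiationDropoutFrac < 0 || radiationDropoutFrac >= 1)
    stop("dropout fractions must lie in [0, 1)")
  if (linkEffect <= 0 || linkEffect > 1)
    stop("linkEffect must lie in (0, 1]")
  if (survivalEffect <= 0 || survivalEffect > 1)
    stop("survivalEffect must lie in (0, 1]")
  if (nbDispersion <= 0) stop("nbDispersion must be positive")
  if (any(c(nTads, tadLength, genesPerTad, peaksPerTad) <= 0))
    stop("genome counts and lengths must be positive")
  if (any(nSamplesPerGroup < 0) || sum(nSamplesPerGroup) < 2)
    stop("need at least 2 samples overall")
  if (!all(names(survivalMeanlog) %in% names(nSamplesPerGroup)) ||
      !all(names(nSamplesPerGroup) %in% names(survivalMeanlog)))
    stop("survivalMeanlog must name the same groups as nSamplesPerGroup")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "SimulationConfig"
  cfg
}

## Exact mean and variance of log2(X + 1) for X ~ NB(mu, dispersion phi),
## by direct summation over the pmf.
.nbLogMoments <- function(mu, phi) {
  hi <- max(10, qnbinom(1 - 1e-10, mu = mu, size = 1 / phi))
  xs <- 0:hi
  p <- dnbinom(xs, mu = mu, size = 1 / phi)
  l <- log2(xs + 1)
  m <- sum(p * l)
  c(mean = m, var = sum(p * l^2) - m^2)
}

## Observation model of a feature whose latent log2 mean is
## base + d, d ~ N(0, latentSd), counted with NB noise: returns, via
## 5-point Gauss-Hermite quadrature over d and the exact NB log-moments,
## the average counting-noise variance (`vm`), the effective regression
## slope of the observed log2 value on d (`slope`, < 1 at low abundance
## because of the +1 pseudocount), and the variance of the observed signal
## component (`vSig`). Used to calibrate planted effect sizes so expected
## observed Pearson correlations equal their configured targets.
.nbObservationStats <- function(cfg, base, latentSd) {
  t <- c(-2.0201829, -0.9585725, 0, 0.9585725, 2.0201829)
  w <- c(0.0199532, 0.3936193, 0.9453087, 0.3936193, 0.0199532) / sqrt(pi)
  d <- sqrt(2) * latentSd * t
  mom <- vapply(2^(base + d), .nbLogMoments, c(mean = 0, var = 0),
                phi = cfg$nbDispersion)
  ef <- sum(w * mom["mean", ])
  list(vm = sum(w * mom["var", ]),
       slope = sum(w * mom["mean", ] * d) / latentSd^2,
       vSig = sum(w * (mom["mean", ] - ef)^2))
}

#' Simulate a TAD-partitioned genome with genes and peaks
#'
#' TADs tile each synthetic chromosome contiguously. Genes (with random
#' strand, hence TSS side) and peaks are placed uniformly inside TADs; a
#' `straddleFraction` of peaks is centred on internal TAD boundaries so
#' that no single TAD contains 90% of them, exercising the containment
#' gate.
#'
#' @param config a [simulationConfig()].
#' @return list with named `GRanges` elements `tads`, `genes`, `peaks`,
#'   plus `straddlers` (ids of boundary-spanning peaks).
#' @export
simulateGenome <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  nChrom <- ceiling(cfg$nTads / cfg$tadsPerChromosome)
  tadChrom <- paste0("chr", rep(seq_len(nChrom),
                                each = cfg$tadsPerChromosome))[seq_len(cfg$nTads)]
  posInChrom <- (seq_len(cfg$nTads) - 1) %% cfg$tadsPerChromosome
  tadStart0 <- posInChrom * cfg$tadLength
  tads <- GenomicRanges::GRanges(
    tadChrom, IRanges::IRanges(start = tadStart0 + 1,
                               end = tadStart0 + cfg$tadLength))
  names(tads) <- sprintf("tad_%03d", seq_len(cfg$nTads))

  geneLen <- 2e4
  peakLen <- 1000
  if (cfg$tadLength < 4 * max(geneLen, peakLen) ||
      cfg$genesPerTad * geneLen > 0.8 * cfg$tadLength ||
      cfg$peaksPerTad * peakLen > 0.8 * cfg$tadLength)
    stop("infeasible placement: too many/large features per TAD")

  placeInside <- function(nPerTad, len) {
    offs <- matrix(runif(cfg$nTads * nPerTad, min = 0.02, max = 0.98 - len / cfg$tadLength),
                   nrow = cfg$nTads)
    start0 <- tadStart0 + round(offs * cfg$tadLength)
    GenomicRanges::GRanges(
      rep(tadChrom, nPerTad),
      IRanges::IRanges(start = as.vector(start0) + 1,
                       end = as.vector(start0) + len))
  }

  genes <- placeInside(cfg$genesPerTad, geneLen)
  GenomicRanges::strand(genes) <- sample(c("+", "-"), length(genes),
                                         replace = TRUE)
  names(genes) <- sprintf("gene_%04d", seq_along(genes))

  peaks <- placeInside(cfg$peaksPerTad, peakLen)
  nStraddle <- round(cfg$straddleFraction * length(peaks))
  straddlers <- character(0)
  ## internal boundaries: TADs that have a successor on the same chromosome
  internal <- which(posInChrom < cfg$tadsPerChromosome - 1 &
                      seq_len(cfg$nTads) < cfg$nTads)
  if (nStraddle > 0 && length(internal) > 0) {
    pick <- sample(seq_along(peaks), nStraddle)
    bnd <- sample(internal, nStraddle, replace = TRUE)
    ## centre the peak so 50-85% lies in the left TAD: both fractions < 0.9
    leftFrac <- runif(nStraddle, 0.5, 0.85)
    bndPos0 <- tadStart0[bnd] + cfg$tadLength
    start0 <- round(bndPos0 - leftFrac * peakLen)
    moved <- GenomicRanges::GRanges(
      tadChrom[bnd], IRanges::IRanges(start = start0 + 1,
                                      end = start0 + peakLen))
    peaks[pick] <- moved
    straddlerIdx <- pick
  } else {
    straddlerIdx <- integer(0)
  }
  ## ensure distinct coordinates (ids are coordinate-derived)
  repeat {
    dup <- duplicated(peakIDsFromCoords(peaks))
    if (!any(dup)) break
    peaks[dup] <- GenomicRanges::shift(peaks[dup], 17L)
  }
  peaks <- GenomicRanges::sort(peaks)
  names(peaks) <- peakIDsFromCoords(peaks)
  if (length(straddlerIdx) > 0) {
    straddleAssign <- assignToTAD(peaks, tads, 0.9)
    ## straddlers are exactly the peaks failing the 90% gate
    straddlers <- setdiff(names(peaks), names(straddleAssign))
  }
  list(tads = tads, genes = genes, peaks = peaks, straddlers = straddlers)
}

#' Simulate a clinical cohort
#'
#' Group sizes are deterministic from the configuration; survival is drawn
#' from a grade/stage-dependent lognormal, IDH1 status with
#' grade-correlated mutation probability (and a small undetermined
#' fraction), ages and histopathology vocabulary by grade, and
#' `nPairedPatients` primary/recurrent pairs share a patient id.
#'
#' @param config a [simulationConfig()].
#' @return A [GliomaCohort-class].
#' @export
simulateCohort <- function(config) {
  cfg <- config
  set.seed(cfg$seed + 1L)
  groups <- rep(names(cfg$nSamplesPerGroup), cfg$nSamplesPerGroup)
  n <- length(groups)
  grade <- sub("\\..*$", "", groups)
  stage <- sub("^.*\\.", "", groups)
  pathologyVocab <- list(
    II = c("Oligodendroglioma", "Astrocytoma"),
    III = c("Anaplastic astrocytoma", "Anaplastic oligodendroglioma"),
    IV = "Glioblastoma")
  ageRange <- list(II = c(25, 55), III = c(25, 60), IV = c(30, 78))
  rec <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    age = vapply(grade, function(g) round(runif(1, ageRange[[g]][1],
                                                ageRange[[g]][2])), 0),
    gender = sample(c("male", "female"), n, replace = TRUE),
    pathology = vapply(grade, function(g)
      sample(pathologyVocab[[g]], 1), ""),
    grade = grade, stage = stage,
    idh1 = NA_character_,
    survival = round(rlnorm(n, cfg$survivalMeanlog[groups],
                            cfg$survivalSdlog), 1),
    has_rnaseq = FALSE,
    patient_id = NA_character_,
    stringsAsFactors = FALSE)
  mutant <- rbinom(n, 1, cfg$idh1MutantProbByGrade[grade]) == 1
  unknown <- rbinom(n, 1, cfg$idh1UnknownProb) == 1
  rec$idh1 <- ifelse(unknown, "unknown", ifelse(mutant, "mutant", "wildtype"))
  rec$has_rnaseq[sample(n, min(cfg$nRNAseq, n))] <- TRUE
  prim <- which(stage == "primary" & grade %in% c("III", "IV"))
  recur <- which(stage == "recurrent")
  nPairs <- min(cfg$nPairedPatients, length(prim), length(recur))
  if (nPairs > 0) {
    p <- sample(prim, nPairs); r <- sample(recur, nPairs)
    rec$patient_id[p] <- sprintf("P%02d", seq_len(nPairs))
    rec$patient_id[r] <- sprintf("P%02d", seq_len(nPairs))
  }
  GliomaCohort(rec)
}

## Partition peak indices into driver / linked / per-group differential
## roles; eligible link peaks must sit in a TAD and satisfy the
## nearest/distal gene availability the link plan needs.
.planTruth <- function(genome, cohort, cfg) {
  peaks <- genome$peaks; genes <- genome$genes; tads <- genome$tads
  peakTads <- assignToTAD(peaks, tads, 0.9)
  geneTads <- assignToTAD(genes, tads, 0.9)
  nearest <- nearestGeneTSS(peaks, genes)
  nearestOf <- setNames(nearest$gene_id, nearest$peak_id)
  genesByTad <- split(names(geneTads), geneTads)

  nLinks <- cfg$nPlantedLinks
  nNearest <- round(cfg$fracNearestGeneLinks * nLinks)
  inTad <- names(peakTads)
  nearestInSameTad <- vapply(inTad, function(p) {
    g <- nearestOf[[p]]
    !is.na(g) && !is.na(geneTads[g]) && geneTads[[g]] == peakTads[[p]]
  }, TRUE)
  hasDistal <- vapply(inTad, function(p) {
    gs <- genesByTad[[peakTads[[p]]]]
    g <- nearestOf[[p]]
    length(setdiff(gs, g)) >= 1
  }, TRUE)

  nearestPool <- inTad[nearestInSameTad]
  distalPool <- inTad[hasDistal]

  ## greedily pair peaks with genes so every linked gene is distinct
  linkPeaks <- character(0); linkGenes <- character(0)
  isNearestLink <- logical(0)
  for (p in sample(nearestPool)) {
    if (length(which(isNearestLink)) >= nNearest) break
    g <- nearestOf[[p]]
    if (g %in% linkGenes) next
    linkPeaks <- c(linkPeaks, p); linkGenes <- c(linkGenes, g)
    isNearestLink <- c(isNearestLink, TRUE)
  }
  for (p in sample(setdiff(distalPool, linkPeaks))) {
    if (length(linkPeaks) >= nLinks) break
    cand <- setdiff(genesByTad[[peakTads[[p]]]],
                    c(nearestOf[[p]], linkGenes))
    if (length(cand) == 0) next
    g <- if (length(cand) == 1) cand else sample(cand, 1)
    linkPeaks <- c(linkPeaks, p); linkGenes <- c(linkGenes, g)
    isNearestLink <- c(isNearestLink, FALSE)
  }
  if (length(linkPeaks) < nLinks ||
      length(which(isNearestLink)) < nNearest)
    stop("infeasible link plan: not enough eligible peak-gene ",
         "combinations (increase genesPerTad or nTads)")
  linkSigns <- ifelse(runif(nLinks) < cfg$fracPositiveLinks, 1, -1)

  remaining <- setdiff(names(peaks), linkPeaks)
  if (length(remaining) < cfg$nSurvivalDrivers)
    stop("infeasible plan: not enough peaks for survival drivers")
  drivers <- sample(remaining, cfg$nSurvivalDrivers)
  driverSigns <- ifelse(runif(cfg$nSurvivalDrivers) < cfg$fracPositiveDrivers,
                        1, -1)
  remaining <- setdiff(remaining, drivers)
  groupNames <- names(cfg$nSamplesPerGroup)
  nDiff <- min(cfg$nDifferentialPerGroup,
               floor(length(remaining) / max(1, length(groupNames))))
  diffPeaks <- list()
  for (g in groupNames) {
    diffPeaks[[g]] <- if (nDiff > 0) sample(remaining, nDiff) else character(0)
    remaining <- setdiff(remaining, diffPeaks[[g]])
  }
  list(peakTads = peakTads, geneTads = geneTads,
       plantedLinks = data.frame(
         peak_id = linkPeaks, gene_id = linkGenes, sign = linkSigns,
         is_nearest = isNearestLink,
         stringsAsFactors = FALSE, row.names = NULL),
       survivalDrivers = data.frame(peak_id = drivers, sign = driverSigns,
                                    stringsAsFactors = FALSE),
       groupDifferentialPeaks = diffPeaks)
}

#' Simulate peak and gene count matrices with ground truth
#'
#' Latent log2 peak accessibility is `a = baseline + beta * z(survival)`
#' (survival drivers) `+ gamma * group` (group-differential peaks)
#' `+ noise`; a planted link's gene expression tracks the peak's latent
#' deviation with a noise level calibrated -- accounting for the
#' negative-binomial counting noise -- so the expected Pearson correlation
#' of the pair on the normalized scale equals `linkEffect`. Counts are
#' negative binomial with lognormal per-sample library sizes; each
#' recurrent sample has a random `recurrentDropoutFrac` of peak means
#' scaled to near zero (global peak dropout).
#'
#' @param genome from [simulateGenome()].
#' @param cohort from [simulateCohort()] (or any [GliomaCohort-class]).
#' @param config the same [simulationConfig()].
#' @return list with `peakCounts` and `geneCounts` (integer matrices,
#'   features x samples) and `groundTruth` (planted links with signs,
#'   survival drivers, per-group differential peaks, per-sample dropped
#'   peaks, and the TAD assignments used).
#' @export
simulateCounts <- function(genome, cohort, config) {
  cfg <- config
  set.seed(cfg$seed + 2L)
  rec <- records(cohort)
  n <- nrow(rec)
  peaks <- genome$peaks; genes <- genome$genes
  nP <- length(peaks); nG <- length(genes)
  truth <- .planTruth(genome, cohort, cfg)

  groups <- paste(rec$grade, rec$stage, sep = ".")
  z <- as.numeric(scale(rec$survival))
  if (any(!is.finite(z))) z <- rep(0, n)

  sigma2 <- cfg$latentSd^2
  ## calibrated effect sizes (see vignette): expected observed Pearson of
  ## a driver with survival, and of a link pair, equals the configured
  ## targets under the latent + counting noise model
  peakBaseMid <- mean(cfg$peakBaselineLogRange)
  geneBaseMid <- mean(cfg$geneBaselineLogRange)
  rhoD <- min(cfg$survivalEffect, 0.999)
  beta <- cfg$latentSd  # initial guess; fixed-point refinements
  for (it in 1:3) {
    st <- .nbObservationStats(cfg, peakBaseMid, sqrt(beta^2 + sigma2))
    beta <- sqrt(rhoD^2 * (sigma2 + st$vm / st$slope^2) / (1 - rhoD^2))
  }
  sL2 <- cfg$linkLatentSd^2
  rhoL <- min(cfg$linkEffect, 0.999)
  stP <- .nbObservationStats(cfg, peakBaseMid, cfg$linkLatentSd)
  stG <- .nbObservationStats(cfg, geneBaseMid, cfg$linkLatentSd)
  ## expected pair correlation:
  ##   r = sP sG sL2 / sqrt((vSigP + vmP) * (sG^2 (sL2 + eta) + vmG))
  etaVar <- max(0, ((stP$slope * stG$slope * sL2)^2 /
                      (rhoL^2 * (stP$vSig + stP$vm)) - stG$vm) /
                  stG$slope^2 - sL2)

  peakBase <- runif(nP, cfg$peakBaselineLogRange[1], cfg$peakBaselineLogRange[2])
  A <- matrix(rnorm(nP * n, 0, cfg$latentSd), nP, n,
              dimnames = list(names(peaks), rec$sample_id))
  linkIdx <- match(truth$plantedLinks$peak_id, names(peaks))
  D <- matrix(rnorm(length(linkIdx) * n, 0, cfg$linkLatentSd),
              length(linkIdx), n)
  A[linkIdx, ] <- D  # linked peaks: latent deviation with boosted variance
  drvIdx <- match(truth$survivalDrivers$peak_id, names(peaks))
  A[drvIdx, ] <- A[drvIdx, ] +
    truth$survivalDrivers$sign * beta * rep(z, each = length(drvIdx))
  for (g in names(truth$groupDifferentialPeaks)) {
    di <- match(truth$groupDifferentialPeaks[[g]], names(peaks))
    if (length(di) > 0)
      A[di, groups == g] <- A[di, groups == g] + cfg$differentialEffect
  }
  A <- A + peakBase

  ## per-sample global dropout in recurrent specimens; peaks carrying
  ## planted links or survival effects are exempt so the planted ground
  ## truth stays coherent (dropout emulates background chromatin closing)
  dropMask <- matrix(1, nP, n)
  dropped <- list()
  droppable <- setdiff(seq_len(nP), c(linkIdx, drvIdx))
  recurSamples <- which(rec$stage == "recurrent")
  for (j in recurSamples) {
    dj <- sample(droppable, min(length(droppable),
                                round(cfg$recurrentDropoutFrac * nP)))
    dropMask[dj, j] <- 0.02
    dropped[[rec$sample_id[j]]] <- names(peaks)[dj]
  }

  sPeak <- rlnorm(n, cfg$librarySizeMeanlog, cfg$librarySizeSdlog)
  muPeak <- sweep(2^A * dropMask, 2, sPeak, "*")
  peakCounts <- matrix(rnbinom(nP * n, mu = muPeak, size = 1 / cfg$nbDispersion),
                       nP, n, dimnames = dimnames(A))

  geneBase <- runif(nG, cfg$geneBaselineLogRange[1], cfg$geneBaselineLogRange[2])
  E <- matrix(rnorm(nG * n, 0, cfg$latentSd), nG, n,
              dimnames = list(names(genes), rec$sample_id))
  gIdx <- match(truth$plantedLinks$gene_id, names(genes))
  E[gIdx, ] <- truth$plantedLinks$sign * D +
    matrix(rnorm(length(gIdx) * n, 0, sqrt(etaVar)), length(gIdx), n)
  E <- E + geneBase
  sGene <- rlnorm(n, cfg$librarySizeMeanlog, cfg$librarySizeSdlog)
  muGene <- sweep(2^E, 2, sGene, "*")
  geneCounts <- matrix(rnbinom(nG * n, mu = muGene, size = 1 / cfg$nbDispersion),
                       nG, n, dimnames = dimnames(E))

  storage.mode(peakCounts) <- "integer"
  storage.mode(geneCounts) <- "integer"
  groundTruth <- list(plantedLinks = truth$plantedLinks,
                      survivalDrivers = truth$survivalDrivers,
                      groupDifferentialPeaks = truth$groupDifferentialPeaks,
                      droppedPeaks = dropped,
                      peakTads = truth$peakTads,
                      geneTads = truth$geneTads)
  list(peakCounts = peakCounts, geneCounts = geneCounts,
       groundTruth = groundTruth)
}

#' Simulate paired pre/post-radiation accessibility profiles
#'
#' For `nLines` cultured lines, draws a pre-treatment count column from
#' the latent accessibility model and a post-treatment column in which a
#' random `radiationDropoutFrac` of peak means is scaled to near zero,
#' emulating global chromatin closing after irradiation. The condition
#' label of the post columns is taken from the configuration.
#'
#' @param genome from [simulateGenome()].
#' @param config a [simulationConfig()].
#' @param nLines number of paired cultures; default 3.
#' @return list with `counts` (peaks x 2*nLines, columns
#'   `<line>_pre`/`<line>_post`), `pairs` (data.frame of column pairs and
#'   the condition label) and `groundTruth` (dropped peaks per line).
#' @export
simulateRadiationPairs <- function(genome, config, nLines = 3) {
  cfg <- config
  set.seed(cfg$seed + 3L)
  peaks <- genome$peaks
  nP <- length(peaks)
  base <- runif(nP, cfg$peakBaselineLogRange[1], cfg$peakBaselineLogRange[2])
  lines <- sprintf("line%d", seq_len(nLines))
  cols <- as.vector(rbind(paste0(lines, "_pre"), paste0(lines, "_post")))
  counts <- matrix(0L, nP, 2 * nLines,
                   dimnames = list(names(peaks), cols))
  dropped <- list()
  for (k in seq_len(nLines)) {
    aPre <- base + rnorm(nP, 0, cfg$latentSd)
    aPost <- base + rnorm(nP, 0, cfg$latentSd)
    mask <- rep(1, nP)
    dk <- sample(nP, round(cfg$radiationDropoutFrac * nP))
    mask[dk] <- 0.02
    dropped[[lines[k]]] <- names(peaks)[dk]
    s <- rlnorm(2, cfg$librarySizeMeanlog, cfg$librarySizeSdlog)
    counts[, 2 * k - 1] <- rnbinom(nP, mu = s[1] * 2^aPre,
                                   size = 1 / cfg$nbDispersion)
    counts[, 2 * k] <- rnbinom(nP, mu = s[2] * 2^aPost * mask,
                               size = 1 / cfg$nbDispersion)
  }
  storage.mode(counts) <- "integer"
  pairs <- data.frame(line = lines,
                      pre = paste0(lines, "_pre"),
                      post = paste0(lines, "_post"),
                      condition = cfg$radiationLabel,
                      stringsAsFactors = FALSE)
  list(counts = counts, pairs = pairs,
       groundTruth = list(droppedPeaks = dropped))
}

#' Serialize simulator ground truth as JSON
#'
#' @param groundTruth the `groundTruth` element of [simulateCounts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(groundTruth, path) {
  jsonlite::write_json(groundTruth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
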