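## Seeded synthetic cell-line panel generator with planted ground truth.
##
## The generator emulates the statistical structure the downstream analyses
## assume: a panel of ~49 cell lines profiled on a binary mutation block with
## one high-prevalence driver, thousands of log-normal transcripts partially
## driven by latent pathway factors, ~88 proteins generated as noisy linear
## readouts of their matched transcripts and latent factors (so proteins are
## predictable from transcripts), a mutually exclusive two-protein "switch",
## drugs grouped into classes with correlated planted sensitivities, null
## drugs with no molecular association, tissue-level AUC offsets, duplicate
## cell lines sharing a patient, and nine-dose 1:3 serial-dilution viability
## curves whose noiseless dose-grid mean equals the planted AUC exactly.
##
## Random-number discipline: one master seed with independent named
## substreams per block, so e.g. adding drugs never perturbs the transcript
## draw.

#' Construct a synthetic-panel configuration
#'
#' See [PanelConfig-class] for the meaning of each parameter. Drug roles are
#' assigned in order: drugs of `drugClasses` row 1 (when present) form the
#' driver-dependent class whose AUC is controlled by the planted driver
#' mutation; further classes with `shared = TRUE` share planted protein
#' effects (correlated sensitivities); remaining non-null drugs each get an
#' independent 5-protein planted signal; the last `nNullDrugs` drugs are null.
#'
#' @param nCellLines,nTissues,nTranscripts,nProteins,nMutations panel sizes.
#' @param driverPrevalence driver-mutation prevalence in (0, 1).
#' @param nDrugs,drugClasses,nNullDrugs drug layout (see above).
#' @param effectSize planted per-drug signal SD as a multiple of the AUC
#'   measurement noise SD `viabilityNoiseSd / sqrt(nDoses)`.
#' @param tissueEffectSd SD of tissue x drug AUC offsets.
#' @param nDoses,doseDilutionFactor dose grid layout.
#' @param viabilityNoiseSd additive viability noise SD (the screen's
#'   measurement noise; magnitude is a free modelling choice).
#' @param nDuplicatePatients number of near-copy cell lines sharing a patient.
#' @param seed master seed.
#' @param nInformativeFeatures planted proteins per informative drug/class.
#' @param driverEffect AUC reduction in driver-mutated lines for the driver
#'   class (AUC units).
#' @return a validated [PanelConfig-class].
#' @export
panelConfig <- function(nCellLines = 49L, nTissues = 1L, nTranscripts = 2000L,
                        nProteins = 88L, nMutations = 300L,
                        driverPrevalence = 0.7, nDrugs = 12L,
                        drugClasses = data.frame(size = c(2L, 3L),
                                                 shared = c(TRUE, TRUE)),
                        nNullDrugs = 3L, effectSize = 2,
                        tissueEffectSd = 0, nDoses = 9L,
                        doseDilutionFactor = 3, viabilityNoiseSd = 0.05,
                        nDuplicatePatients = 0L, seed = 1L,
                        nInformativeFeatures = 5L, driverEffect = 0.25) {
  cfg <- new("PanelConfig",
             nCellLines = as.integer(nCellLines),
             nTissues = as.integer(nTissues),
             nTranscripts = as.integer(nTranscripts),
             nProteins = as.integer(nProteins),
             nMutations = as.integer(nMutations),
             driverPrevalence = driverPrevalence,
             nDrugs = as.integer(nDrugs), drugClasses = drugClasses,
             nNullDrugs = as.integer(nNullDrugs), effectSize = effectSize,
             tissueEffectSd = tissueEffectSd, nDoses = as.integer(nDoses),
             doseDilutionFactor = doseDilutionFactor,
             viabilityNoiseSd = viabilityNoiseSd,
             nDuplicatePatients = as.integer(nDuplicatePatients),
             seed = as.integer(seed))
  validObject(cfg)
  attr(cfg, "nInformativeFeatures") <- as.integer(nInformativeFeatures)
  attr(cfg, "driverEffect") <- driverEffect
  cfg
}

## Dose grid implied by a config (arbitrary absolute anchor; the AUC summary
## depends only on the log-spacing).
.doseGrid <- function(config) {
  1e-3 * config@doseDilutionFactor^(seq_len(config@nDoses) - 1L)
}

## Noiseless sigmoid viabilities on `doses` whose arithmetic mean equals
## `target`: 1/(1 + d/ec50) with ec50 solved numerically; flat curve for
## target >= 1 (viability above control at all doses).
.solveCurve <- function(target, doses) {
  if (target >= 1) return(rep(target, length(doses)))
  f <- function(le) mean(1 / (1 + doses / exp(le))) - target
  lo <- log(min(doses)) - 30; hi <- log(max(doses)) + 30
  le <- uniroot(f, c(lo, hi), tol = 1e-13)$root
  1 / (1 + doses / exp(le))
}

#' Generate a long dose-response table from a true-AUC matrix
#'
#' For every (cell line, drug) pair, a monotone-decreasing logistic curve in
#' log-dose (upper asymptote 1, lower asymptote 0, inflection solved
#' numerically) whose noiseless mean over the dose grid equals the target AUC
#' exactly; additive Gaussian noise of SD `viabilityNoiseSd` is then applied
#' per dose (truncated at 0, since viability is non-negative). Targets at or
#' above 1 yield flat curves at the target value.
#'
#' @param trueAuc cell line x drug matrix of target AUCs in [0, 1.2].
#' @param config a [PanelConfig-class] (dose grid and noise SD).
#' @param seed seed for the noise draw (default: derived from the config).
#' @return data.frame with columns cell_line, drug, dose, viability.
#' @export
generateDoseResponse <- function(trueAuc, config,
                                 seed = streamSeed(config@seed,
                                                   "dose_response")) {
  if (any(trueAuc < 0 | trueAuc > 1.2))
    stop("true AUC values must lie within [0, 1.2]")
  doses <- .doseGrid(config)
  nd <- length(doses)
  lines <- rownames(trueAuc) %||% paste0("line_", seq_len(nrow(trueAuc)))
  drugs <- colnames(trueAuc) %||% paste0("drug_", seq_len(ncol(trueAuc)))
  viab <- matrix(0, nd, length(lines) * length(drugs))
  k <- 0L
  for (j in seq_along(drugs)) for (i in seq_along(lines)) {
    k <- k + 1L
    viab[, k] <- .solveCurve(trueAuc[i, j], doses)
  }
  if (config@viabilityNoiseSd > 0)
    viab <- withSeed(seed,
      pmax(viab + rnorm(length(viab), 0, config@viabilityNoiseSd), 0))
  data.frame(
    cell_line = rep(rep(lines, each = nd), times = length(drugs)),
    drug = rep(drugs, each = nd * length(lines)),
    dose = rep(doses, times = length(lines) * length(drugs)),
    viability = as.vector(viab))
}

#' Generate a synthetic multi-omic drug-screen panel
#'
#' Deterministic for a fixed config (same config, same seed: byte-identical
#' panels). See the package vignette for the full generative model; in brief:
#' transcript log2(1 + x) values are Gaussian per gene with partial loadings
#' on three latent pathway factors; each protein is a noisy linear readout of
#' one matched transcript plus a latent factor (emitted on a positive linear
#' intensity scale, so the standard log2 transform applies); the first two
#' proteins form an anti-correlated expression switch driven by a bimodal
#' cluster factor; mutations are Bernoulli columns plus one driver column hit
#' in round(driverPrevalence * n) lines; each non-null drug's true AUC is
#' baseline + planted linear effect of standardized log2 proteins (or the
#' driver mutation for the driver class) + tissue offset; duplicate lines are
#' near-copies of an original sharing its patient id.
#'
#' @param config a [PanelConfig-class].
#' @return a [CellLinePanel-class] carrying its [GroundTruth-class].
#' @examples
#' panel <- generatePanel(panelConfig(nCellLines = 20, nTranscripts = 100,
#'                                    nMutations = 40, nDrugs = 6,
#'                                    nNullDrugs = 2, seed = 7))
#' panel
#' @export
generatePanel <- function(config) {
  stopifnot(is(config, "PanelConfig"))
  validObject(config)
  seed <- config@seed
  nTot <- config@nCellLines
  nDup <- config@nDuplicatePatients
  nOrig <- nTot - nDup
  nInf <- attr(config, "nInformativeFeatures") %||% 5L
  drvEff <- attr(config, "driverEffect") %||% 0.25
  lines <- sprintf("CL%03d", seq_len(nTot))
  orig <- seq_len(nOrig)

  ## tissues: balanced assignment, shuffled
  tissueNames <- sprintf("tissue_%d", seq_len(config@nTissues))
  tissue <- withSeed(streamSeed(seed, "tissues"),
    sample(rep(tissueNames, length.out = nOrig)))

  ## latent pathway factors and the bimodal switch factor
  K <- 3L
  lat <- withSeed(streamSeed(seed, "latent"), {
    Z <- matrix(rnorm(nOrig * K), nOrig, K)
    cl <- rbinom(nOrig, 1, 0.5)
    list(Z = Z, zSwitch = ifelse(cl == 1, 1, -1) + rnorm(nOrig, 0, 0.3))
  })

  ## transcripts: per-gene Gaussian log2(1 + x) marginals + factor loadings
  nT <- config@nTranscripts
  trs <- withSeed(streamSeed(seed, "transcripts"), {
    geneMean <- rnorm(nT, 4, 2)
    geneSd <- runif(nT, 0.2, 1.5)
    fac <- sample(K, nT, replace = TRUE)
    loadW <- ifelse(runif(nT) < 0.5, runif(nT, 0.3, 0.9), 0) * geneSd
    eps <- matrix(rnorm(nOrig * nT), nOrig, nT)
    log2T <- sweep(lat$Z[, fac, drop = FALSE] *
                     rep(loadW, each = nOrig) +
                     eps * rep(geneSd, each = nOrig), 2, geneMean, `+`)
    log2T
  })
  colnames(trs) <- sprintf("gene_%04d", seq_len(nT))
  transcriptRaw <- pmax(2^trs - 1, 0)

  ## proteins: noisy linear readout of matched transcript + latent factor;
  ## proteins 1 and 2 are the mutually exclusive switch pair
  nP <- config@nProteins
  protNames <- sprintf("prot_%03d", seq_len(nP))
  prot <- withSeed(streamSeed(seed, "proteins"), {
    mMap <- sample(nT, nP, replace = TRUE)
    fac <- sample(K, nP, replace = TRUE)
    tStd <- scale(trs[, mMap, drop = FALSE])
    M <- 3 + 0.8 * tStd + 0.5 * lat$Z[, fac, drop = FALSE] +
      matrix(rnorm(nOrig * nP, 0, 0.4), nOrig, nP)
    if (nP >= 2L) {
      M[, 1] <- 3 + 1.2 * lat$zSwitch + rnorm(nOrig, 0, 0.4)
      M[, 2] <- 3 - 1.2 * lat$zSwitch + rnorm(nOrig, 0, 0.4)
    }
    list(M = M, fac = fac)
  })
  log2P <- prot$M
  attr(log2P, "scaled:center") <- NULL
  attr(log2P, "scaled:scale") <- NULL
  colnames(log2P) <- protNames
  proteinRaw <- 2^log2P
  switchPair <- if (nP >= 2L) protNames[1:2] else character(0)

  ## mutations: Bernoulli columns + one planted driver column
  nM <- config@nMutations
  mutNames <- sprintf("mut_%04d", seq_len(nM))
  mut <- withSeed(streamSeed(seed, "mutations"), {
    prev <- runif(nM, min(3.5 / nOrig, 0.4), 0.45)
    matrix(rbinom(nOrig * nM, 1, rep(prev, each = nOrig)), nOrig, nM)
  })
  driverIdx <- withSeed(streamSeed(seed, "driver"), sample(nM, 1))
  nHit <- max(1L, min(nOrig - 1L, round(config@driverPrevalence * nOrig)))
  driverLines <- withSeed(streamSeed(seed, "driver_lines"),
                          sample(nOrig, nHit))
  mut[, driverIdx] <- 0
  mut[driverLines, driverIdx] <- 1
  colnames(mut) <- mutNames
  driverId <- mutNames[driverIdx]

  ## drugs: roles, baselines, planted effects
  nD <- config@nDrugs
  drugNames <- sprintf("drug_%02d", seq_len(nD))
  classes <- config@drugClasses
  nClassDrugs <- if (nrow(classes)) sum(classes$size) else 0L
  nSingle <- nD - nClassDrugs - config@nNullDrugs
  role <- rep("null", nD)
  classOf <- rep(NA_integer_, nD)
  pos <- 1L
  if (nrow(classes)) for (ci in seq_len(nrow(classes))) {
    idx <- pos:(pos + classes$size[ci] - 1L)
    role[idx] <- if (ci == 1L) "driver" else
      if (isTRUE(classes$shared[ci])) "shared" else "single"
    classOf[idx] <- ci
    pos <- pos + classes$size[ci]
  }
  if (nSingle > 0L) {
    role[pos:(pos + nSingle - 1L)] <- "single"
    pos <- pos + nSingle
  }

  noiseSd <- config@viabilityNoiseSd / sqrt(config@nDoses)
  sdTarget <- config@effectSize * noiseSd
  Xp <- scale(log2P)             # planted effects act on standardized log2
  plantable <- if (nP > 2L) 3:nP else seq_len(nP)

  drugsOut <- withSeed(streamSeed(seed, "drugs"), {
    baseline <- runif(nD, 0.45, 0.85)
    sig <- matrix(0, nOrig, nD)
    planted <- setNames(vector("list", nD), drugNames)
    for (d in seq_len(nD)) planted[[d]] <- numeric(0)
    classBeta <- list()
    for (d in seq_len(nD)) {
      if (role[d] == "driver") {
        eff <- drvEff * runif(1, 0.9, 1.1)
        sig[, d] <- -eff * mut[, driverIdx]
        planted[[d]] <- setNames(-eff, driverId)
      } else if (role[d] %in% c("shared", "single")) {
        keyi <- classOf[d]
        if (role[d] == "shared" && !is.null(classBeta[[as.character(keyi)]])) {
          cb <- classBeta[[as.character(keyi)]]
        } else {
          ## informative markers form a coherent pathway signature: features
          ## sharing one latent factor, with effect magnitudes bounded away
          ## from zero so every planted marker carries real signal
          fSel <- sample(K, 1)
          pool <- intersect(which(prot$fac == fSel), plantable)
          if (!length(pool)) pool <- plantable
          ## strongest readouts of the pathway factor first, so the signature
          ## is a coherent correlated marker group
          pool <- pool[order(-abs(cor(Xp[, pool, drop = FALSE],
                                      lat$Z[, fSel])))]
          nPick <- min(nInf, length(plantable))
          feat <- head(pool, nPick)
          if (length(feat) < nPick)
            feat <- c(feat, sample(setdiff(plantable, feat),
                                   nPick - length(feat)))
          sgn <- sign(as.vector(cor(Xp[, feat, drop = FALSE], lat$Z[, fSel])))
          beta <- runif(length(feat), 0.8, 1.2) * sgn * sample(c(-1, 1), 1)
          raw <- as.vector(Xp[, feat, drop = FALSE] %*% beta)
          beta <- beta * sdTarget / sd(raw)
          cb <- list(feat = feat, beta = beta)
          if (role[d] == "shared")
            classBeta[[as.character(keyi)]] <- cb
        }
        sc <- runif(1, 0.8, 1.2)
        sig[, d] <- as.vector(Xp[, cb$feat, drop = FALSE] %*% cb$beta) * sc
        planted[[d]] <- setNames(cb$beta * sc, protNames[cb$feat])
      }
    }
    tiss <- matrix(if (config@tissueEffectSd > 0)
      rnorm(config@nTissues * nD, 0, config@tissueEffectSd) else 0,
      config@nTissues, nD, dimnames = list(tissueNames, drugNames))
    list(baseline = baseline, sig = sig, planted = planted, tissueOffsets = tiss)
  })

  tIdx <- match(tissue, tissueNames)
  trueAuc <- sweep(drugsOut$sig, 2, drugsOut$baseline, `+`) +
    drugsOut$tissueOffsets[tIdx, , drop = FALSE]
  trueAuc <- pmin(pmax(trueAuc, 0.02), 1.18)
  dimnames(trueAuc) <- list(lines[orig], drugNames)

  ## duplicates: near-copies of distinct originals, same patient
  patients <- sprintf("patient_%03d", seq_len(nOrig))
  if (nDup > 0L) {
    dupOf <- withSeed(streamSeed(seed, "duplicates_pick"),
                      sample(nOrig, nDup))
    dupNoise <- function(m) {
      s <- colSds(m)
      withSeed(streamSeed(seed, "duplicates_noise"),
        m[dupOf, , drop = FALSE] +
          matrix(rnorm(nDup * ncol(m), 0, rep(0.05 * s, each = nDup)),
                 nDup, ncol(m)))
    }
    transcriptRaw <- rbind(transcriptRaw, pmax(dupNoise(transcriptRaw), 0))
    proteinRaw <- rbind(proteinRaw,
                        pmax(dupNoise(proteinRaw), min(proteinRaw) / 2))
    mut <- rbind(mut, mut[dupOf, , drop = FALSE])  # binary block: exact copy
    trueAuc <- rbind(trueAuc,
      pmin(pmax(trueAuc[dupOf, , drop = FALSE] +
        withSeed(streamSeed(seed, "duplicates_auc"),
                 matrix(rnorm(nDup * nD, 0, 0.01), nDup, nD)), 0.02), 1.18))
    tissue <- c(tissue, tissue[dupOf])
    patients <- c(patients, patients[dupOf])
  }
  rownames(transcriptRaw) <- rownames(proteinRaw) <- rownames(mut) <-
    rownames(trueAuc) <- lines
  names(tissue) <- names(patients) <- lines

  doseTab <- generateDoseResponse(trueAuc, config)

  gt <- new("GroundTruth",
            plantedCoefficients = drugsOut$planted,
            driverMutationId = driverId,
            driverDependentDrugs = drugNames[role == "driver"],
            nullDrugs = drugNames[role == "null"],
            tissueOffsets = drugsOut$tissueOffsets,
            trueAuc = trueAuc, patientIds = patients,
            switchPair = switchPair)
  new("CellLinePanel", mutationMatrix = mut, transcriptMatrix = transcriptRaw,
      proteinMatrix = proteinRaw, doseResponse = doseTab,
      tissues = tissue, patients = patients, groundTruth = gt)
}
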