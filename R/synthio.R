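#' @importFrom stats rnorm runif rpois median setNames
NULL

# Ground truth bundles returned by every generator; downstream tests use
# them for parameter-recovery checks.
newSimTruth <- function(...) structure(list(...), class = "SimTruth")

#' @export
print.SimTruth <- function(x, ...) {
  cat("SimTruth:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a spike-in absolute-quantification experiment
#'
#' Emulates a label-free run in which protein standards of known, staggered
#' amounts (UPS2-style) are added to a lysate: standards and sample proteins
#' obey the same log-linear signal law
#' \deqn{\log_{10}(signal) = slope \cdot \log_{10}(amount) + intercept + N(0, noiseSd)}
#' with log-normal measurement noise. Sample-protein true concentrations are
#' drawn log-uniformly over \code{dynamicRangeOrders} orders of magnitude,
#' matching the deep dynamic range of egg proteomes.
#'
#' @param nStandards number of spike-in standards (>= 3), log-spaced over the
#'   dynamic range.
#' @param nSampleProteins number of sample proteins.
#' @param slope,intercept parameters of the signal law (slope must be
#'   non-zero; intercept in log10-signal units).
#' @param noiseSd measurement noise sd in log10 units.
#' @param dynamicRangeOrders orders of magnitude spanned (default 8).
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @return list with \code{spikeins} (standards table), \code{signals}
#'   (single-stage [StageExperiment-class] of sample-protein signals) and
#'   \code{truth} (\code{SimTruth} with \code{trueConcentrations} in nM,
#'   \code{curveSlope}, \code{curveIntercept}, \code{seed}).
#' @examples
#' sim <- simulateSpikeIn(8, 20, slope = 0.9, intercept = 2,
#'                        noiseSd = 0, seed = 1)
#' fitStandardCurve(sim$spikeins)
#' @export
simulateSpikeIn <- function(nStandards = 48, nSampleProteins = 1000,
                            slope = 1, intercept = 0, noiseSd = 0.2,
                            dynamicRangeOrders = 8, seed = 1) {
  stopIfNot(nStandards >= 3, "invalid parameter: nStandards must be >= 3")
  stopIfNot(nSampleProteins >= 1,
            "invalid parameter: nSampleProteins must be positive")
  stopIfNot(slope != 0, "invalid parameter: slope must be non-zero")
  stopIfNot(dynamicRangeOrders > 0,
            "invalid parameter: dynamicRangeOrders must be > 0")
  stopIfNot(noiseSd >= 0, "invalid parameter: noiseSd must be >= 0")
  withSeed(seed, {
    # standards: log-spaced known amounts (nM) centred on 1
    lo <- -dynamicRangeOrders / 2
    hi <- dynamicRangeOrders / 2
    logAmount <- seq(lo, hi, length.out = nStandards)
    amount <- 10^logAmount
    sigStd <- 10^(slope * logAmount + intercept +
                    stats::rnorm(nStandards, 0, noiseSd))
    spikeins <- data.frame(
      standard_id = sprintf("UPS_%03d", seq_len(nStandards)),
      known_amount = amount, measured_signal = sigStd)
    # sample proteins: log-uniform true concentrations, same signal law
    logConc <- stats::runif(nSampleProteins, lo, hi)
    sigSmp <- 10^(slope * logConc + intercept +
                    stats::rnorm(nSampleProteins, 0, noiseSd))
    ids <- sprintf("prot_%05d", seq_len(nSampleProteins))
    m <- matrix(sigSmp, ncol = 1L, dimnames = list(ids, "unfE"))
    signals <- StageExperiment(m, modality = "protein_relative",
                               species = "synthetic")
    truth <- newSimTruth(trueConcentrations = stats::setNames(10^logConc, ids),
                         curveSlope = slope, curveIntercept = intercept,
                         seed = seed)
    list(spikeins = spikeins, signals = signals, truth = truth)
  })
}

# Stage-dependent decorrelation weight in normalized time t in [0,1]: how
# strongly the species-B partner profile is replaced by an independent one.
# The mid-development window is the clamped quadratic hump
# q(t) = max(0, 1 - 16 (t - 1/2)^2), which is ~1 inside t in [0.4, 0.6]
# (gastrulation/neurulation in an 8-stage series) and 0 outside
# t in [0.25, 0.75]; the hourglass shape decorrelates the complement.
# Concentrating the window keeps the mid stages -- not their flanks -- the
# extreme ones, which is what the shape labels mean.
shapeWeight <- function(shape, t, effectSize) {
  q <- pmax(0, 1 - 16 * (t - 0.5)^2)
  w <- switch(shape,
    inverse_hourglass = q,
    hourglass         = 1 - q,
    flat              = rep(0.5, length(t)),
    stop("invalid parameter: unknown shape '", shape, "'")
  )
  pmin(pmax(effectSize * w, 0), 1)
}

# Smooth random temporal program: a draw from a stationary Gaussian
# process over normalized time with squared-exponential covariance, so
# every stage has the same marginal variance and neighbouring stages are
# autocorrelated, as in real developmental series. Amplitude is in log10
# units; 0.4 gives the few-fold relative dynamics typical of embryonic
# proteome time courses. Per-entity abundance baselines are added
# separately (they cancel under sum-to-one scaling).
# Returns an n x length(t) matrix of log10 curves.
smoothPrograms <- function(n, t, lengthScale = 0.2, amplitude = 0.4) {
  K <- amplitude^2 * exp(-0.5 * (outer(t, t, `-`) / lengthScale)^2)
  diag(K) <- diag(K) + 1e-10
  matrix(stats::rnorm(n * length(t)), n) %*% chol(K)
}

#' Simulate paired two-species developmental time series
#'
#' Each ortholog pair shares a smooth latent temporal program (a draw from
#' a stationary Gaussian process over normalized stage index, so
#' neighbouring stages are autocorrelated as in real developmental
#' series). Stage-dependent decorrelation is injected by mixing the
#' species-B partner with an independent program, with a mixing weight
#' that follows a clamped quadratic window in normalized stage index:
#' maximal at mid-development for \code{"inverse_hourglass"}, maximal
#' outside mid-development for \code{"hourglass"}, and uniform for
#' \code{"flat"}.
#' \code{effectSize = 0} makes all shapes indistinguishable from flat.
#' Abundances are \eqn{10^{x}} of the log10 latent value plus
#' \code{N(0, noiseSd)} log10 noise, hence strictly positive.
#'
#' @param nOrthologs number of one-to-one ortholog pairs.
#' @param nStagesA,nStagesB stages per species (>= 4).
#' @param shape \code{"hourglass"}, \code{"inverse_hourglass"} or
#'   \code{"flat"}.
#' @param effectSize decorrelation strength (>= 0; 1 = full replacement at
#'   the weight maximum).
#' @param noiseSd log10 measurement noise sd.
#' @param seed integer seed.
#' @param stagesA,stagesB optional stage label vectors.
#' @return list with \code{exprA}, \code{exprB} ([StageExperiment-class]),
#'   \code{map} ([OrthologMap-class]) and \code{truth} (\code{SimTruth} with
#'   \code{shapeLabel}, per-stage mixing weights, seed).
#' @examples
#' sim <- simulateTwoSpeciesSeries(50, shape = "flat", effectSize = 0,
#'                                 noiseSd = 0, seed = 1)
#' sim$map
#' @export
simulateTwoSpeciesSeries <- function(nOrthologs = 300, nStagesA = 8,
                                     nStagesB = 8,
                                     shape = c("flat", "inverse_hourglass",
                                               "hourglass"),
                                     effectSize = 1, noiseSd = 0.05,
                                     seed = 1, stagesA = NULL,
                                     stagesB = NULL) {
  if (is.character(shape) && length(shape) >= 1L)
    shape <- shape[1L]
  if (!shape %in% c("flat", "inverse_hourglass", "hourglass"))
    stop("invalid parameter: unknown shape '", shape, "'")
  stopIfNot(nStagesA >= 4 && nStagesB >= 4,
            "invalid parameter: both species need >= 4 stages")
  stopIfNot(effectSize >= 0, "invalid parameter: effectSize must be >= 0")
  stopIfNot(nOrthologs >= 2, "invalid parameter: nOrthologs must be >= 2")
  if (is.null(stagesA)) stagesA <- sprintf("A%02d", seq_len(nStagesA))
  if (is.null(stagesB)) stagesB <- sprintf("B%02d", seq_len(nStagesB))
  stopIfNot(length(stagesA) == nStagesA && length(stagesB) == nStagesB,
            "stage label vectors must match the stage counts")
  withSeed(seed, {
    tA <- seq(0, 1, length.out = nStagesA)
    tB <- seq(0, 1, length.out = nStagesB)
    tAll <- sort(unique(c(tA, tB)))
    shared <- smoothPrograms(nOrthologs, tAll)
    indep <- smoothPrograms(nOrthologs, tAll)
    iA <- match(tA, tAll)
    iB <- match(tB, tAll)
    w <- shapeWeight(shape, tB, effectSize)
    # per-ortholog abundance baseline, shared by the pair; cancels under
    # sum-to-one scaling so only temporal shape carries cross-species signal
    base <- stats::rnorm(nOrthologs, 0, 1)
    logA <- base + shared[, iA, drop = FALSE] +
      matrix(stats::rnorm(nOrthologs * nStagesA, 0, noiseSd), nOrthologs)
    mixB <- sweep(shared[, iB, drop = FALSE], 2L, 1 - w, `*`) +
      sweep(indep[, iB, drop = FALSE], 2L, w, `*`)
    logB <- base + mixB +
      matrix(stats::rnorm(nOrthologs * nStagesB, 0, noiseSd), nOrthologs)
    idsA <- sprintf("a_%05d", seq_len(nOrthologs))
    idsB <- sprintf("b_%05d", seq_len(nOrthologs))
    exprA <- StageExperiment(
      matrix(10^logA, nOrthologs, dimnames = list(idsA, stagesA)),
      modality = "protein_relative", species = "speciesA")
    exprB <- StageExperiment(
      matrix(10^logB, nOrthologs, dimnames = list(idsB, stagesB)),
      modality = "protein_relative", species = "speciesB")
    map <- OrthologMap(idsA, idsB, speciesA = "speciesA",
                       speciesB = "speciesB")
    truth <- newSimTruth(shapeLabel = shape, mixingWeightsB = w,
                         effectSize = effectSize, seed = seed)
    list(exprA = exprA, exprB = exprB, map = map, truth = truth)
  })
}

#' Simulate two sequence batches differing by SNP-level substitutions
#'
#' Batch 1 holds random protein sequences; batch 2 is a copy in which each
#' residue is independently substituted (to a different residue) with
#' probability \code{snpRate}, emulating protein-level polymorphism between
#' animal batches. Identifiers are identical across batches.
#'
#' @param nSequences number of sequences.
#' @param meanLength mean sequence length (Poisson-distributed, min 1).
#' @param snpRate per-residue substitution probability (must be < 0.1).
#' @param seed integer seed.
#' @return list with \code{batch1}, \code{batch2}
#'   ([Biostrings::AAStringSet]) and \code{truth} (\code{SimTruth} with
#'   \code{snpPositions}, a per-sequence list of substituted residue
#'   indices).
#' @examples
#' sim <- simulateSnpBatches(5, 50, snpRate = 0.01, seed = 1)
#' sum(lengths(sim$truth$snpPositions))
#' @export
simulateSnpBatches <- function(nSequences, meanLength, snpRate, seed = 1) {
  stopIfNot(nSequences >= 1, "invalid parameter: nSequences must be >= 1")
  stopIfNot(meanLength > 0, "invalid parameter: meanLength must be > 0")
  stopIfNot(snpRate >= 0 && snpRate < 0.1,
            "invalid parameter: snpRate must be in [0, 0.1)")
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withSeed(seed, {
    lens <- pmax(1L, stats::rpois(nSequences, meanLength))
    seqs1 <- vapply(lens, function(L)
      paste(sample(alphabet, L, replace = TRUE), collapse = ""), "")
    seqs2 <- seqs1
    snpPositions <- vector("list", nSequences)
    for (i in seq_len(nSequences)) {
      hit <- which(stats::runif(lens[i]) < snpRate)
      snpPositions[[i]] <- hit
      if (length(hit)) {
        ch <- strsplit(seqs2[i], "")[[1]]
        for (p in hit)
          ch[p] <- sample(setdiff(alphabet, ch[p]), 1L)
        seqs2[i] <- paste(ch, collapse = "")
      }
    }
    ids <- sprintf("seq_%05d", seq_len(nSequences))
    names(seqs1) <- names(seqs2) <- ids
    names(snpPositions) <- ids
    list(batch1 = Biostrings::AAStringSet(seqs1),
         batch2 = Biostrings::AAStringSet(seqs2),
         truth = newSimTruth(snpPositions = snpPositions, seed = seed))
  })
}

#' Simulate reciprocal alignment hit tables with planted best hits
#'
#' For every pair in \code{map}, the true partner appears as the best hit in
#' both directions (e-value <= 1e-50); decoy hits are strictly worse
#' (e-value >= 1e-40 and lower bit score), so reciprocal best-hit
#' resolution recovers \code{map} exactly; with \code{nDecoys = 0} recovery
#' is guaranteed trivially.
#'
#' @param map an [OrthologMap-class] (or data.frame with \code{idA},
#'   \code{idB}); ids must be unique on each side.
#' @param nDecoys number of decoy hits added per direction.
#' @param seed integer seed.
#' @return list with \code{hitsAB} and \code{hitsBA}, both 12-column hit
#'   data.frames as from [readBlastTab()].
#' @examples
#' map <- OrthologMap(c("a1","a2"), c("b1","b2"))
#' ht <- simulateHitTables(map, nDecoys = 5, seed = 1)
#' reciprocalBestHits(ht$hitsAB, ht$hitsBA)
#' @export
simulateHitTables <- function(map, nDecoys = 0, seed = 1) {
  p <- if (is(map, "OrthologMap")) as.data.frame(orthologPairs(map)) else
    as.data.frame(map)
  if (nrow(p) && (anyDuplicated(p$idA) || anyDuplicated(p$idB)))
    stop("invalid input: duplicated ids in map")
  emptyTab <- function() as.data.frame(stats::setNames(
    c(list(character(), character()), rep(list(numeric()), 10L)),
    .BLAST_COLS))
  if (!nrow(p)) return(list(hitsAB = emptyTab(), hitsBA = emptyTab()))
  withSeed(seed, {
    n <- nrow(p)
    mkRow <- function(q, s, evalue, bits) data.frame(
      qseqid = q, sseqid = s,
      pident = round(stats::runif(length(q), 40, 99), 1),
      length = round(stats::runif(length(q), 80, 600)),
      mismatch = round(stats::runif(length(q), 0, 80)),
      gapopen = round(stats::runif(length(q), 0, 5)),
      qstart = 1, qend = round(stats::runif(length(q), 80, 600)),
      sstart = 1, send = round(stats::runif(length(q), 80, 600)),
      evalue = evalue, bitscore = bits, stringsAsFactors = FALSE)
    trueE <- 10^-stats::runif(n, 50, 180)
    trueBits <- round(stats::runif(n, 300, 900), 1)
    ab <- mkRow(p$idA, p$idB, trueE, trueBits)
    ba <- mkRow(p$idB, p$idA, trueE, trueBits)
    if (nDecoys > 0) {
      dq <- sample(p$idA, nDecoys, replace = TRUE)
      ds <- vapply(dq, function(q) {
        partner <- p$idB[match(q, p$idA)]
        sample(setdiff(p$idB, partner), 1L)
      }, "")
      dAB <- mkRow(dq, ds, 10^-stats::runif(nDecoys, 3, 40),
                   round(stats::runif(nDecoys, 30, 250), 1))
      dq2 <- sample(p$idB, nDecoys, replace = TRUE)
      ds2 <- vapply(dq2, function(q) {
        partner <- p$idA[match(q, p$idB)]
        sample(setdiff(p$idA, partner), 1L)
      }, "")
      dBA <- mkRow(dq2, ds2, 10^-stats::runif(nDecoys, 3, 40),
                   round(stats::runif(nDecoys, 30, 250), 1))
      ab <- rbind(ab, dAB)
      ba <- rbind(ba, dBA)
      # shuffle row order so nothing depends on planted-first layout
      ab <- ab[sample(nrow(ab)), , drop = FALSE]
      ba <- ba[sample(nrow(ba)), , drop = FALSE]
      rownames(ab) <- rownames(ba) <- NULL
    }
    list(hitsAB = ab, hitsBA = ba)
  })
}

#' Simulate a concentration table with planted protein complexes
#'
#' Background protein log10 concentrations are normal with sd
#' \code{globalSd} around a bulk median; each complex's subunits are drawn
#' tightly (sd \code{withinSd}) around a complex-specific mean placed
#' 1.5-3 orders of magnitude above the bulk, emulating the abundant
#' molecular machines (ribosome-, chaperonin-, replication-machinery-class
#' complexes) that dominate complex catalogs in deep single-cell-type
#' proteomes.
#'
#' @param nComplexes number of complexes (0 allowed: empty catalog).
#' @param subunitsPerComplex subunits per complex (>= 2).
#' @param withinSd within-complex log10 sd (must be < \code{globalSd}).
#' @param globalSd background log10 sd.
#' @param nBackground number of background proteins.
#' @param medianLog10nM bulk median log10 concentration (default
#'   \code{log10(22)}, i.e. 22 nM).
#' @param complexOffsetRange range (log10 units) of complex-mean offsets
#'   above the bulk median.
#' @param seed integer seed.
#' @return list with \code{concentrations}
#'   ([S4Vectors::DataFrame] with \code{entity}, \code{concentration_nM}),
#'   \code{catalog} (complex membership data.frame) and \code{truth}
#'   (\code{SimTruth} with the complex means).
#' @examples
#' sim <- simulateComplexData(3, 4, withinSd = 0.1, globalSd = 1, seed = 1)
#' sim$catalog$complexId
#' @export
simulateComplexData <- function(nComplexes = 20, subunitsPerComplex = 5,
                                withinSd = 0.1, globalSd = 1.0,
                                nBackground = 100,
                                medianLog10nM = log10(22),
                                complexOffsetRange = c(1.5, 3),
                                seed = 1) {
  stopIfNot(nComplexes >= 0, "invalid parameter: nComplexes must be >= 0")
  stopIfNot(nComplexes == 0 || subunitsPerComplex >= 2,
            "invalid parameter: subunitsPerComplex must be >= 2")
  stopIfNot(withinSd < globalSd,
            "invalid parameter: withinSd must be < globalSd")
  stopIfNot(withinSd >= 0 && globalSd > 0,
            "invalid parameter: sds must be non-negative")
  withSeed(seed, {
    bgIds <- sprintf("bg_%05d", seq_len(nBackground))
    bgLog <- stats::rnorm(nBackground, medianLog10nM, globalSd)
    ids <- bgIds
    logs <- bgLog
    catalog <- data.frame(complexId = character(),
                          complexName = character(),
                          members = I(list()), stringsAsFactors = FALSE)
    complexMeans <- numeric(0)
    if (nComplexes > 0) {
      offs <- stats::runif(nComplexes, complexOffsetRange[1L],
                           complexOffsetRange[2L])
      complexMeans <- medianLog10nM + offs
      memberIds <- vector("list", nComplexes)
      for (i in seq_len(nComplexes)) {
        mid <- sprintf("cx%02d_su%02d", i, seq_len(subunitsPerComplex))
        memberIds[[i]] <- mid
        ids <- c(ids, mid)
        logs <- c(logs, stats::rnorm(subunitsPerComplex,
                                     complexMeans[i], withinSd))
      }
      catalog <- data.frame(complexId = sprintf("CPX%02d",
                                                seq_len(nComplexes)),
                            complexName = sprintf("complex_%02d",
                                                  seq_len(nComplexes)),
                            members = I(memberIds), stringsAsFactors = FALSE)
      names(complexMeans) <- catalog$complexId
    }
    conc <- S4Vectors::DataFrame(entity = ids, concentration_nM = 10^logs)
    list(concentrations = conc, catalog = catalog,
         truth = newSimTruth(complexMeans = complexMeans, seed = seed))
  })
}
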