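#' @importFrom yaml read_yaml write_yaml
#' @importFrom jsonlite write_json
NULL

.defaultConfig <- function() list(
  seed = 17L,
  outputDir = NULL,
  spikein = list(nStandards = 48L, nSampleProteins = 500L, slope = 1,
                 intercept = 3, noiseSd = 0.2, dynamicRangeOrders = 8),
  absquant = list(totalConcentrationM = 2e-3, cutoffM = 1e-8),
  complexes = list(nComplexes = 20L, subunitsPerComplex = 5L,
                   withinSd = 0.1, globalSd = 1.0, nBackground = 100L,
                   alpha = 0.01),
  twoSpecies = list(nOrthologs = 300L, nStagesA = 8L, nStagesB = 8L,
                    shape = "inverse_hourglass", effectSize = 1,
                    noiseSd = 0.05, metric = "pearson", kCoCluster = 5L),
  dynamics = list(k = 8L, nRestarts = 100L),
  rnaProtein = list(nPairs = 500L),
  orthology = list(nDecoys = 20L, evalueMax = 0.01),
  snp = list(nSequences = 300L, meanLength = 120, snpRate = 0.001,
             protease = "trypsin", missedCleavages = 0L)
)

# Merge user config over defaults and check the schema: known keys only,
# right basic types. Fails before any computation.
validateConfig <- function(config) {
  def <- .defaultConfig()
  stopIfNot(is.list(config), "config error: config must be a list")
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  for (blk in names(config)) {
    if (blk %in% c("seed", "outputDir")) next
    stopIfNot(is.list(config[[blk]]),
              "config error: '%s' must be a parameter block", blk)
    bad <- setdiff(names(config[[blk]]), names(def[[blk]]))
    if (length(bad))
      stop(sprintf("config error: unknown key(s) in '%s': %s", blk,
                   paste(bad, collapse = ", ")))
    def[[blk]][names(config[[blk]])] <- config[[blk]]
  }
  if (!is.null(config$seed)) def$seed <- config$seed
  if (!is.null(config$outputDir)) def$outputDir <- config$outputDir
  stopIfNot(is.numeric(def$seed) && length(def$seed) == 1L &&
              is.finite(def$seed), "config error: seed must be an integer")
  stopIfNot(def$twoSpecies$shape %in%
              c("flat", "hourglass", "inverse_hourglass"),
            "config error: unknown shape '%s'", def$twoSpecies$shape)
  stopIfNot(def$twoSpecies$metric %in% c("pearson", "spearman", "cosine"),
            "config error: unknown metric '%s'", def$twoSpecies$metric)
  stopIfNot(def$snp$protease %in% c("trypsin", "lysC"),
            "config error: unknown protease '%s'", def$snp$protease)
  def
}

#' Run the full synthetic demonstration pipeline
#'
#' Executes every analysis stage in dependency order on synthetic inputs
#' generated from the config seed: spike-in simulation, standard-curve fit
#' and absolute quantification; complex stoichiometry testing; two-species
#' time-series simulation, normalization, within-species clustering,
#' RNA-protein correlation; reciprocal best-hit orthology from simulated
#' hit tables; cross-species stage similarity, best-match trace, divergence
#' curve and hourglass classification; and the SNP-robustness digestion
#' report. All synthetic inputs are round-tripped through the package's
#' file readers and writers, so a run exercises the real I/O paths. A rerun
#' with an identical config reproduces identical numeric outputs.
#'
#' @param config a config list or path to a YAML config file; unknown keys
#'   are a config error before any computation. See
#'   \code{system.file("extdata", "demo_config.yaml",
#'   package = "DevoProteomics")}.
#' @param outputDir output directory (overrides \code{config$outputDir}).
#' @return invisibly, a list with the main result objects (standard curve,
#'   concentration table, stoichiometry table, cluster models, ortholog
#'   map, similarity matrix, divergence curve, classification, SNP report)
#'   and \code{paths} to the written files.
#' @examples
#' \donttest{
#' res <- runPipeline(list(seed = 1,
#'                         twoSpecies = list(nOrthologs = 60),
#'                         dynamics = list(nRestarts = 5),
#'                         snp = list(nSequences = 20)),
#'                    outputDir = tempfile("demo"))
#' res$classification$shape
#' }
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    stopIfNot(file.exists(config), "config error: config file not found: %s",
              config)
    config <- yaml::read_yaml(config)
  }
  cfg <- validateConfig(config)
  if (!is.null(outputDir)) cfg$outputDir <- outputDir
  stopIfNot(is.character(cfg$outputDir) && length(cfg$outputDir) == 1L,
            "config error: outputDir is required")
  dir.create(file.path(cfg$outputDir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(cfg$outputDir, "results"), showWarnings = FALSE)
  inp <- function(f) file.path(cfg$outputDir, "inputs", f)
  res <- function(f) file.path(cfg$outputDir, "results", f)
  logFile <- file.path(cfg$outputDir, "log.txt")
  logCon <- file(logFile, open = "wt")
  on.exit(close(logCon))
  logLine <- function(stage, msg)
    writeLines(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                       stage, msg), logCon)
  stageNames <- c("unfE", "fertE", "cell-16", "iniG", "latN", "midTII",
                  "latTII", "larva")
  seed <- as.integer(cfg$seed)
  runStage <- function(stage, expr) {
    logLine(stage, "start")
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        logLine(stage, paste("FAILED:", conditionMessage(e)))
        stop(sprintf("pipeline stage '%s' failed: %s", stage,
                     conditionMessage(e)), call. = FALSE)
      }),
      message = function(m) {
        logLine(stage, sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
  }
  yaml::write_yaml(cfg, res("resolved_config.yaml"))
  out <- list(config = cfg)

  out$absquant <- runStage("absquant", {
    sp <- cfg$spikein
    sim <- simulateSpikeIn(sp$nStandards, sp$nSampleProteins, sp$slope,
                           sp$intercept, sp$noiseSd, sp$dynamicRangeOrders,
                           seed = seed)
    writeSpikeInTsv(sim$spikeins, inp("spikeins.tsv"))
    writeExpressionTsv(sim$signals, inp("egg_signals.tsv"))
    spikeins <- readSpikeInTsv(inp("spikeins.tsv"))
    signals <- readExpressionTsv(inp("egg_signals.tsv"),
                                 "protein_relative", "synthetic")
    curve <- fitStandardCurve(spikeins)
    conc <- estimateConcentrations(curve, signals,
                                   cfg$absquant$totalConcentrationM,
                                   cfg$absquant$cutoffM)
    utils::write.table(as.data.frame(conc), res("concentrations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(slope = curveSlope(curve), intercept = curveIntercept(curve),
           nPointsUsed = curve@nPointsUsed, nDropped = curve@nDropped,
           medianConcentration_nM = medianConcentration(conc),
           nBelowCutoff = S4Vectors::metadata(conc)$nBelowCutoff),
      res("standard_curve.json"), auto_unbox = TRUE, digits = NA)
    list(curve = curve, concentrations = conc, truth = sim$truth)
  })

  out$stoichiometry <- runStage("stoichiometry", {
    cx <- cfg$complexes
    sim <- simulateComplexData(cx$nComplexes, cx$subunitsPerComplex,
                               cx$withinSd, cx$globalSd, cx$nBackground,
                               seed = seed + 1L)
    writeComplexCatalog(sim$catalog, inp("complexes.tsv"))
    catalog <- readComplexCatalog(inp("complexes.tsv"))
    st <- complexStoichiometryTest(sim$concentrations, catalog,
                                   alpha = cx$alpha)
    utils::write.table(st, res("stoichiometry.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    logLine("stoichiometry",
            sprintf("%d/%d complexes significant at alpha %g",
                    sum(st$significant), nrow(st), cx$alpha))
    st
  })

  ts <- cfg$twoSpecies
  sim2 <- runStage("simulate_two_species", {
    sim2 <- simulateTwoSpeciesSeries(ts$nOrthologs, ts$nStagesA,
                                     ts$nStagesB, ts$shape, ts$effectSize,
                                     ts$noiseSd, seed = seed + 2L,
                                     stagesA = if (ts$nStagesA == 8L)
                                       stageNames else NULL)
    writeExpressionTsv(sim2$exprA, inp("prot_a.tsv"))
    writeExpressionTsv(sim2$exprB, inp("prot_b.tsv"))
    sim2
  })
  protA <- readExpressionTsv(inp("prot_a.tsv"), "protein_relative",
                             "speciesA")
  protB <- readExpressionTsv(inp("prot_b.tsv"), "protein_relative",
                             "speciesB")

  out$orthology <- runStage("orthology", {
    ht <- simulateHitTables(sim2$map, cfg$orthology$nDecoys,
                            seed = seed + 3L)
    writeBlastTab(ht$hitsAB, inp("hits_ab.tsv"))
    writeBlastTab(ht$hitsBA, inp("hits_ba.tsv"))
    map <- reciprocalBestHits(readBlastTab(inp("hits_ab.tsv")),
                              readBlastTab(inp("hits_ba.tsv")),
                              evalueMax = cfg$orthology$evalueMax,
                              speciesA = "speciesA", speciesB = "speciesB")
    writeOrthologMap(map, res("ortholog_pairs.tsv"))
    logLine("orthology", sprintf("%d reciprocal best-hit pairs", length(map)))
    map
  })

  out$dynamics <- runStage("dynamics", {
    profA <- sumToOne(medianNormalize(protA))
    profB <- sumToOne(medianNormalize(protB))
    cl <- kmeansProfiles(profA, k = cfg$dynamics$k,
                         nRestarts = cfg$dynamics$nRestarts,
                         seed = seed + 4L)
    utils::write.table(
      data.frame(entity = names(cl$assignments),
                 cluster = unname(cl$assignments)),
      res("clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    co <- coClusterOrthologs(profA, profB, out$orthology,
                             k = ts$kCoCluster,
                             nRestarts = cfg$dynamics$nRestarts,
                             seed = seed + 5L)
    # RNA profiles independent of protein dynamics, as a negative control
    nP <- min(cfg$rnaProtein$nPairs, nrow(protA))
    rnaSim <- simulateTwoSpeciesSeries(max(nP, 2L), ts$nStagesA,
                                       ts$nStagesA, "flat", 0, 0.05,
                                       seed = seed + 6L,
                                       stagesA = stageLabels(protA))
    rna <- StageExperiment(
      matrix(exprValues(rnaSim$exprA)[seq_len(nP), , drop = FALSE], nP,
             dimnames = list(rownames(protA)[seq_len(nP)],
                             stageLabels(protA))),
      modality = "rna_tpm", species = "speciesA")
    rp <- rnaProteinCorrelation(sumToOne(rna), profA,
                                data.frame(rnaId = rownames(rna),
                                           proteinId = rownames(rna)))
    utils::write.table(rp$records, res("rna_protein_corr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(medianPearsonR = rp$medianR,
                              nPairs = nrow(rp$records)),
                         res("rna_protein_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(clusters = cl, coClusters = co, rnaProtein = rp,
         profilesA = profA, profilesB = profB)
  })

  out$xspecies <- runStage("xspecies", {
    simMat <- stageSimilarity(out$dynamics$profilesA,
                              out$dynamics$profilesB, out$orthology,
                              metric = ts$metric)
    utils::write.table(similarityValues(simMat),
                       res("similarity_matrix.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    trace <- bestMatchTrace(simMat)
    utils::write.table(trace, res("best_match_trace.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    curve <- divergenceCurve(simMat)
    utils::write.table(curve, res("divergence_curve.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    classes <- stageClasses(stageLabels(out$dynamics$profilesA))
    cls <- hourglassClassify(curve, classes, seed = seed + 7L)
    jsonlite::write_json(
      list(shape = cls$shape, statistic = cls$statistic,
           pValue = cls$pValue, generatorShape = sim2$truth$shapeLabel),
      res("classification.json"), auto_unbox = TRUE, digits = NA)
    logLine("xspecies", sprintf("classified %s (H = %.4f, p = %.4g)",
                                cls$shape, cls$statistic, cls$pValue))
    list(similarity = simMat, trace = trace, divergence = curve,
         classification = cls)
  })
  out$classification <- out$xspecies$classification

  out$snp <- runStage("snp_digest", {
    sn <- cfg$snp
    simS <- simulateSnpBatches(sn$nSequences, sn$meanLength, sn$snpRate,
                               seed = seed + 8L)
    writeProteinFasta(simS$batch1, inp("batch1.fasta"))
    writeProteinFasta(simS$batch2, inp("batch2.fasta"))
    rep <- snpRobustnessReport(readProteinFasta(inp("batch1.fasta")),
                               readProteinFasta(inp("batch2.fasta")),
                               protease = sn$protease,
                               missedCleavages = sn$missedCleavages)
    jsonlite::write_json(rep, res("snp_report.json"), auto_unbox = TRUE,
                         digits = NA)
    logLine("snp_digest", sprintf("%.2f%% of peptides shared",
                                  rep$sharedFraction))
    rep
  })

  out$paths <- list(outputDir = cfg$outputDir, log = logFile)
  logLine("pipeline", "done")
  invisible(out)
}
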