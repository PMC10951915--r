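# Independent oracles and fixture builders used across the suite.
# Oracles are written as plain loops so they stay independent of the
# implementation paths they check.

# brute-force Theil-Sen: all pairwise slopes via explicit double loop
theilSenOracle <- function(x, y) {
  slopes <- c()
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (j > i && x[j] != x[i])
        slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
    }
  }
  slope <- median(slopes)
  list(slope = slope, intercept = median(y - slope * x))
}

# brute-force best hit per query: filter, then scan row by row
bestHitOracle <- function(hits, evalueMax = 0.01) {
  hits <- hits[hits$evalue <= evalueMax, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(hits))) {
    q <- hits$qseqid[i]
    cur <- out[[q]]
    if (is.null(cur) ||
        hits$evalue[i] < cur$evalue ||
        (hits$evalue[i] == cur$evalue && hits$bitscore[i] > cur$bitscore))
      out[[q]] <- list(sseqid = hits$sseqid[i], evalue = hits$evalue[i],
                       bitscore = hits$bitscore[i])
  }
  out
}

# random 12-column hit table
randomHitTable <- function(nQueries, nHits, seed) {
  set.seed(seed)
  data.frame(
    qseqid = sample(sprintf("q%02d", seq_len(nQueries)), nHits,
                    replace = TRUE),
    sseqid = sample(sprintf("s%02d", seq_len(nQueries)), nHits,
                    replace = TRUE),
    pident = runif(nHits, 30, 100), length = round(runif(nHits, 50, 500)),
    mismatch = round(runif(nHits, 0, 50)), gapopen = round(runif(nHits, 0, 5)),
    qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = 10^-round(runif(nHits, 0, 30)),
    bitscore = round(runif(nHits, 30, 500)),
    stringsAsFactors = FALSE)
}

# stage experiment from a bare matrix
makeSE <- function(m, modality = "protein_relative", species = "test",
                   normalization = "raw") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("e%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  StageExperiment(m, modality = modality, species = species,
                  normalization = normalization)
}

# full synthetic divergence-curve classification for one generated dataset
classifyShape <- function(shape, seed, nOrthologs = 300, effectSize = 1,
                          noiseSd = 0.05, metric = "pearson") {
  sim <- simulateTwoSpeciesSeries(nOrthologs, 8, 8, shape,
                                  effectSize, noiseSd, seed = seed)
  sm <- stageSimilarity(sumToOne(sim$exprA), sumToOne(sim$exprB), sim$map,
                        metric = metric)
  hourglassClassify(divergenceCurve(sm),
                    stageClasses(rownames(similarityValues(sm))),
                    seed = seed)
}

# H statistic computed directly from a divergence curve (test-side copy)
hStatOracle <- function(div, cls) {
  mean(div[cls == "mid"]) -
    mean(c(mean(div[cls == "early"]), mean(div[cls == "late"])))
}

randomProteinSeq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}
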