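#' Quantile normalization of an expression matrix
#'
#' Standard procedure: each column's values are replaced by the reference
#' distribution (the mean of the columns' sorted values at each rank);
#' tied values within a column receive the mean of the reference values
#' they span (average ranks interpolated into the reference). Entities with
#' any missing value are dropped with a logged count; a single-column
#' matrix is returned unchanged with a warning.
#'
#' @param x a [StageExperiment-class].
#' @return a [StageExperiment-class] with
#'   \code{metadata()$normalization = "quantile_normalized"}.
#' @examples
#' m <- matrix(c(2,4,6, 3,1,2), 3, 2,
#'             dimnames = list(paste0("g",1:3), c("s1","s2")))
#' se <- quantileNormalize(StageExperiment(m, "rna_tpm", "x"))
#' SummarizedExperiment::assay(se)  # columns share sorted values
#' @export
quantileNormalize <- function(x) {
  v <- exprValues(x)
  if (ncol(v) < 2L) {
    warning("quantile normalization skipped: single-column matrix")
    return(x)
  }
  complete <- rowSums(!is.finite(v)) == 0L
  if (any(!complete))
    logNote("quantileNormalize: %d entit(ies) with missing values dropped",
            sum(!complete))
  v <- v[complete, , drop = FALSE]
  stopIfNot(nrow(v) > 0, "no complete entities to normalize")
  ref <- rowMeans(apply(v, 2L, sort))
  out <- apply(v, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    stats::approx(seq_along(ref), ref, xout = r)$y
  })
  dimnames(out) <- dimnames(v)
  StageExperiment(out, modality = modality(x), species = speciesLabel(x),
                  normalization = "quantile_normalized")
}

cosineSim <- function(a, b) {
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

#' Cross-species stage similarity matrix
#'
#' Entry \code{(s, t)} is the chosen similarity between the vector of
#' species-A ortholog values at stage \code{s} and the species-B partner
#' values at stage \code{t}, computed over all mapped pairs non-missing in
#' both. Spearman uses average ranks for ties. Zero-variance stage vectors
#' make Pearson/Spearman entries undefined; those are recorded as missing.
#'
#' @param profilesA,profilesB sum-to-one [StageExperiment-class] objects
#'   (each over its own stage series).
#' @param map an [OrthologMap-class] with >= 10 mapped pairs present in
#'   both sets.
#' @param metric \code{"pearson"}, \code{"spearman"} or \code{"cosine"}.
#' @return a [StageSimilarity-class].
#' @examples
#' sim <- simulateTwoSpeciesSeries(60, shape = "flat", effectSize = 0,
#'                                 noiseSd = 0, seed = 1)
#' sm <- stageSimilarity(sumToOne(sim$exprA), sumToOne(sim$exprB), sim$map)
#' diag(similarityValues(sm))  # ~1 on the matched-stage diagonal
#' @export
stageSimilarity <- function(profilesA, profilesB, map,
                            metric = c("pearson", "spearman", "cosine")) {
  metric <- match.arg(metric)
  p <- as.data.frame(orthologPairs(map))
  va <- exprValues(profilesA)
  vb <- exprValues(profilesB)
  keep <- p$idA %in% rownames(va) & p$idB %in% rownames(vb)
  p <- p[keep, , drop = FALSE]
  stopIfNot(nrow(p) >= 10L,
            "need >= 10 mapped orthologs present in both profile sets")
  A <- va[p$idA, , drop = FALSE]
  B <- vb[p$idB, , drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  m <- matrix(NA_real_, nA, nB, dimnames = list(colnames(A), colnames(B)))
  for (s in seq_len(nA)) {
    for (t in seq_len(nB)) {
      a <- A[, s]; b <- B[, t]
      ok <- is.finite(a) & is.finite(b)
      a <- a[ok]; b <- b[ok]
      if (length(a) < 3L) next
      m[s, t] <- switch(metric,
        cosine = cosineSim(a, b),
        pearson = ,
        spearman = if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
                   else stats::cor(a, b, method = metric))
    }
  }
  if (anyNA(m))
    logNote("stageSimilarity: %d undefined entr(ies) recorded as missing",
            sum(is.na(m)))
  new("StageSimilarity", values = m, metric = metric,
      nOrthologs = nrow(p), speciesA = speciesLabel(profilesA),
      speciesB = speciesLabel(profilesB))
}

#' Best-matching partner stage per species-A stage
#'
#' For each row of the similarity matrix, returns the species-B stage with
#' the maximum similarity; ties are broken toward the earlier stage and
#' logged. A row with no defined entry is an error naming the stage.
#'
#' @param sim a [StageSimilarity-class].
#' @return data.frame with \code{stageA}, \code{bestMatchStage},
#'   \code{bestSimilarity}.
#' @export
bestMatchTrace <- function(sim) {
  v <- similarityValues(sim)
  allMissing <- rowSums(is.finite(v)) == 0L
  if (any(allMissing))
    stop("all-missing similarity row for stage(s): ",
         paste(rownames(v)[allMissing], collapse = ", "))
  idx <- integer(nrow(v))
  for (i in seq_len(nrow(v))) {
    row <- v[i, ]
    mx <- max(row, na.rm = TRUE)
    hits <- which(row == mx)
    if (length(hits) > 1L)
      logNote("bestMatchTrace: tie at stage '%s' broken toward the earlier stage",
              rownames(v)[i])
    idx[i] <- hits[1L]
  }
  data.frame(stageA = rownames(v), bestMatchStage = colnames(v)[idx],
             bestSimilarity = v[cbind(seq_len(nrow(v)), idx)],
             stringsAsFactors = FALSE)
}

#' Per-stage cross-species divergence curve
#'
#' Divergence of each species-A stage is one minus its best similarity to
#' any species-B stage. For Pearson similarity this can exceed 1 (it is not
#' clamped); for cosine similarity on non-negative profiles it lies in
#' \code{[0, 1]}.
#'
#' @param sim a [StageSimilarity-class].
#' @return data.frame with \code{stageA}, \code{bestMatchStage},
#'   \code{bestSimilarity}, \code{divergence}.
#' @export
divergenceCurve <- function(sim) {
  tr <- bestMatchTrace(sim)
  tr$divergence <- 1 - tr$bestSimilarity
  tr
}

#' Assign stages to early / mid / late developmental classes
#'
#' Default split follows normalized stage index tertiles, which for the
#' eight-stage ascidian series places gastrulation and neurulation
#' (stages 4-5) in the mid class; fully overridable by passing explicit
#' label vectors.
#'
#' @param stages ordered stage labels.
#' @param early,mid,late optional explicit stage label vectors; together
#'   they must cover every stage exactly once.
#' @return named factor mapping stage to class, levels
#'   \code{early, mid, late}.
#' @examples
#' stageClasses(c("unfE","fertE","cell-16","iniG","latN","midTII",
#'                "latTII","larva"))
#' @export
stageClasses <- function(stages, early = NULL, mid = NULL, late = NULL) {
  if (is.null(early) && is.null(mid) && is.null(late)) {
    t <- seq(0, 1, length.out = length(stages))
    cls <- ifelse(t < 1 / 3, "early", ifelse(t <= 2 / 3, "mid", "late"))
  } else {
    stopIfNot(!is.null(early) && !is.null(mid) && !is.null(late),
              "provide all three classes or none")
    all3 <- c(early, mid, late)
    stopIfNot(setequal(all3, stages) && !anyDuplicated(all3),
              "early/mid/late must partition the stage labels")
    cls <- ifelse(stages %in% early, "early",
                  ifelse(stages %in% mid, "mid", "late"))
  }
  if (!all(c("early", "mid", "late") %in% cls))
    stop("invalid parameter: every class needs at least one stage")
  stats::setNames(factor(cls, levels = c("early", "mid", "late")), stages)
}

hourglassStatistic <- function(div, cls) {
  mean(div[cls == "mid"]) -
    mean(c(mean(div[cls == "early"]), mean(div[cls == "late"])))
}

#' Classify the shape of a cross-species divergence curve
#'
#' The shape statistic is
#' \deqn{H = \bar d_{mid} - \tfrac{1}{2}(\bar d_{early} + \bar d_{late}),}
#' the mean divergence at mid-developmental stages minus the average of the
#' early- and late-stage means. \eqn{H > 0} indicates an inverse-hourglass
#' pattern (maximal divergence at mid-development), \eqn{H < 0} an
#' hourglass. Significance is assessed by permuting the stage-class labels
#' (two-sided); if the permutation p-value is >= 0.05 the curve is called
#' flat. The statistic and its permutation null operationalize a pattern
#' that is usually judged visually; they are a package-defined test, not a
#' community standard.
#'
#' @param curve divergence curve from [divergenceCurve()] (or any
#'   data.frame with \code{stageA} and \code{divergence}).
#' @param classes named factor from [stageClasses()] covering every stage
#'   of the curve, each class non-empty.
#' @param nPermutations number of label permutations (default 1000).
#' @param seed integer seed for the permutation draw.
#' @param flatAlpha p-value at or above which the curve is called flat
#'   (default 0.05).
#' @return list with \code{shape} (\code{"hourglass"},
#'   \code{"inverse_hourglass"} or \code{"flat"}), \code{statistic} and
#'   \code{pValue}.
#' @examples
#' curve <- data.frame(stageA = c("e1","m1","l1"),
#'                     divergence = c(0.1, 0.5, 0.1))
#' cls <- stageClasses(c("e1","m1","l1"),
#'                     early = "e1", mid = "m1", late = "l1")
#' hourglassClassify(curve, cls, seed = 1)$statistic  # 0.4
#' @export
hourglassClassify <- function(curve, classes, nPermutations = 1000L,
                              seed = 1, flatAlpha = 0.05) {
  stopIfNot(nrow(curve) >= 3L, "need >= 3 stages")
  cls <- classes[curve$stageA]
  if (anyNA(cls))
    stop("invalid parameter: classes missing for stage(s): ",
         paste(curve$stageA[is.na(cls)], collapse = ", "))
  if (!all(c("early", "mid", "late") %in% cls))
    stop("invalid parameter: every class needs at least one stage")
  d <- curve$divergence
  H <- hourglassStatistic(d, cls)
  perm <- withSeed(seed, {
    vapply(seq_len(nPermutations), function(i)
      hourglassStatistic(d, sample(cls)), 0)
  })
  p <- (1 + sum(abs(perm) >= abs(H))) / (nPermutations + 1)
  shape <- if (p >= flatAlpha || H == 0) "flat"
           else if (H > 0) "inverse_hourglass" else "hourglass"
  list(shape = shape, statistic = H, pValue = p)
}

#' Fraction of orthologs expressed in both species, per stage class
#'
#' An ortholog counts as expressed within a class if it is expressed at
#' one or more stages of that class; the fraction is the number of
#' orthologs expressed in the class in *both* species over the total
#' mapped orthologs present in both flag matrices.
#'
#' @param flagsA,flagsB logical gene-by-stage matrices from
#'   [expressedFlags()].
#' @param map an [OrthologMap-class].
#' @param classesA,classesB stage-class factors from [stageClasses()] for
#'   the two species' stage series.
#' @return named numeric vector with one fraction per class
#'   (\code{early}, \code{mid}, \code{late}).
#' @export
sharedExpressionFraction <- function(flagsA, flagsB, map, classesA,
                                     classesB) {
  p <- as.data.frame(orthologPairs(map))
  keep <- p$idA %in% rownames(flagsA) & p$idB %in% rownames(flagsB)
  p <- p[keep, , drop = FALSE]
  stopIfNot(nrow(p) > 0, "no mapped orthologs present in both flag matrices")
  out <- numeric(0)
  for (cl in c("early", "mid", "late")) {
    stA <- names(classesA)[classesA == cl]
    stB <- names(classesB)[classesB == cl]
    if (!length(stA) || !length(stB))
      stop("invalid parameter: empty class '", cl, "'")
    exprA <- rowSums(flagsA[p$idA, stA, drop = FALSE]) > 0
    exprB <- rowSums(flagsB[p$idB, stB, drop = FALSE]) > 0
    out[cl] <- mean(exprA & exprB)
  }
  out
}
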