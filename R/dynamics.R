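#' @importFrom stats cor
NULL

#' Median-based column normalization
#'
#' Rescales each stage column so that its median equals the grand median of
#' the input (the median of the column medians, over non-missing values).
#' Relative within-stage structure is untouched; values stay non-negative.
#'
#' @param x a [StageExperiment-class].
#' @return a [StageExperiment-class] with
#'   \code{metadata()$normalization = "median_normalized"}.
#' @examples
#' m <- matrix(c(1,1,2,2,4,4), 2, 3,
#'             dimnames = list(c("p1","p2"), c("s1","s2","s3")))
#' exprValues <- SummarizedExperiment::assay
#' medianNormalize(StageExperiment(m, "protein_relative", "Ciona"))
#' @export
medianNormalize <- function(x) {
  v <- exprValues(x)
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  bad <- !is.finite(med) | med <= 0
  if (any(bad))
    stop("median normalization impossible for stage(s) with non-positive median: ",
         paste(colnames(v)[bad], collapse = ", "))
  grand <- stats::median(med)
  out <- sweep(v, 2L, grand / med, `*`)
  res <- StageExperiment(out, modality = modality(x),
                         species = speciesLabel(x),
                         normalization = "median_normalized")
  res
}

#' Scale each profile to sum to one across the stage series
#'
#' Divides every entity's profile by its row sum over non-missing stages,
#' turning abundances into compositional temporal profiles that are
#' comparable across entities and species. All-zero profiles are dropped
#' with a logged count; missing stages remain missing.
#'
#' @param x a [StageExperiment-class].
#' @return a [StageExperiment-class] with
#'   \code{metadata()$normalization = "sum_to_one"}.
#' @examples
#' m <- matrix(c(2, 0, 2), 1, 3, dimnames = list("p", c("s1","s2","s3")))
#' se <- sumToOne(StageExperiment(m, "protein_relative", "Ciona"))
#' SummarizedExperiment::assay(se)  # 0.5 0 0.5
#' @export
sumToOne <- function(x) {
  v <- exprValues(x)
  rs <- rowSums(v, na.rm = TRUE)
  drop <- rs <= 0
  if (any(drop))
    logNote("sumToOne: %d all-zero profile(s) dropped", sum(drop))
  v <- v[!drop, , drop = FALSE]
  out <- v / rowSums(v, na.rm = TRUE)
  StageExperiment(out, modality = modality(x), species = speciesLabel(x),
                  normalization = "sum_to_one")
}

#' Per-pair RNA-protein temporal correlation
#'
#' Pearson correlation between each paired mRNA and protein profile over
#' their shared, mutually non-missing stages (matched by stage label).
#' Pairs with fewer than \code{minStages} usable stages, or with a
#' zero-variance profile, are excluded with logged counts.
#'
#' @param rna,protein [StageExperiment-class] objects sharing stage labels.
#' @param pairing data.frame with columns \code{rnaId}, \code{proteinId}.
#' @param minStages minimum shared non-missing stages (default 3).
#' @param method correlation method (default \code{"pearson"}).
#' @return list with \code{records} (data.frame \code{rnaId},
#'   \code{proteinId}, \code{r}, \code{nStagesUsed}) and \code{medianR}.
#' @examples
#' m <- matrix(runif(12), 3, 4, dimnames = list(paste0("g", 1:3),
#'                                              paste0("s", 1:4)))
#' rna <- StageExperiment(m, "rna_tpm", "Ciona")
#' prot <- StageExperiment(m, "protein_relative", "Ciona")
#' rnaProteinCorrelation(rna, prot,
#'   data.frame(rnaId = paste0("g", 1:3), proteinId = paste0("g", 1:3)))$medianR
#' @export
rnaProteinCorrelation <- function(rna, protein, pairing, minStages = 3L,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopIfNot(all(c("rnaId", "proteinId") %in% names(pairing)),
            "pairing needs columns rnaId and proteinId")
  shared <- intersect(stageLabels(rna), stageLabels(protein))
  stopIfNot(length(shared) >= minStages,
            "need >= %d shared stage labels", minStages)
  vr <- exprValues(rna)[, shared, drop = FALSE]
  vp <- exprValues(protein)[, shared, drop = FALSE]
  keep <- pairing$rnaId %in% rownames(vr) & pairing$proteinId %in% rownames(vp)
  if (any(!keep))
    logNote("rnaProteinCorrelation: %d pair(s) missing from a dataset excluded",
            sum(!keep))
  pairing <- pairing[keep, , drop = FALSE]
  r <- rep(NA_real_, nrow(pairing))
  nUsed <- integer(nrow(pairing))
  for (i in seq_len(nrow(pairing))) {
    a <- vr[pairing$rnaId[i], ]
    b <- vp[pairing$proteinId[i], ]
    ok <- is.finite(a) & is.finite(b)
    nUsed[i] <- sum(ok)
    if (nUsed[i] >= minStages) {
      sa <- stats::sd(a[ok]); sb <- stats::sd(b[ok])
      if (sa > 0 && sb > 0)
        r[i] <- stats::cor(a[ok], b[ok], method = method)
    }
  }
  excl <- !is.finite(r)
  if (any(excl))
    logNote("rnaProteinCorrelation: %d pair(s) excluded (too few stages or zero variance)",
            sum(excl))
  records <- data.frame(rnaId = pairing$rnaId[!excl],
                        proteinId = pairing$proteinId[!excl],
                        r = r[!excl], nStagesUsed = nUsed[!excl],
                        stringsAsFactors = FALSE)
  list(records = records,
       medianR = if (nrow(records)) stats::median(records$r) else NA_real_)
}

# Lloyd iterations from a fixed set of initial centers; empty clusters are
# re-seeded from the point farthest from its assigned center.
lloydKmeans <- function(x, centers, maxIter = 100L) {
  k <- nrow(centers)
  n <- nrow(x)
  x2 <- rowSums(x^2)
  assign <- rep(0L, n)
  for (iter in seq_len(maxIter)) {
    dd <- matrix(x2, n, k) - 2 * x %*% t(centers) +
      matrix(rowSums(centers^2), n, k, byrow = TRUE)
    newAssign <- max.col(-dd, ties.method = "first")
    counts <- tabulate(newAssign, k)
    while (any(counts == 0L)) {
      d2own <- dd[cbind(seq_len(n), newAssign)]
      far <- which.max(d2own)
      emptyC <- which(counts == 0L)[1L]
      centers[emptyC, ] <- x[far, ]
      dd[, emptyC] <- x2 - 2 * x %*% centers[emptyC, ] +
        sum(centers[emptyC, ]^2)
      newAssign <- max.col(-dd, ties.method = "first")
      counts <- tabulate(newAssign, k)
    }
    if (identical(newAssign, assign)) break
    assign <- newAssign
    centers <- rowsum(x, assign) / as.numeric(counts)
  }
  dd <- matrix(x2, n, k) - 2 * x %*% t(centers) +
    matrix(rowSums(centers^2), n, k, byrow = TRUE)
  wss <- sum(pmax(dd[cbind(seq_len(n), assign)], 0))
  list(assign = assign, centers = centers, wss = wss)
}

#' K-means clustering of temporal profiles with multiple restarts
#'
#' Euclidean k-means on complete profiles (entities with missing stages are
#' excluded and counted). Each restart initializes centroids as a uniform
#' random sample of \code{k} distinct entities; the best of
#' \code{nRestarts} runs by total within-cluster sum of squares is kept.
#' Deterministic given \code{seed}. Cluster ids are relabelled in order of
#' descending cluster size (ties broken by first-occurring entity).
#'
#' @param profiles a [StageExperiment-class] (any normalization).
#' @param k number of clusters (>= 1; must not exceed the number of
#'   complete entities).
#' @param nRestarts number of random restarts (default 100).
#' @param seed integer seed.
#' @return list of class \code{"profileKmeans"} with \code{k},
#'   \code{assignments} (named integer vector), \code{centroids}
#'   (k x stages matrix), \code{totalWithinSS}, \code{nRestarts},
#'   \code{seed}, \code{nExcluded}.
#' @examples
#' m <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 8), 10))
#' dimnames(m) <- list(sprintf("p%02d", 1:20), paste0("s", 1:4))
#' cl <- kmeansProfiles(StageExperiment(abs(m), "protein_relative", "x"),
#'                      k = 2, nRestarts = 10, seed = 1)
#' table(cl$assignments)
#' @export
kmeansProfiles <- function(profiles, k, nRestarts = 100L, seed = 1) {
  v <- exprValues(profiles)
  complete <- rowSums(!is.finite(v)) == 0L
  if (any(!complete))
    logNote("kmeansProfiles: %d incomplete profile(s) excluded",
            sum(!complete))
  x <- v[complete, , drop = FALSE]
  stopIfNot(k >= 1, "invalid parameter: k must be >= 1")
  if (k > nrow(x))
    stop("invalid parameter: k exceeds the number of complete entities")
  stopIfNot(nRestarts >= 1, "invalid parameter: nRestarts must be >= 1")
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      init <- x[sample(nrow(x), k), , drop = FALSE]
      fit <- lloydKmeans(x, init)
      if (is.null(best) || fit$wss < best$wss) best <- fit
    }
  })
  # relabel by descending size; ties by first-occurring entity
  counts <- tabulate(best$assign, k)
  firstSeen <- vapply(seq_len(k), function(c)
    which(best$assign == c)[1L], 0L)
  ord <- order(-counts, firstSeen)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  assignments <- stats::setNames(relabel[best$assign], rownames(x))
  centroids <- best$centers[ord, , drop = FALSE]
  dimnames(centroids) <- list(paste0("cluster", seq_len(k)), colnames(x))
  structure(list(k = k, assignments = assignments, centroids = centroids,
                 totalWithinSS = best$wss, nRestarts = nRestarts,
                 seed = seed, nExcluded = sum(!complete)),
            class = "profileKmeans")
}

#' @export
print.profileKmeans <- function(x, ...) {
  cat(sprintf("profileKmeans: k = %d, %d entities, total within-SS %.6g (%d restarts)\n",
              x$k, length(x$assignments), x$totalWithinSS, x$nRestarts))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Co-cluster ortholog pairs across two species
#'
#' Represents each one-to-one ortholog pair by the concatenation of its two
#' sum-to-one temporal profiles and clusters the concatenated vectors with
#' [kmeansProfiles()]. Pairs missing from either profile set are excluded
#' with a logged count.
#'
#' @param profilesA,profilesB sum-to-one [StageExperiment-class] objects.
#' @param map an [OrthologMap-class].
#' @param k number of clusters (default 5).
#' @param nRestarts,seed see [kmeansProfiles()].
#' @return a \code{"profileKmeans"} object; assignment names are
#'   \code{idA|idB} pair labels.
#' @export
coClusterOrthologs <- function(profilesA, profilesB, map, k = 5L,
                               nRestarts = 100L, seed = 1) {
  p <- as.data.frame(orthologPairs(map))
  if (!nrow(p)) stop("invalid input: empty ortholog map")
  for (se in list(profilesA, profilesB)) {
    norm <- S4Vectors::metadata(se)$normalization
    if (!identical(norm, "sum_to_one"))
      stop("profiles must be sum-to-one normalized (see sumToOne())")
  }
  va <- exprValues(profilesA)
  vb <- exprValues(profilesB)
  keep <- p$idA %in% rownames(va) & p$idB %in% rownames(vb)
  if (any(!keep))
    logNote("coClusterOrthologs: %d pair(s) missing from a profile set excluded",
            sum(!keep))
  p <- p[keep, , drop = FALSE]
  if (!nrow(p)) stop("invalid input: no ortholog pair present in both sets")
  x <- cbind(va[p$idA, , drop = FALSE], vb[p$idB, , drop = FALSE])
  rownames(x) <- paste(p$idA, p$idB, sep = "|")
  colnames(x) <- c(paste0("A:", colnames(va)), paste0("B:", colnames(vb)))
  se <- StageExperiment(x, modality = modality(profilesA),
                        species = "paired", normalization = "sum_to_one")
  kmeansProfiles(se, k = k, nRestarts = nRestarts, seed = seed)
}

#' Fold change between two stages
#'
#' \code{FC = (numerator + pseudo) / (denominator + pseudo)} per entity,
#' with \code{log2FC = log2(FC)}. With \code{pseudo = 0}, entities with a
#' zero denominator are excluded with a logged count.
#'
#' @param x a [StageExperiment-class].
#' @param numeratorStage,denominatorStage stage labels (e.g. larva vs egg).
#' @param pseudo pseudocount added to both stages (default 0).
#' @return data.frame with \code{entity}, \code{FC}, \code{log2FC}.
#' @examples
#' m <- matrix(c(2, 8), 1, 2, dimnames = list("p", c("egg", "larva")))
#' foldChange(StageExperiment(m, "protein_relative", "x"), "larva", "egg")
#' @export
foldChange <- function(x, numeratorStage, denominatorStage, pseudo = 0) {
  v <- exprValues(x)
  for (stg in c(numeratorStage, denominatorStage))
    if (!stg %in% colnames(v))
      stop("invalid parameter: unknown stage label '", stg, "'")
  num <- v[, numeratorStage] + pseudo
  den <- v[, denominatorStage] + pseudo
  ok <- is.finite(num) & is.finite(den) & den > 0
  if (any(!ok))
    logNote("foldChange: %d entit(ies) excluded (missing or zero denominator)",
            sum(!ok))
  fc <- num[ok] / den[ok]
  data.frame(entity = rownames(v)[ok], FC = unname(fc),
             log2FC = unname(log2(fc)), stringsAsFactors = FALSE)
}

#' Rank entities by change across consecutive stage transitions
#'
#' For each consecutive stage pair, entities are ranked by descending
#' absolute log2 ratio \eqn{|\log_2((s + \epsilon)/(t + \epsilon))|} with
#' \eqn{\epsilon} = half the smallest positive value of the matrix, so
#' zero-containing profiles remain rankable. Ties are broken by entity id.
#'
#' @param profiles a [StageExperiment-class] with >= 2 stages.
#' @param topN entities returned per transition (default all).
#' @return named list (one element per transition \code{"s1->s2"}) of
#'   data.frames with \code{entity}, \code{absLog2Ratio}.
#' @export
stageTransitionRanking <- function(profiles, topN = Inf) {
  v <- exprValues(profiles)
  stopIfNot(ncol(v) >= 2L, "need >= 2 stages")
  pos <- v[is.finite(v) & v > 0]
  stopIfNot(length(pos) > 0, "matrix has no positive values")
  eps <- min(pos) * 0.5
  out <- list()
  for (j in seq_len(ncol(v) - 1L)) {
    score <- abs(log2((v[, j + 1L] + eps) / (v[, j] + eps)))
    ord <- order(-score, rownames(v))
    n <- min(topN, sum(is.finite(score)))
    sel <- ord[seq_len(n)]
    out[[paste0(colnames(v)[j], "->", colnames(v)[j + 1L])]] <-
      data.frame(entity = rownames(v)[sel],
                 absLog2Ratio = unname(score[sel]),
                 stringsAsFactors = FALSE)
  }
  out
}

#' Aggregate transcript-level TPM to gene level
#'
#' Gene TPM is the sum of its transcript isoforms' TPM at each stage;
#' column sums are conserved.
#'
#' @param x a \code{"rna_tpm"} [StageExperiment-class] at transcript level.
#' @param txToGene named character vector mapping transcript id to gene id;
#'   every transcript must be mapped.
#' @return gene-level [StageExperiment-class].
#' @export
aggregateIsoformTpm <- function(x, txToGene) {
  stopIfNot(modality(x) == "rna_tpm", "input must be rna_tpm modality")
  v <- exprValues(x)
  un <- setdiff(rownames(v), names(txToGene))
  if (length(un))
    stop("unmapped transcript(s): ", paste(un, collapse = ", "))
  g <- txToGene[rownames(v)]
  agg <- rowsum(v, g, na.rm = TRUE)
  # rowsum turns all-NA groups into 0; restore missingness
  allNA <- rowsum((!is.na(v)) * 1, g) == 0
  agg[allNA] <- NA_real_
  StageExperiment(agg, modality = "rna_tpm", species = speciesLabel(x),
                  normalization = S4Vectors::metadata(x)$normalization)
}

#' Expression flags at a TPM threshold
#'
#' A gene is flagged expressed at a stage if its TPM is at or above
#' \code{threshold} (inclusive, default 2); missing values are not
#' expressed.
#'
#' @param x a \code{"rna_tpm"} [StageExperiment-class].
#' @param threshold detection threshold (default 2).
#' @return logical matrix, genes x stages.
#' @examples
#' m <- matrix(c(2, 1.999), 1, 2, dimnames = list("g", c("s1","s2")))
#' expressedFlags(StageExperiment(m, "rna_tpm", "x"))
#' @export
expressedFlags <- function(x, threshold = 2) {
  stopIfNot(modality(x) == "rna_tpm", "input must be rna_tpm modality")
  v <- exprValues(x)
  f <- v >= threshold
  f[is.na(f)] <- FALSE
  f
}
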