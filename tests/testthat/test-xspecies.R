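test_that("quantile normalization reproduces the hand-worked example", {
  m <- matrix(c(2, 4, 6, 3, 1, 2), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  out <- SummarizedExperiment::assay(quantileNormalize(makeSE(m, "rna_tpm")))
  expect_equal(unname(out[, "s1"]), c(1.5, 3, 4.5))
  expect_equal(unname(out[, "s2"]), c(4.5, 1.5, 3))
  # identical columns are unchanged
  eqm <- matrix(c(1, 5, 9, 1, 5, 9), 3, 2)
  expect_equal(unname(SummarizedExperiment::assay(
    quantileNormalize(makeSE(eqm, "rna_tpm")))), unname(eqm))
  expect_warning(quantileNormalize(makeSE(matrix(1:3, 3, 1), "rna_tpm")),
                 "single-column")
})

test_that("normalized columns share identical sorted values", {
  set.seed(4)
  for (i in 1:5) {
    m <- matrix(10^runif(120, 0, 4), 24, 5)
    out <- SummarizedExperiment::assay(quantileNormalize(makeSE(m, "rna_tpm")))
    srt <- apply(out, 2, sort)
    for (j in 2:5) expect_equal(srt[, j], srt[, 1], tolerance = 1e-9)
  }
})

test_that("quantile normalization agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(9)
  m <- matrix(10^runif(200, 0, 3), 40, 5,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:5)))
  got <- SummarizedExperiment::assay(quantileNormalize(makeSE(m, "rna_tpm")))
  ref <- limma::normalizeQuantiles(m)
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("stage similarity behaves on a perfect species copy", {
  set.seed(6)
  m <- matrix(runif(400, 0.2, 2), 50, 8,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:8)))
  a <- sumToOne(makeSE(m))
  bm <- SummarizedExperiment::assay(a)
  rownames(bm) <- sprintf("h%02d", 1:50)
  b <- makeSE(bm, normalization = "sum_to_one")
  map <- OrthologMap(sprintf("g%02d", 1:50), sprintf("h%02d", 1:50))
  for (metric in c("pearson", "spearman", "cosine")) {
    sm <- stageSimilarity(a, b, map, metric = metric)
    d <- diag(similarityValues(sm))
    expect_equal(unname(d), rep(1, 8), tolerance = 1e-9)
    # the diagonal is the row maximum everywhere for a perfect copy
    expect_equal(bestMatchTrace(sm)$bestMatchStage, paste0("s", 1:8))
    expect_equal(divergenceCurve(sm)$divergence, rep(0, 8),
                 tolerance = 1e-9)
  }
})

test_that("stage similarity is symmetric and respects metric ranges", {
  sim <- simulateTwoSpeciesSeries(80, shape = "inverse_hourglass",
                                  effectSize = 1, noiseSd = 0.05, seed = 2)
  a <- sumToOne(sim$exprA); b <- sumToOne(sim$exprB)
  swapMap <- OrthologMap(orthologPairs(sim$map)$idB,
                         orthologPairs(sim$map)$idA)
  for (metric in c("pearson", "cosine")) {
    fwd <- similarityValues(stageSimilarity(a, b, sim$map, metric = metric))
    rev <- similarityValues(stageSimilarity(b, a, swapMap, metric = metric))
    expect_equal(fwd, t(rev), tolerance = 1e-12)
  }
  cosv <- similarityValues(stageSimilarity(a, b, sim$map, "cosine"))
  expect_true(all(cosv >= 0 & cosv <= 1))
  pear <- similarityValues(stageSimilarity(a, b, sim$map, "pearson"))
  expect_true(all(abs(pear) <= 1 + 1e-12))
  expect_error(stageSimilarity(a, b, OrthologMap("x1", "y1")), ">= 10")
})

test_that("cosine similarity of orthogonal stage vectors is zero", {
  # 10 orthologs, half expressed only at the first stage in A and only at
  # the second stage in B: the two stage vectors are orthogonal and nonzero
  m <- rbind(matrix(rep(c(1, 0), 5), 5, 2, byrow = TRUE),
             matrix(rep(c(0, 1), 5), 5, 2, byrow = TRUE))
  dimnames(m) <- list(sprintf("g%02d", 1:10), c("s1", "s2"))
  b <- m[, 2:1]; colnames(b) <- c("t1", "t2")
  rownames(b) <- sprintf("h%02d", 1:10)
  sm <- stageSimilarity(makeSE(m, normalization = "sum_to_one"),
                        makeSE(b, normalization = "sum_to_one"),
                        OrthologMap(rownames(m), rownames(b)), "cosine")
  v <- similarityValues(sm)
  expect_equal(unname(v["s1", "t1"]), 0)
  expect_equal(unname(v["s1", "t2"]), 1)
})

test_that("best-match trace breaks ties toward the earlier stage", {
  v <- matrix(c(0.2, 0.9, 0.9), 1, 3,
              dimnames = list("A1", c("B1", "B2", "B3")))
  sim <- new("StageSimilarity", values = v, metric = "pearson",
             nOrthologs = 10L, speciesA = "a", speciesB = "b")
  expect_message(tr <- bestMatchTrace(sim), "tie")
  expect_identical(tr$bestMatchStage, "B2")
  expect_equal(divergenceCurve(sim)$divergence, 1 - 0.9)
  vNA <- matrix(NA_real_, 1, 2, dimnames = list("A1", c("B1", "B2")))
  simNA <- new("StageSimilarity", values = vNA, metric = "pearson",
               nOrthologs = 10L, speciesA = "a", speciesB = "b")
  expect_error(bestMatchTrace(simNA), "A1")
  # random matrices: trace equals brute-force argmax
  set.seed(8)
  for (i in 1:20) {
    v <- matrix(runif(48, -1, 1), 6, 8,
                dimnames = list(paste0("A", 1:6), paste0("B", 1:8)))
    s <- new("StageSimilarity", values = v, metric = "pearson",
             nOrthologs = 10L, speciesA = "a", speciesB = "b")
    expect_identical(bestMatchTrace(s)$bestMatchStage,
                     colnames(v)[apply(v, 1, which.max)])
  }
})

test_that("stage classes partition the series with a sensible default", {
  stages <- c("unfE", "fertE", "cell-16", "iniG", "latN", "midTII",
              "latTII", "larva")
  cls <- stageClasses(stages)
  expect_identical(names(cls)[cls == "mid"], c("iniG", "latN"))
  expect_identical(sum(cls == "early"), 3L)
  custom <- stageClasses(stages, early = stages[1:2], mid = stages[3:6],
                         late = stages[7:8])
  expect_identical(sum(custom == "mid"), 4L)
  expect_error(stageClasses(stages, early = stages[1:7], mid = stages[8],
                            late = character()), "partition|class")
})

test_that("hourglass classification matches forced arithmetic", {
  curve <- data.frame(stageA = c("e1", "m1", "l1"),
                      divergence = c(0.1, 0.5, 0.1))
  cls <- stageClasses(c("e1", "m1", "l1"), early = "e1", mid = "m1",
                      late = "l1")
  got <- hourglassClassify(curve, cls, seed = 1)
  expect_equal(got$statistic, 0.4)
  # constant divergence: H = 0, flat
  flatC <- data.frame(stageA = c("e1", "m1", "l1"),
                      divergence = rep(0.3, 3))
  gotF <- hourglassClassify(flatC, cls, seed = 1)
  expect_equal(gotF$statistic, 0)
  expect_identical(gotF$shape, "flat")
  expect_error(hourglassClassify(curve, cls[1:2], seed = 1), "classes")
})

test_that("shared expression fractions follow the analytic expectation", {
  map <- OrthologMap(sprintf("a%04d", 1:5000), sprintf("b%04d", 1:5000))
  stA <- paste0("sA", 1:6); stB <- paste0("sB", 1:6)
  clsA <- stageClasses(stA); clsB <- stageClasses(stB)
  allT <- matrix(TRUE, 5000, 6, dimnames = list(sprintf("a%04d", 1:5000), stA))
  allTB <- matrix(TRUE, 5000, 6, dimnames = list(sprintf("b%04d", 1:5000), stB))
  expect_equal(unname(sharedExpressionFraction(allT, allTB, map, clsA, clsB)),
               rep(1, 3))
  # disjoint halves: nothing commonly expressed
  disA <- allT; disA[2501:5000, ] <- FALSE
  disB <- allTB; disB[1:2500, ] <- FALSE
  expect_equal(unname(sharedExpressionFraction(disA, disB, map, clsA, clsB)),
               rep(0, 3))
  # independent marginal rate p in each species: fraction ~ p^2 per class
  # (one stage per class so class-level and stage-level rates coincide)
  p <- 0.6
  st1A <- "sA1"; st1B <- "sB1"
  cls1A <- stageClasses(c("sA1", "sA2", "sA3"),
                        early = "sA1", mid = "sA2", late = "sA3")
  cls1B <- stageClasses(c("sB1", "sB2", "sB3"),
                        early = "sB1", mid = "sB2", late = "sB3")
  set.seed(10)
  fA <- matrix(runif(15000) < p, 5000, 3,
               dimnames = list(sprintf("a%04d", 1:5000), paste0("sA", 1:3)))
  fB <- matrix(runif(15000) < p, 5000, 3,
               dimnames = list(sprintf("b%04d", 1:5000), paste0("sB", 1:3)))
  frac <- sharedExpressionFraction(fA, fB, map, cls1A, cls1B)
  expect_true(all(abs(frac - p^2) < 3 * sqrt(p^2 * (1 - p^2) / 5000)))
  expect_error(sharedExpressionFraction(fA[0, , drop = FALSE], fB, map,
                                        cls1A, cls1B), "no mapped")
})
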