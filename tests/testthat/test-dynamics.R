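test_that("median normalization equalizes column medians", {
  m <- matrix(c(0.5, 1, 1.5,  1, 2, 3,  2, 4, 6), 3, 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  # column medians 1, 2, 4 -> grand median 2 -> scale factors 2, 1, 0.5
  out <- SummarizedExperiment::assay(medianNormalize(makeSE(m)))
  expect_equal(unname(apply(out, 2, median)), c(2, 2, 2))
  expect_equal(out[, "s1"], m[, "s1"] * 2)
  expect_equal(out[, "s3"], m[, "s3"] * 0.5)
  # already-equal medians: unchanged
  eq <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2)
  expect_equal(SummarizedExperiment::assay(medianNormalize(makeSE(eq))),
               SummarizedExperiment::assay(makeSE(eq)))
  # single column: unchanged
  one <- matrix(c(1, 5), 2, 1)
  expect_equal(SummarizedExperiment::assay(medianNormalize(makeSE(one))),
               SummarizedExperiment::assay(makeSE(one)))
  allz <- matrix(c(1, 2, 0, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("ok", "dead")))
  expect_error(medianNormalize(makeSE(allz)), "dead")
  # invariance: per-column positive rescaling is undone up to one factor
  set.seed(1)
  r <- matrix(runif(40, 0.5, 2), 8, 5)
  scaled <- sweep(r, 2, c(2, 0.1, 7, 1, 0.4), `*`)
  outA <- SummarizedExperiment::assay(medianNormalize(makeSE(r)))
  outB <- SummarizedExperiment::assay(medianNormalize(makeSE(scaled)))
  expect_equal(apply(outB, 2, median), apply(outA, 2, median) /
                 median(apply(r, 2, median)) * median(apply(scaled, 2, median)))
})

test_that("sum-to-one scaling is compositional and idempotent", {
  flat <- matrix(rep(3, 8), 1, 8)
  expect_equal(unname(SummarizedExperiment::assay(sumToOne(makeSE(flat)))[1, ]),
               rep(0.125, 8))
  sp <- matrix(c(2, 0, 2), 1, 3)
  expect_equal(unname(SummarizedExperiment::assay(sumToOne(makeSE(sp)))[1, ]),
               c(0.5, 0, 0.5))
  set.seed(3)
  r <- makeSE(matrix(runif(60), 10, 6))
  p1 <- sumToOne(r)
  expect_equal(unname(rowSums(SummarizedExperiment::assay(p1))),
               rep(1, 10), tolerance = 1e-9)
  p2 <- sumToOne(p1)
  expect_equal(SummarizedExperiment::assay(p2),
               SummarizedExperiment::assay(p1), tolerance = 1e-12)
  # all-zero rows are dropped with a message; missing stays missing
  z <- matrix(c(1, 0, NA, 2, 0, 4), 3, 2,
              dimnames = list(c("a", "zero", "na1"), c("s1", "s2")))
  expect_message(out <- sumToOne(makeSE(z)), "1 all-zero")
  expect_identical(entityIds(out), c("a", "na1"))
  expect_true(is.na(SummarizedExperiment::assay(out)["na1", "s1"]))
})

test_that("RNA-protein correlation handles edge profiles and recovers rho", {
  m <- matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("g", paste0("s", 1:4)))
  rna <- makeSE(m, "rna_tpm")
  protSame <- makeSE(m)
  protRev <- makeSE(matrix(c(4, 3, 2, 1), 1, 4,
                           dimnames = dimnames(m)))
  pairing <- data.frame(rnaId = "g", proteinId = "g")
  expect_equal(rnaProteinCorrelation(rna, protSame, pairing)$medianR, 1)
  expect_equal(rnaProteinCorrelation(rna, protRev, pairing)$medianR, -1)
  # zero-variance profiles are excluded with a message
  protFlat <- makeSE(matrix(1, 1, 4, dimnames = dimnames(m)))
  expect_message(
    out <- rnaProteinCorrelation(rna, protFlat, pairing), "excluded")
  expect_identical(nrow(out$records), 0L)
  # pairs generated at target correlation 0.5: median r within 0.05
  set.seed(7)
  n <- 2000; ns <- 8
  x <- matrix(rnorm(n * ns, 10, 1), n,
              dimnames = list(sprintf("g%04d", 1:n), paste0("s", 1:ns)))
  y <- 10 + 0.5 * (x - 10) + sqrt(0.75) * matrix(rnorm(n * ns), n)
  rna2 <- makeSE(pmax(x, 0), "rna_tpm")
  prot2 <- makeSE(pmax(y, 0))
  res <- rnaProteinCorrelation(rna2, prot2,
                               data.frame(rnaId = rownames(x),
                                          proteinId = rownames(x)))
  expect_lt(abs(res$medianR - 0.5), 0.05)
})

test_that("independent RNA and protein profiles give a median r near zero", {
  set.seed(15)
  n <- 2000; ns <- 8
  ids <- sprintf("g%04d", 1:n)
  x <- matrix(rnorm(n * ns, 10, 1), n,
              dimnames = list(ids, paste0("s", 1:ns)))
  y <- matrix(rnorm(n * ns, 10, 1), n,
              dimnames = list(ids, paste0("s", 1:ns)))
  res <- rnaProteinCorrelation(makeSE(pmax(x, 0), "rna_tpm"),
                               makeSE(pmax(y, 0)),
                               data.frame(rnaId = ids, proteinId = ids))
  expect_lt(abs(res$medianR), 0.05)
})

test_that("profile k-means recovers planted groups and honours restarts", {
  set.seed(5)
  g1 <- matrix(rnorm(80, 0, 0.2) + rep(c(1, 0, 0, 0), each = 20), 20)
  g2 <- matrix(rnorm(80, 0, 0.2) + rep(c(0, 0, 0, 1), each = 20), 20)
  m <- abs(rbind(g1, g2))
  rownames(m) <- sprintf("p%02d", 1:40)
  colnames(m) <- paste0("s", 1:4)
  se <- makeSE(m)
  cl <- kmeansProfiles(se, k = 2, nRestarts = 20, seed = 3)
  expect_identical(length(unique(cl$assignments[1:20])), 1L)
  expect_identical(length(unique(cl$assignments[21:40])), 1L)
  expect_false(cl$assignments[1] == cl$assignments[21])
  # deterministic given seed
  expect_identical(cl, kmeansProfiles(se, k = 2, nRestarts = 20, seed = 3))
  # independent reference: stats::kmeans reaches the same optimum here
  ref <- stats::kmeans(m, centers = 2, nstart = 20)
  expect_equal(cl$totalWithinSS, ref$tot.withinss, tolerance = 1e-8)
  # best-of-restarts never beats a larger restart budget
  w1 <- kmeansProfiles(se, k = 3, nRestarts = 1, seed = 9)$totalWithinSS
  w20 <- kmeansProfiles(se, k = 3, nRestarts = 20, seed = 9)$totalWithinSS
  expect_lte(w20, w1)
  # increasing k never increases the best within-SS
  wByK <- vapply(2:5, function(k)
    kmeansProfiles(se, k = k, nRestarts = 20, seed = 4)$totalWithinSS, 0)
  expect_true(all(diff(wByK) <= 1e-9))
  # k equal to the entity count gives zero within-SS
  clFull <- kmeansProfiles(se, k = 40, nRestarts = 1, seed = 1)
  expect_equal(clFull$totalWithinSS, 0)
  expect_error(kmeansProfiles(se, k = 41, seed = 1), "exceeds")
  # incomplete profiles are excluded with a message
  m2 <- m; m2[1, 1] <- NA
  expect_message(cl2 <- kmeansProfiles(makeSE(m2), k = 2, nRestarts = 5,
                                       seed = 1), "incomplete")
  expect_identical(cl2$nExcluded, 1L)
  # cluster ids ordered by descending size
  expect_true(all(diff(as.integer(table(cl$assignments))) <= 0))
})

test_that("ortholog co-clustering works on concatenated profiles", {
  set.seed(11)
  n <- 30
  early <- c(0.6, 0.25, 0.1, 0.05)
  late <- rev(early)
  mk <- function(centre) t(vapply(seq_len(n), function(i) {
    p <- abs(centre + rnorm(4, 0, 0.02)); p / sum(p) }, numeric(4)))
  a <- rbind(mk(early), mk(late))
  rownames(a) <- sprintf("a%02d", 1:(2 * n))
  colnames(a) <- paste0("sA", 1:4)
  b <- rbind(mk(early), mk(late))
  rownames(b) <- sprintf("b%02d", 1:(2 * n))
  colnames(b) <- paste0("sB", 1:4)
  profA <- makeSE(a, normalization = "sum_to_one")
  profB <- makeSE(b, normalization = "sum_to_one")
  map <- OrthologMap(rownames(a), rownames(b))
  co <- coClusterOrthologs(profA, profB, map, k = 2, nRestarts = 10,
                           seed = 2)
  expect_identical(length(unique(co$assignments[1:n])), 1L)
  expect_false(co$assignments[1] == co$assignments[n + 1])
  # k = 1: single centroid equals the mean concatenated profile
  co1 <- coClusterOrthologs(profA, profB, map, k = 1, nRestarts = 2,
                            seed = 2)
  expect_equal(unname(co1$centroids[1, ]),
               unname(colMeans(cbind(a, b))), tolerance = 1e-9)
  expect_error(coClusterOrthologs(profA, profB,
                                  OrthologMap(character(), character())),
               "empty")
  rawA <- makeSE(a)  # not tagged sum_to_one
  expect_error(coClusterOrthologs(rawA, profB, map), "sum-to-one")
})

test_that("fold changes invert under stage swap", {
  m <- matrix(c(2, 5, 8, 5), 2, 2,
              dimnames = list(c("p1", "p2"), c("egg", "larva")))
  se <- makeSE(m)
  fc <- foldChange(se, "larva", "egg")
  expect_equal(fc$FC, c(4, 1))
  expect_equal(fc$log2FC, c(2, 0))
  back <- foldChange(se, "egg", "larva")
  expect_equal(fc$FC * back$FC, c(1, 1))
  expect_error(foldChange(se, "larva", "blastula"), "unknown stage")
  mz <- matrix(c(0, 1, 2, 3), 2, 2,
               dimnames = list(c("z", "p"), c("egg", "larva")))
  expect_message(fcz <- foldChange(makeSE(mz), "larva", "egg"), "excluded")
  expect_identical(fcz$entity, "p")
})

test_that("stage-transition ranking matches brute-force recomputation", {
  m <- matrix(c(1, 1, 1,   2, 1, 1,  2, 1, 1), 3, 3,
              dimnames = list(c("doubler", "f1", "f2"),
                              c("s1", "s2", "s3")))
  rk <- stageTransitionRanking(makeSE(m))
  expect_identical(rk[["s1->s2"]]$entity[1], "doubler")
  # flat matrix: all tied, id order
  fl <- matrix(1, 3, 2, dimnames = list(c("b", "a", "c"), c("s1", "s2")))
  expect_identical(stageTransitionRanking(makeSE(fl))[[1]]$entity,
                   c("a", "b", "c"))
  set.seed(13)
  r <- matrix(runif(40), 8, 5,
              dimnames = list(sprintf("e%02d", 1:8), paste0("s", 1:5)))
  rk <- stageTransitionRanking(makeSE(r), topN = 8)
  eps <- min(r[r > 0]) * 0.5
  for (j in 1:4) {
    want <- abs(log2((r[, j + 1] + eps) / (r[, j] + eps)))
    got <- rk[[j]]
    expect_equal(got$absLog2Ratio, unname(sort(want, decreasing = TRUE)))
  }
})

test_that("isoform TPM aggregation conserves stage totals", {
  m <- matrix(c(3, 7, 5, 1, 2, 4), 3, 2,
              dimnames = list(c("tx1", "tx2", "tx3"), c("s1", "s2")))
  se <- makeSE(m, "rna_tpm")
  mapping <- c(tx1 = "gA", tx2 = "gA", tx3 = "gB")
  out <- aggregateIsoformTpm(se, mapping)
  v <- SummarizedExperiment::assay(out)
  expect_equal(v["gA", "s1"], 10)
  expect_equal(unname(colSums(v)), unname(colSums(m)))
  # one isoform per gene: values unchanged up to relabelling
  one <- aggregateIsoformTpm(se, c(tx1 = "g1", tx2 = "g2", tx3 = "g3"))
  expect_equal(unname(SummarizedExperiment::assay(one)[paste0("g", 1:3), ]),
               unname(m))
  expect_error(aggregateIsoformTpm(se, c(tx1 = "gA")), "tx2")
})

test_that("expression flags use an inclusive TPM threshold", {
  m <- matrix(c(2, 1.999, NA, 0.5), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  f <- expressedFlags(makeSE(m, "rna_tpm"))
  expect_true(f["g1", "s1"])            # TPM exactly 2 counts as expressed
  expect_false(f["g2", "s1"])
  expect_false(f["g1", "s2"])           # missing is not expressed
  fAll <- expressedFlags(makeSE(m, "rna_tpm"), threshold = 0)
  expect_true(all(fAll[!is.na(m)]))
})
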