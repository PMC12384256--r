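# Decision-performance and dose-error evaluation.

test_that("dose error statistics follow the closed forms and the voxel oracle", {
  dims <- c(6L, 6L, 5L)
  sp <- c(3, 3, 3)
  set.seed(19)
  refArr <- array(runif(prod(dims), 10, 70), dims)
  masks <- list(full = VoxelGrid(array(1, dims), sp))
  oar <- "full"
  ss <- StructureSet(masks)

  ref <- VoxelGrid(refArr, sp)
  same <- doseErrorStats(list(ref), list(ref), list(ss), 73.92, oars = oar)
  expect_equal(same$mae_pct, 0)
  expect_equal(same$me_pct, 0)

  shifted <- VoxelGrid(refArr + 1, sp)
  st <- doseErrorStats(list(shifted), list(ref), list(ss), 73.92, oars = oar)
  expect_equal(st$mae_pct, 1 / 73.92 * 100)
  expect_equal(st$me_pct, 1 / 73.92 * 100)

  # brute-force two-loop oracle on random paired grids, two cases
  predArr1 <- refArr + array(rnorm(prod(dims), 0, 2), dims)
  predArr2 <- refArr + array(rnorm(prod(dims), 0, 2), dims)
  m <- array(rbinom(prod(dims), 1, 0.5), dims)
  m[1, 1, 1] <- 1
  ssm <- StructureSet(list(roi = VoxelGrid(m, sp)))
  got <- doseErrorStats(list(VoxelGrid(predArr1, sp), VoxelGrid(predArr2, sp)),
                        list(ref, ref), list(ssm, ssm), 73.92, oars = "roi")
  maeCase <- meCase <- numeric(2)
  for (j in 1:2) {
    pa <- if (j == 1) predArr1 else predArr2
    sAbs <- s <- 0; cnt <- 0
    for (i in seq_len(dims[1])) for (jj in seq_len(dims[2]))
      for (k in seq_len(dims[3])) if (m[i, jj, k] > 0) {
        diff <- pa[i, jj, k] - refArr[i, jj, k]
        sAbs <- sAbs + abs(diff); s <- s + diff; cnt <- cnt + 1
      }
    maeCase[j] <- sAbs / cnt; meCase[j] <- s / cnt
  }
  expect_equal(got$mae_pct, mean(maeCase) / 73.92 * 100)
  expect_equal(got$me_pct, mean(meCase) / 73.92 * 100)
  expect_gte(got$mae_pct, abs(got$me_pct))

  expect_error(doseErrorStats(list(ref), list(ref, ref), list(ssm, ssm),
                              73.92), "paired")
})

test_that("MAE bounds the absolute ME, with equality iff single-signed errors", {
  dims <- c(4L, 4L, 4L)
  ss <- StructureSet(list(roi = VoxelGrid(array(1, dims))))
  ref <- VoxelGrid(array(30, dims))
  set.seed(33)
  for (rep in 1:10) {
    pred <- VoxelGrid(array(30 + rnorm(64, 0, 3), dims))
    st <- doseErrorStats(list(pred), list(ref), list(ss), 73.92, oars = "roi")
    expect_gte(st$mae_pct, abs(st$me_pct))
  }
  onesided <- VoxelGrid(array(30 + runif(64, 0, 5), dims))
  st <- doseErrorStats(list(onesided), list(ref), list(ss), 73.92,
                       oars = "roi")
  expect_equal(st$mae_pct, st$me_pct)
})

test_that("confusion counts follow the positive-means-PT convention", {
  expect_equal(confusionCounts(c("PT", "PT", "XT"), c("PT", "XT", "XT")),
               c(tp = 1L, fp = 1L, fn = 0L, tn = 1L))
  ref <- c(rep("PT", 5), rep("XT", 3))
  allRight <- confusionCounts(ref, ref)
  expect_equal(allRight[["fp"]] + allRight[["fn"]], 0)
  inverted <- ifelse(ref == "PT", "XT", "PT")
  inv <- confusionCounts(inverted, ref)
  expect_equal(inv[["tp"]] + inv[["tn"]], 0)
  # a 48-case cohort with 3 errors leaves 45 correct
  dec <- c(rep("PT", 33), rep("XT", 15))
  truth <- dec
  truth[1] <- "XT"; truth[34] <- "PT"; truth[35] <- "PT"
  cc <- confusionCounts(dec, truth)
  expect_equal(sum(cc), 48L)
  expect_equal(cc[["tp"]] + cc[["tn"]], 45L)
  expect_error(confusionCounts(c("PT"), c("PT", "XT")), "paired")
  expect_error(confusionCounts(c("pt"), c("PT")), "PT")
})

test_that("metrics reproduce exact rational arithmetic", {
  m <- decisionMetrics(c(tp = 33, fp = 1, fn = 2, tn = 12))
  expect_equal(m$accuracy, 45 / 48)
  expect_equal(m$sensitivity, 33 / 35)
  expect_equal(m$specificity, 12 / 13)
  expect_equal(m$f_score, 66 / 69)
  expect_length(m$flags, 0)

  perfect <- decisionMetrics(c(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                "f_score")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 f_score = 1))

  degenerate <- decisionMetrics(c(tp = 0, fp = 0, fn = 0, tn = 4))
  expect_true(is.na(degenerate$sensitivity))
  expect_true(all(c("sensitivity", "f_score") %in% degenerate$flags))
})

test_that("accuracy is the prevalence-weighted mix of sensitivity and specificity", {
  set.seed(8)
  for (rep in 1:25) {
    counts <- c(tp = sample(1:20, 1), fp = sample(1:20, 1),
                fn = sample(1:20, 1), tn = sample(1:20, 1))
    m <- decisionMetrics(counts)
    prev <- (counts[["tp"]] + counts[["fn"]]) / sum(counts)
    expect_equal(m$accuracy,
                 prev * m$sensitivity + (1 - prev) * m$specificity)
  }
})

test_that("rank-based AUC matches its definition and an independent package", {
  expect_equal(rocAuc(c(1, 2, 3, 10, 11), c("XT", "XT", "XT", "PT", "PT")), 1)
  expect_equal(rocAuc(rep(0.3, 6), c(rep("PT", 3), rep("XT", 3))), 0.5)

  set.seed(14)
  scores <- rnorm(40)
  labels <- sample(c("PT", "XT"), 40, replace = TRUE, prob = c(0.6, 0.4))
  # pairwise-count oracle with half-weight ties
  pos <- scores[labels == "PT"]; neg <- scores[labels == "XT"]
  acc <- 0
  for (p in pos) for (q in neg)
    acc <- acc + (p > q) + 0.5 * (p == q)
  expect_equal(rocAuc(scores, labels), acc / (length(pos) * length(neg)))

  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("XT", "PT"),
    direction = "<", quiet = TRUE)))
  expect_equal(rocAuc(scores, labels), ref)

  # invariance under strictly monotone transforms
  expect_equal(rocAuc(exp(scores), labels), rocAuc(scores, labels))
  expect_equal(rocAuc(rank(scores), labels), rocAuc(scores, labels))
  expect_error(rocAuc(scores, rep("PT", 40)), "both classes")
})

test_that("paired t-test matches stats::t.test and flags degeneracies", {
  set.seed(3)
  a <- rnorm(20, 10, 2); b <- rnorm(20, 9, 2)
  got <- pairedTTest(a, b)
  want <- t.test(a, b, paired = TRUE)
  expect_equal(got$t, unname(want$statistic))
  expect_equal(got$p, want$p.value)
  # textbook formula oracle
  d <- a - b
  tOracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$t, tOracle)

  same <- pairedTTest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_match(same$flag, "identical")

  shift <- pairedTTest(a + 2, a)
  expect_true(is.infinite(shift$t))
  expect_match(shift$flag, "constant shift")
})
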