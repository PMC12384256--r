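# Dose/mask reductions: mean dose, DVH, distance-to-target.

test_that("mean dose matches hand values and the voxel-loop oracle", {
  dims <- c(4L, 3L, 2L)
  uniform <- VoxelGrid(array(50, dims))
  m <- array(0, dims); m[2:3, 2, 1] <- 1
  mask <- VoxelGrid(m)
  expect_equal(meanDose(uniform, mask), 50)

  two <- array(0, dims); two[1, 1, 1] <- 10; two[2, 1, 1] <- 30
  tm <- array(0, dims); tm[1:2, 1, 1] <- 1
  expect_equal(meanDose(VoxelGrid(two), VoxelGrid(tm)), 20)

  set.seed(41)
  for (rep in 1:5) {
    d <- array(runif(512, 0, 80), c(8L, 8L, 8L))
    msk <- array(rbinom(512, 1, 0.3), c(8L, 8L, 8L))
    if (!any(msk > 0)) next
    acc <- 0; cnt <- 0
    for (i in 1:8) for (j in 1:8) for (k in 1:8)
      if (msk[i, j, k] > 0) { acc <- acc + d[i, j, k]; cnt <- cnt + 1 }
    expect_equal(meanDose(VoxelGrid(d), VoxelGrid(msk)), acc / cnt)
  }
})

test_that("mean dose ignores voxels outside the mask and rejects bad input", {
  set.seed(7)
  dims <- c(6L, 6L, 6L)
  d <- array(runif(216, 0, 70), dims)
  m <- array(rbinom(216, 1, 0.4), dims)
  mask <- VoxelGrid(m)
  base <- meanDose(VoxelGrid(d), mask)
  for (rep in 1:10) {
    d2 <- d
    d2[m == 0] <- runif(sum(m == 0), 0, 200) # fuzz outside the mask
    expect_identical(meanDose(VoxelGrid(d2), mask), base)
  }

  expect_error(meanDose(VoxelGrid(d), VoxelGrid(array(0, dims)), "parotid_l"),
               "empty mask for 'parotid_l'")
  expect_error(meanDose(VoxelGrid(d), VoxelGrid(array(1, dims), spacing = 2)),
               "lattice")
})

test_that("cumulative DVH is a non-increasing curve starting at 100%", {
  dims <- c(5L, 5L, 4L)
  mask <- VoxelGrid(array(1, dims))

  dvh <- cumulativeDVH(VoxelGrid(array(60, dims)), mask, binWidth = 0.1)
  expect_equal(dvh$volume_pct[1], 100)
  expect_true(all(diff(dvh$volume_pct) <= 0))
  expect_equal(volumeAtDose(VoxelGrid(array(60, dims)), mask, 59.9), 100)
  expect_equal(volumeAtDose(VoxelGrid(array(60, dims)), mask, 60.1), 0)

  bimodal <- array(rep(c(70, 74), each = 50), dims)
  expect_equal(volumeAtDose(VoxelGrid(bimodal), mask, 73.92), 50)

  set.seed(11)
  d <- array(runif(prod(dims), 0, 80), dims)
  g <- VoxelGrid(d)
  for (lvl in c(0, 13.7, 40, 79.9)) {
    expect_equal(volumeAtDose(g, mask, lvl), 100 * sum(d >= lvl) / length(d))
  }
  expect_equal(maxDose(g, mask), max(d))
  expect_error(cumulativeDVH(g, mask, binWidth = 0), "positive")
})

test_that("distance-to-target is zero inside PTV, spacing-aware outside", {
  st <- fixtureBoxStructures(spacing = c(2, 1, 3))
  dm <- distanceToTarget(st$ptv, st$body)
  v <- gridValues(dm)
  expect_true(all(v[gridValues(st$ptv) > 0] == 0))
  # face-adjacent along x: one 2 mm step
  expect_equal(v[3, 5, 5], 2)
  # face-adjacent along y: one 1 mm step
  expect_equal(v[5, 3, 5], 1)
  # face-adjacent along z: one 3 mm step
  expect_equal(v[5, 5, 7], 3)
})

test_that("distance map equals all-pairs brute force on toy volumes", {
  set.seed(5)
  for (rep in 1:3) {
    dims <- c(10L, 9L, 8L)
    sp <- runif(3, 0.8, 3)
    ptv <- array(0, dims)
    n <- sample(3:10, 1)
    idx <- cbind(sample(3:8, n, TRUE), sample(3:7, n, TRUE),
                 sample(3:6, n, TRUE))
    ptv[idx] <- 1
    body <- array(rbinom(prod(dims), 1, 0.9), dims)
    body[ptv > 0] <- 1
    pg <- VoxelGrid(ptv, sp); bg <- VoxelGrid(body, sp)
    got <- gridValues(distanceToTarget(pg, bg))
    want <- bruteForceDptv(pg, bg)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(is.na(got[body == 0])))
  }
  st <- fixtureBoxStructures()
  expect_error(distanceToTarget(VoxelGrid(array(0, c(10L, 10L, 10L)),
                                          c(2, 2, 2)), st$body), "empty PTV")
})

test_that("summarizeCase returns one mean dose per NTCP organ", {
  spec <- fixtureSpec()
  ss <- hnPhantomStructures(spec, caseSeed = 3)
  dose <- predictDose(ss, "XT", spec$params)
  s <- summarizeCase(dose, ss, prescription = 73.92)
  expect_setequal(names(doseMeans(s)), ntcpOars())
  expect_equal(doseMeans(s)[["oral_cavity"]],
               meanDose(dose, structureMask(ss, "oral_cavity")))
  expect_identical(doseMeans(summarizeCase(dose, ss)), doseMeans(s))

  keep <- setdiff(structureNames(ss), "pcm_m")
  ss2 <- StructureSet(setNames(lapply(keep, structureMask, x = ss), keep))
  expect_error(summarizeCase(dose, ss2), "pcm_m")
})
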