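# NIPP delta-NTCP decision tree.

# Independent flat re-statement of the five rules (no early exit, no trace):
# used as the oracle against decide().
flatDecision <- function(d2x, d2d, d3x, d3d, thr, xtXer2 = 0.5,
                         xtDys2 = 0.5) {
  if (thr@gateEnabled && max(xtXer2, xtDys2) < thr@xtGate) return("XT")
  pt <- (d2x >= thr@t2Single) || (d2d >= thr@t2Single) ||
    ((d2x + d2d) >= thr@t2Sum) ||
    (d3x >= thr@t3Single) || (d3d >= thr@t3Single) ||
    ((d3x + d3d) >= thr@t3Sum)
  if (pt) "PT" else "XT"
}

test_that("delta profiles are elementwise XT minus PT", {
  xt <- fixtureProfile("XT", 0.47, 0.13, 0.17, 0.04)
  pt <- fixtureProfile("PT", 0.44, 0.12, 0.06, 0.01)
  dp <- deltaProfile(xt, pt)
  expect_equal(deltaValues(dp)[["Xer2+"]], 0.03)
  expect_equal(deltaValues(dp)[["Dys2+"]], 0.11)
  expect_equal(xtLevels(dp), ntcpValues(xt))
  expect_equal(deltaSum2(dp), 0.03 + 0.11)
  expect_equal(deltaSum3(dp), 0.01 + 0.03)

  same <- deltaProfile(xt, fixtureProfile("PT", 0.47, 0.13, 0.17, 0.04))
  expect_equal(unname(deltaValues(same)), rep(0, 4))

  set.seed(23)
  for (rep in 1:10) {
    a <- runif(4, 0.05, 0.9); b <- runif(4, 0.02, 0.8)
    pa <- NTCPProfile("XT", setNames(a, ntcpEndpoints()))
    pb <- NTCPProfile("PT", setNames(b, ntcpEndpoints()))
    expect_equal(unname(deltaValues(deltaProfile(pa, pb))), a - b)
  }

  expect_error(deltaProfile(pt, xt), "XT and one PT")
  expect_error(deltaProfile(xt, xt), "XT and one PT")
})

test_that("single cases route through the documented rules", {
  thrNoGate <- decisionThresholds(gateEnabled = FALSE)

  r <- decide(fixtureDelta(dXer2 = 0.12), thrNoGate)
  expect_identical(modality(r), "PT")
  expect_identical(ruleFired(r), "single2")

  r <- decide(fixtureDelta(), thrNoGate)
  expect_identical(modality(r), "XT")
  expect_identical(ruleFired(r), "none")

  # a mismatched-case magnitude just below the 10% threshold
  r <- decide(fixtureDelta(dDys2 = 0.0994), thrNoGate)
  expect_identical(modality(r), "XT")

  # combined grade-2 step under the default 15% sum threshold
  r <- decide(fixtureDelta(dXer2 = 0.06, dDys2 = 0.09), thrNoGate)
  expect_identical(modality(r), "PT")
  expect_identical(ruleFired(r), "sum2")

  # grade-3 branch at its 5% threshold
  r <- decide(fixtureDelta(dDys3 = 0.05), thrNoGate)
  expect_identical(ruleFired(r), "single3")
  r <- decide(fixtureDelta(dXer3 = 0.04, dDys3 = 0.035), thrNoGate)
  expect_identical(ruleFired(r), "sum3")

  # photon-level gate stops low-risk patients before any delta is considered
  gated <- decide(fixtureDelta(dXer2 = 0.2, xtXer2 = 0.05, xtDys2 = 0.08))
  expect_identical(modality(gated), "XT")
  expect_identical(ruleFired(gated), "gate")
  ungated <- decide(fixtureDelta(dXer2 = 0.2, xtXer2 = 0.05, xtDys2 = 0.08),
                    decisionThresholds(gateEnabled = FALSE))
  expect_identical(modality(ungated), "PT")
})

test_that("thresholds are inclusive at every boundary", {
  thr <- decisionThresholds(gateEnabled = FALSE)
  at <- list(
    list(dp = fixtureDelta(dXer2 = 0.10), rule = "single2"),
    list(dp = fixtureDelta(dDys2 = 0.10), rule = "single2"),
    list(dp = fixtureDelta(dXer2 = 0.075, dDys2 = 0.075), rule = "sum2"),
    list(dp = fixtureDelta(dXer3 = 0.05), rule = "single3"),
    list(dp = fixtureDelta(dDys3 = 0.05), rule = "single3"),
    list(dp = fixtureDelta(dXer3 = 0.0375, dDys3 = 0.0375), rule = "sum3"))
  for (case in at) {
    r <- decide(case$dp, thr)
    expect_identical(modality(r), "PT")
    expect_identical(ruleFired(r), case$rule)
  }
  # gate boundary is inclusive too
  r <- decide(fixtureDelta(dXer2 = 0.2, xtXer2 = 0.10, xtDys2 = 0.01))
  expect_identical(modality(r), "PT")
})

test_that("decide matches the flat boolean oracle on the full delta grid", {
  thr <- decisionThresholds(gateEnabled = FALSE)
  grid <- seq(0, 0.20, by = 0.025)
  cases <- expand.grid(d2x = grid, d2d = grid, d3x = grid, d3d = grid)
  got <- character(nrow(cases))
  want <- character(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    dp <- fixtureDelta(dXer2 = cs$d2x, dDys2 = cs$d2d,
                       dXer3 = cs$d3x, dDys3 = cs$d3d)
    got[i] <- modality(decide(dp, thr))
    want[i] <- flatDecision(cs$d2x, cs$d2d, cs$d3x, cs$d3d, thr)
  }
  expect_identical(got, want)
  expect_gt(sum(want == "PT"), 0)
  expect_gt(sum(want == "XT"), 0)
})

test_that("increasing any single delta never flips PT to XT", {
  thr <- decisionThresholds(gateEnabled = FALSE)
  set.seed(97)
  eps <- c(0.01, 0.03, 0.08)
  for (rep in 1:40) {
    d <- runif(4, 0, 0.12)
    dp <- fixtureDelta(d[1], d[2], d[3], d[4])
    base <- modality(decide(dp, thr))
    for (j in 1:4) for (e in eps) {
      d2 <- d; d2[j] <- d2[j] + e
      up <- modality(decide(fixtureDelta(d2[1], d2[2], d2[3], d2[4]), thr))
      if (base == "PT") expect_identical(up, "PT")
    }
  }
})

test_that("traces are deterministic and consistent with the decision", {
  dp <- fixtureDelta(dXer2 = 0.04, dDys2 = 0.06, dXer3 = 0.02, dDys3 = 0.03)
  r1 <- decide(dp)
  r2 <- decide(dp)
  expect_identical(decisionTrace(r1), decisionTrace(r2))
  expect_identical(modality(r1), modality(r2))
  tr <- decisionTrace(r1)
  expect_identical(tr$rule, c("gate", "single2", "sum2", "single3", "sum3"))
  expect_true(all(tr$outcome %in% c("pass", "continue", "accept", "reject")))

  xt <- list(fixtureProfile("XT", 0.5, 0.1, 0.2, 0.05),
             fixtureProfile("XT", 0.4, 0.1, 0.3, 0.05))
  pt <- list(fixtureProfile("PT", 0.45, 0.08, 0.05, 0.01),
             fixtureProfile("PT", 0.39, 0.09, 0.29, 0.04))
  res <- decideCohort(xt, pt)
  expect_length(res, 2)
  expect_identical(modality(res[[1]]), "PT")
  expect_identical(modality(res[[2]]), "XT")
  expect_error(decideCohort(xt, pt[1]), "paired")
})

test_that("benefit score crosses 1 exactly where the ungated tree accepts", {
  thr <- decisionThresholds(gateEnabled = FALSE)
  set.seed(61)
  for (rep in 1:60) {
    d <- runif(4, 0, 0.16)
    dp <- fixtureDelta(d[1], d[2], d[3], d[4])
    expect_identical(benefitScore(dp, thr) >= 1,
                     modality(decide(dp, thr)) == "PT")
  }
})
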