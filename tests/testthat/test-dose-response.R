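test_that("probit fitting recovers noiseless parameters and rejects short series", {
  x <- log10(dilution7)
  v <- 100 * pnorm(2 + 1.5 * x)
  fit <- fitProbitCurve(doseResponseCurve(dilution7, v))
  expect_true(fit@converged)
  expect_equal(fit@intercept, 2, tolerance = 1e-4)
  expect_equal(fit@slope, 1.5, tolerance = 1e-4)

  # decreasing-viability orientation (negative slope)
  v2 <- 100 * pnorm(-0.5 - 1.2 * x)
  fit2 <- fitProbitCurve(doseResponseCurve(dilution7, v2))
  expect_equal(fit2@slope, -1.2, tolerance = 1e-4)

  expect_error(fitProbitCurve(doseResponseCurve(c(10, 1, 0.1), c(90, 50, 10))),
               "4 distinct")
})

test_that("flat viability series use the closed form", {
  fit <- fitProbitCurve(doseResponseCurve(dilution7, rep(50, 7)))
  expect_equal(fit@slope, 0)
  expect_equal(fit@flatLevel, 50)
  expect_equal(pairVote:::probitViability(fit, c(-1, 0, 1)), rep(50, 3))
  expect_equal(probitAuc(fit), 50)
})

test_that("AUC anchors: flat 100 gives exactly 100, flat 0 gives 0, symmetry gives 50", {
  flat100 <- fitProbitCurve(doseResponseCurve(dilution7, rep(100, 7)))
  expect_identical(probitAuc(flat100), 100)
  expect_identical(labelByAuc(probitAuc(flat100)), "resistant")

  flat0 <- fitProbitCurve(doseResponseCurve(dilution7, rep(0, 7)))
  expect_identical(probitAuc(flat0), 0)

  # growth-stimulated flat profile integrates above 100
  flat120 <- fitProbitCurve(doseResponseCurve(dilution7, rep(120, 7)))
  expect_identical(probitAuc(flat120), 120)

  # mean of 100*pnorm(x) over [-1, 1] is 50 by symmetry of the normal CDF
  sym <- new("ProbitFit", intercept = 0, slope = 1, converged = TRUE,
             xLo = -1, xHi = 1, flatLevel = NA_real_)
  expect_equal(probitAuc(sym), 50, tolerance = 1e-8)
})

test_that("AUC is invariant to the direction of the concentration series", {
  x <- log10(dilution7)
  v <- 100 * pnorm(0.8 - 1.1 * x)
  up <- doseResponseCurve(rev(dilution7), rev(v))
  down <- doseResponseCurve(dilution7, v)
  expect_equal(probitAuc(fitProbitCurve(up)), probitAuc(fitProbitCurve(down)),
               tolerance = 1e-8)
})

test_that("sensitivity calls split exactly at AUC = 100", {
  expect_identical(labelByAuc(99.9), "sensitive")
  expect_identical(labelByAuc(100), "resistant")
  expect_identical(labelByAuc(150), "resistant")
  expect_identical(labelByAuc(c(0, 100, 299)),
                   c("sensitive", "resistant", "resistant"))
  expect_error(labelByAuc(301), "\\[0, 300\\]")
  expect_error(labelByAuc(-1), "\\[0, 300\\]")
})

test_that("computeDss reproduces the closed-form scores", {
  # hand evaluation: (200 - 10*2) / ((100 - 10) * 3)
  d1 <- computeDss(aucResp = 200, x1 = -1, x2 = 1, cMin = -1.5, cMax = 1.5,
                   aMin = 10)
  expect_equal(d1, 180 / 270, tolerance = 1e-12)

  # numerator vanishes when the area equals the threshold rectangle
  expect_equal(computeDss(aucResp = 10 * 2, x1 = -1, x2 = 1, cMin = -1.5,
                          cMax = 1.5, aMin = 10), 0)

  # log10(10) = 1 makes DSS2 equal DSS1
  d2 <- computeDss(200, -1, 1, -1.5, 1.5, aMin = 10, rMax = 10, version = 2)
  expect_equal(d2, d1)

  # DSS3 rescales by the active fraction of the dose range
  d3 <- computeDss(200, -1, 1, -1.5, 1.5, aMin = 10, rMax = 10, version = 3)
  expect_equal(d3, d2 * 2 / 3)

  expect_error(computeDss(200, -1, 1, -1.5, 1.5, rMax = 1, version = 2),
               "rMax")
  expect_error(computeDss(200, -1, 1, -1.5, 1.5, rMax = 0.5, version = 3),
               "rMax")
})

test_that("dssFromFit handles non-responders and full responders", {
  # viability at or above 100 everywhere: inhibition never exceeds Amin
  nonresp <- fitProbitCurve(doseResponseCurve(dilution7, rep(110, 7)))
  expect_identical(dssFromFit(nonresp), 0)

  # full inhibition with aMin = 0: DSS1 = 1 exactly
  full <- fitProbitCurve(doseResponseCurve(dilution7, rep(0, 7)))
  expect_equal(dssFromFit(full, aMin = 0), 1, tolerance = 1e-9)
})

test_that("dssFromFit crossing points and scores match a dense-grid oracle", {
  set.seed(21)
  for (i in 1:25) {
    b0 <- runif(1, -2, 2)
    b1 <- runif(1, -3, -0.3)
    fit <- new("ProbitFit", intercept = b0, slope = b1, converged = TRUE,
               xLo = log10(min(dilution7)), xHi = log10(max(dilution7)),
               flatLevel = NA_real_)
    for (vs in c(1, 2)) {
      got <- dssFromFit(fit, aMin = 10, version = vs)
      want <- denseGridDss(fit, aMin = 10, version = vs)
      expect_equal(got, want, tolerance = 1e-4)
    }
  }
})

test_that("sdss is the exact control-mean subtraction", {
  expect_identical(sdss(5, c(2, 4)), 2)
  expect_identical(sdss(3.5, c(3.5)), 0)
  expect_identical(sdss(7, 4), 3)
  expect_error(sdss(5, numeric(0)), "control")
  # inversion identity
  set.seed(5)
  for (i in 1:20) {
    p <- rnorm(1); ctl <- rnorm(sample(1:6, 1))
    expect_equal(sdss(p, ctl) + mean(ctl), p)
  }
})

test_that("sDSS percentile labelling matches a sort-and-count oracle", {
  rec <- data.frame(sample_id = paste0("s", 1:100), drug_id = "d",
                    sdss = 1:100)
  out <- labelBySdssPercentile(rec, 95)
  thr <- attr(out, "threshold")
  expect_equal(thr, unname(quantile(1:100, 0.95)))
  # oracle: count values strictly above the interpolated percentile
  expect_identical(sum(out$label == "sensitive"), sum(1:100 > thr))
  expect_identical(sum(out$label == "sensitive"), 5L)

  same <- data.frame(sample_id = "x", drug_id = rep("d", 8), sdss = rep(2, 8))
  expect_true(all(labelBySdssPercentile(same, 95)$label == "resistant"))

  out0 <- labelBySdssPercentile(rec, 0)
  expect_identical(sum(out0$label == "sensitive"), 99L)

  expect_error(labelBySdssPercentile(rec[0, ], 95), "non-empty")
})
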