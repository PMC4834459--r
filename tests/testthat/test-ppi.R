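make_run <- function(arr) volumeGrid(arr, voxelSizeMm = c(2, 2, 2))

test_that("seed extraction averages the roi voxels per volume", {
  set.seed(2)
  arr <- array(rnorm(4 * 4 * 3 * 6), c(4, 4, 3, 6))
  run <- make_run(arr)
  roi1 <- array(FALSE, c(4, 4, 3)); roi1[2, 3, 1] <- TRUE
  expect_equal(extractSeedTimeseries(run, roi1), arr[2, 3, 1, ])
  roi2 <- roi1; roi2[4, 1, 2] <- TRUE
  expect_equal(extractSeedTimeseries(run, roi2),
               (arr[2, 3, 1, ] + arr[4, 1, 2, ]) / 2)
  constRun <- make_run(array(7, c(4, 4, 3, 6)))
  expect_equal(extractSeedTimeseries(constRun, roi2), rep(7, 6))
  expect_error(extractSeedTimeseries(run, array(FALSE, c(4, 4, 3))), "empty")
  expect_error(extractSeedTimeseries(run, array(TRUE, c(5, 4, 3))), "match")
})

test_that("psychological regressor matches a direct convolution oracle", {
  ev <- new("EventSchedule", onsetsS = 20, durationsS = 4,
            conditions = "guilt")
  hrf <- hrfSpec()
  w <- c(guilt = 1, indignation = -1, baseline = 0)
  reg <- buildPsychRegressor(ev, w, hrf, nVolumes = 60L, trS = 2)
  oracle <- direct_psych_regressor(ev, w, hrf, nVolumes = 60L, trS = 2)
  expect_equal(reg, oracle, tolerance = 1e-8)

  # maximal near onset + HRF peak delay; back toward baseline 16 s after offset
  tAcq <- (0:59) * 2
  peakT <- tAcq[which.max(reg)]
  expect_gte(peakT, 20 + 4)      # rises through the event
  expect_lte(peakT, 20 + 4 + 8)  # peaks within the HRF delay of the offset
  late <- reg[tAcq > 20 + 4 + 16 + 8]
  expect_lt(max(abs(late - late[length(late)])), 0.05 * max(reg))
})

test_that("psychological regressor is linear in the condition weights", {
  set.seed(4)
  ev <- new("EventSchedule", onsetsS = c(10, 30, 55), durationsS = c(4, 5, 3),
            conditions = c("guilt", "indignation", "guilt"))
  zero <- buildPsychRegressor(ev, c(guilt = 0, indignation = 0, baseline = 0),
                              nVolumes = 50L, trS = 2)
  expect_identical(zero, rep(0, 50))
  a <- buildPsychRegressor(ev, c(guilt = 1, indignation = -1, baseline = 0),
                           nVolumes = 50L, trS = 2)
  b <- buildPsychRegressor(ev, c(guilt = -1, indignation = 1, baseline = 0),
                           nVolumes = 50L, trS = 2)
  expect_equal(a, -b, tolerance = 1e-12)
  expect_error(buildPsychRegressor(ev, c(guilt = 1), nVolumes = 50L, trS = 2),
               "indignation")
})

test_that("PPI design centers, multiplies and guards rank", {
  # orthogonal centered pair: interaction column has mean ~ 0
  n <- 40
  psych <- rep(c(1, -1), n / 2)                 # centered
  seed <- rep(c(1, 1, -1, -1), n / 4)           # centered, orthogonal to psych
  des <- assemblePPIDesign(seed, psych)
  expect_lt(abs(mean(des@values[, "interaction"])), 1e-10)
  expect_identical(colnames(des@values)[1:3],
                   c("psych", "physio", "interaction"))

  # constant seed: interaction all-zero -> rank deficiency, column named
  expect_error(assemblePPIDesign(rep(2, n), psych),
               "rank deficient.*(interaction|physio)")

  # hand-computed products on a 4-volume toy
  s4 <- c(1, 2, 3, 6); p4 <- c(1, -1, 1, -1)
  d4 <- assemblePPIDesign(s4, p4)
  expect_equal(unname(d4@values[, "interaction"]),
               (s4 - 3) * (p4 - 0), tolerance = 1e-12)

  # per-run centering and per-run intercepts
  runIdx <- rep(1:2, each = 4)
  s8 <- c(1, 3, 5, 8, 10, 20, 30, 44)
  p8 <- rep(c(1, -1), 4)
  d2 <- assemblePPIDesign(s8, p8, runIndex = runIdx)
  expect_equal(unname(d2@values[, "interaction"]),
               c(s8[1:4] - mean(s8[1:4]), s8[5:8] - mean(s8[5:8])) * p8)
  expect_true(all(c("intercept_run1", "intercept_run2") %in%
                  colnames(d2@values)))
  expect_error(assemblePPIDesign(1:4, 1:3), "equal length")
})

test_that("voxelwise t-maps match a normal-equations oracle", {
  set.seed(8)
  n <- 8
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), intercept = 1)
  des <- designMatrix(X)
  y <- c(2.1, -0.3, 1.7, 0.4, -1.2, 0.8, 0.05, -0.6)
  arr <- array(0, c(1, 1, 1, n)); arr[1, 1, 1, ] <- y
  run <- make_run(arr)
  cvec <- c(1, 0, 0)
  pm <- fitGLMTmap(run, des, contrast = cvec)
  expect_equal(volData(tValues(pm))[1, 1, 1], glm_t_oracle(y, X, cvec),
               tolerance = 1e-10)
  expect_equal(dof(pm), n - 3)

  # GLM equivariance: scaling y leaves t unchanged
  arr2 <- arr * 13.7
  pm2 <- fitGLMTmap(make_run(arr2), des, contrast = cvec)
  expect_equal(volData(tValues(pm2)), volData(tValues(pm)), tolerance = 1e-10)
})

test_that("zero-residual voxels are flagged, not fatal", {
  n <- 10
  X <- cbind(x1 = sin(1:n), x2 = cos(1:n), intercept = 1)
  des <- designMatrix(X)
  beta <- c(0, 2, 1)   # contrast picks the zero component
  y <- drop(X %*% beta)
  arr <- array(0, c(2, 1, 1, n))
  arr[1, 1, 1, ] <- y
  arr[2, 1, 1, ] <- rnorm(n)
  pm <- fitGLMTmap(make_run(arr), des, contrast = c(1, 0, 0))
  expect_true(pm@flagged[1, 1, 1])
  expect_false(pm@flagged[2, 1, 1])
  expect_true(is.finite(volData(tValues(pm))[2, 1, 1]))
})

test_that("pure-noise t-maps are calibrated to the t distribution", {
  set.seed(12)
  n <- 100
  nVox <- 1000
  psych <- rep(c(1, -1), n / 2) + rnorm(n, sd = 0.1)
  seed <- rnorm(n)
  des <- assemblePPIDesign(seed, psych)
  arr <- array(rnorm(nVox * n), c(10, 10, 10, n))
  pm <- fitGLMTmap(make_run(arr), des, contrast = "interaction")
  tv <- volData(tValues(pm))
  frac <- mean(abs(tv) > qt(0.975, dof(pm)))
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nVox))
})

test_that("gray-matter masking keeps strictly supra-threshold voxels and back-projects exactly", {
  set.seed(14)
  dims <- c(6, 5, 4)
  vol <- volumeGrid(array(rnorm(prod(dims)), dims))
  gmAll <- array(1, dims)
  f <- maskToFeatures(vol, gmAll)
  expect_length(f$features, prod(dims))

  # boundary semantics: values exactly at the threshold are excluded
  gmEdge <- array(0.25, dims)
  expect_error(maskToFeatures(vol, gmEdge), "> 0.25")
  gmEdge[2, 2, 2] <- 0.2500001
  f1 <- maskToFeatures(vol, gmEdge)
  expect_length(f1$features, 1)

  # round trip: back-projection restores the in-mask volume exactly
  gm <- array(runif(prod(dims)), dims)
  fx <- maskToFeatures(vol, gm, 0.25)
  back <- featuresToVolume(fx$features, fx$index, fx$dim)
  expect_identical(back[fx$index], volData(vol)[fx$index])
  expect_true(all(back[-fx$index] == 0))
  expect_error(featuresToVolume(fx$features, fx$index, c(2, 2, 2)),
               "do not match")
})

test_that("implanted interaction effects are recovered at high SNR", {
  cfg <- simConfig(gridShape = c(10, 10, 8), nVolumes = 120L, nRuns = 1L,
                   nPatients = 3L, nControls = 3L, noiseSd = 0.05,
                   seedNoiseSd = 0.3, signalFraction = 0.02,
                   betaPpiControl = 0.6, betaPpiPatient = 0, rngSeed = 17L)
  grid <- makeDefaultGrid(cfg)
  mask <- array(TRUE, c(10, 10, 8))
  set.seed(17)
  ev <- list(makeEventSchedule(cfg))
  co <- generateTimeseriesCohort(cfg, mask, events = ev, grid = grid)
  gm <- array(1, c(10, 10, 8))
  fm <- cohortPPIFeatures(co, ev, gm, contrast = "interaction")
  # a control subject's top-|t| voxels coincide with the implanted voxels
  truthIdx <- which(truthMask(co))
  ctl <- which(cohortLabels(co) == "control")[1]
  tv <- abs(fm$X[ctl, ])
  tv[!is.finite(tv)] <- 0
  top <- fm$index[order(-tv)[seq_along(truthIdx)]]
  expect_gt(jaccard(top, truthIdx), 0.8)
})

test_that("the physio control contrast carries no group difference", {
  # groups differ only in the interaction coefficient; seed-coupling maps
  # should show no systematic separation
  nRep <- 6
  hits <- 0
  for (rep_i in seq_len(nRep)) {
    cfg <- simConfig(gridShape = c(8, 8, 6), nVolumes = 100L, nRuns = 1L,
                     nPatients = 5L, nControls = 5L, noiseSd = 0.6,
                     signalFraction = 0.02, rngSeed = 100L + rep_i)
    grid <- makeDefaultGrid(cfg)
    mask <- array(TRUE, c(8, 8, 6))
    withr::with_seed(100 + rep_i, ev <- list(makeEventSchedule(cfg)))
    co <- generateTimeseriesCohort(cfg, mask, events = ev, grid = grid)
    gm <- array(1, c(8, 8, 6))
    fm <- cohortPPIFeatures(co, ev, gm, contrast = "physio")
    truthCols <- match(which(truthMask(co)), fm$index)
    pat <- fm$y == "patient"
    pvals <- vapply(truthCols, function(j)
      t.test(fm$X[pat, j], fm$X[!pat, j])$p.value, numeric(1))
    # no truth voxel significant at the Bonferroni-corrected level
    hits <- hits + (min(pvals) > 0.05 / length(truthCols))
  }
  expect_gte(hits, nRep - 1)
})
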