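test_that("MLDA reproduces the hand-worked two-feature case", {
  # patients at x=0, controls at x=2; only feature 2 varies within class
  X <- rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1))
  y <- factor(c("patient", "patient", "control", "control"),
              levels = c("control", "patient"))
  m <- fitMLDA(X, y)
  # Sp = diag(0, 0.5); lambdaBar = 0.25; regularized spectrum diag(0.25, 0.5)
  expect_equal(m@lambdaBar, 0.25)
  expect_equal(m@eigvalsRaw, 0.5)
  expect_equal(m@eigvalsReg, 0.5)
  # w = S*^-1 (mu_pat - mu_ctl) = diag(4, 2) %*% (-2, 0) = (-8, 0)
  expect_equal(discriminantWeights(m), c(-8, 0), tolerance = 1e-12)
  # decision boundary at x = 1: b = 8
  expect_equal(bias(m), 8, tolerance = 1e-12)
  expect_equal(decisionValue(m, c(1, 0.5)), 0, tolerance = 1e-12)
  expect_gt(decisionValue(m, c(0.2, 0.3)), 0)   # patient side
  expect_lt(decisionValue(m, c(1.8, 0.7)), 0)   # control side
})

test_that("with an isotropic within-class covariance w is proportional to the mean difference", {
  base <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))  # isotropic sample cov
  shift <- c(3, 1)
  X <- rbind(base, sweep(base, 2, shift, `+`))
  y <- factor(rep(c("control", "patient"), each = 4),
              levels = c("control", "patient"))
  m <- fitMLDA(X, y)
  w <- discriminantWeights(m)
  expect_equal(w / sqrt(sum(w^2)), shift / sqrt(sum(shift^2)),
               tolerance = 1e-10)
})

test_that("subspace MLDA matches the dense-matrix definition on random instances", {
  set.seed(101)
  for (i in 1:30) {
    inst <- random_instance()
    for (meth in c("trace_p", "nonzero")) {
      m <- fitMLDA(inst$X, inst$y, meth)
      o <- dense_mlda(inst$X, inst$y, meth)
      expect_equal(m@lambdaBar, o$lambdaBar, tolerance = 1e-8)
      expect_equal(discriminantWeights(m), o$w, tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_equal(bias(m), o$b, tolerance = 1e-8)
      expect_equal(decisionValue(m, inst$X), o$z, tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  }
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(fitMLDA(X, rep("patient", 5)), "both classes")
  expect_error(fitMLDA(matrix(1, 4, 3),
                       c("patient", "patient", "control", "control")),
               "zero total within-class variance")
  expect_error(fitMLDA(X[1:2, ], c("patient", "control")), "at least 3")
})

test_that("feature selection keeps the top fraction by |w| with index tie-breaks", {
  set.seed(102)
  n <- 60
  X <- matrix(rnorm(n * 200), n, 200)
  y <- factor(rep(c("control", "patient"), each = n / 2),
              levels = c("control", "patient"))
  # fraction 1 returns all features in rank order
  selAll <- selectFeatures(X, y, fraction = 1)
  expect_setequal(selAll, 1:200)
  w <- abs(discriminantWeights(fitMLDA(X, y)))
  expect_identical(selAll, order(-w, 1:200))
  # ceil arithmetic: 1% of 200 features -> exactly 2
  expect_length(selectFeatures(X, y, fraction = 0.01), 2)
  expect_length(selectFeatures(X, y, fraction = 0.011), 3)

  # a single informative feature is ranked first under both criteria
  X2 <- matrix(rnorm(n * 50), n, 50)
  X2[y == "patient", 17] <- X2[y == "patient", 17] + 4
  expect_identical(selectFeatures(X2, y, 1 / 50, ranking = "weight"), 17L)
  expect_identical(selectFeatures(X2, y, 1 / 50, ranking = "t"), 17L)

  # exact ties broken by ascending feature index
  X3 <- cbind(X2, X2[, 17])
  sel3 <- selectFeatures(X3, y, 2 / 51, ranking = "t")
  expect_identical(sel3[1], 17L)
})

test_that("selection + MLDA composition behaves as the pieces", {
  set.seed(103)
  inst <- random_instance()
  mFull <- fitMLDA(inst$X, inst$y)
  mPipe <- fitMLDAPipeline(inst$X, inst$y, fraction = 1)
  # fraction 1: identical decision values (features merely reordered)
  expect_equal(decisionValue(mPipe, inst$X[, selectedFeatures(mPipe)]),
               decisionValue(mFull, inst$X), tolerance = 1e-10)

  # separable toy data: training accuracy 1
  Xs <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 6), 10, 2))
  ys <- factor(rep(c("control", "patient"), each = 10),
               levels = c("control", "patient"))
  ms <- fitMLDAPipeline(Xs, ys, fraction = 0.5)
  pred <- decisionValue(ms, Xs[, selectedFeatures(ms)]) > 0
  expect_identical(pred, ys == "patient", ignore_attr = TRUE)

  # refit determinism
  ms2 <- fitMLDAPipeline(Xs, ys, fraction = 0.5)
  expect_identical(discriminantWeights(ms), discriminantWeights(ms2))
})

test_that("LOOCV classifies separable classes perfectly and handles the minimal cohort", {
  set.seed(104)
  X <- rbind(matrix(rnorm(100), 10, 10),
             matrix(rnorm(100, mean = 5), 10, 10))
  y <- rep(c("control", "patient"), each = 10)
  cv <- loocvMLDA(X, y, fraction = 1)
  expect_equal(mean(predictions(cv) == trueLabels(cv)), 1)

  X4 <- rbind(c(0, 0), c(0.5, 0), c(5, 5), c(5.5, 5))
  cv4 <- loocvMLDA(X4, c("control", "control", "patient", "patient"),
                   fraction = 1)
  expect_length(decisionValues(cv4), 4)
  expect_error(loocvMLDA(X4[1:3, ], c("control", "control", "patient")),
               "at least")
})

test_that("label swap negates decision values; feature scaling leaves predictions unchanged", {
  set.seed(105)
  X <- matrix(rnorm(18 * 40), 18, 40)
  y <- rep(c("control", "patient"), c(8, 10))
  X[y == "patient", 1:4] <- X[y == "patient", 1:4] + 1
  cv <- loocvMLDA(X, y, fraction = 0.1)
  ySwap <- ifelse(y == "patient", "control", "patient")
  cvSwap <- loocvMLDA(X, ySwap, fraction = 0.1)
  expect_equal(decisionValues(cvSwap), -decisionValues(cv), tolerance = 1e-10)

  cvScaled <- loocvMLDA(X * 7.3, y, fraction = 0.1)
  expect_identical(predictions(cvScaled), predictions(cv))
  expect_equal(decisionValues(cvScaled), decisionValues(cv), tolerance = 1e-8)
})

test_that("weight maps back-project exactly and honor the selection", {
  set.seed(106)
  dims <- c(6, 5, 4)
  gm <- array(runif(prod(dims)), dims)
  vol <- volumeGrid(array(rnorm(prod(dims)), dims))
  fx <- maskToFeatures(vol, gm, 0.25)
  p <- length(fx$features)
  n <- 14
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("control", "patient"), each = n / 2)
  m <- fitMLDAPipeline(X, y, fraction = 0.1)
  wmap <- exportWeightMap(m, fx$index, fx$dim)
  # re-masking recovers w exactly, unselected voxels are zero
  full <- numeric(p); full[selectedFeatures(m)] <- discriminantWeights(m)
  expect_identical(wmap[fx$index], full)
  expect_equal(sum(wmap != 0), sum(discriminantWeights(m) != 0))
  expect_error(exportWeightMap(m, fx$index[-1], fx$dim), "does not match")

  # single nonzero weight lands at the mapped voxel
  m1 <- m; m1@w <- c(3, rep(0, length(m@w) - 1))
  wm1 <- exportWeightMap(m1, fx$index, fx$dim)
  expect_equal(which(wm1 != 0), fx$index[selectedFeatures(m)[1]])

  # NIfTI export writes the same volume
  tf <- tempfile(fileext = ".nii.gz")
  aff <- diag(c(2, 2, 2, 1))
  exportWeightMap(m, fx$index, fx$dim, affine = aff, path = tf)
  expect_equal(volData(readVolume(tf)), wmap)
  unlink(tf)
})

test_that("LOOCV accuracy increases with the implanted effect size", {
  accs <- vapply(c(0, 1, 2.5), function(d) {
    meds <- vapply(1:5, function(s) {
      cfg <- simConfig(gridShape = c(10, 10, 8), nPatients = 10L,
                       nControls = 10L, effectSizeD = d,
                       signalFraction = 0.02, rngSeed = 200L + s)
      grid <- makeDefaultGrid(cfg)
      mask <- volData(makeGrayMatterMap(grid, 77L)) > 0.25
      co <- generatePPIMaps(cfg, mask, grid)
      fm <- cohortFeatureMatrix(co)
      cv <- loocvMLDA(fm$X, fm$y, fraction = 0.02)
      mean(predictions(cv) == trueLabels(cv))
    }, numeric(1))
    median(meds)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], accs[1])
})
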