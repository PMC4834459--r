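#' Construct a SimConfig
#'
#' Defaults follow the emulated study: TR 2 s, 400 volumes per run, 3 runs,
#' 2.29 x 2.29 x 3 mm voxels, 25 patients and 21 controls, 6 mm FWHM
#' smoothing, and a sparse group effect at 1% of in-mask voxels. The grid
#' defaults to a reduced 20 x 24 x 20 patch so that cohorts are desk-scale;
#' full-size grids are supported by setting \code{gridShape}.
#'
#' @param gridShape integer(3) voxel counts.
#' @param voxelSizeMm numeric(3) voxel size in mm.
#' @param trS repetition time (s).
#' @param nVolumes volumes per run.
#' @param nRuns runs per subject.
#' @param nPatients,nControls group sizes.
#' @param effectSizeD standardized mean difference implanted at signal voxels
#'   of the map cohort (patients minus controls, after per-voxel
#'   standardization of the smoothed noise).
#' @param signalFraction fraction of in-mask voxels carrying the effect.
#' @param nClusters number of contiguous clusters the signal voxels form.
#' @param smoothFwhmMm smoothing kernel FWHM (mm).
#' @param noiseAr1 lag-1 autocorrelation of time-series noise.
#' @param noiseSd marginal sd of voxel time-series noise.
#' @param seedNoiseSd sd of noise on the seed time series.
#' @param betaPsych,betaPhysio task and seed-coupling coefficients of the
#'   time-series model.
#' @param betaPpiControl,betaPpiPatient interaction coefficients at signal
#'   voxels (patients reduced relative to controls).
#' @param rngSeed integer seed.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(gridShape = c(20L, 24L, 20L),
                      voxelSizeMm = c(2.29, 2.29, 3),
                      trS = 2, nVolumes = 400L, nRuns = 3L,
                      nPatients = 25L, nControls = 21L,
                      effectSizeD = 1.2, signalFraction = 0.01,
                      nClusters = 4L, smoothFwhmMm = 6,
                      noiseAr1 = 0.3, noiseSd = 1, seedNoiseSd = 0.5,
                      betaPsych = 0.3, betaPhysio = 0.7,
                      betaPpiControl = 0.5, betaPpiPatient = 0,
                      rngSeed = 1L) {
  new("SimConfig",
      gridShape = as.integer(gridShape), voxelSizeMm = as.numeric(voxelSizeMm),
      trS = trS, nVolumes = as.integer(nVolumes), nRuns = as.integer(nRuns),
      nPatients = as.integer(nPatients), nControls = as.integer(nControls),
      effectSizeD = effectSizeD, signalFraction = signalFraction,
      nClusters = as.integer(nClusters), smoothFwhmMm = smoothFwhmMm,
      noiseAr1 = noiseAr1, noiseSd = noiseSd, seedNoiseSd = seedNoiseSd,
      betaPsych = betaPsych, betaPhysio = betaPhysio,
      betaPpiControl = betaPpiControl, betaPpiPatient = betaPpiPatient,
      rngSeed = as.integer(rngSeed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %s grid (%s mm), TR %.3g s, %d volumes x %d runs\n",
    paste(object@gridShape, collapse = "x"),
    paste(object@voxelSizeMm, collapse = "x"),
    object@trS, object@nVolumes, object@nRuns))
  cat(sprintf("  cohort: %d patients / %d controls; effect d = %.3g at %.3g%% of mask (%d clusters)\n",
              object@nPatients, object@nControls, object@effectSizeD,
              100 * object@signalFraction, object@nClusters))
  cat(sprintf("  smoothing FWHM %.3g mm; AR(1) rho = %.3g; seed %d\n",
              object@smoothFwhmMm, object@noiseAr1, object@rngSeed))
})

#' Default VolumeGrid for a SimConfig
#'
#' The grid is centered on the world origin so small test patches have a
#' well-defined geometry; supply \code{centerMm} to position the patch
#' elsewhere (e.g. around an anterior temporal seed coordinate).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param centerMm world coordinate of the grid center.
#' @return an empty (zero-filled) \linkS4class{VolumeGrid}.
#' @export
makeDefaultGrid <- function(config, centerMm = c(0, 0, 0)) {
  volumeGrid(array(0, config@gridShape), voxelSizeMm = config@voxelSizeMm,
             centerMm = centerMm)
}

#' Synthetic gray-matter probability map
#'
#' A smooth random field rescaled to [0, 1], biased so that well over a
#' quarter of voxels exceed the conventional 0.25 tissue-probability
#' threshold. Deterministic for a fixed seed.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param rngSeed integer seed.
#' @return a \linkS4class{VolumeGrid} of probabilities in [0, 1].
#' @export
makeGrayMatterMap <- function(grid, rngSeed = 1L) {
  d3 <- dim(grid@data)[1:3]
  vs <- voxelSizeMm(grid)
  withr_seed(rngSeed, {
    f <- array(stats::rnorm(prod(d3)), d3)
  })
  f <- gaussianSmooth(f, fwhmMm = 4 * vs, voxelSize = vs)
  # probability-integral transform of the standardized smooth field gives an
  # approximately uniform marginal, so ~75% of voxels exceed 0.25
  f <- stats::pnorm((f - mean(f)) / stats::sd(f))
  out <- grid
  out@data <- f
  out
}

# run expr with a local RNG state seeded at seed
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# sample nTruth in-mask voxels as nClusters contiguous-ish clusters:
# distance-to-nearest-center growth over in-mask voxel coordinates
sample_truth_mask <- function(mask, nTruth, nClusters, voxelSize) {
  idx <- which(mask)
  d3 <- dim(mask)
  coord <- arrayInd(idx, d3)
  coord <- sweep(coord, 2, voxelSize, `*`)
  centers <- coord[sample.int(nrow(coord), min(nClusters, nrow(coord))), ,
                   drop = FALSE]
  dmin <- rep(Inf, nrow(coord))
  for (c_i in seq_len(nrow(centers)))
    dmin <- pmin(dmin, rowSums(sweep(coord, 2, centers[c_i, ])^2))
  keep <- order(dmin, idx)[seq_len(nTruth)]
  tm <- array(FALSE, d3)
  tm[idx[keep]] <- TRUE
  tm
}

#' Generate a cohort of PPI-like 3D maps with an implanted group effect
#'
#' Each subject's map is smoothed Gaussian noise standardized to unit
#' variance per voxel (exactly, via the kernel's variance map); patients
#' additionally receive a mean shift of \code{effectSizeD} at a sparse set
#' of truth voxels, so the realized voxelwise standardized difference
#' matches \code{effectSizeD} up to sampling error.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param mask logical 3D array of in-analysis voxels (non-empty).
#' @param grid optional \linkS4class{VolumeGrid} (defaults to
#'   \code{makeDefaultGrid(config)}).
#' @return a \linkS4class{SyntheticCohort} of 3D maps.
#' @export
generatePPIMaps <- function(config, mask, grid = makeDefaultGrid(config)) {
  d3 <- config@gridShape
  stopifnot(all(dim(mask) == d3))
  nMask <- sum(mask)
  if (nMask == 0L) stop("mask is empty")
  if (config@signalFraction * nMask < 1)
    stop(sprintf("signalFraction x |mask| = %.3g < 1: no voxel would carry the effect",
                 config@signalFraction * nMask))
  nTruth <- ceiling(config@signalFraction * nMask)
  vs <- config@voxelSizeMm
  sdMap <- smooth_sd_map(d3, config@smoothFwhmMm, vs)
  n <- config@nPatients + config@nControls
  labels <- factor(rep(c("patient", "control"),
                       c(config@nPatients, config@nControls)),
                   levels = c("control", "patient"))
  maps <- vector("list", n)
  withr_seed(config@rngSeed, {
    tm <- sample_truth_mask(mask, nTruth, config@nClusters, vs)
    for (s in seq_len(n)) {
      f <- array(stats::rnorm(prod(d3)), d3)
      f <- gaussianSmooth(f, config@smoothFwhmMm, vs) / sdMap
      if (labels[s] == "patient") f[tm] <- f[tm] + config@effectSizeD
      maps[[s]] <- volumeGrid(f, affine = grid@affine)
    }
  })
  new("SyntheticCohort", maps = maps, labels = labels, truthMask = tm,
      mask = mask, seedRoi = array(FALSE, c(1L, 1L, 1L)), config = config)
}

#' Default randomized event schedule for one run
#'
#' Thirty trials of each condition (guilt, indignation, baseline) in random
#' order, 5 s events with a jittered inter-trial interval, spanning the run.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param nPerCondition trials per condition; NULL fits as many as the run
#'   length allows, up to 30.
#' @param durationS event duration (s), at most 5 in the emulated paradigm.
#' @return an \linkS4class{EventSchedule}. Uses the current RNG state.
#' @export
makeEventSchedule <- function(config, nPerCondition = NULL, durationS = 5) {
  runLen <- config@nVolumes * config@trS
  if (is.null(nPerCondition))
    nPerCondition <- max(1L, min(30L, floor((runLen - 22) / (3 * (durationS + 1)))))
  conds <- sample(rep(c("guilt", "indignation", "baseline"), nPerCondition))
  nTrial <- length(conds)
  # fit trials into the run with jittered ITI; leave room for the HRF tail
  usable <- runLen - 20
  slot <- usable / nTrial
  iti <- pmax(0.5, slot - durationS)
  onsets <- cumsum(c(2, rep(durationS, nTrial - 1) +
                       stats::runif(nTrial - 1, 0.5 * iti, 1.5 * iti)))
  # keep the HRF tail inside the run whatever the jitter drew
  lastAllowed <- runLen - 16 - durationS
  if (max(onsets) > lastAllowed && nTrial > 1)
    onsets <- 2 + (onsets - 2) * (lastAllowed - 2) / (max(onsets) - 2)
  new("EventSchedule", onsetsS = onsets,
      durationsS = rep(durationS, nTrial), conditions = conds)
}

setMethod("show", "EventSchedule", function(object) {
  tab <- table(object@conditions)
  cat(sprintf("EventSchedule: %d trials (%s), %.4g-%.4g s\n",
              length(object@onsetsS),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              min(object@onsetsS), max(object@onsetsS)))
})

#' Generate a cohort of event-related 4D BOLD runs with an implanted
#' psychophysiological interaction
#'
#' The seed signal is HRF-convolved task drive plus noise. Every voxel
#' follows \code{y = b1 p + b2 s + b3 (s_c * p_c) + AR(1) noise}, where p is
#' the guilt-minus-indignation psychological regressor, s the seed series and
#' the interaction is the product of the mean-centered pair. At truth voxels
#' the interaction coefficient b3 is reduced in patients relative to controls
#' (a guilt-context-selective disconnection); at all other voxels
#' coefficients are identical across groups (b3 = 0).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param mask logical 3D array (non-empty).
#' @param events list of \linkS4class{EventSchedule}s, one per run; NULL
#'   generates default schedules.
#' @param grid optional \linkS4class{VolumeGrid}.
#' @param seedRoi logical 3D array marking seed voxels; NULL takes a sphere
#'   (radius one voxel-diagonal) at the grid center.
#' @param hrf an \linkS4class{HRFSpec}.
#' @return a \linkS4class{SyntheticCohort} whose \code{maps} element per
#'   subject is a list of 4D \linkS4class{VolumeGrid} runs; \code{seedRoi}
#'   records the seed voxels.
#' @export
generateTimeseriesCohort <- function(config, mask, events = NULL,
                                     grid = makeDefaultGrid(config),
                                     seedRoi = NULL, hrf = hrfSpec()) {
  d3 <- config@gridShape
  stopifnot(all(dim(mask) == d3))
  if (sum(mask) == 0L) stop("mask is empty")
  if (config@signalFraction * sum(mask) < 1)
    stop("signalFraction x |mask| < 1: no voxel would carry the effect")
  if (is.null(seedRoi)) {
    ctr <- voxelToWorld(grid, (d3 - 1) / 2)
    seedRoi <- makeSphereROI(drop(ctr), sqrt(sum(config@voxelSizeMm^2)), grid)
  }
  nVol <- config@nVolumes
  nTruth <- ceiling(config@signalFraction * sum(mask))
  n <- config@nPatients + config@nControls
  labels <- factor(rep(c("patient", "control"),
                       c(config@nPatients, config@nControls)),
                   levels = c("control", "patient"))
  nVox <- prod(d3)
  maskIdx <- which(mask)
  maps <- vector("list", n)
  withr_seed(config@rngSeed, {
    tm <- sample_truth_mask(mask, nTruth, config@nClusters, config@voxelSizeMm)
    truthIdx <- which(tm)
    if (is.null(events))
      events <- replicate(config@nRuns, makeEventSchedule(config),
                          simplify = FALSE)
    if (length(events) != config@nRuns)
      stop(sprintf("need %d event schedules, got %d",
                   config@nRuns, length(events)))
    for (ev in events)
      if (max(ev@onsetsS + ev@durationsS) > nVol * config@trS)
        stop("events extend past the run length implied by nVolumes")
    # condition regressors per run (noise-free building blocks)
    psych <- lapply(events, buildPsychRegressor, hrf = hrf,
                    nVolumes = nVol, trS = config@trS)
    drive <- lapply(events, buildPsychRegressor, hrf = hrf,
                    nVolumes = nVol, trS = config@trS,
                    weights = c(guilt = 1, indignation = 1, baseline = 0))
    for (s in seq_len(n)) {
      b3 <- numeric(nVox)
      b3[truthIdx] <- if (labels[s] == "patient") config@betaPpiPatient
                      else config@betaPpiControl
      runs <- vector("list", config@nRuns)
      for (r in seq_len(config@nRuns)) {
        seedTs <- drive[[r]] + ar1_noise(nVol, config@noiseAr1,
                                         config@seedNoiseSd)
        sc <- seedTs - mean(seedTs)
        pc <- psych[[r]] - mean(psych[[r]])
        inter <- sc * pc
        base <- config@betaPsych * psych[[r]] + config@betaPhysio * seedTs
        y <- matrix(base, nrow = nVol, ncol = nVox) +
          outer(inter, b3) +
          ar1_noise_matrix(nVol, nVox, config@noiseAr1, config@noiseSd)
        # seed voxels carry the seed series (plus tiny independent noise)
        y[, seedRoi] <- seedTs +
          matrix(stats::rnorm(nVol * sum(seedRoi), sd = 0.01 * max(config@noiseSd, 1e-8)),
                 nVol, sum(seedRoi))
        arr <- array(t(y), dim = c(d3, nVol))
        runs[[r]] <- volumeGrid(arr, affine = grid@affine)
      }
      maps[[s]] <- runs
    }
  })
  out <- new("SyntheticCohort", maps = maps, labels = labels, truthMask = tm,
             mask = mask, seedRoi = seedRoi, config = config)
  # the schedules actually used (possibly generated here) travel with the
  # cohort so first-level fitting can rebuild the same regressors
  attr(out, "events") <- events
  out
}

# AR(1) series with marginal sd `sd` (stationary start)
ar1_noise <- function(n, rho, sd) {
  if (sd == 0) return(numeric(n))
  e <- stats::rnorm(n)
  if (rho == 0) return(sd * e)
  x <- as.numeric(stats::filter(e * sqrt(1 - rho^2), rho,
                                method = "recursive",
                                init = stats::rnorm(1)))
  sd * x
}

ar1_noise_matrix <- function(n, p, rho, sd) {
  if (sd == 0) return(matrix(0, n, p))
  e <- matrix(stats::rnorm(n * p), n, p)
  if (rho == 0) return(sd * e)
  x <- stats::filter(e * sqrt(1 - rho^2), rho, method = "recursive",
                     init = matrix(stats::rnorm(p), 1))
  sd * matrix(as.numeric(x), n, p)
}

#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortLabels", "SyntheticCohort", function(x) x@labels)

#' @rdname SyntheticCohort-class
#' @export
setMethod("truthMask", "SyntheticCohort", function(x) x@truthMask)

#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortMask", "SyntheticCohort", function(x) x@mask)

setMethod("show", "SyntheticCohort", function(object) {
  kind <- if (is(object@maps[[1]], "VolumeGrid")) "3D maps" else "4D time series"
  cat(sprintf("SyntheticCohort: %d subjects (%d patients / %d controls), %s\n",
              length(object@maps), sum(object@labels == "patient"),
              sum(object@labels == "control"), kind))
  cat(sprintf("  mask %d voxels, truth %d voxels\n",
              sum(object@mask), sum(object@truthMask)))
})

#' Extract the in-mask feature matrix of a 3D map cohort
#'
#' @param cohort a \linkS4class{SyntheticCohort} of 3D maps.
#' @return list with \code{X} (subjects x in-mask voxels, ascending linear
#'   voxel index order), \code{y} (labels) and \code{index} (linear voxel
#'   indices of the columns).
#' @export
cohortFeatureMatrix <- function(cohort) {
  stopifnot(is(cohort@maps[[1]], "VolumeGrid"))
  idx <- which(cohort@mask)
  X <- t(vapply(cohort@maps, function(m) m@data[idx], numeric(length(idx))))
  list(X = X, y = cohort@labels, index = idx)
}
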