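#' Mean time series of a seed region
#'
#' @param run 4D \linkS4class{VolumeGrid} (x, y, z, time).
#' @param roi logical 3D array on the same grid.
#' @return numeric vector, per-volume mean across roi voxels (no detrending;
#'   confounds belong in the design matrix).
#' @export
extractSeedTimeseries <- function(run, roi) {
  stopifnot(is(run, "VolumeGrid"))
  d <- dim(run@data)
  if (length(d) != 4L) stop("run must be a 4D VolumeGrid")
  if (!all(dim(roi) == d[1:3])) stop("roi grid does not match the run")
  idx <- which(roi)
  if (length(idx) == 0L) stop("seed roi is empty")
  m <- matrix(run@data, nrow = prod(d[1:3]), ncol = d[4])
  colMeans(m[idx, , drop = FALSE])
}

#' Assemble a PPI design matrix
#'
#' Columns: per-run intercepts, the psychological regressor, the seed
#' (physiological) regressor and their interaction, formed as the elementwise
#' product of the mean-centered pair (centering per run). Optional confounds
#' are appended. Rank deficiency raises an error naming the collinear
#' columns.
#'
#' @param seedTs seed time series (runs concatenated).
#' @param psych psychological regressor (same length).
#' @param confounds optional numeric matrix of extra regressors.
#' @param runIndex integer vector assigning rows to runs (default: one run).
#' @return a \linkS4class{DesignMatrix} with named columns
#'   \code{psych}, \code{physio}, \code{interaction}, one intercept per run,
#'   then confounds.
#' @export
assemblePPIDesign <- function(seedTs, psych, confounds = NULL,
                              runIndex = rep(1L, length(seedTs))) {
  n <- length(seedTs)
  if (length(psych) != n || length(runIndex) != n)
    stop("seedTs, psych and runIndex must have equal length")
  runs <- sort(unique(runIndex))
  sc <- pc <- numeric(n)
  for (r in runs) {
    i <- runIndex == r
    sc[i] <- seedTs[i] - mean(seedTs[i])
    pc[i] <- psych[i] - mean(psych[i])
  }
  X <- cbind(psych = psych, physio = seedTs, interaction = sc * pc)
  for (r in runs) {
    ic <- as.numeric(runIndex == r)
    X <- cbind(X, ic)
    colnames(X)[ncol(X)] <- paste0("intercept_run", r)
  }
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n) stop("confounds must have one row per volume")
    if (is.null(colnames(confounds)))
      colnames(confounds) <- paste0("confound", seq_len(ncol(confounds)))
    X <- cbind(X, confounds)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(paste("design matrix is rank deficient; collinear column(s):",
               paste(dropped, collapse = ", ")))
  }
  new("DesignMatrix", values = X, runIndex = as.integer(runIndex))
}

#' Construct a DesignMatrix from an explicit regressor matrix
#'
#' For custom first-level models; \code{\link{assemblePPIDesign}} builds the
#' standard PPI design. Rank deficiency raises an error.
#'
#' @param values numeric matrix with named columns.
#' @param runIndex integer vector assigning rows to runs.
#' @return a \linkS4class{DesignMatrix}.
#' @export
designMatrix <- function(values, runIndex = rep(1L, nrow(values))) {
  if (is.null(colnames(values)))
    colnames(values) <- paste0("x", seq_len(ncol(values)))
  qrX <- qr(values)
  if (qrX$rank < ncol(values)) {
    dropped <- colnames(values)[qrX$pivot[(qrX$rank + 1):ncol(values)]]
    stop(paste("design matrix is rank deficient; collinear column(s):",
               paste(dropped, collapse = ", ")))
  }
  new("DesignMatrix", values = values, runIndex = as.integer(runIndex))
}

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d volumes x %d regressors (%s), %d run(s)\n",
              nrow(object@values), ncol(object@values),
              paste(colnames(object@values), collapse = ", "),
              length(unique(object@runIndex))))
})

#' Voxelwise GLM contrast t-map
#'
#' Ordinary least squares per voxel: \code{t = c'beta / sqrt(s2 c'(X'X)^-1 c)}
#' with \code{s2 = RSS / dof} and \code{dof = n - rank(X)}. Voxels with zero
#' residual variance get a signed-infinite t and are flagged rather than
#' raising an error.
#'
#' @param run 4D \linkS4class{VolumeGrid}, or a list of runs (concatenated
#'   along time to match the design).
#' @param design a \linkS4class{DesignMatrix}.
#' @param contrast numeric weight vector, or the name of a design column.
#' @param contrastName label stored on the result (defaults to the column
#'   name when \code{contrast} is one).
#' @return a \linkS4class{PPIMap}.
#' @export
fitGLMTmap <- function(run, design, contrast = "interaction",
                       contrastName = NULL) {
  runs <- if (is(run, "VolumeGrid")) list(run) else run
  d3 <- dim(runs[[1]]@data)[1:3]
  Y <- do.call(rbind, lapply(runs, function(r) {
    d <- dim(r@data)
    t(matrix(r@data, nrow = prod(d[1:3]), ncol = d[4]))
  }))
  X <- design@values
  if (nrow(Y) != nrow(X))
    stop(sprintf("design has %d rows but data %d volumes", nrow(X), nrow(Y)))
  if (is.character(contrast)) {
    if (is.null(contrastName)) contrastName <- contrast
    cvec <- as.numeric(colnames(X) == contrast)
    if (sum(cvec) != 1L) stop(sprintf("no design column named '%s'", contrast))
  } else {
    cvec <- contrast
    if (length(cvec) != ncol(X))
      stop("contrast length must equal the number of regressors")
    if (is.null(contrastName)) contrastName <- "custom"
  }
  qrX <- qr(X)
  rk <- qrX$rank
  if (rk < ncol(X)) stop("design matrix is rank deficient")
  n <- nrow(X)
  if (n <= rk) stop("need more volumes than regressors")
  dof <- n - rk
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  rss <- colSums(res^2)
  cXXc <- drop(crossprod(cvec, chol2inv(qr.R(qrX))[order(qrX$pivot),
                                                   order(qrX$pivot)]) %*% cvec)
  cb <- drop(crossprod(cvec, beta))
  s2 <- rss / dof
  se <- sqrt(s2 * cXXc)
  # zero residual variance up to numerical precision: flag, signed infinity
  sy2 <- colSums(Y^2)
  flagged <- rss <= sy2 * 1e-12
  tv <- cb / se
  tv[flagged] <- sign(cb[flagged]) * Inf
  tv[flagged & abs(cb) <= sqrt(sy2) * 1e-8] <- 0
  tmap <- volumeGrid(array(tv, d3), affine = runs[[1]]@affine)
  new("PPIMap", tValues = tmap, dof = dof, contrastName = contrastName,
      flagged = array(flagged, d3))
}

#' @rdname PPIMap-class
#' @export
setMethod("tValues", "PPIMap", function(x) x@tValues)

#' @rdname PPIMap-class
#' @export
setMethod("dof", "PPIMap", function(x) x@dof)

setMethod("show", "PPIMap", function(object) {
  tv <- object@tValues@data
  cat(sprintf("PPIMap (%s contrast): %s voxels, dof = %g, %d flagged\n",
              object@contrastName,
              paste(dim(tv), collapse = " x "), object@dof,
              sum(object@flagged)))
  fin <- tv[is.finite(tv)]
  if (length(fin))
    cat(sprintf("  t range: [%.3g, %.3g]\n", min(fin), max(fin)))
})

#' Reduce a map to a masked feature vector
#'
#' Keeps voxels whose gray-matter value strictly exceeds the threshold, in
#' ascending linear voxel index order (x fastest), and returns the index
#' table allowing exact back-projection.
#'
#' @param map a \linkS4class{PPIMap} or \linkS4class{VolumeGrid}.
#' @param gmMap \linkS4class{VolumeGrid} (or array) of tissue probabilities.
#' @param threshold strict lower cutoff (default 0.25).
#' @return list with \code{features} (numeric vector), \code{index}
#'   (linear voxel indices of each feature) and \code{dim} (grid dims).
#' @export
maskToFeatures <- function(map, gmMap, threshold = 0.25) {
  vol <- if (is(map, "PPIMap")) map@tValues@data else
    if (is(map, "VolumeGrid")) map@data else map
  gm <- if (is(gmMap, "VolumeGrid")) gmMap@data else gmMap
  if (!all(dim(gm) == dim(vol)[1:3]))
    stop("gray-matter map grid does not match the map")
  idx <- which(gm > threshold)
  if (length(idx) == 0L)
    stop(sprintf("no voxels with gray-matter value > %g", threshold))
  list(features = vol[idx], index = idx, dim = dim(vol)[1:3])
}

#' Back-project a feature vector into a volume
#'
#' Inverse of \code{\link{maskToFeatures}}: out-of-mask voxels are zero.
#'
#' @param features numeric vector.
#' @param index linear voxel indices (from \code{maskToFeatures}).
#' @param dims grid dimensions.
#' @param affine optional affine for the returned \linkS4class{VolumeGrid};
#'   NULL returns a bare array.
#' @export
featuresToVolume <- function(features, index, dims, affine = NULL) {
  if (length(features) != length(index))
    stop("features and index must share length")
  if (max(index) > prod(dims))
    stop("index exceeds the grid size: index table and grid do not match")
  v <- array(0, dims)
  v[index] <- features
  if (is.null(affine)) v else new("VolumeGrid", data = v, affine = affine)
}

#' Feature matrix of a time-series cohort via PPI t-maps
#'
#' Runs the full first-level pipeline per subject: seed extraction, psych
#' regressor, PPI design (runs concatenated, per-run intercepts), voxelwise
#' t-map for the requested contrast, and gray-matter masking.
#'
#' @param cohort a time-series \linkS4class{SyntheticCohort}.
#' @param events list of \linkS4class{EventSchedule}s per run (the schedules
#'   used at generation time must be re-supplied when they were custom;
#'   defaults regenerate under the cohort's seed and match generation).
#' @param gmMap gray-matter \linkS4class{VolumeGrid} or array.
#' @param threshold gray-matter cutoff (strict).
#' @param contrast \code{"interaction"} or \code{"physio"}.
#' @param hrf an \linkS4class{HRFSpec}.
#' @return list with \code{X} (subjects x features), \code{y}, \code{index},
#'   \code{dim}, \code{tmaps} (list of \linkS4class{PPIMap}).
#' @export
cohortPPIFeatures <- function(cohort, events, gmMap, threshold = 0.25,
                              contrast = "interaction", hrf = hrfSpec()) {
  cfg <- cohort@config
  nVol <- cfg@nVolumes
  runIndex <- rep(seq_len(cfg@nRuns), each = nVol)
  psych <- unlist(lapply(events, buildPsychRegressor, hrf = hrf,
                         nVolumes = nVol, trS = cfg@trS))
  tmaps <- vector("list", length(cohort@maps))
  X <- NULL
  idx <- NULL
  for (s in seq_along(cohort@maps)) {
    runs <- cohort@maps[[s]]
    seedTs <- unlist(lapply(runs, extractSeedTimeseries, roi = cohort@seedRoi))
    design <- assemblePPIDesign(seedTs, psych, runIndex = runIndex)
    tm <- fitGLMTmap(runs, design, contrast = contrast)
    tmaps[[s]] <- tm
    f <- maskToFeatures(tm, gmMap, threshold)
    if (is.null(X)) {
      X <- matrix(0, length(cohort@maps), length(f$features))
      idx <- f$index
    }
    X[s, ] <- f$features
  }
  list(X = X, y = cohort@labels, index = idx, dim = cfg@gridShape,
       tmaps = tmaps)
}
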