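#' @import methods
NULL

#' VolumeGrid: a voxel array with a voxel-to-world affine
#'
#' The common substrate for maps, masks and 4D time series. The affine maps
#' 0-based voxel indices \code{(i, j, k, 1)} to world (e.g. MNI) millimetre
#' coordinates, following the NIfTI sform convention.
#'
#' @slot data 3D or 4D numeric/logical array; the fourth dimension, when
#'   present, indexes volumes (time).
#' @slot affine 4x4 numeric matrix mapping 0-based voxel indices to mm.
#' @export
setClass("VolumeGrid",
  representation(data = "array", affine = "matrix"),
  validity = function(object) {
    msgs <- character()
    nd <- length(dim(object@data))
    if (!nd %in% c(3L, 4L))
      msgs <- c(msgs, sprintf("data must be a 3D or 4D array, got %dD", nd))
    if (!all(dim(object@affine) == c(4L, 4L)))
      msgs <- c(msgs, "affine must be a 4x4 matrix")
    else {
      if (!all(is.finite(object@affine)))
        msgs <- c(msgs, "affine must be finite")
      else if (abs(det(object@affine[1:3, 1:3])) < .Machine$double.eps * 100)
        msgs <- c(msgs, "affine must be invertible")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' SimConfig: parameters of the synthetic cohort generator
#'
#' Holds the acquisition geometry (grid, voxel size, TR, volumes, runs), the
#' cohort composition and the parameters of the implanted group effect.
#'
#' @slot gridShape integer(3), voxel counts per axis.
#' @slot voxelSizeMm numeric(3), voxel edge lengths in mm.
#' @slot trS repetition time in seconds.
#' @slot nVolumes volumes per run.
#' @slot nRuns number of runs.
#' @slot nPatients,nControls subjects per group.
#' @slot effectSizeD standardized group difference implanted at signal voxels.
#' @slot signalFraction fraction of in-mask voxels carrying the group effect.
#' @slot nClusters number of contiguous clusters the signal voxels form.
#' @slot smoothFwhmMm Gaussian smoothing kernel FWHM in mm.
#' @slot noiseAr1 lag-1 autocorrelation of time-series noise.
#' @slot noiseSd marginal standard deviation of voxel time-series noise.
#' @slot seedNoiseSd standard deviation of noise added to the seed signal.
#' @slot betaPsych,betaPhysio task and seed coupling coefficients of the
#'   time-series generative model.
#' @slot betaPpiControl,betaPpiPatient interaction coefficient at signal
#'   voxels for controls and patients (patients reduced: the implanted
#'   context-selective disconnection).
#' @slot rngSeed integer seed driving all randomness.
#' @export
setClass("SimConfig",
  representation(
    gridShape = "integer", voxelSizeMm = "numeric", trS = "numeric",
    nVolumes = "integer", nRuns = "integer",
    nPatients = "integer", nControls = "integer",
    effectSizeD = "numeric", signalFraction = "numeric",
    nClusters = "integer", smoothFwhmMm = "numeric",
    noiseAr1 = "numeric", noiseSd = "numeric", seedNoiseSd = "numeric",
    betaPsych = "numeric", betaPhysio = "numeric",
    betaPpiControl = "numeric", betaPpiPatient = "numeric",
    rngSeed = "integer"
  ),
  validity = function(object) {
    msgs <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
      msgs <- c(msgs, "gridShape must be 3 positive voxel counts")
    if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
      msgs <- c(msgs, "voxelSizeMm must be 3 positive lengths")
    if (object@trS <= 0) msgs <- c(msgs, "trS must be > 0")
    for (fld in c("nVolumes", "nRuns", "nPatients", "nControls"))
      if (slot(object, fld) < 1L)
        msgs <- c(msgs, sprintf("%s must be positive", fld))
    if (object@signalFraction < 0 || object@signalFraction > 1)
      msgs <- c(msgs, "signalFraction must be in [0, 1]")
    if (object@noiseAr1 < 0 || object@noiseAr1 >= 1)
      msgs <- c(msgs, "noiseAr1 must be in [0, 1)")
    if (object@smoothFwhmMm < 0) msgs <- c(msgs, "smoothFwhmMm must be >= 0")
    if (object@nClusters < 1L) msgs <- c(msgs, "nClusters must be positive")
    if (length(msgs)) msgs else TRUE
  }
)

#' EventSchedule: trial onsets, durations and condition labels for one run
#'
#' @slot onsetsS trial onsets in seconds, strictly increasing.
#' @slot durationsS per-trial durations in seconds (positive, at most 5 s in
#'   the emulated paradigm, not enforced here).
#' @slot conditions per-trial condition label, one of \code{guilt},
#'   \code{indignation}, \code{baseline}.
#' @export
setClass("EventSchedule",
  representation(onsetsS = "numeric", durationsS = "numeric",
                 conditions = "character"),
  validity = function(object) {
    msgs <- character()
    n <- length(object@onsetsS)
    if (length(object@durationsS) != n || length(object@conditions) != n)
      msgs <- c(msgs, "onsetsS, durationsS and conditions must share length")
    if (n > 1 && any(diff(object@onsetsS) <= 0))
      msgs <- c(msgs, "onsets must be strictly increasing within a run")
    if (any(object@onsetsS < 0)) msgs <- c(msgs, "onsets must be non-negative")
    if (any(object@durationsS <= 0)) msgs <- c(msgs, "durations must be positive")
    bad <- setdiff(unique(object@conditions),
                   c("guilt", "indignation", "baseline"))
    if (length(bad))
      msgs <- c(msgs, paste("unknown conditions:", paste(bad, collapse = ", ")))
    if (length(msgs)) msgs else TRUE
  }
)

#' SyntheticCohort: generated subject maps or time series with ground truth
#'
#' @slot maps list with one element per subject: a \linkS4class{VolumeGrid}
#'   (3D map cohort) or a list of 4D \linkS4class{VolumeGrid} runs
#'   (time-series cohort).
#' @slot labels factor of group labels, levels \code{control}, \code{patient}.
#' @slot truthMask logical 3D array marking the voxels carrying the implanted
#'   effect (subset of \code{mask}).
#' @slot mask logical 3D array, the gray-matter mask used.
#' @slot seedRoi logical 3D array (seed region; empty array for map cohorts).
#' @slot config the \linkS4class{SimConfig} that generated the cohort.
#' @export
setClass("SyntheticCohort",
  representation(maps = "list", labels = "factor", truthMask = "array",
                 mask = "array", seedRoi = "array", config = "SimConfig"),
  validity = function(object) {
    msgs <- character()
    if (length(object@maps) != length(object@labels))
      msgs <- c(msgs, "one label per subject required")
    if (!all(levels(object@labels) == c("control", "patient")))
      msgs <- c(msgs, "labels must be a factor with levels control, patient")
    if (nlevels(droplevels(object@labels)) < 2L)
      msgs <- c(msgs, "labels must contain both groups")
    if (any(object@truthMask & !object@mask))
      msgs <- c(msgs, "truthMask must be a subset of mask")
    if (length(msgs)) msgs else TRUE
  }
)

#' HRFSpec: double-gamma hemodynamic response function parameters
#'
#' @slot peakDelayS,undershootDelayS gamma shape parameters (seconds to peak
#'   and to undershoot, with unit dispersion).
#' @slot peakDispersion,undershootDispersion gamma rate scalings.
#' @slot ratio undershoot amplitude relative to the peak.
#' @slot lengthS kernel length in seconds (>= 16).
#' @slot dtS sampling resolution of the internal fine time grid.
#' @export
setClass("HRFSpec",
  representation(peakDelayS = "numeric", undershootDelayS = "numeric",
                 peakDispersion = "numeric", undershootDispersion = "numeric",
                 ratio = "numeric", lengthS = "numeric", dtS = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (object@lengthS < 16) msgs <- c(msgs, "kernel length must be >= 16 s")
    if (object@dtS <= 0) msgs <- c(msgs, "dtS must be positive")
    if (object@peakDelayS <= 0 || object@undershootDelayS <= 0)
      msgs <- c(msgs, "gamma delays must be positive")
    if (length(msgs)) msgs else TRUE
  }
)

#' DesignMatrix: named regressors for the PPI GLM
#'
#' @slot values numeric matrix, one row per volume (runs concatenated).
#' @slot runIndex integer vector assigning each row to a run.
#' @export
setClass("DesignMatrix",
  representation(values = "matrix", runIndex = "integer"),
  validity = function(object) {
    msgs <- character()
    if (is.null(colnames(object@values)))
      msgs <- c(msgs, "design columns must be named")
    if (length(object@runIndex) != nrow(object@values))
      msgs <- c(msgs, "runIndex length must equal row count")
    if (length(msgs)) msgs else TRUE
  }
)

#' PPIMap: one subject's voxelwise contrast t-map
#'
#' @slot tValues \linkS4class{VolumeGrid} of t statistics.
#' @slot dof residual degrees of freedom (n volumes minus design rank).
#' @slot contrastName \code{"interaction"} or \code{"physio"}.
#' @slot flagged logical 3D array marking voxels where the residual variance
#'   was zero (t set to signed infinity rather than raising an error).
#' @export
setClass("PPIMap",
  representation(tValues = "VolumeGrid", dof = "numeric",
                 contrastName = "character", flagged = "array"),
  validity = function(object) {
    if (object@dof <= 0) "dof must be positive" else TRUE
  }
)

#' MLDAModel: a fitted maximum-uncertainty linear discriminant
#'
#' @slot w discriminant weight vector over the selected features.
#' @slot b bias; the decision value is \code{z(x) = w'x + b} and the positive
#'   class (patients) is predicted when z > 0.
#' @slot selectedIdx feature indices (into the full feature vector) retained
#'   by discriminative-voxel selection.
#' @slot eigvalsRaw nonzero eigenvalues of the pooled within-class covariance.
#' @slot eigvalsReg the same spectrum after raising sub-average eigenvalues
#'   to the average.
#' @slot lambdaBar the average eigenvalue used for shrinkage.
#' @slot lambdaBarMethod \code{"trace_p"} (trace/p, zeros included; default)
#'   or \code{"nonzero"} (mean of the nonzero spectrum).
#' @slot classMeans 2-row matrix of class means (control, patient) over the
#'   selected features.
#' @slot nFeaturesTotal length of the full feature vector the selection
#'   indices refer to.
#' @export
setClass("MLDAModel",
  representation(w = "numeric", b = "numeric", selectedIdx = "integer",
                 eigvalsRaw = "numeric", eigvalsReg = "numeric",
                 lambdaBar = "numeric", lambdaBarMethod = "character",
                 classMeans = "matrix", nFeaturesTotal = "integer"),
  validity = function(object) {
    msgs <- character()
    if (length(object@w) != length(object@selectedIdx))
      msgs <- c(msgs, "w and selectedIdx must share length")
    if (length(object@eigvalsRaw) != length(object@eigvalsReg))
      msgs <- c(msgs, "raw and regularized spectra must share length")
    if (length(object@eigvalsReg) &&
        any(object@eigvalsReg < object@lambdaBar - 1e-12))
      msgs <- c(msgs, "regularized eigenvalues must be >= lambdaBar")
    if (length(msgs)) msgs else TRUE
  }
)

#' CVResult: leave-one-subject-out cross-validation output
#'
#' @slot decisionValues one scalar per subject, computed in the fold that
#'   excluded that subject.
#' @slot predictions factor of predicted groups (patient iff decision > 0).
#' @slot trueLabels factor of true groups.
#' @slot subjectIds character subject identifiers.
#' @slot foldModels optional list of per-fold \linkS4class{MLDAModel}s.
#' @export
setClass("CVResult",
  representation(decisionValues = "numeric", predictions = "factor",
                 trueLabels = "factor", subjectIds = "character",
                 foldModels = "list"),
  validity = function(object) {
    msgs <- character()
    n <- length(object@decisionValues)
    if (length(object@predictions) != n || length(object@trueLabels) != n ||
        length(object@subjectIds) != n)
      msgs <- c(msgs, "exactly one decision value, prediction and label per subject")
    disagree <- (object@decisionValues > 0) !=
      (as.character(object@predictions) == "patient")
    if (any(disagree))
      msgs <- c(msgs, "prediction must be patient iff decision value > 0")
    if (length(msgs)) msgs else TRUE
  }
)

#' MetricsReport: evaluation statistics for a cross-validated classifier
#'
#' @slot tp,fn,tn,fp confusion counts (patients are the positive class).
#' @slot accuracy,sensitivity,specificity proportions.
#' @slot auc area under the ROC curve (NA until computed).
#' @slot pBinomial one-sided exact binomial tail p against chance.
#' @slot rocPoints two-column matrix (FPR, TPR), from (0,0) to (1,1).
#' @slot notes named list of metadata (conventions, warnings).
#' @export
setClass("MetricsReport",
  representation(tp = "integer", fn = "integer", tn = "integer", fp = "integer",
                 accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", auc = "numeric",
                 pBinomial = "numeric", rocPoints = "matrix", notes = "list"),
  validity = function(object) {
    msgs <- character()
    tot <- object@tp + object@fn + object@tn + object@fp
    if (tot > 0 &&
        abs(object@accuracy - (object@tp + object@tn) / tot) > 1e-12)
      msgs <- c(msgs, "accuracy inconsistent with counts")
    if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
      msgs <- c(msgs, "auc must lie in [0, 1]")
    if (length(msgs)) msgs else TRUE
  }
)

#' PipelineConfig: one object driving the full synthetic pipeline
#'
#' Every analysis constant appears explicitly: the seed sphere radius (4 mm),
#' the gray-matter threshold (0.25, strict), and the selection fraction (1%)
#' default to the values of the analysis the package reproduces.
#'
#' @slot sim the \linkS4class{SimConfig} block.
#' @slot mode \code{"maps"} (generate PPI-like 3D maps directly) or
#'   \code{"timeseries"} (generate 4D runs and estimate PPI t-maps).
#' @slot seedCenterMm world coordinate of the seed-sphere center.
#' @slot seedRadiusMm sphere radius in mm.
#' @slot gmThreshold gray-matter probability threshold (strict >).
#' @slot contrast \code{"interaction"} or \code{"physio"} (control variant).
#' @slot fraction fraction of features retained by selection.
#' @slot ranking \code{"weight"} (|w| of a full-feature fit) or \code{"t"}
#'   (univariate two-sample t).
#' @slot lambdaBarMethod \code{"trace_p"} or \code{"nonzero"}.
#' @slot outDir output directory for artifacts.
#' @export
setClass("PipelineConfig",
  representation(sim = "SimConfig", mode = "character",
                 seedCenterMm = "numeric", seedRadiusMm = "numeric",
                 gmThreshold = "numeric", contrast = "character",
                 fraction = "numeric", ranking = "character",
                 lambdaBarMethod = "character", outDir = "character"),
  validity = function(object) {
    msgs <- character()
    if (!object@mode %in% c("maps", "timeseries"))
      msgs <- c(msgs, "mode must be 'maps' or 'timeseries'")
    if (!object@contrast %in% c("interaction", "physio"))
      msgs <- c(msgs, "contrast must be 'interaction' or 'physio'")
    if (object@mode == "maps" && object@contrast == "physio")
      msgs <- c(msgs, "the physio control contrast requires mode = 'timeseries'")
    if (object@fraction <= 0 || object@fraction > 1)
      msgs <- c(msgs, "fraction must be in (0, 1]")
    if (length(object@seedCenterMm) != 3L)
      msgs <- c(msgs, "seedCenterMm must have 3 coordinates")
    if (length(msgs)) msgs else TRUE
  }
)
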