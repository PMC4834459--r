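#' @rdname VolumeGrid-class
#' @param object,x an object.
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname VolumeGrid-class
#' @export
setGeneric("volAffine", function(x) standardGeneric("volAffine"))

#' @rdname VolumeGrid-class
#' @export
setGeneric("voxelSizeMm", function(x) standardGeneric("voxelSizeMm"))

#' @rdname MLDAModel-class
#' @export
setGeneric("discriminantWeights",
           function(x) standardGeneric("discriminantWeights"))

#' @rdname MLDAModel-class
#' @export
setGeneric("bias", function(x) standardGeneric("bias"))

#' @rdname MLDAModel-class
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname CVResult-class
#' @export
setGeneric("decisionValues", function(x) standardGeneric("decisionValues"))

#' @rdname CVResult-class
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))

#' @rdname CVResult-class
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))

#' @rdname PPIMap-class
#' @export
setGeneric("tValues", function(x) standardGeneric("tValues"))

#' @rdname PPIMap-class
#' @export
setGeneric("dof", function(x) standardGeneric("dof"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("truthMask", function(x) standardGeneric("truthMask"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortMask", function(x) standardGeneric("cohortMask"))
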