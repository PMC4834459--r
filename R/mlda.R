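#' Fit a maximum-uncertainty linear discriminant (MLDA)
#'
#' Fisher's linear discriminant with the pooled within-class covariance
#' spectrum regularized by raising every eigenvalue below the average up to
#' the average: with \code{Sp = Phi Lambda Phi'} and
#' \code{lambdaBar = trace(Sp)/p}, the shrunken covariance is
#' \code{S* = Phi max(Lambda, lambdaBar) Phi'}, and
#' \code{w = S*^-1 (mu_patient - mu_control)},
#' \code{b = -w'(mu_patient + mu_control)/2}. The decision value is
#' \code{z(x) = w'x + b}; z > 0 predicts the positive class (patients).
#'
#' The inverse is applied through the spectral shortcut
#' \code{S*^-1 = (1/lambdaBar)(I - V V') + V diag(1/lambda*) V'}, where V
#' spans the nonzero-eigenvalue subspace of the within-class-centered data
#' (rank at most n - 2), so no p x p matrix is ever formed and the fit is
#' linear in the number of voxels.
#'
#' @param X numeric matrix, subjects x features.
#' @param y factor (or coercible) with levels \code{control}, \code{patient};
#'   patients are the positive class.
#' @param lambdaBarMethod \code{"trace_p"}: lambdaBar = trace(Sp)/p, the mean
#'   over all p eigenvalues including zeros (default); \code{"nonzero"}: mean
#'   of the nonzero spectrum.
#' @param selectedIdx feature indices the columns of X correspond to
#'   (bookkeeping for back-projection; default all).
#' @param nFeaturesTotal total feature-vector length the indices refer to.
#' @return an \linkS4class{MLDAModel}.
#' @export
fitMLDA <- function(X, y, lambdaBarMethod = c("trace_p", "nonzero"),
                    selectedIdx = seq_len(ncol(X)),
                    nFeaturesTotal = ncol(X)) {
  lambdaBarMethod <- match.arg(lambdaBarMethod)
  X <- as.matrix(X)
  y <- as_group_factor(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 1L) stop("need at least one feature")
  i1 <- which(y == "patient"); i2 <- which(y == "control")
  if (length(i1) == 0L || length(i2) == 0L)
    stop("both classes must be present")
  if (n < 3L) stop("need at least 3 samples (dof n - 2 >= 1)")
  mu1 <- colMeans(X[i1, , drop = FALSE])
  mu2 <- colMeans(X[i2, , drop = FALSE])
  Xc <- X
  Xc[i1, ] <- sweep(X[i1, , drop = FALSE], 2, mu1)
  Xc[i2, ] <- sweep(X[i2, , drop = FALSE], 2, mu2)
  traceSp <- sum(Xc^2) / (n - 2)
  if (traceSp <= 0) stop("zero total within-class variance")
  # nonzero spectrum of Sp = Xc'Xc/(n-2) via the n x n Gram matrix
  G <- tcrossprod(Xc) / (n - 2)
  eg <- eigen(G, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-12
  lambda <- eg$values[keep]
  r <- length(lambda)
  # V (p x r): orthonormal eigenvectors of Sp; Xc' U = V D, D = sqrt(lambda (n-2))
  V <- crossprod(Xc, eg$vectors[, keep, drop = FALSE]) %*%
    diag(1 / sqrt(lambda * (n - 2)), r)
  lambdaBar <- switch(lambdaBarMethod,
                      trace_p = traceSp / p,
                      nonzero = mean(lambda))
  lambdaReg <- pmax(lambda, lambdaBar)
  d <- mu1 - mu2
  Vtd <- crossprod(V, d)
  w <- drop((d - V %*% Vtd) / lambdaBar + V %*% (Vtd / lambdaReg))
  b <- -sum(w * (mu1 + mu2)) / 2
  new("MLDAModel", w = w, b = b, selectedIdx = as.integer(selectedIdx),
      eigvalsRaw = lambda, eigvalsReg = lambdaReg, lambdaBar = lambdaBar,
      lambdaBarMethod = lambdaBarMethod,
      classMeans = rbind(control = mu2, patient = mu1),
      nFeaturesTotal = as.integer(nFeaturesTotal))
}

as_group_factor <- function(y) {
  y <- as.factor(y)
  if (!all(levels(y) %in% c("control", "patient")))
    stop("labels must use levels 'control' and 'patient'")
  factor(y, levels = c("control", "patient"))
}

#' Decision values of an MLDA model
#'
#' @param model an \linkS4class{MLDAModel}.
#' @param X feature matrix; either already restricted to
#'   \code{selectedFeatures(model)} columns, or the full feature matrix
#'   (\code{nFeaturesTotal} columns), which is subset automatically.
#' @return numeric vector of \code{z = w'x + b}, one per row.
#' @export
decisionValue <- function(model, X) {
  pSel <- length(model@w)
  if (is.null(dim(X))) {
    X <- if (length(X) %in% c(pSel, model@nFeaturesTotal))
      matrix(X, nrow = 1)           # one sample
    else if (pSel == 1L) matrix(X, ncol = 1)  # many samples, one feature
    else matrix(X, nrow = 1)
  } else X <- as.matrix(X)
  if (ncol(X) == model@nFeaturesTotal && model@nFeaturesTotal != pSel)
    X <- X[, model@selectedIdx, drop = FALSE]
  if (ncol(X) != pSel)
    stop("feature count does not match the model")
  drop(X %*% model@w) + model@b
}

#' Rank features and keep the most discriminative fraction
#'
#' Default criterion: fit an MLDA on all features of the training data and
#' rank by the absolute discriminant weight, descending (ties broken by
#' ascending feature index); keep the top \code{ceiling(fraction * p)}.
#' The alternative \code{"t"} criterion ranks by absolute univariate
#' two-sample t.
#'
#' @param X training feature matrix (subjects x features).
#' @param y labels.
#' @param fraction fraction of features to keep, in (0, 1].
#' @param ranking \code{"weight"} (default) or \code{"t"}.
#' @param lambdaBarMethod passed to \code{\link{fitMLDA}}.
#' @return integer vector of selected feature indices, in rank order.
#' @export
selectFeatures <- function(X, y, fraction = 0.01,
                           ranking = c("weight", "t"),
                           lambdaBarMethod = "trace_p") {
  ranking <- match.arg(ranking)
  stopifnot(fraction > 0, fraction <= 1)
  p <- ncol(X)
  k <- ceiling(fraction * p)
  score <- if (ranking == "weight") {
    abs(fitMLDA(X, y, lambdaBarMethod)@w)
  } else {
    abs(univariate_t(X, as_group_factor(y)))
  }
  order(-score, seq_len(p))[seq_len(k)]
}

univariate_t <- function(X, y) {
  i1 <- y == "patient"; i2 <- y == "control"
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- colMeans(X[i1, , drop = FALSE]); m2 <- colMeans(X[i2, , drop = FALSE])
  v1 <- if (n1 > 1) apply(X[i1, , drop = FALSE], 2, stats::var) else 0
  v2 <- if (n2 > 1) apply(X[i2, , drop = FALSE], 2, stats::var) else 0
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  tt[!is.finite(tt)] <- 0
  tt
}

#' Feature selection followed by MLDA on the selected voxels
#'
#' @inheritParams selectFeatures
#' @return an \linkS4class{MLDAModel} whose \code{selectedIdx} records the
#'   selection and whose \code{w} is the discriminant over those features.
#' @export
fitMLDAPipeline <- function(X, y, fraction = 0.01,
                            ranking = "weight", lambdaBarMethod = "trace_p") {
  sel <- selectFeatures(X, y, fraction, ranking, lambdaBarMethod)
  fitMLDA(X[, sel, drop = FALSE], y, lambdaBarMethod,
          selectedIdx = sel, nFeaturesTotal = ncol(X))
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject the model (feature selection re-run inside the fold,
#' then MLDA on the selected voxels) is fitted on all other subjects, and
#' the held-out subject's decision value and predicted group are recorded.
#'
#' @inheritParams selectFeatures
#' @param subjectIds optional character ids (default S1..Sn).
#' @param keepModels store the per-fold models (memory permitting).
#' @return a \linkS4class{CVResult}.
#' @export
loocvMLDA <- function(X, y, fraction = 0.01, ranking = "weight",
                      lambdaBarMethod = "trace_p",
                      subjectIds = paste0("S", seq_len(nrow(X))),
                      keepModels = FALSE) {
  y <- as_group_factor(y)
  n <- nrow(X)
  if (n < 4L) stop("LOOCV needs at least 4 subjects")
  if (min(table(y)) < 2L) stop("both classes need at least 2 subjects")
  z <- numeric(n)
  models <- if (keepModels) vector("list", n) else list()
  for (i in seq_len(n)) {
    if (nlevels(droplevels(y[-i])) < 2L)
      stop("a fold lost an entire class")
    m <- fitMLDAPipeline(X[-i, , drop = FALSE], y[-i], fraction,
                         ranking, lambdaBarMethod)
    z[i] <- decisionValue(m, X[i, m@selectedIdx, drop = FALSE])
    if (keepModels) models[[i]] <- m
  }
  pred <- factor(ifelse(z > 0, "patient", "control"),
                 levels = c("control", "patient"))
  new("CVResult", decisionValues = z, predictions = pred, trueLabels = y,
      subjectIds = subjectIds, foldModels = models)
}

#' Construct a CVResult from decision values and true labels
#'
#' @param decisionValues numeric vector; positive predicts patient.
#' @param trueLabels labels (levels control/patient).
#' @param subjectIds optional ids.
#' @return a \linkS4class{CVResult}.
#' @export
cvResult <- function(decisionValues, trueLabels,
                     subjectIds = paste0("S", seq_along(decisionValues))) {
  tl <- as_group_factor(trueLabels)
  pred <- factor(ifelse(decisionValues > 0, "patient", "control"),
                 levels = c("control", "patient"))
  new("CVResult", decisionValues = decisionValues, predictions = pred,
      trueLabels = tl, subjectIds = subjectIds, foldModels = list())
}

#' @rdname MLDAModel-class
#' @export
setMethod("discriminantWeights", "MLDAModel", function(x) x@w)

#' @rdname MLDAModel-class
#' @export
setMethod("bias", "MLDAModel", function(x) x@b)

#' @rdname MLDAModel-class
#' @export
setMethod("selectedFeatures", "MLDAModel", function(x) x@selectedIdx)

setMethod("show", "MLDAModel", function(object) {
  cat(sprintf("MLDAModel: %d of %d features selected; lambdaBar = %.4g (%s)\n",
              length(object@w), object@nFeaturesTotal, object@lambdaBar,
              object@lambdaBarMethod))
  cat(sprintf("  spectrum: %d nonzero eigenvalues, %d raised to lambdaBar\n",
              length(object@eigvalsRaw),
              sum(object@eigvalsRaw < object@lambdaBar)))
})

#' @rdname CVResult-class
#' @export
setMethod("decisionValues", "CVResult", function(x) x@decisionValues)

#' @rdname CVResult-class
#' @export
setMethod("predictions", "CVResult", function(x) x@predictions)

#' @rdname CVResult-class
#' @export
setMethod("trueLabels", "CVResult", function(x) x@trueLabels)

setMethod("show", "CVResult", function(object) {
  acc <- mean(object@predictions == object@trueLabels)
  cat(sprintf("CVResult: %d subjects, LOOCV accuracy %.4g%%\n",
              length(object@decisionValues), 100 * acc))
})

#' Back-project discriminant weights to a volume
#'
#' Voxels outside the model's selection are zero, matching how
#' discriminative-voxel weight maps are displayed.
#'
#' @param model an \linkS4class{MLDAModel} fitted on features from
#'   \code{\link{maskToFeatures}}.
#' @param index linear voxel indices of the full feature vector.
#' @param dims grid dimensions.
#' @param affine optional 4x4 affine (returns a \linkS4class{VolumeGrid}).
#' @param path optional NIfTI output path (requires \code{affine}).
#' @return volume (array or \linkS4class{VolumeGrid}).
#' @export
exportWeightMap <- function(model, index, dims, affine = NULL, path = NULL) {
  if (model@nFeaturesTotal != length(index))
    stop("index table length does not match the model's feature space")
  full <- numeric(length(index))
  full[model@selectedIdx] <- model@w
  vol <- featuresToVolume(full, index, dims, affine)
  if (!is.null(path)) {
    if (is.null(affine)) stop("writing NIfTI requires an affine")
    writeVolume(vol, path)
  }
  vol
}
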