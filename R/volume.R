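#' Construct a VolumeGrid
#'
#' @param data 3D or 4D array.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices). If NULL,
#'   a diagonal affine with the given voxel size is built, centered so the
#'   world origin falls at the middle of the grid (plus \code{centerMm}).
#' @param voxelSizeMm numeric(3), used only when \code{affine} is NULL.
#' @param centerMm world coordinate of the grid center when building a
#'   default affine.
#' @return a \linkS4class{VolumeGrid}.
#' @examples
#' g <- volumeGrid(array(0, c(10, 10, 8)), voxelSizeMm = c(2.29, 2.29, 3))
#' voxelSizeMm(g)
#' @export
volumeGrid <- function(data, affine = NULL,
                       voxelSizeMm = c(2.29, 2.29, 3),
                       centerMm = c(0, 0, 0)) {
  if (is.null(affine)) {
    d3 <- dim(data)[1:3]
    affine <- diag(c(voxelSizeMm, 1))
    # place the grid center (voxel index (d-1)/2, 0-based) at centerMm
    affine[1:3, 4] <- centerMm - voxelSizeMm * (d3 - 1) / 2
  }
  new("VolumeGrid", data = data, affine = affine)
}

#' @rdname VolumeGrid-class
#' @export
setMethod("volData", "VolumeGrid", function(x) x@data)

#' @rdname VolumeGrid-class
#' @export
setMethod("volAffine", "VolumeGrid", function(x) x@affine)

#' @rdname VolumeGrid-class
#' @export
setMethod("voxelSizeMm", "VolumeGrid", function(x)
  sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' @rdname VolumeGrid-class
#' @export
setMethod("dim", "VolumeGrid", function(x) dim(x@data))

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeGrid: %s voxels, voxel size %s mm\n",
              paste(d, collapse = " x "),
              paste(signif(voxelSizeMm(object), 4), collapse = " x ")))
  org <- object@affine[1:3, 4]
  cat(sprintf("  origin (mm): %s\n", paste(signif(org, 4), collapse = ", ")))
})

#' Voxel/world coordinate transforms
#'
#' Voxel indices are 0-based, following the NIfTI convention; R array
#' subscripts are these indices plus one.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param vox matrix (n x 3) or vector of 0-based voxel indices.
#' @param mm matrix (n x 3) or vector of world coordinates in mm.
#' @return matrix of transformed coordinates.
#' @export
voxelToWorld <- function(grid, vox) {
  vox <- rbind_coords(vox)
  t(grid@affine %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(grid, mm) {
  mm <- rbind_coords(mm)
  t(solve(grid@affine) %*% rbind(t(mm), 1))[, 1:3, drop = FALSE]
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3, byrow = TRUE) else as.matrix(x)
}

#' Spherical region of interest by voxel-center distance
#'
#' Marks every voxel whose center lies within \code{radiusMm} of
#' \code{centerMm} in world coordinates. The default center and radius are
#' the right superior anterior temporal lobe seed used for the guilt-selective
#' connectivity analysis.
#'
#' @param centerMm world coordinate of the sphere center (mm).
#' @param radiusMm sphere radius in mm; radius 0 keeps only voxels whose
#'   center coincides with \code{centerMm}.
#' @param grid a \linkS4class{VolumeGrid} defining geometry.
#' @return logical 3D array (a binary mask).
#' @export
makeSphereROI <- function(centerMm = c(58, 0, -12), radiusMm = 4, grid) {
  stopifnot(is(grid, "VolumeGrid"), radiusMm >= 0)
  d3 <- dim(grid@data)[1:3]
  vox <- worldToVoxel(grid, centerMm)
  if (any(vox < -0.5) || any(vox > d3 - 0.5))
    stop(sprintf("sphere center (%s) mm lies outside the grid (voxel index %s)",
                 paste(centerMm, collapse = ", "),
                 paste(signif(vox, 4), collapse = ", ")))
  A <- grid@affine
  # world coordinates of all voxel centers, one axis at a time
  cx <- A[1, 4] + (0:(d3[1] - 1)) * A[1, 1]
  cy <- A[2, 4] + (0:(d3[2] - 1)) * A[2, 2]
  cz <- A[3, 4] + (0:(d3[3] - 1)) * A[3, 3]
  if (any(A[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))] != 0)) {
    # oblique affine: fall back to full coordinate expansion
    idx <- as.matrix(expand.grid(i = 0:(d3[1] - 1), j = 0:(d3[2] - 1),
                                 k = 0:(d3[3] - 1)))
    wc <- voxelToWorld(grid, idx)
    dist2 <- rowSums(sweep(wc, 2, centerMm)^2)
    return(array(dist2 <= radiusMm^2 + 1e-9, dim = d3))
  }
  dx2 <- (cx - centerMm[1])^2
  dy2 <- (cy - centerMm[2])^2
  dz2 <- (cz - centerMm[3])^2
  dist2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(dist2 <= radiusMm^2 + 1e-9, dim = d3)
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Convolves each axis with a normalized 1D Gaussian kernel of
#' \code{sigma = FWHM / (2 sqrt(2 log 2)) / voxel size}, truncated at 4 sigma,
#' with zero padding at the boundaries. A constant field is reproduced exactly
#' at interior voxels (kernels sum to one).
#'
#' @param x 3D array or \linkS4class{VolumeGrid}.
#' @param fwhmMm kernel full width at half maximum in mm (scalar or per-axis).
#' @param voxelSize voxel edge lengths in mm; taken from the grid when
#'   \code{x} is a VolumeGrid.
#' @return smoothed object of the same type as \code{x}.
#' @export
gaussianSmooth <- function(x, fwhmMm = 6, voxelSize = NULL) {
  if (is(x, "VolumeGrid")) {
    vs <- voxelSizeMm(x)
    out <- x
    out@data <- gaussianSmooth(x@data, fwhmMm, vs)
    return(out)
  }
  stopifnot(length(dim(x)) == 3L, !is.null(voxelSize))
  fwhmMm <- rep_len(fwhmMm, 3L)
  for (ax in 1:3) {
    k <- gauss_kernel_1d(fwhmMm[ax], voxelSize[ax])
    if (length(k) > 1L) x <- conv_axis(x, k, ax)
  }
  x
}

# normalized 1D Gaussian taps, truncated at 4 sigma
gauss_kernel_1d <- function(fwhm_mm, voxel_mm) {
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# convolve one axis of a 3D array with taps k (zero padding), via a banded
# convolution matrix so the inner work is one matrix product per axis
conv_axis <- function(x, k, ax) {
  d <- dim(x)
  n <- d[ax]
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- k[off + r + 1L]
  }
  perm <- c(ax, setdiff(1:3, ax))
  xp <- aperm(x, perm)
  m <- K %*% matrix(xp, nrow = n)
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

# exact per-voxel standard deviation of gaussianSmooth applied to iid unit
# noise: convolution of a ones-field with the squared (unnormalized) kernels
smooth_sd_map <- function(dims, fwhmMm, voxelSize) {
  fwhmMm <- rep_len(fwhmMm, 3L)
  v <- array(1, dims)
  for (ax in 1:3) {
    k <- gauss_kernel_1d(fwhmMm[ax], voxelSize[ax])
    if (length(k) > 1L) v <- conv_axis(v, k^2, ax)
  }
  sqrt(v)
}

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers around \pkg{RNifti} that carry the affine into and out of
#' \linkS4class{VolumeGrid}. Plain and gzipped files are both accepted.
#'
#' @param path file path (.nii or .nii.gz).
#' @param grid a \linkS4class{VolumeGrid} to write.
#' @return \code{readVolume} returns a \linkS4class{VolumeGrid};
#'   \code{writeVolume} returns \code{path} invisibly.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) < 3L)
    stop(sprintf("expected a 3D or 4D image, got %dD (dim field: %s)",
                 length(d), paste(d, collapse = " x ")))
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  new("VolumeGrid", data = array(as.numeric(img), dim = d),
      affine = matrix(as.numeric(aff), 4, 4))
}

#' @rdname readVolume
#' @export
writeVolume <- function(grid, path) {
  stopifnot(is(grid, "VolumeGrid"))
  img <- RNifti::asNifti(grid@data, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(grid@affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
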