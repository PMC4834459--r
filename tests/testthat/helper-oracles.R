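# Independent oracles: every function here recomputes a quantity from its
# definition, without reusing the package's computational path.

# Dense-matrix MLDA: forms the p x p pooled covariance, eigendecomposes the
# full spectrum, regularizes and inverts explicitly.
dense_mlda <- function(X, y, lambdaBarMethod = "trace_p") {
  y <- factor(y, levels = c("control", "patient"))
  X1 <- X[y == "patient", , drop = FALSE]
  X2 <- X[y == "control", , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  Sp <- (crossprod(sweep(X1, 2, mu1)) + crossprod(sweep(X2, 2, mu2))) / (n - 2)
  e <- eigen(Sp, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  lbar <- switch(lambdaBarMethod,
                 trace_p = sum(vals) / p,
                 nonzero = mean(vals[vals > max(vals) * 1e-12]))
  lreg <- pmax(vals, lbar)
  Sinv <- e$vectors %*% diag(1 / lreg, p) %*% t(e$vectors)
  w <- drop(Sinv %*% (mu1 - mu2))
  b <- -sum(w * (mu1 + mu2)) / 2
  list(w = w, b = b, z = drop(X %*% w) + b, lambdaBar = lbar)
}

# Brute-force AUC by exhaustive pair counting, ties counted half.
pair_auc <- function(z, y) {
  zp <- z[y == "patient"]; zc <- z[y == "control"]
  s <- 0
  for (a in zp) for (b in zc) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(zp) * length(zc))
}

# Trapezoidal integral of an ROC point set (sorted by FPR then TPR).
trapz_auc <- function(pts) {
  o <- order(pts[, 1], pts[, 2])
  x <- pts[o, 1]; y <- pts[o, 2]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Exact binomial upper tail: C(n, j) is integer-exact in doubles for n <= 50,
# so the tail sum over 2^n is an exact rational evaluated exactly.
binom_tail_exact <- function(k, n, p0 = 0.5) {
  stopifnot(p0 == 0.5, n <= 50)
  sum(choose(n, k:n)) / 2^n
}

# Exact one-sided rank-sum p by full enumeration of group assignments.
ranksum_enum_p <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  rk <- rank(vals)
  wobs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(vals), n1)
  ws <- apply(combos, 2, function(i) sum(rk[i]) - n1 * (n1 + 1) / 2)
  mean(ws >= wobs)
}

# Direct (loop-based) construction of an HRF-convolved, downsampled,
# mean-centered condition regressor on a fine time grid.
direct_psych_regressor <- function(events, weights, hrf, nVolumes, trS) {
  dt <- hrf@dtS
  tk <- seq(0, hrf@lengthS, by = dt)
  h <- stats::dgamma(tk, shape = hrf@peakDelayS, rate = 1) -
    hrf@ratio * stats::dgamma(tk, shape = hrf@undershootDelayS, rate = 1)
  h <- h / max(h)
  nFine <- ceiling(nVolumes * trS / dt) + length(h)
  box <- numeric(nFine)
  for (i in seq_along(events@onsetsS)) {
    w <- weights[[events@conditions[i]]]
    a <- floor(events@onsetsS[i] / dt) + 1L
    b <- min(nFine, ceiling((events@onsetsS[i] + events@durationsS[i]) / dt))
    box[a:b] <- box[a:b] + w
  }
  conv <- numeric(nFine)
  for (ti in seq_len(nFine))
    for (ki in seq_along(h)) {
      j <- ti - ki + 1L
      if (j >= 1L) conv[ti] <- conv[ti] + box[j] * h[ki]
    }
  acq <- (seq_len(nVolumes) - 1) * trS
  reg <- conv[pmin(nFine, floor(acq / dt) + 1L)]
  reg - mean(reg)
}

# Normal-equations GLM t for one voxel.
glm_t_oracle <- function(y, X, cvec) {
  XtX <- solve(t(X) %*% X)
  beta <- XtX %*% t(X) %*% y
  res <- y - X %*% beta
  dofr <- length(y) - qr(X)$rank
  s2 <- sum(res^2) / dofr
  drop(t(cvec) %*% beta) / sqrt(s2 * drop(t(cvec) %*% XtX %*% cvec))
}

# Small random classification instance with both classes >= 2.
random_instance <- function(pMax = 12, nMax = 20) {
  p <- sample(1:pMax, 1)
  n1 <- sample(2:(nMax %/% 2), 1)
  n2 <- sample(2:(nMax %/% 2), 1)
  X <- matrix(rnorm((n1 + n2) * p), n1 + n2, p)
  X[seq_len(n1), ] <- X[seq_len(n1), ] + rnorm(p)
  y <- factor(rep(c("patient", "control"), c(n1, n2)),
              levels = c("control", "patient"))
  list(X = X, y = y)
}

# Tiny grid for volumetric tests.
small_grid <- function(dims = c(10, 10, 8), vox = c(2.29, 2.29, 3)) {
  volumeGrid(array(0, dims), voxelSizeMm = vox)
}

# Jaccard overlap of two index sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
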