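# Independent oracles and small fixture builders used across the suite.
# Each oracle is written as the direct textbook computation (explicit
# loops, closed forms) so it shares no code path with the package.

# closed-form two-shape orthogonal Procrustes distance: center both,
# scale to unit centroid size, then d^2 = 2 - 2 * sum of singular
# values of the cross-covariance (last one signed when reflections are
# disallowed and the optimum would be improper)
opa_distance_oracle <- function(A, B, allow_reflection = FALSE) {
  norm1 <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    M / sqrt(sum(M^2))
  }
  A <- norm1(A); B <- norm1(B)
  sv <- svd(t(A) %*% B)
  d <- sv$d
  if (!allow_reflection && det(sv$u %*% t(sv$v)) < 0)
    d[length(d)] <- -d[length(d)]
  sqrt(max(0, 2 - 2 * sum(d)))
}

# brute-force Blomberg K: explicit GLS mean and quadratic forms
k_oracle <- function(x, tree) {
  C <- ape::vcv.phylo(tree)
  x <- x[rownames(C)]
  n <- length(x)
  Ci <- solve(C)
  one <- rep(1, n)
  ahat <- drop((t(one) %*% Ci %*% x) / (t(one) %*% Ci %*% one))
  d <- x - ahat
  mse0 <- drop(t(d) %*% d) / (n - 1)
  mse <- drop(t(d) %*% Ci %*% d) / (n - 1)
  expected <- (sum(diag(C)) - n / drop(t(one) %*% Ci %*% one)) / (n - 1)
  (mse0 / mse) / expected
}

# brute-force multivariate K: per-descriptor numerators/denominators
# accumulated in an explicit loop before the ratio
kmult_oracle <- function(X, tree) {
  C <- ape::vcv.phylo(tree)
  X <- X[rownames(C), , drop = FALSE]
  n <- nrow(X)
  Ci <- solve(C)
  one <- rep(1, n)
  denom_a <- drop(t(one) %*% Ci %*% one)
  num <- 0; den <- 0
  for (j in seq_len(ncol(X))) {
    aj <- drop((t(one) %*% Ci %*% X[, j]) / denom_a)
    dj <- X[, j] - aj
    num <- num + sum(dj^2)
    den <- den + drop(t(dj) %*% Ci %*% dj)
  }
  expected <- (sum(diag(C)) - n / denom_a) / (n - 1)
  (num / den) / expected
}

# step-by-step GLS pPCA oracle: phylogenetic mean, evolutionary rate
# matrix, eigen-decomposition, scores; no sign convention applied
ppca_oracle <- function(X, tree) {
  C <- ape::vcv.phylo(tree)
  X <- X[rownames(C), , drop = FALSE]
  n <- nrow(X)
  Ci <- solve(C)
  one <- matrix(1, n, 1)
  a <- solve(t(one) %*% Ci %*% one) %*% t(one) %*% Ci %*% X
  D <- X - one %*% a
  R <- t(D) %*% Ci %*% D / (n - 1)
  e <- eigen(R, symmetric = TRUE)
  list(mean = drop(a), R = R, values = e$values,
       scores = D %*% e$vectors)
}

# build an ma_curve directly from values (through the public table API)
curve_from_values <- function(id, s, ma) {
  ma_from_curve_table(data.frame(specimen_id = id, s = s, ma = ma))[[1]]
}

# random polygonal configuration with k landmarks in d dimensions
random_config <- function(id, k = 6, d = 2) {
  landmark_config(id, matrix(stats::rnorm(k * d, sd = 2), k, d))
}

# random rigid motion (+ optional reflection, uniform scale) of a
# coordinate matrix
random_similarity <- function(pts, scale = 1, reflect = FALSE) {
  d <- ncol(pts)
  Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))
  if ((det(Q) < 0) != reflect) Q[, 1] <- -Q[, 1]
  sweep(pts %*% Q * scale, 2, stats::rnorm(d, sd = 5), `+`)
}

# simple 2D lever fixture: pivot at origin, adductor on the y axis,
# edge a parametric polyline given by radii/angles
lever_fixture <- function(r, theta, inlever = c(0, -1)) {
  pts <- rbind(condyle = c(0, 0), adductor = inlever,
               cbind(r * cos(theta), r * sin(theta)))
  rownames(pts) <- c("condyle", "adductor",
                     sprintf("e%03d", seq_along(r)))
  roles <- c(condyle = "condyle_anterior",
             adductor = "adductor_attachment",
             stats::setNames(rep("edge_point", length(r)),
                             rownames(pts)[-(1:2)]))
  lever_geometry_from_landmarks(
    landmark_config("fix", pts, side = "right", roles = roles))
}
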