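# Generalized Procrustes alignment and composite (mean-shape) fossils.
#
# Scaling convention throughout: every configuration is translated to
# its centroid and rescaled to unit centroid size before rotation. MA is
# a dimensionless ratio and all downstream use is shape-only, so size is
# deliberately removed.

centroid_size <- function(points) {
  ctr <- colMeans(points)
  sqrt(sum(sweep(points, 2, ctr)^2))
}

# center + unit-centroid-size normalization; errors on degenerate input
normalize_config <- function(points, id = "?") {
  ctr <- colMeans(points)
  pts <- sweep(points, 2, ctr)
  cs <- sqrt(sum(pts^2))
  if (cs < .Machine$double.eps * nrow(points))
    stop("degenerate configuration '", id,
         "': all landmarks coincide (zero centroid size)")
  list(points = pts / cs, csize = cs)
}

# optimal rotation of A onto B (both centered); reflection optionally
# excluded by forcing det(R) = +1 via the smallest singular direction
opa_rotation <- function(A, B, allow_reflection = FALSE) {
  s <- svd(crossprod(A, B))
  R <- s$u %*% t(s$v)
  if (!allow_reflection && det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

# canonical orientation: rotate a set of aligned configurations so the
# mean shape lies on its principal axes, with a fixed sign convention
# and det +1 (no reflection is ever introduced here)
canonical_rotation <- function(mean_mat) {
  e <- eigen(crossprod(mean_mat), symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, ncol(V)] <- -V[, ncol(V)]
  V
}

check_shared_labels <- function(configs) {
  ref <- rownames(configs[[1]]$points)
  for (cfg in configs[-1]) {
    labs <- rownames(cfg$points)
    if (!setequal(labs, ref)) {
      diff <- c(setdiff(ref, labs), setdiff(labs, ref))
      stop("configurations do not share a label set; symmetric difference: ",
           paste(diff, collapse = ", "))
    }
  }
  d <- vapply(configs, config_dim, integer(1))
  if (length(unique(d)) != 1L)
    stop("configurations mix dimensions: ", paste(unique(d), collapse = ", "))
  ref
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of two or more landmark configurations:
#' each is translated to its centroid and scaled to unit centroid size,
#' then repeatedly rotated onto the current mean shape by orthogonal
#' Procrustes; the mean is recomputed and renormalized until the summed
#' squared Procrustes distance to the mean stabilises. Reflections are
#' never introduced silently (use [reflect_to_reference] beforehand)
#' unless `allow_reflection = TRUE`.
#'
#' @param configs List of at least two [landmark_config] objects sharing
#'   one label set and dimension. Landmarks are matched by label.
#' @param allow_reflection Permit improper rotations during alignment.
#' @param tol Convergence tolerance on the change in summed squared
#'   Procrustes distance. The default is near machine precision: the
#'   objective is quadratic around the optimum, so coordinate accuracy
#'   is roughly the square root of `tol`.
#' @param max_iter Iteration cap.
#'
#' @return An object of class `aligned_shapes` with elements
#'   `configurations` (aligned [landmark_config]s), `mean_shape`
#'   (unit-size mean, a [landmark_config]), `centroid_sizes`,
#'   `procrustes_distances` (per specimen, to the mean), `rss_history`
#'   (summed squared distance per iteration), `iterations`, `converged`.
#' @export
generalized_procrustes <- function(configs, allow_reflection = FALSE,
                                   tol = 1e-15, max_iter = 500L) {
  stopifnot(is.list(configs))
  if (length(configs) < 2L)
    stop("generalized Procrustes needs at least 2 configurations")
  ref_labels <- check_shared_labels(configs)
  # match landmarks by label against the first configuration's order
  mats <- lapply(configs, function(cfg) {
    norm <- normalize_config(cfg$points[ref_labels, , drop = FALSE],
                             cfg$specimen_id)
    norm
  })
  X <- lapply(mats, `[[`, "points")
  csizes <- vapply(mats, `[[`, numeric(1), "csize")
  names(csizes) <- vapply(configs, `[[`, character(1), "specimen_id")

  mean_mat <- normalize_config(Reduce(`+`, X) / length(X), "mean")$points
  rss <- function(Xs, M) sum(vapply(Xs, function(A) sum((A - M)^2),
                                    numeric(1)))
  history <- numeric(0)
  q_prev <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    X <- lapply(X, function(A) A %*% opa_rotation(A, mean_mat,
                                                  allow_reflection))
    mean_mat <- normalize_config(Reduce(`+`, X) / length(X), "mean")$points
    q <- rss(X, mean_mat)
    history <- c(history, q)
    if (is.finite(q_prev) && abs(q_prev - q) < tol) {
      converged <- TRUE
      break
    }
    q_prev <- q
  }
  # the optimum is unique only up to a common rotation; fix it by
  # aligning the mean to its principal axes
  V <- canonical_rotation(mean_mat)
  mean_mat <- mean_mat %*% V
  X <- lapply(X, function(A) A %*% V)
  aligned <- mapply(function(cfg, A) {
    landmark_config(cfg$specimen_id, A, side = cfg$side, roles = cfg$roles)
  }, configs, X, SIMPLIFY = FALSE)
  dists <- vapply(X, function(A) sqrt(sum((A - mean_mat)^2)), numeric(1))
  names(dists) <- names(csizes)
  mean_cfg <- landmark_config("mean", mean_mat,
                              roles = configs[[1]]$roles)
  structure(
    list(configurations = aligned, mean_shape = mean_cfg,
         centroid_sizes = csizes, procrustes_distances = dists,
         rss_history = history, iterations = iter, converged = converged),
    class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat("aligned_shapes:", length(x$configurations), "configurations,",
      nrow(x$mean_shape$points), "landmarks;",
      x$iterations, "GPA iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

#' Composite representation of fragmentary specimens
#'
#' Builds a single terminal unit from several configurations of the same
#' (incomplete or distorted) individual or taxon: the configurations are
#' aligned by [generalized_procrustes] and the unit-centroid-size mean
#' shape is returned, retaining the semantic role labels so the result
#' can enter the lever-geometry pipeline like any other specimen. This
#' is how a composite fossil mandible representation is assembled from
#' several compression-fossil replicates.
#'
#' @param configs List of at least two [landmark_config] objects with
#'   identical label sets (roles taken from the first).
#' @param specimen_id Identifier for the composite (default `"CFMR"`).
#' @param allow_reflection Passed to [generalized_procrustes].
#' @return A [landmark_config]: the mean shape.
#' @export
composite_representation <- function(configs, specimen_id = "CFMR",
                                     allow_reflection = FALSE) {
  if (length(configs) < 2L)
    stop("a composite needs at least 2 configurations")
  gpa <- generalized_procrustes(configs, allow_reflection = allow_reflection)
  m <- gpa$mean_shape
  landmark_config(specimen_id, m$points, roles = configs[[1]]$roles)
}

#' Procrustes distance between two configurations
#'
#' Full Procrustes distance after translation, unit-size scaling and
#' optimal rotation (two-shape alignment).
#'
#' @param a,b [landmark_config] objects with identical label sets.
#' @param allow_reflection Permit improper rotations.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b, allow_reflection = FALSE) {
  labs <- check_shared_labels(list(a, b))
  A <- normalize_config(a$points[labs, , drop = FALSE], a$specimen_id)$points
  B <- normalize_config(b$points[labs, , drop = FALSE], b$specimen_id)$points
  R <- opa_rotation(A, B, allow_reflection)
  sqrt(sum((A %*% R - B)^2))
}
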