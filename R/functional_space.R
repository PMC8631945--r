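# Polynomial functional space: per-specimen polynomial coefficients of
# the MA curve, a common order selected by AIC, and ordination by PCA.
#
# Fitting is ordinary least squares of MA on raw powers of s; because s
# is fixed to [0, 1] before fitting, coefficients are comparable across
# specimens and act as shape descriptors of the curve (level, slope,
# curvature, ...).

#' Fit a polynomial to an MA curve
#'
#' Ordinary least squares of `ma` on `1, s, s^2, ..., s^order`.
#'
#' @param curve An `ma_curve`.
#' @param order Polynomial order (>= 0; `order + 1` must not exceed the
#'   number of curve points).
#' @return An object of class `polynomial_fit` with `specimen_id`,
#'   `order`, `coefficients` (named `beta0..betaq`), `rss`, `n`.
#' @export
fit_polynomial <- function(curve, order) {
  stopifnot(inherits(curve, "ma_curve"))
  order <- as.integer(order)
  if (order < 0L) stop("order must be >= 0")
  if (order + 1L > curve$n_points)
    stop("curve '", curve$specimen_id, "': order ", order,
         " needs at least ", order + 1L, " points, curve has ",
         curve$n_points)
  X <- outer(curve$s, 0:order, `^`)
  fit <- stats::lm.fit(X, curve$ma)
  if (fit$rank < order + 1L)
    stop("curve '", curve$specimen_id,
         "': rank-deficient polynomial design (degenerate s values)")
  coefs <- stats::setNames(fit$coefficients, paste0("beta", 0:order))
  structure(list(specimen_id = curve$specimen_id, order = order,
                 coefficients = coefs,
                 rss = sum(fit$residuals^2), n = curve$n_points),
            class = "polynomial_fit")
}

#' Evaluate a polynomial fit
#' @param fit A `polynomial_fit`.
#' @param s Positions in [0, 1].
#' @return Fitted MA values.
#' @export
predict_polynomial <- function(fit, s) {
  drop(outer(s, 0:fit$order, `^`) %*% fit$coefficients)
}

#' @export
print.polynomial_fit <- function(x, ...) {
  cat("polynomial_fit '", x$specimen_id, "': order ", x$order,
      ", rss ", signif(x$rss, 4), " on n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Select a common polynomial order by AIC
#'
#' For each candidate order, every curve is fitted by OLS and the
#' Gaussian log-likelihoods (each with its own maximum-likelihood
#' residual variance) are pooled by summation; the parameter count is
#' `n_curves * (order + 2)` (coefficients plus one variance per curve).
#' The order minimising AIC = 2k - 2 logLik wins; ties break toward the
#' lower order (parsimony).
#'
#' @param curves List of `ma_curve` objects (>= 2).
#' @param candidate_orders Integer vector of orders to compare.
#' @return A list with `best_order` and `aic_by_order` (named vector).
#' @export
select_order_by_aic <- function(curves, candidate_orders = 1:8) {
  if (inherits(curves, "ma_curve")) curves <- list(curves)
  if (length(curves) == 0L) stop("no curves supplied")
  candidate_orders <- sort(unique(as.integer(candidate_orders)))
  aic <- vapply(candidate_orders, function(q) {
    ll <- sum(vapply(curves, function(cu) {
      f <- fit_polynomial(cu, q)
      # clamp variances below numerical resolution so machine-noise
      # rss differences between exact fits cannot drive the selection
      sig2 <- max(f$rss / f$n, .Machine$double.eps^1.5)
      -f$n / 2 * (log(2 * pi) + log(sig2) + 1)
    }, numeric(1)))
    k <- length(curves) * (q + 2)
    2 * k - 2 * ll
  }, numeric(1))
  names(aic) <- candidate_orders
  best <- candidate_orders[which.min(aic)]  # first minimum = lowest order
  list(best_order = best, aic_by_order = aic)
}

#' Assemble the coefficient matrix of a functional space
#'
#' Rows are specimens, columns the polynomial coefficients used as
#' functional descriptors. Under the default `exclude_intercept` policy
#' the intercept is dropped, leaving `order` descriptors (five at order
#' 5); `include_intercept` keeps all `order + 1`.
#'
#' @param fits List of `polynomial_fit` objects, all of the same order.
#' @param policy `"exclude_intercept"` (default) or
#'   `"include_intercept"`.
#' @return An object of class `functional_space` with `specimen_ids`,
#'   `coefficient_matrix`, `descriptor_policy`, `order`; ordination
#'   slots are filled by [functional_pca].
#' @export
build_coefficient_matrix <- function(fits,
                                     policy = c("exclude_intercept",
                                                "include_intercept")) {
  policy <- match.arg(policy)
  if (inherits(fits, "polynomial_fit")) fits <- list(fits)
  orders <- vapply(fits, `[[`, integer(1), "order")
  if (length(unique(orders)) != 1L)
    stop("fits have heterogeneous orders: ",
         paste(sort(unique(orders)), collapse = ", "))
  q <- orders[1]
  M <- do.call(rbind, lapply(fits, `[[`, "coefficients"))
  rownames(M) <- vapply(fits, `[[`, character(1), "specimen_id")
  if (policy == "exclude_intercept") M <- M[, -1, drop = FALSE]
  structure(list(specimen_ids = rownames(M), coefficient_matrix = M,
                 descriptor_policy = policy, order = q,
                 pc_scores = NULL, pc_loadings = NULL,
                 eigenvalues = NULL, variance_explained = NULL),
            class = "functional_space")
}

# eigen-decomposition of a covariance with the package's fixed sign
# convention: the largest-magnitude loading of each PC is positive
eigen_with_signs <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  vals <- pmax(e$values, 0)
  dimnames(V) <- list(colnames(S), paste0("PC", seq_len(ncol(V))))
  list(values = vals, vectors = V)
}

#' Principal component analysis of the coefficient matrix
#'
#' Column-centers (and optionally standardises) the coefficient matrix
#' and eigen-decomposes its covariance. Component signs are fixed by
#' forcing the largest-magnitude loading of each PC to be positive, so
#' results are reproducible across platforms.
#'
#' @param space A `functional_space` from [build_coefficient_matrix].
#' @param scale_to_correlation Use the correlation rather than the
#'   covariance matrix. Default `FALSE`: the coefficients share units
#'   (dimensionless MA), so covariance PCA is appropriate.
#' @return The `functional_space` with `pc_scores`, `pc_loadings`,
#'   `eigenvalues` and `variance_explained` (percentages summing to
#'   100) filled in.
#' @export
functional_pca <- function(space, scale_to_correlation = FALSE) {
  stopifnot(inherits(space, "functional_space"))
  X <- space$coefficient_matrix
  if (nrow(X) < 3L) stop("PCA needs at least 3 specimens")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (scale_to_correlation) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance descriptor(s): ",
           paste(colnames(X)[sds == 0], collapse = ", "),
           " (cannot scale to correlation)")
    Xc <- sweep(Xc, 2, sds, "/")
  }
  S <- crossprod(Xc) / (nrow(Xc) - 1)
  e <- eigen_with_signs(S)
  scores <- Xc %*% e$vectors
  space$pc_scores <- scores
  space$pc_loadings <- e$vectors
  space$eigenvalues <- e$values
  space$variance_explained <- 100 * e$values / sum(e$values)
  space$pca_mode <- if (scale_to_correlation) "correlation" else "covariance"
  space
}

#' @export
print.functional_space <- function(x, ...) {
  cat("functional_space: ", nrow(x$coefficient_matrix), " specimens x ",
      ncol(x$coefficient_matrix), " descriptors (order ", x$order, ", ",
      x$descriptor_policy, ")\n", sep = "")
  if (!is.null(x$variance_explained))
    cat("  PCA variance explained (%):",
        paste(signif(x$variance_explained, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Scatter plot of a functional space
#'
#' PC1-PC2 scatter with optional diet-class coloring and a highlighted
#' specimen (typically the composite fossil).
#'
#' @param space A `functional_space` after [functional_pca], or a
#'   `phylo_pca` result.
#' @param groups Optional factor of group (diet) labels named by
#'   specimen.
#' @param highlight Optional specimen id drawn as a filled star.
#' @param ... Passed to [graphics::plot].
#' @export
plot_functional_space <- function(space, groups = NULL, highlight = NULL,
                                  ...) {
  scores <- space$pc_scores
  if (is.null(scores)) stop("run functional_pca() first")
  ve <- space$variance_explained
  cols <- "grey30"
  if (!is.null(groups)) {
    groups <- factor(groups[rownames(scores)])
    pal <- grDevices::hcl.colors(nlevels(groups), "Dark 3")
    cols <- pal[as.integer(groups)]
  }
  graphics::plot(scores[, 1], scores[, 2], col = cols, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", ve[1]),
                 ylab = sprintf("PC2 (%.1f%%)", ve[2]), ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(groups),
                     col = pal, pch = 19, bty = "n")
  if (!is.null(highlight) && highlight %in% rownames(scores))
    graphics::points(scores[highlight, 1], scores[highlight, 2],
                     pch = 8, cex = 2, lwd = 2)
  invisible(scores)
}
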