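# Lever geometry and mechanical-advantage curves.
#
# The mechanical advantage (MA) at a bite point is the ratio of the
# adductor inlever to the outlever at that point: the fraction of muscle
# force transmitted to the food item. In 2D (compression fossils) the
# mandibular joint is a single pivot point; in 3D it is the dicondylar
# axis through the anterior and posterior condyles, and moment arms are
# perpendicular distances to that axis.

#' Assemble lever geometry from a landmark configuration
#'
#' Uses the configuration's semantic roles: the joint is the condyle
#' point (2D; the anterior condyle when both are digitized) or the axis
#' through both condyles (3D); the inlever endpoint is the adductor
#' attachment; the gnathal edge is the ordered polyline of `edge_point`
#' landmarks, stored proximal (molar region) to distal (incisivus apex).
#'
#' @param config A [landmark_config] with role labels.
#' @return An object of class `mandible_geometry` with elements
#'   `specimen_id`, `d`, `pivot` (2D) or `axis_point`/`axis_dir` (3D),
#'   `inlever_point`, `edge` (matrix of edge points in stored order).
#' @export
lever_geometry_from_landmarks <- function(config) {
  stopifnot(inherits(config, "landmark_config"))
  roles <- config$roles
  if (is.null(roles)) stop("configuration '", config$specimen_id,
                           "' carries no role labels")
  pts <- config$points
  d <- ncol(pts)
  pick <- function(role) names(roles)[roles == role]
  add <- pick("adductor_attachment")
  if (length(add) != 1L)
    stop("configuration '", config$specimen_id,
         "': exactly one 'adductor_attachment' role required")
  edge_labs <- pick("edge_point")
  if (length(edge_labs) < 4L)
    stop("configuration '", config$specimen_id,
         "': at least 4 'edge_point' landmarks required, found ",
         length(edge_labs))
  # keep stored (digitization) order, proximal -> distal
  edge_labs <- rownames(pts)[rownames(pts) %in% edge_labs]
  ca <- pick("condyle_anterior")
  cp <- pick("condyle_posterior")
  geom <- list(specimen_id = config$specimen_id, d = d,
               inlever_point = pts[add, ],
               edge = pts[edge_labs, , drop = FALSE])
  if (d == 2L) {
    joint_lab <- if (length(ca)) ca[1] else if (length(cp)) cp[1] else
      stop("configuration '", config$specimen_id,
           "': missing role 'condyle_anterior' (joint pivot)")
    geom$pivot <- pts[joint_lab, ]
  } else {
    if (length(ca) != 1L || length(cp) != 1L)
      stop("configuration '", config$specimen_id,
           "': 3D geometry needs both 'condyle_anterior' and ",
           "'condyle_posterior'")
    p1 <- pts[ca, ]; p2 <- pts[cp, ]
    v <- p2 - p1
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12)
      stop("configuration '", config$specimen_id,
           "': condyles coincide, dicondylar axis undefined")
    geom$axis_point <- p1
    geom$axis_dir <- v / nv
  }
  dup <- which(rowSums((geom$edge[-1, , drop = FALSE] -
                        geom$edge[-nrow(geom$edge), , drop = FALSE])^2) == 0)
  if (length(dup))
    stop("configuration '", config$specimen_id,
         "': repeated consecutive edge points at position ", dup[1])
  structure(geom, class = "mandible_geometry")
}

#' @export
print.mandible_geometry <- function(x, ...) {
  cat("mandible_geometry '", x$specimen_id, "': ", x$d, "D joint ",
      if (x$d == 2L) "pivot" else "dicondylar axis",
      ", ", nrow(x$edge), " edge points\n", sep = "")
  invisible(x)
}

# distance of points (rows of M) to the joint: pivot distance in 2D,
# perpendicular distance to the dicondylar axis in 3D
joint_distance <- function(geom, M) {
  M <- matrix(M, ncol = geom$d)
  if (geom$d == 2L) {
    sqrt(rowSums(sweep(M, 2, geom$pivot)^2))
  } else {
    V <- sweep(M, 2, geom$axis_point)
    proj <- V %*% geom$axis_dir
    sqrt(pmax(rowSums(V^2) - drop(proj)^2, 0))
  }
}

#' Inlever length of a mandible geometry
#'
#' The adductor moment arm: Euclidean distance from the pivot to the
#' adductor attachment (2D), or perpendicular distance from the
#' attachment to the dicondylar axis (3D).
#'
#' @param geom A `mandible_geometry`.
#' @return Positive scalar.
#' @export
inlever_length <- function(geom) {
  stopifnot(inherits(geom, "mandible_geometry"))
  il <- joint_distance(geom, geom$inlever_point)
  if (il < 1e-12)
    stop("specimen '", geom$specimen_id,
         "': adductor attachment lies on the joint (inlever length 0)")
  il
}

#' Mechanical-advantage curve along the gnathal edge
#'
#' Resamples the edge polyline at `n_points` positions equally spaced in
#' arc length and computes MA = inlever / outlever at each, where the
#' outlever is the straight-line distance to the pivot (2D) or the
#' perpendicular distance to the dicondylar axis (3D). Positions are
#' reported as normalized arc length `s` in [0, 1], `s = 0` proximal
#' (molar region), `s = 1` the distal incisivus apex.
#'
#' @param geom A `mandible_geometry`.
#' @param n_points Number of sample positions (>= 4; default 100).
#' @return An object of class `ma_curve` with `specimen_id`, `s`, `ma`,
#'   `n_points`.
#' @export
ma_curve <- function(geom, n_points = 100L) {
  stopifnot(inherits(geom, "mandible_geometry"))
  n_points <- as.integer(n_points)
  if (n_points < 4L) stop("n_points must be >= 4")
  edge <- geom$edge
  seg <- sqrt(rowSums((edge[-1, , drop = FALSE] -
                       edge[-nrow(edge), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L <= 0) stop("specimen '", geom$specimen_id,
                   "': edge polyline has zero length")
  target <- seq(0, L, length.out = n_points)
  resampled <- vapply(seq_len(ncol(edge)), function(j)
    stats::approx(cum, edge[, j], xout = target, ties = "ordered")$y,
    numeric(n_points))
  resampled <- matrix(resampled, ncol = ncol(edge))
  outlever <- joint_distance(geom, resampled)
  s <- target / L
  if (any(outlever < 1e-12)) {
    bad <- s[which(outlever < 1e-12)[1]]
    stop("specimen '", geom$specimen_id,
         "': gnathal edge touches the joint (outlever 0) near s = ",
         signif(bad, 4))
  }
  new_ma_curve(geom$specimen_id, s, inlever_length(geom) / outlever)
}

# validating constructor shared by ma_curve() and the table reader
new_ma_curve <- function(specimen_id, s, ma) {
  stopifnot(length(s) == length(ma))
  if (length(s) < 2L) stop("an MA curve needs at least 2 points")
  if (any(diff(s) <= 0))
    stop("curve '", specimen_id, "': s must be strictly increasing")
  if (abs(s[1]) > 1e-12 || abs(s[length(s)] - 1) > 1e-12)
    stop("curve '", specimen_id, "': s must span [0, 1]")
  if (!all(is.finite(ma)) || any(ma <= 0))
    stop("curve '", specimen_id, "': MA values must be finite and positive")
  structure(list(specimen_id = specimen_id, s = as.numeric(s),
                 ma = as.numeric(ma), n_points = length(s)),
            class = "ma_curve")
}

#' @export
print.ma_curve <- function(x, ...) {
  cat("ma_curve '", x$specimen_id, "': ", x$n_points, " points, MA ",
      signif(x$ma[1], 4), " (proximal) -> ", signif(x$ma[x$n_points], 4),
      " (distal)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.ma_curve <- function(x, ...) {
  data.frame(specimen_id = x$specimen_id, s = x$s, ma = x$ma,
             stringsAsFactors = FALSE)
}

#' Read MA curves from a long-format table
#'
#' Ingests precomputed MA curve tables (e.g. data deposited alongside a
#' study) directly, bypassing lever geometry. Rows are sorted by `s` per
#' specimen and `s` is rescaled to [0, 1] when given on another range.
#'
#' @param path CSV path, or a data frame, with columns `specimen_id`,
#'   `s`, `ma`.
#' @return A list of `ma_curve` objects, one per specimen.
#' @export
ma_from_curve_table <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "s", "ma")
  if (!all(need %in% names(df)))
    stop("curve table must contain columns: ", paste(need, collapse = ", "))
  lapply(split(df, factor(df$specimen_id, levels = unique(df$specimen_id))),
         function(sub) {
    if (anyDuplicated(sub$s))
      stop("curve '", sub$specimen_id[1],
           "': duplicated s positions in the table")
    sub <- sub[order(sub$s), ]
    rng <- range(sub$s)
    if (diff(rng) <= 0)
      stop("curve '", sub$specimen_id[1], "': degenerate s range")
    s <- (sub$s - rng[1]) / diff(rng)
    new_ma_curve(sub$specimen_id[1], s, sub$ma)
  })
}

#' Write MA curves to a long-format CSV
#' @param curves List of `ma_curve` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_table <- function(curves, path) {
  if (inherits(curves, "ma_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot MA curves
#'
#' @param curves List of `ma_curve` objects.
#' @param col Optional vector of colors, one per curve (recycled).
#' @param ... Passed to [graphics::matplot]-style plotting.
#' @export
plot_ma_curves <- function(curves, col = NULL, ...) {
  if (inherits(curves, "ma_curve")) curves <- list(curves)
  if (is.null(col)) col <- grDevices::hcl.colors(length(curves), "Dark 3")
  col <- rep_len(col, length(curves))
  rng <- range(unlist(lapply(curves, `[[`, "ma")))
  graphics::plot(NA, xlim = c(0, 1), ylim = rng,
                 xlab = "normalized position along gnathal edge (s)",
                 ylab = "mechanical advantage", ...)
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$s, curves[[i]]$ma, col = col[i])
  invisible(curves)
}
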