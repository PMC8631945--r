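make_2d_config <- function(edge, pivot = c(0, 0), adductor = c(0, -1),
                           id = "m") {
  pts <- rbind(condyle = pivot, adductor = adductor, edge)
  rownames(pts) <- c("condyle", "adductor",
                     sprintf("e%03d", seq_len(nrow(edge))))
  roles <- c(condyle = "condyle_anterior",
             adductor = "adductor_attachment",
             stats::setNames(rep("edge_point", nrow(edge)),
                             rownames(pts)[-(1:2)]))
  landmark_config(id, pts, side = "right", roles = roles)
}

test_that("lever geometry assembly uses the role labels", {
  edge <- cbind(seq(2, 4, length.out = 5), 0)
  g <- lever_geometry_from_landmarks(make_2d_config(edge))
  expect_equal(unname(g$pivot), c(0, 0))
  expect_equal(nrow(g$edge), 5)
  # 3D: dicondylar axis through both condyles
  pts <- rbind(ca = c(0, 0, 0), cp = c(0, 0, 1), ad = c(0, 2, 0),
               e1 = c(3, 0, 0), e2 = c(3.5, 0.5, 0), e3 = c(4, 1, 0),
               e4 = c(4.5, 1.5, 0))
  roles <- c(ca = "condyle_anterior", cp = "condyle_posterior",
             ad = "adductor_attachment", e1 = "edge_point",
             e2 = "edge_point", e3 = "edge_point", e4 = "edge_point")
  g3 <- lever_geometry_from_landmarks(landmark_config("x", pts,
                                                      roles = roles))
  expect_equal(unname(g3$axis_dir), c(0, 0, 1))
  # missing roles fail naming the role
  cfg <- make_2d_config(edge)
  cfg$roles <- cfg$roles[cfg$roles != "adductor_attachment"]
  expect_error(lever_geometry_from_landmarks(cfg), "adductor_attachment")
  pts2 <- pts; pts2["cp", ] <- pts2["ca", ]
  expect_error(lever_geometry_from_landmarks(
    landmark_config("x", pts2, roles = roles)), "coincide")
})

test_that("inlever length is a pivot distance in 2D and an axis distance in 3D", {
  edge <- cbind(seq(2, 4, length.out = 4), 0)
  g <- lever_geometry_from_landmarks(
    make_2d_config(edge, adductor = c(0, 10)))
  expect_equal(inlever_length(g), 10)
  pts <- rbind(ca = c(0, 0, 0), cp = c(0, 0, 1), ad = c(3, 4, 7),
               e1 = c(6, 0, 0), e2 = c(6, 1, 0), e3 = c(6, 2, 0),
               e4 = c(6, 3, 0))
  roles <- c(ca = "condyle_anterior", cp = "condyle_posterior",
             ad = "adductor_attachment", e1 = "edge_point",
             e2 = "edge_point", e3 = "edge_point", e4 = "edge_point")
  g3 <- lever_geometry_from_landmarks(landmark_config("x", pts,
                                                      roles = roles))
  expect_equal(inlever_length(g3), 5)  # axial component ignored
  pts["ad", ] <- c(0, 0, 5)            # attachment on the axis
  g3b <- lever_geometry_from_landmarks(landmark_config("x", pts,
                                                       roles = roles))
  expect_error(inlever_length(g3b), "inlever length 0")
})

test_that("collinear geometry reproduces the closed-form MA curve", {
  # pivot (0,0), inlever (1,0), straight edge (2,0)->(4,0):
  # ma(s) = 1/(2 + 2 s), so 0.5 proximally and 0.25 distally
  edge <- cbind(seq(2, 4, length.out = 12), 0)
  g <- lever_geometry_from_landmarks(make_2d_config(edge,
                                                    adductor = c(1, 0)))
  cu <- ma_curve(g, 50)
  expect_equal(cu$ma[1], 0.5)
  expect_equal(cu$ma[50], 0.25)
  expect_equal(cu$ma, 1 / (2 + 2 * cu$s), tolerance = 1e-12)
  expect_true(all(diff(cu$ma) < 0))
})

test_that("the closed form holds over random collinear instances", {
  set.seed(21)
  for (i in 1:100) {
    d0 <- runif(1, 0.5, 5); L <- runif(1, 0.5, 4)
    il <- runif(1, 0.2, 2)
    edge <- cbind(seq(d0, d0 + L, length.out = 8), 0)
    g <- lever_geometry_from_landmarks(
      make_2d_config(edge, adductor = c(il, 0)))
    cu <- ma_curve(g, 25)
    expect_equal(cu$ma, il / (d0 + cu$s * L), tolerance = 1e-10)
  }
})

test_that("MA curves are invariant under similarity transforms", {
  set.seed(22)
  sp <- diet_profile("carnivore")
  cfg <- mandible_from_profile(sp, 60)
  base <- ma_curve(lever_geometry_from_landmarks(cfg), 80)
  for (i in 1:20) {
    reflect <- i %% 2 == 0
    scl <- exp(runif(1, -2, 2))
    moved <- landmark_config(cfg$specimen_id,
      random_similarity(cfg$points, scale = scl, reflect = reflect),
      side = cfg$side, roles = cfg$roles)
    cu <- ma_curve(lever_geometry_from_landmarks(moved), 80)
    expect_equal(cu$ma, base$ma, tolerance = 1e-10)
    expect_equal(cu$s, base$s, tolerance = 1e-12)
  }
  # the trivially checkable case: uniform scaling by 7.3
  scaled <- landmark_config(cfg$specimen_id, cfg$points * 7.3,
                            side = cfg$side, roles = cfg$roles)
  expect_equal(ma_curve(lever_geometry_from_landmarks(scaled), 80)$ma,
               base$ma, tolerance = 1e-12)
})

test_that("MA is positive, bounded, and stable under refinement", {
  set.seed(23)
  theta <- seq(pi / 2, 2.2, length.out = 40)
  r <- seq(2, 5, length.out = 40) + 0.1 * sin(6 * theta)
  g <- lever_fixture(r, theta)
  cu1 <- ma_curve(g, 100)
  cu2 <- ma_curve(g, 200)
  expect_true(all(cu1$ma > 0))
  min_outlever <- min(sqrt(rowSums(g$edge^2)))
  expect_lte(max(cu1$ma), inlever_length(g) / (0.999 * min_outlever))
  # refinement changes interpolated values by less than local chord error
  at <- cu1$s
  interp <- approx(cu2$s, cu2$ma, xout = at)$y
  expect_lt(max(abs(interp - cu1$ma)), 2e-3)
})

test_that("degenerate lever geometry is rejected", {
  edge <- rbind(c(2, 0), c(3, 0), c(3, 0), c(4, 0))
  expect_error(lever_geometry_from_landmarks(make_2d_config(edge)),
               "repeated consecutive")
  edge2 <- rbind(c(2, 0), c(1, 0), c(0, 0), c(-1, 0))  # passes the pivot
  g <- lever_geometry_from_landmarks(make_2d_config(edge2))
  expect_error(ma_curve(g, 10), "outlever 0")
  g3 <- lever_geometry_from_landmarks(
    make_2d_config(cbind(seq(2, 4, length.out = 4), 0)))
  expect_error(ma_curve(g3, 3), "n_points")
})

test_that("curve tables round-trip, rescale s, and reject duplicates", {
  s <- seq(0, 100, length.out = 100)
  df <- rbind(data.frame(specimen_id = "A", s = s,
                         ma = 0.6 - 0.003 * s),
              data.frame(specimen_id = "B", s = s,
                         ma = 0.4 * exp(-0.01 * s) + 0.1))
  curves <- ma_from_curve_table(df)
  expect_length(curves, 2)
  expect_equal(curves[["A"]]$n_points, 100)
  expect_equal(range(curves[["A"]]$s), c(0, 1))  # rescaled from [0, 100]
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_curve_table(curves, tmp)
  back <- ma_from_curve_table(tmp)
  expect_equal(back[["B"]]$ma, curves[["B"]]$ma)
  df_bad <- rbind(df, data.frame(specimen_id = "A", s = 0, ma = 0.5))
  expect_error(ma_from_curve_table(df_bad), "duplicated s")
})
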