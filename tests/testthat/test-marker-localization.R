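test_that("closest points between lines solve the textbook cases", {
  a <- ProjectionLine(c(0, 0, 0), c(1, 0, 0))
  b <- ProjectionLine(c(0, 1, 0), c(0, 0, 1))
  nad <- closestPointsBetweenLines(a, b)
  expect_equal(nad@nadir_a, c(0, 0, 0))
  expect_equal(nad@nadir_b, c(0, 1, 0))
  expect_equal(nad@gap_mm, 1)
  expect_equal(nad@midpoint, c(0, 0.5, 0))

  # intersecting lines meet at the intersection with zero gap
  c1 <- ProjectionLine(c(-5, 3, 3), c(1, 0, 0))
  c2 <- ProjectionLine(c(2, 3, -4), c(0, 0, 1))
  nad2 <- closestPointsBetweenLines(c1, c2)
  expect_equal(nad2@gap_mm, 0, tolerance = 1e-9)
  expect_equal(nad2@nadir_a, c(2, 3, 3), tolerance = 1e-9)
  expect_equal(nad2@nadir_b, c(2, 3, 3), tolerance = 1e-9)

  expect_error(closestPointsBetweenLines(a, ProjectionLine(c(0, 5, 0), c(1, 0, 0))),
               "parallel")
})

test_that("closest points match brute-force minimization on random skew lines", {
  set.seed(101)
  for (i in 1:100) {
    a <- random_line()
    b <- random_line()
    nad <- closestPointsBetweenLines(a, b)
    bf <- bf_closest_lines(a, b)
    expect_equal(nad@gap_mm, bf$gap, tolerance = 1e-6)
    expect_equal(nad@nadir_a, bf$nadir_a, tolerance = 1e-5)
    expect_equal(nad@nadir_b, bf$nadir_b, tolerance = 1e-5)
    # independent closed form for the gap
    expect_equal(nad@gap_mm, cross_gap(a, b), tolerance = 1e-9)
    # connecting segment orthogonal to both directions
    seg <- nad@nadir_a - nad@nadir_b
    expect_lt(abs(sum(seg * a@direction)), 1e-9)
    expect_lt(abs(sum(seg * b@direction)), 1e-9)
  }
})

test_that("noiseless two-view triangulation recovers the point exactly", {
  g <- ap_lao60()
  p <- c(12, -7, 30)
  loc <- triangulatePair(g[[1]], projectPoint(g[[1]], p),
                         g[[2]], projectPoint(g[[2]], p))
  expect_lt(sqrt(sum((loc@p_pair - p)^2)), 1e-9)
  expect_lt(loc@nadirs@gap_mm, 1e-9)
  expect_equal(loc@angular_separation_deg, 60, tolerance = 1e-9)

  set.seed(41)
  for (i in 1:30) {
    g1 <- random_geometry()
    g2 <- random_geometry()
    w1 <- viewFrame(g1)$view_axis
    w2 <- viewFrame(g2)$view_axis
    ang <- acos(max(-1, min(1, sum(w1 * w2)))) * 180 / pi
    if (ang < 30 || ang > 150) next
    p <- runif(3, -80, 80)
    loc <- triangulatePair(g1, projectPoint(g1, p), g2, projectPoint(g2, p))
    expect_lt(sqrt(sum((loc@p_pair - p)^2)), 1e-9)
  }
})

test_that("perturbed triangulation equals the two-line solution on perturbed rays", {
  g <- ap_lao60()
  p <- c(12, -7, 30)
  set.seed(51)
  for (i in 1:20) {
    d1 <- projectPoint(g[[1]], p) + runif(2, -0.1, 0.1)
    d2 <- projectPoint(g[[2]], p) + runif(2, -0.1, 0.1)
    loc <- triangulatePair(g[[1]], d1, g[[2]], d2)
    bf <- bf_closest_lines(backprojectPoint(g[[1]], d1),
                           backprojectPoint(g[[2]], d2))
    expect_equal(sqrt(sum((loc@p_pair - p)^2)),
                 sqrt(sum(((bf$nadir_a + bf$nadir_b) / 2 - p)^2)),
                 tolerance = 1e-6)
  }
})

test_that("degenerate and near-degenerate view configurations are flagged", {
  g <- CArmGeometry(label = "AP")
  expect_error(triangulatePair(g, c(0, 0), g, c(1, 1)), "degenerate")
  g2 <- CArmGeometry(label = "LAO10", primary_deg = 10)
  expect_warning(triangulatePair(g, c(0, 0), g2, c(1, 1)),
                 "small angular separation")
})

test_that("reprojection error reflects the forward model", {
  g <- CArmGeometry(sid_mm = 1200, sod_mm = 800)
  p <- c(12, -7, 30)
  expect_equal(reprojectionError(g, p, projectPoint(g, p)), 0)
  # 1 mm perpendicular displacement at the isocenter projects to 1.5 mm
  f <- viewFrame(g)
  d0 <- projectPoint(g, c(0, 0, 0))
  expect_equal(reprojectionError(g, 1 * f$u_axis, d0), 1.5, tolerance = 0.015)
  # 1 mm along the view axis is nearly invisible near the isocenter
  for (p0 in list(c(0, 0, 0), c(30, 0, 30), c(-40, 20, 10))) {
    err <- reprojectionError(g, p0 + f$view_axis, projectPoint(g, p0))
    expect_lt(err, 0.11)  # exact 0 at the isocenter, O(|p|/sod) off-axis
  }
  err_iso <- reprojectionError(g, f$view_axis, projectPoint(g, c(0, 0, 0)))
  expect_lt(err_iso, 0.01)
})

test_that("nadir on a line is the closest point", {
  l <- ProjectionLine(c(0, 0, 0), c(1, 0, 0))
  on_line <- nadirOnLine(l, c(3, 0, 0))
  expect_equal(on_line$distance_mm, 0)
  expect_equal(on_line$nadir, c(3, 0, 0))
  n345 <- nadirOnLine(l, c(3, 4, 0))
  expect_equal(n345$nadir, c(3, 0, 0))
  expect_equal(n345$distance_mm, 4)

  set.seed(61)
  for (i in 1:100) {
    line <- random_line()
    q <- runif(3, -300, 300)
    res <- nadirOnLine(line, q)
    expect_equal(res$distance_mm, bf_point_line(line, q), tolerance = 1e-9)
    # optimality: no point on the line is closer
    for (t in runif(5, -500, 500)) {
      x <- line@origin + t * line@direction
      expect_gte(sqrt(sum((q - x)^2)) + 1e-12, res$distance_mm)
    }
  }
})

test_that("triangulation precision degrades as the views close in", {
  set.seed(71)
  g1 <- CArmGeometry(label = "AP")
  errs <- vapply(c(10, 30, 60, 90), function(ang) {
    g2 <- CArmGeometry(primary_deg = ang)
    mean(vapply(1:60, function(i) {
      p <- runif(3, -50, 50)
      d1 <- projectPoint(g1, p) + rnorm(2, 0, 0.1)
      d2 <- projectPoint(g2, p) + rnorm(2, 0, 0.1)
      loc <- suppressWarnings(triangulatePair(g1, d1, g2, d2))
      sqrt(sum((loc@p_pair - p)^2))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
})
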