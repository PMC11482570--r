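test_that("side lengths reproduce closed-form distances and reject coincident points", {
  tri <- landmark_triple(c(0, 0), c(3, 0), c(0, 4))
  s <- side_lengths(tri)
  expect_equal(unname(s), c(3, 4, 5))

  expect_error(landmark_triple(c(1, 1), c(1, 1), c(0, 4)),
               "degenerate geometry.*A and B")
  expect_error(landmark_triple(c(0, 0), c(3, 0), c(3, 0)),
               "degenerate geometry.*B and C")

  set.seed(101)
  for (i in 1:1000) {
    tri <- random_triple()
    s <- side_lengths(tri)
    expect_equal(s[["AB"]], oracle_dist(tri$A, tri$B), tolerance = 1e-9)
    expect_equal(s[["AC"]], oracle_dist(tri$A, tri$C), tolerance = 1e-9)
    expect_equal(s[["BC"]], oracle_dist(tri$B, tri$C), tolerance = 1e-9)
  }
})

test_that("cosine-law angles match closed forms and an atan2 oracle", {
  a345 <- triangle_angles(landmark_triple(c(0, 0), c(3, 0), c(0, 4)))
  expect_equal(a345[["A"]], 90, tolerance = 1e-9)
  expect_equal(a345[["B"]], 53.13010235, tolerance = 1e-6)
  expect_equal(a345[["C"]], 36.86989765, tolerance = 1e-6)

  eq <- triangle_angles(landmark_triple(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  expect_equal(unname(eq), c(60, 60, 60), tolerance = 1e-9)

  set.seed(202)
  for (i in 1:2000) {
    tri <- random_triple()
    ang <- triangle_angles(tri)
    expect_equal(sum(ang), 180, tolerance = 1e-6)
    expect_equal(ang[["A"]], oracle_angle(tri$A, tri$B, tri$C),
                 tolerance = 1e-6)
    expect_equal(ang[["B"]], oracle_angle(tri$B, tri$A, tri$C),
                 tolerance = 1e-6)
    expect_equal(ang[["C"]], oracle_angle(tri$C, tri$A, tri$B),
                 tolerance = 1e-6)
  }
})

test_that("collinear points give angles {180, 0, 0} without error", {
  ang <- triangle_angles(landmark_triple(c(0, 0), c(-1, 0), c(2, 0)))
  expect_equal(sort(unname(ang), decreasing = TRUE), c(180, 0, 0))
  expect_equal(remaining_angle(ang), 180)
})

test_that("remaining angle is 360 minus the largest interior angle", {
  expect_identical(remaining_angle(c(A = 90, B = 45, C = 45)), 270)
  expect_identical(remaining_angle(c(A = 60, B = 60, C = 60)), 300)
  expect_identical(remaining_angle(c(A = 180, B = 0, C = 0)), 180)
  set.seed(303)
  for (i in 1:200) {
    ang <- triangle_angles(random_triple())
    expect_identical(remaining_angle(ang) + max(ang), 360)
  }
})

test_that("angles are invariant under rigid transforms and uniform scaling", {
  set.seed(404)
  for (i in 1:50) {
    tri <- random_triple()
    ang <- triangle_angles(tri)
    prof <- profile_angle(tri, c(0, -1))
    th <- runif(1, -pi, pi)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    sc <- runif(1, 0.1, 10)
    shift <- runif(2, -100, 100)
    mv <- function(p) as.numeric(sc * R %*% p + shift)
    tri2 <- landmark_triple(mv(tri$A), mv(tri$B), mv(tri$C))
    expect_equal(unname(triangle_angles(tri2)), unname(ang),
                 tolerance = 1e-6)
    # dorsal reference transformed along with the points
    d2 <- as.numeric(R %*% c(0, -1))
    expect_equal(profile_angle(tri2, d2), prof, tolerance = 1e-6)
  }
})

test_that("profile angle resolves dorsal vs ventral nail orientation", {
  up <- c(0, -1) # image rows grow downward; dorsal side is up
  clubbed <- landmark_triple(c(0, 0), c(-10, 0), c(10, -3.5))
  normal <- landmark_triple(c(0, 0), c(-10, 0), c(10, 3.5))
  expected <- 180 + atan(3.5 / 10) * 180 / pi
  expect_equal(profile_angle(clubbed, up), expected, tolerance = 1e-6)
  expect_equal(profile_angle(normal, up), 360 - expected, tolerance = 1e-6)
  expect_equal(profile_angle(clubbed, up),
               oracle_profile(c(0, 0), c(-10, 0), c(10, -3.5), up),
               tolerance = 1e-9)
  # collinear: straight profile
  expect_equal(profile_angle(landmark_triple(c(0, 0), c(-10, 0), c(10, 0)),
                             up), 180)
})

test_that("mirror reflection across AB maps profile angle to 360 minus itself", {
  set.seed(505)
  for (i in 1:50) {
    A <- runif(2, -10, 10)
    B <- A + runif(2, 1, 5)
    C <- A + runif(2, -5, 5)
    tri <- tryCatch(landmark_triple(A, B, C), error = function(e) NULL)
    if (is.null(tri)) next
    d <- c(0.3, -0.95)
    d <- d / sqrt(sum(d^2))
    p1 <- profile_angle(tri, d)
    if (abs(p1 - 180) < 1e-6) next
    # reflect C (and the dorsal reference) across the AB line
    ab <- (B - A) / sqrt(sum((B - A)^2))
    refl <- function(v) 2 * sum(v * ab) * ab - v
    C2 <- A + refl(C - A)
    d2 <- refl(d)
    p2 <- profile_angle(landmark_triple(A, B, C2), d2)
    expect_equal(p2, p1, tolerance = 1e-6)
    # with the dorsal reference fixed, reflection flips the angle
    p3 <- profile_angle(landmark_triple(A, B, C2), d)
    expect_equal(p3, 360 - p1, tolerance = 1e-6)
  }
})

test_that("severity grading follows the Lovibond thresholds and is monotone", {
  expect_identical(grade_severity(160), "normal")
  expect_identical(grade_severity(150), "normal")
  expect_identical(grade_severity(170), "mild")
  expect_identical(grade_severity(180), "moderate")
  expect_identical(grade_severity(190), "severe")
  expect_identical(grade_severity(195), "severe")
  expect_identical(grade_severity(200), "severe")

  # total monotone step function across the whole domain
  angles <- seq(0.5, 359.5, by = 0.25)
  lev <- match(grade_severity(angles), severity_levels())
  expect_true(all(diff(lev) >= 0))
  expect_setequal(unique(lev), 1:4)

  expect_error(grade_severity(0), "0, 360")
  expect_error(grade_severity(360), "0, 360")

  # configurable thresholds
  cfg <- grading_config(normal_max = 150, moderate_halfwidth = 2)
  expect_identical(grade_severity(155, cfg), "mild")
  expect_identical(grade_severity(178.5, cfg), "moderate")
  expect_error(grading_config(normal_max = 190), "normal_max")
  expect_error(grading_config(moderate_halfwidth = 25), "moderate_halfwidth")
})

test_that("cfsa composes the stages and grades on the configured basis", {
  up <- c(0, -1)
  res <- cfsa(landmark_triple(c(0, 0), c(-10, 0), c(10, -3.5)), up)
  expect_s3_class(res, "cfsa_result")
  expect_equal(res$profile_angle, 180 + atan(0.35) * 180 / pi,
               tolerance = 1e-6)
  expect_identical(res$severity, "severe")
  expect_identical(res$remaining_angle + max(res$angles), 360)

  res2 <- cfsa(landmark_triple(c(0, 0), c(-10, 0), c(10, 3.5)), up)
  expect_identical(res2$severity, "mild")

  # equilateral: remaining angle 300 regardless of orientation
  eq <- landmark_triple(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  res3 <- cfsa(eq, up)
  expect_equal(res3$remaining_angle, 300, tolerance = 1e-9)

  # grading on the literal remaining angle collapses sub- and
  # super-180 profiles onto the same value
  cfg <- grading_config(grading_basis = "remaining")
  r1 <- cfsa(landmark_triple(c(0, 0), c(-10, 0), c(10, -3.5)), up, cfg)
  r2 <- cfsa(landmark_triple(c(0, 0), c(-10, 0), c(10, 3.5)), up, cfg)
  expect_equal(r1$graded_angle, r2$graded_angle, tolerance = 1e-9)
  expect_identical(r1$severity, r2$severity)
})

test_that("landmark CSV and result JSON round-trip", {
  tri <- landmark_triple(c(1.5, 2.25), c(10, 2), c(20, -3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(tri, path)
  tri2 <- read_landmarks(path)
  expect_equal(tri2$A, tri$A)
  expect_equal(tri2$C, tri$C)

  res <- cfsa(tri, c(0, -1))
  js <- jsonlite::fromJSON(cfsa_to_json(res))
  expect_equal(js$profile_angle, res$profile_angle)
  expect_identical(js$severity, res$severity)
  expect_equal(js$angles$A, unname(res$angles["A"]))
})
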