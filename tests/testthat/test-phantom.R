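test_that("phantom ground truth reproduces the requested profile angle", {
  for (a in seq(140, 220, by = 1)) {
    ph <- generate_phantom(phantom_spec(true_angle = a))
    r <- cfsa(ph$truth, ph$dorsal_outward)
    expect_equal(r$profile_angle, a, tolerance = 0.5)
    expect_identical(ph$severity_label, grade_severity(a))
  }
})

test_that("phantom masks are disjoint and the nail sits on the finger", {
  ph <- generate_phantom(phantom_spec(true_angle = 200))
  expect_false(any(ph$finger_mask & ph$nail_mask))
  expect_gt(sum(ph$nail_mask), 0)
  # nail pixels touch the finger region (8-neighbourhood)
  both <- ph$finger_mask | ph$nail_mask
  expect_true(sum(both) == sum(ph$finger_mask) + sum(ph$nail_mask))
})

test_that("phantom generation is bit-identical given the spec", {
  sp <- phantom_spec(true_angle = 187.3, noise_density = 0.02,
                     blur_sigma = 1, rotation = 12, seed = 99L)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$finger_mask, p2$finger_mask)
  expect_identical(p1$truth, p2$truth)
})

test_that("phantom spec validation rejects ill-posed configurations", {
  expect_error(phantom_spec(nail_length = 150), "nail_length")
  expect_error(phantom_spec(finger_thickness = 200), "finger_thickness")
  expect_error(phantom_spec(finger_gray = 0.5, nail_gray = 0.6),
               "separated")
  expect_error(phantom_spec(true_angle = 130), "true_angle")
  expect_error(phantom_spec(noise_density = 1.5), "corruption")
})

test_that("rotation is exact on landmarks and composes as a group", {
  ph <- generate_phantom(phantom_spec(true_angle = 165))
  d <- dim(ph$image)
  # identity
  r0 <- rotate_image(ph, 0)
  expect_equal(r0$truth$A, ph$truth$A, tolerance = 1e-9)
  expect_equal(r0$image, ph$image, tolerance = 1e-9)
  # two quarter turns equal a half turn on landmarks
  r90 <- rotate_image(ph, 90)
  r90x2 <- rotate_image(r90, 90)
  r180 <- rotate_image(ph, 180)
  expect_equal(r90x2$truth$A, r180$truth$A, tolerance = 1e-6)
  expect_equal(r90x2$truth$C, r180$truth$C, tolerance = 1e-6)
  # profile angle is rigidly invariant
  for (ang in c(17, -33, 90)) {
    rr <- rotate_image(ph, ang)
    r <- cfsa(rr$truth, rr$dorsal_outward)
    expect_equal(r$profile_angle, 165, tolerance = 0.5)
  }
  # canvas holds every foreground pixel
  r37 <- rotate_image(ph, 37)
  expect_equal(sum(r37$finger_mask) / sum(ph$finger_mask), 1,
               tolerance = 0.02)
})

test_that("gaussian blur conserves intensity and matches the sampled kernel", {
  img <- matrix(runif(40 * 30), 30, 40)
  expect_identical(gaussian_blur(img, 0), img)
  # constant image is an eigenfunction
  const <- matrix(0.7, 20, 20)
  expect_equal(gaussian_blur(const, 2), const, tolerance = 1e-12)
  # intensity conservation under the reflective boundary
  expect_equal(sum(gaussian_blur(img, 3)), sum(img), tolerance = 1e-6)
  # impulse response equals the separable sampled Gaussian
  imp <- matrix(0, 31, 31)
  imp[16, 16] <- 1
  out <- gaussian_blur(imp, 2)
  r <- 8 # kernel radius ceiling(4*sigma)
  k <- exp(-(-r:r)^2 / (2 * 4))
  k <- k / sum(k)
  expected <- outer(k, k)
  expect_equal(out[16 + (-r:r), 16 + (-r:r)], expected, tolerance = 1e-6)
  expect_equal(max(abs(out[1, ])), 0, tolerance = 1e-6)
  expect_error(gaussian_blur(img, -1), "sigma")
})

test_that("salt-and-pepper noise hits the binomial count and is seeded", {
  img <- matrix(0.5, 256, 256)
  expect_identical(salt_pepper(img, 0), img)
  all_noise <- salt_pepper(img, 1, seed = 1)
  expect_true(all(all_noise %in% c(0, 1)))
  n1 <- salt_pepper(img, 0.02, seed = 42)
  n2 <- salt_pepper(img, 0.02, seed = 42)
  expect_identical(n1, n2)
  corrupted <- sum(n1 != img)
  bounds <- qbinom(c(0.0005, 0.9995), 256^2, 0.02)
  expect_gte(corrupted, bounds[1])
  expect_lte(corrupted, bounds[2])
  # salt and pepper roughly equiprobable
  expect_gt(sum(n1 == 1), 0.3 * corrupted)
  expect_gt(sum(n1 == 0), 0.3 * corrupted)
  expect_error(salt_pepper(img, 1.2), "density")
})

test_that("make_dataset builds a balanced, reproducible, split dataset", {
  ds <- make_dataset(n_per_class = 5, seed = 7)
  expect_length(ds$phantoms, 20)
  expect_identical(as.vector(table(ds$manifest$label)[severity_levels()]),
                   rep(5L, 4))
  expect_identical(as.vector(table(ds$manifest$split)[c("train", "test",
                                                        "validation")]),
                   c(16L, 2L, 2L))
  ds2 <- make_dataset(n_per_class = 5, seed = 7)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$phantoms[[3]]$image, ds2$phantoms[[3]]$image)
  # labels agree with the grading of the sampled angle
  expect_identical(ds$manifest$label, grade_severity(ds$manifest$true_angle))
  expect_error(make_dataset(0), "n_per_class")
  expect_error(make_dataset(2, split = c(0.5, 0.5, 0.5)), "split")
})

test_that("dataset files round-trip through PNG and CSV", {
  dir <- withr::local_tempdir()
  ds <- make_dataset(n_per_class = 1, seed = 3, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  m <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(m), 4L)
  mask <- read_mask_png(ds$manifest$mask_path[1])
  gt <- phantom_mask(ds$phantoms[[1]])
  expect_identical(unclass(mask), unclass(gt))
  tri <- read_landmarks(ds$manifest$landmarks_path[1])
  expect_equal(tri$A, ds$phantoms[[1]]$truth$A, tolerance = 1e-6)
  img <- png::readPNG(ds$manifest$image_path[1])
  expect_identical(dim(img), dim(ds$phantoms[[1]]$image))
})
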