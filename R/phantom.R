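# Synthetic finger-profile phantoms with exact ground truth.
#
# The phantom is a horizontal finger silhouette seen in profile, dorsal
# side up (towards row 0). The nail occupies a thin band on the dorsal
# edge near the tip; its dorsal edge leaves the phalanx dorsal line at
# the nail base A with a controlled profile angle theta*. Because the
# true landmarks are placed analytically, cfsa() on the ground truth
# reproduces theta* exactly, which makes every downstream stage
# verifiable against a known answer.

#' Specification of a synthetic finger-profile phantom
#'
#' @param width,height Image size in pixels.
#' @param finger_thickness Dorsoventral thickness of the finger band
#'   (pixels).
#' @param nail_length Arc length of the nail dorsal edge from the nail
#'   base to its distal end (pixels).
#' @param true_angle The ground-truth Lovibond profile angle theta* in
#'   degrees; 140-220 covers all four severity classes.
#' @param phalanx_axis_angle Pose of the finger axis in degrees
#'   (counter-clockwise on screen); the phantom is rendered horizontal
#'   and then rotated.
#' @param finger_gray,nail_gray,background_gray Intensity levels in
#'   `[0, 1]`; must be pairwise separated by at least 0.15 so the
#'   intensity-based baseline segmenter is well-posed.
#' @param blur_sigma Gaussian blur applied after rotation (pixels, 0 =
#'   none).
#' @param rotation Additional corruption rotation in degrees applied
#'   before blur (augmentation, distinct from the pose angle).
#' @param noise_density Salt-and-pepper corruption probability per pixel.
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   spec (the seed only drives the impulse noise).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 200, height = 150, finger_thickness = 56,
                         nail_length = 44, true_angle = 160,
                         phalanx_axis_angle = 0,
                         finger_gray = 0.55, nail_gray = 0.95,
                         background_gray = 0.05,
                         blur_sigma = 0, rotation = 0, noise_density = 0,
                         seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               finger_thickness = finger_thickness, nail_length = nail_length,
               true_angle = true_angle,
               phalanx_axis_angle = phalanx_axis_angle,
               finger_gray = finger_gray, nail_gray = nail_gray,
               background_gray = background_gray,
               blur_sigma = blur_sigma, rotation = rotation,
               noise_density = noise_density, seed = as.integer(seed))
  if (spec$nail_length >= spec$width / 2) {
    stop("phantom configuration error: nail_length must be < width/2",
         call. = FALSE)
  }
  if (spec$finger_thickness >= spec$height) {
    stop("phantom configuration error: finger_thickness must be < height",
         call. = FALSE)
  }
  g <- c(spec$background_gray, spec$finger_gray, spec$nail_gray)
  if (any(g < 0) || any(g > 1) || min(dist(g)) < 0.15) {
    stop("phantom configuration error: gray levels must be in [0,1] and ",
         "pairwise separated by >= 0.15", call. = FALSE)
  }
  if (!is.finite(spec$true_angle) || spec$true_angle < 140 ||
      spec$true_angle > 220) {
    stop("phantom configuration error: true_angle must be in [140, 220]",
         call. = FALSE)
  }
  if (spec$blur_sigma < 0 || spec$noise_density < 0 ||
      spec$noise_density > 1) {
    stop("phantom configuration error: invalid corruption settings",
         call. = FALSE)
  }
  structure(spec, class = "phantom_spec")
}

#' Generate a synthetic finger-profile phantom
#'
#' Renders the silhouette described by a [phantom_spec()]: a horizontal
#' finger band with a rounded ventral tip, a nail band on the dorsal
#' edge whose dorsal profile leaves the phalanx line at the nail base A
#' with exterior dorsal angle `true_angle`, ground-truth masks and
#' landmarks, then applies pose rotation and the corruptions in the
#' fixed order rotate -> blur -> salt-and-pepper.
#'
#' Ground-truth landmarks: A is the nail base on the phalanx dorsal
#' line, B lies on the dorsal contour `0.6 * nail_length` proximal to A,
#' C on the nail dorsal edge `nail_length` distal to A.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: list with `image` (numeric
#'   matrix, rows = y), `finger_mask`, `nail_mask` (logical matrices),
#'   `truth` ([landmark_triple()]), `dorsal_outward`, `true_angle`,
#'   `severity_label`, `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(true_angle = 200))
#' ph$severity_label
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  w <- spec$width; h <- spec$height
  th <- spec$finger_thickness
  L <- spec$nail_length
  beta <- (spec$true_angle - 180) * pi / 180  # dorsal rise angle of the nail
  nail_th <- max(4, round(th / 10))
  y_dorsal <- round((h - th) / 2)
  y_vent <- y_dorsal + th
  x0 <- 6
  xA <- w - 60
  x_nail_end <- xA + L * cos(beta)
  r <- th / 3  # ventral tip rounding radius
  x_tip <- x_nail_end

  xs <- seq(x0, floor(x_tip))
  # dorsal (top) edge per column
  y_top <- ifelse(xs < xA, y_dorsal, y_dorsal - (xs - xA) * tan(beta))
  # ventral (bottom) edge with rounded distal corner
  y_bot <- rep(y_vent, length(xs))
  in_round <- xs > x_tip - r
  y_bot[in_round] <- (y_vent - r) +
    sqrt(pmax(0, r^2 - (xs[in_round] - (x_tip - r))^2))
  if (any(y_top + nail_th >= y_bot)) {
    stop("phantom configuration error: nail band would cross the ventral ",
         "contour; increase finger_thickness or reduce nail dip",
         call. = FALSE)
  }

  img <- matrix(spec$background_gray, h, w)
  finger <- matrix(FALSE, h, w)
  nail <- matrix(FALSE, h, w)
  for (i in seq_along(xs)) {
    x <- xs[i]
    rt <- round(y_top[i]); rb <- round(y_bot[i])
    rows <- seq(rt, rb) + 1L
    rows <- rows[rows >= 1 & rows <= h]
    if (x >= xA) {
      nr <- seq(rt, min(rt + nail_th - 1L, rb)) + 1L
      nail[nr, x + 1L] <- TRUE
      fr <- setdiff(rows, nr)
      finger[fr, x + 1L] <- TRUE
    } else {
      finger[rows, x + 1L] <- TRUE
    }
  }
  img[finger] <- spec$finger_gray
  img[nail] <- spec$nail_gray

  truth <- landmark_triple(
    A = c(xA, y_dorsal),
    B = c(xA - 0.6 * L, y_dorsal),
    C = c(xA + L * cos(beta), y_dorsal - L * sin(beta)))
  ph <- structure(list(image = img, finger_mask = finger, nail_mask = nail,
                       truth = truth, dorsal_outward = c(0, -1),
                       true_angle = spec$true_angle,
                       severity_label = grade_severity(spec$true_angle),
                       spec = spec),
                  class = "phantom")
  if (spec$phalanx_axis_angle != 0) {
    ph <- rotate_image(ph, spec$phalanx_axis_angle)
  }
  # corruptions, fixed order: rotate -> blur -> salt-and-pepper
  if (spec$rotation != 0) ph <- rotate_image(ph, spec$rotation)
  if (spec$blur_sigma > 0) ph$image <- gaussian_blur(ph$image, spec$blur_sigma)
  if (spec$noise_density > 0) {
    ph$image <- salt_pepper(ph$image, spec$noise_density, seed = spec$seed)
  }
  ph
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Finger-profile phantom %dx%d px\n",
              ncol(x$image), nrow(x$image)))
  cat(sprintf("  true profile angle: %.2f deg (%s)\n",
              x$true_angle, x$severity_label))
  cat(sprintf("  finger px: %d, nail px: %d\n",
              sum(x$finger_mask), sum(x$nail_mask)))
  invisible(x)
}

#' @export
plot.phantom <- function(x, ...) {
  img <- x$image
  graphics::image(t(img)[, nrow(img):1], col = gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(img) / ncol(img), ...)
  invisible(x)
}

default_class_ranges <- function(config = grading_config(), buffer = 2) {
  eps <- config$moderate_halfwidth
  list(normal = c(140, config$normal_max - buffer),
       mild = c(config$normal_max + buffer, 180 - eps - buffer),
       moderate = c(180, 180),  # the band minus buffer is empty; use 180
       severe = c(180 + eps + buffer, 220))
}

#' Generate a balanced labelled phantom dataset
#'
#' Samples `n_per_class` ground-truth angles uniformly from each class
#' angle range (a +/- 2 degree exclusion buffer around grading
#' boundaries keeps labels unambiguous; the moderate class, a narrow
#' band around 180, is generated at exactly 180), renders the phantoms,
#' assigns train/test/validation splits, and optionally writes images,
#' masks and landmark sidecars to disk with a manifest CSV.
#'
#' @param n_per_class Phantoms per severity class.
#' @param class_angle_ranges Named list of `c(lo, hi)` angle ranges, one
#'   per severity level; defaults derived from the grading config.
#' @param corruption Named list of [phantom_spec()] corruption fields
#'   (`rotation`, `blur_sigma`, `noise_density`) applied to every
#'   phantom.
#' @param split Train/test/validation fractions (sums to 1).
#' @param seed Integer seed; the manifest is identical across runs.
#' @param out_dir Optional directory; when given, per-phantom PNGs
#'   (image + mask), landmark CSVs and `manifest.csv` are written there.
#' @return List with `phantoms` (list) and `manifest` (data.frame with
#'   id, true_angle, label, split, seed and file paths when written).
#' @export
make_dataset <- function(n_per_class, class_angle_ranges = NULL,
                         corruption = list(), split = c(0.8, 0.1, 0.1),
                         seed = 1L, out_dir = NULL) {
  if (is.null(class_angle_ranges)) class_angle_ranges <- default_class_ranges()
  if (length(class_angle_ranges) == 0 || n_per_class < 1) {
    stop("dataset configuration error: need >= 1 class range and ",
         "n_per_class >= 1", call. = FALSE)
  }
  if (abs(sum(split) - 1) > 1e-9 || length(split) != 3L) {
    stop("dataset configuration error: split must be three fractions ",
         "summing to 1", call. = FALSE)
  }
  for (rg in class_angle_ranges) {
    if (length(rg) != 2L || rg[2] < rg[1]) {
      stop("dataset configuration error: empty class angle range",
           call. = FALSE)
    }
  }
  labels <- names(class_angle_ranges)
  with_local_seed(seed, {
    rows <- list(); phantoms <- list(); k <- 0L
    for (lb in labels) {
      rg <- class_angle_ranges[[lb]]
      for (i in seq_len(n_per_class)) {
        k <- k + 1L
        ang <- if (rg[1] == rg[2]) rg[1] else stats::runif(1, rg[1], rg[2])
        ph_seed <- sample.int(.Machine$integer.max, 1)
        sp <- do.call(phantom_spec, c(list(true_angle = ang, seed = ph_seed),
                                      corruption))
        phantoms[[k]] <- generate_phantom(sp)
        rows[[k]] <- data.frame(id = sprintf("phantom_%03d", k),
                                true_angle = ang, label = lb,
                                seed = ph_seed, stringsAsFactors = FALSE)
      }
    }
    manifest <- do.call(rbind, rows)
    # deterministic split over the shuffled dataset, cut by fractions
    manifest$split <- NA_character_
    idx <- sample(nrow(manifest))
    n <- length(idx)
    n_tr <- round(split[1] * n)
    n_te <- round(split[2] * n)
    manifest$split[idx[seq_len(n_tr)]] <- "train"
    if (n_te > 0) manifest$split[idx[n_tr + seq_len(n_te)]] <- "test"
    rest <- idx[setdiff(seq_len(n), seq_len(n_tr + n_te))]
    manifest$split[rest] <- "validation"
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      manifest$image_path <- file.path(out_dir,
                                       paste0(manifest$id, ".png"))
      manifest$mask_path <- file.path(out_dir,
                                      paste0(manifest$id, "_mask.png"))
      manifest$landmarks_path <- file.path(out_dir,
                                           paste0(manifest$id, "_landmarks.csv"))
      for (k in seq_along(phantoms)) {
        ph <- phantoms[[k]]
        png::writePNG(pmin(pmax(ph$image, 0), 1), manifest$image_path[k])
        write_mask_png(phantom_mask(ph), manifest$mask_path[k])
        write_landmarks(ph$truth, manifest$landmarks_path[k])
      }
      utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    list(phantoms = phantoms, manifest = manifest)
  })
}

#' Ground-truth label mask of a phantom
#'
#' @param ph A `phantom`.
#' @return A `seg_mask` label matrix (0 background, 1 finger, 2 nail).
#' @export
phantom_mask <- function(ph) {
  stopifnot(inherits(ph, "phantom"))
  m <- matrix(0L, nrow(ph$image), ncol(ph$image))
  m[ph$finger_mask] <- 1L
  m[ph$nail_mask] <- 2L
  seg_mask(m)
}
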