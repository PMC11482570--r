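# Image corruptions used for augmentation and robustness testing.
# Images are numeric matrices [row = y, col = x], intensities in [0, 1].
# Positive rotation angles turn the displayed image counter-clockwise.

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# rotation matrix acting on image coordinates (y down); positive angle =
# counter-clockwise on screen
rot_mat_img <- function(angle) {
  a <- angle * pi / 180
  matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
}

rotated_canvas <- function(w, h, angle) {
  a <- abs(angle) * pi / 180
  c(w = ceiling(w * abs(cos(a)) + h * abs(sin(a)) - 1e-9),
    h = ceiling(w * abs(sin(a)) + h * abs(cos(a)) - 1e-9))
}

#' Rotate landmark points with an image rotation
#'
#' Applies the exact coordinate transform that [rotate_image()] applies
#' to pixel centres: rotation about the image centre onto the enlarged
#' output canvas.
#'
#' @param pts Numeric matrix with columns x, y (0-based pixel coords) or
#'   a length-2 vector.
#' @param angle Rotation in degrees, positive counter-clockwise on
#'   screen; must lie in (-180, 180].
#' @param dim_in Input image dimension `c(height, width)`.
#' @return Transformed coordinates, same shape as `pts`.
#' @export
rotate_points <- function(pts, angle, dim_in) {
  single <- is.null(dim(pts))
  pts <- rbind(pts)
  h <- dim_in[1]; w <- dim_in[2]
  out_dim <- rotated_canvas(w, h, angle)
  c_in <- c((w - 1) / 2, (h - 1) / 2)
  c_out <- c((out_dim["w"] - 1) / 2, (out_dim["h"] - 1) / 2)
  R <- rot_mat_img(angle)
  res <- t(R %*% (t(pts) - c_in) + c_out)
  colnames(res) <- c("x", "y")
  if (single) res[1, ] else res
}

#' Rotate an image about its centre
#'
#' Rotates by inverse-mapping resampling onto a canvas enlarged to hold
#' every input pixel (no foreground is clipped). Intensities are
#' interpolated bilinearly; label masks should use
#' `filter = "nearest"` to stay discrete. Landmarks are transformed
#' exactly with [rotate_points()]. Rotating a [generate_phantom()] result
#' rotates the image, both masks, the ground-truth landmarks and the
#' dorsal reference direction together.
#'
#' @param x Numeric matrix (grayscale image or label mask), or a
#'   `phantom`.
#' @param angle Degrees in (-180, 180], positive counter-clockwise on
#'   screen.
#' @param filter `"bilinear"` (intensities) or `"nearest"` (labels).
#' @param pad Fill value for canvas regions outside the source image.
#' @param ... Unused.
#' @return Rotated object of the same kind as `x`.
#' @export
rotate_image <- function(x, angle, ...) UseMethod("rotate_image")

#' @rdname rotate_image
#' @export
rotate_image.matrix <- function(x, angle, filter = c("bilinear", "nearest"),
                                pad = 0, ...) {
  filter <- match.arg(filter)
  if (!is.finite(angle) || angle <= -180 || angle > 180) {
    stop("rotation angle must lie in (-180, 180]", call. = FALSE)
  }
  h <- nrow(x); w <- ncol(x)
  out_dim <- rotated_canvas(w, h, angle)
  wo <- out_dim["w"]; ho <- out_dim["h"]
  c_in <- c((w - 1) / 2, (h - 1) / 2)
  c_out <- c((wo - 1) / 2, (ho - 1) / 2)
  Rinv <- rot_mat_img(-angle)
  xo <- rep(seq_len(wo) - 1, each = ho)
  yo <- rep(seq_len(ho) - 1, times = wo)
  src <- Rinv %*% rbind(xo - c_out[1], yo - c_out[2]) + c_in
  xs <- src[1, ]; ys <- src[2, ]
  out <- rep(as.numeric(pad), wo * ho)
  if (filter == "nearest") {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    out[ok] <- x[cbind(yi[ok] + 1, xi[ok] + 1)]
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    ok <- x0 >= -1 & x0 <= w - 1 & y0 >= -1 & y0 <= h - 1
    cl <- function(xi, yi) {
      xi <- pmin(pmax(xi, 0), w - 1)
      yi <- pmin(pmax(yi, 0), h - 1)
      x[cbind(yi + 1, xi + 1)]
    }
    # sample within the valid strip (clamped edges), keep pad elsewhere
    idx <- which(ok & xs >= 0 & xs <= w - 1 & ys >= 0 & ys <= h - 1)
    v <- (1 - fx[idx]) * (1 - fy[idx]) * cl(x0[idx], y0[idx]) +
      fx[idx] * (1 - fy[idx]) * cl(x0[idx] + 1, y0[idx]) +
      (1 - fx[idx]) * fy[idx] * cl(x0[idx], y0[idx] + 1) +
      fx[idx] * fy[idx] * cl(x0[idx] + 1, y0[idx] + 1)
    out[idx] <- v
  }
  matrix(out, nrow = ho, ncol = wo)
}

#' @rdname rotate_image
#' @export
rotate_image.phantom <- function(x, angle, ...) {
  dim_in <- dim(x$image)
  img <- rotate_image.matrix(x$image, angle, filter = "bilinear",
                             pad = x$spec$background_gray)
  fm <- rotate_image.matrix(x$finger_mask + 0, angle, filter = "nearest") > 0.5
  nm <- rotate_image.matrix(x$nail_mask + 0, angle, filter = "nearest") > 0.5
  pts <- rbind(x$truth$A, x$truth$B, x$truth$C)
  pts <- rotate_points(pts, angle, dim_in)
  R <- rot_mat_img(angle)
  x$image <- img
  x$finger_mask <- fm
  x$nail_mask <- nm
  x$truth <- landmark_triple(pts[1, ], pts[2, ], pts[3, ])
  x$dorsal_outward <- as.numeric(R %*% x$dorsal_outward)
  x
}

gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

# mirror (with edge duplication) index vector for length n, radius r
mirror_idx <- function(n, r) {
  i <- seq(1 - r, n + r)
  i <- ifelse(i < 1, 1 - i, i)
  i <- ifelse(i > n, 2 * n + 1 - i, i)
  i
}

#' Gaussian blur with reflective boundaries
#'
#' Separable convolution with a sampled, normalised Gaussian kernel
#' (radius `ceiling(4 sigma)`), mirror boundary handling. The symmetric
#' kernel plus mirror padding conserves total image intensity exactly.
#' `sigma = 0` is the identity.
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels, `>= 0`.
#' @return Blurred matrix of the same dimension.
#' @export
gaussian_blur <- function(image, sigma) {
  if (!is.finite(sigma) || sigma < 0) {
    stop("sigma must be a non-negative number", call. = FALSE)
  }
  if (sigma == 0) return(image)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  conv_cols <- function(m) {
    # convolve down each column with mirror padding
    mp <- m[mirror_idx(nrow(m), r), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[seq_len(nrow(m)) + (j - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(image))))
}

#' Salt-and-pepper (impulse) noise
#'
#' Each pixel is independently corrupted with probability `density`;
#' corrupted pixels are set to the maximum (salt) or minimum (pepper)
#' intensity with equal probability. Deterministic given `seed`.
#'
#' @param image Numeric matrix with intensities in `[lo, hi]`.
#' @param density Corruption probability per pixel, in `[0, 1]`.
#' @param seed Optional integer seed; the caller's RNG state is left
#'   untouched.
#' @param lo,hi Pepper and salt intensities (defaults 0 and 1).
#' @return Corrupted matrix.
#' @export
salt_pepper <- function(image, density, seed = NULL, lo = 0, hi = 1) {
  if (!is.finite(density) || density < 0 || density > 1) {
    stop("density must lie in [0, 1]", call. = FALSE)
  }
  if (density == 0) return(image)
  with_local_seed(seed, {
    n <- length(image)
    hit <- stats::runif(n) < density
    salt <- stats::runif(n) < 0.5
    image[hit & salt] <- hi
    image[hit & !salt] <- lo
    image
  })
}
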