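# Classical baseline segmentation: background / finger / nail by
# intensity, behind a pluggable segmenter contract. Label codes:
# 0 = background, 1 = finger, 2 = nail.

SEG_LEVELS <- c(background = 0L, finger = 1L, nail = 2L)

#' Segmentation label mask
#'
#' Wraps an integer label matrix (0 background, 1 finger, 2 nail) as a
#' `seg_mask`.
#'
#' @param labels Integer matrix with values in `{0, 1, 2}`.
#' @return A `seg_mask` object.
#' @export
seg_mask <- function(labels) {
  if (!is.matrix(labels) || !all(labels %in% SEG_LEVELS)) {
    stop("labels must be a matrix over {0 (background), 1 (finger), 2 (nail)}",
         call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(labels, class = c("seg_mask", "matrix", "array"))
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("Segmentation mask %dx%d px: %d finger px, %d nail px\n",
              ncol(x), nrow(x), sum(x == 1L), sum(x == 2L)))
  invisible(x)
}

# 8-connected component labelling by vectorized label propagation:
# every foreground pixel starts with its own index and repeatedly takes
# the maximum over its 8-neighbourhood until convergence. O(diameter)
# sweeps, each a handful of shifted matrix maxima.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- which(mask)
  if (!any(mask)) return(lab)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, h, w)
    rs <- seq_len(h - abs(dr)); cs <- seq_len(w - abs(dc))
    out[rs + max(dr, 0), cs + max(dc, 0)] <-
      m[rs + max(-dr, 0), cs + max(-dc, 0)]
    out
  }
  repeat {
    nb <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- pmax(nb, shift(lab, dr, dc))
    }
    nb[!mask] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  # renumber to 1..k by decreasing size
  sizes <- sort(table(lab[lab > 0]), decreasing = TRUE)
  ren <- stats::setNames(seq_along(sizes), names(sizes))
  lab[lab > 0] <- ren[as.character(lab[lab > 0])]
  lab
}

dilate1 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    tmp <- matrix(FALSE, h, w)
    rs <- seq_len(h - abs(dr)); cs <- seq_len(w - abs(dc))
    tmp[rs + max(dr, 0), cs + max(dc, 0)] <-
      mask[rs + max(-dr, 0), cs + max(-dc, 0)]
    out <- out | tmp
  }
  out
}

# two-threshold Otsu split of a [0,1] image into three intensity classes
otsu_two_thresholds <- function(v, nbins = 256L) {
  b <- pmin(floor(v * nbins), nbins - 1L)
  h <- tabulate(b + 1L, nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  P <- cumsum(p)
  M <- cumsum(p * mids)
  total_mean <- M[nbins]
  best <- c(-Inf, NA, NA)
  for (t1 in seq_len(nbins - 2L)) {
    w0 <- P[t1]; m0 <- M[t1]
    if (w0 == 0) next
    t2 <- seq(t1 + 1L, nbins - 1L)
    w1 <- P[t2] - w0
    w2 <- 1 - P[t2]
    m1 <- M[t2] - m0
    m2 <- total_mean - M[t2]
    ok <- w1 > 0 & w2 > 0
    if (!any(ok)) next
    sb <- rep(-Inf, length(t2))
    sb[ok] <- m0^2 / w0 + m1[ok]^2 / w1[ok] + m2[ok]^2 / w2[ok]
    j <- which.max(sb)
    if (sb[j] > best[1]) best <- c(sb[j], t1, t2[j])
  }
  if (!is.finite(best[1])) {
    stop("segmentation failure: image intensity histogram does not support ",
         "a three-class split", call. = FALSE)
  }
  c(best[2] / nbins, best[3] / nbins)
}

normalize_image <- function(image) {
  if (length(dim(image)) == 3L) image <- apply(image, c(1, 2), mean)
  if (!is.matrix(image)) stop("image must be a matrix or H x W x C array",
                              call. = FALSE)
  if (max(image) > 1) image <- image / 255
  image
}

#' Baseline segmentation configuration
#'
#' @param median_prefilter Apply a 3x3 median prefilter before
#'   thresholding (robust to impulse noise). Default `TRUE`.
#' @param min_area Minimum pixel area of the finger component; below
#'   this the segmenter reports failure. Default 100.
#' @param open_radius,close_radius Disc radii of the per-class
#'   morphological opening and closing.
#' @return A `segment_config` list.
#' @export
segment_config <- function(median_prefilter = TRUE, min_area = 100,
                           open_radius = 1, close_radius = 2) {
  structure(list(median_prefilter = isTRUE(median_prefilter),
                 min_area = min_area, open_radius = open_radius,
                 close_radius = close_radius),
            class = "segment_config")
}

#' Classical three-class finger/nail segmentation
#'
#' Intensity-based stand-in for a learned segmenter, satisfying the
#' segmenter contract (image in, `seg_mask` out). Steps: optional 3x3
#' median prefilter; two-threshold Otsu split into three intensity
#' classes assigned background/finger/nail in increasing mean-intensity
#' order; per-class morphological opening (radius `open_radius`) and
#' closing (radius `close_radius`); retain the largest 8-connected
#' finger component and the largest nail component adjacent to it;
#' smaller components are reassigned to finger when they touch the kept
#' finger component, otherwise to background.
#'
#' @param image Grayscale matrix or RGB array, intensities in `[0, 1]`
#'   (or `[0, 255]`, normalised automatically).
#' @param config A [segment_config()].
#' @return A [seg_mask()].
#' @export
baseline_segment <- function(image, config = segment_config()) {
  img <- normalize_image(image)
  if (config$median_prefilter) {
    img <- EBImage::medianFilter(pmin(pmax(img, 0), 1), 1)
  }
  if (stats::sd(img) < 1e-8) {
    stop("segmentation failure: constant image", call. = FALSE)
  }
  thr <- tryCatch(otsu_two_thresholds(pmin(pmax(img, 0), 1)),
                  error = function(e) NULL)
  cls <- matrix(0L, nrow(img), ncol(img))
  if (is.null(thr)) {
    # two intensity populations only (no nail visible): single Otsu split
    t1 <- EBImage::otsu(EBImage::Image(t(pmin(pmax(img, 0), 1))))
    cls[img > t1] <- 1L
  } else {
    cls[img > thr[1] & img <= thr[2]] <- 1L
    cls[img > thr[2]] <- 2L
  }

  brush <- function(r) EBImage::makeBrush(2 * r + 1, shape = "disc")
  morph <- function(m, cfg) {
    m <- EBImage::opening(m + 0, brush(cfg$open_radius))
    EBImage::closing(m, brush(cfg$close_radius)) > 0.5
  }
  nail <- morph(cls == 2L, config)
  finger <- morph(cls == 1L, config) & !nail

  flab <- label_components(finger)
  if (!any(flab == 1L) || sum(flab == 1L) < config$min_area) {
    stop("segmentation failure: no finger component of at least ",
         config$min_area, " px", call. = FALSE)
  }
  finger_keep <- flab == 1L
  nlab <- label_components(nail)
  nail_keep <- matrix(FALSE, nrow(img), ncol(img))
  if (any(nlab > 0)) {
    fd <- dilate1(finger_keep)
    adj <- sort(unique(nlab[nlab > 0 & fd]))
    if (length(adj)) {
      # components are numbered by decreasing size, so min(adj) is largest
      nail_keep <- nlab == min(adj)
    }
  }
  labels <- matrix(0L, nrow(img), ncol(img))
  labels[finger_keep] <- 1L
  labels[nail_keep] <- 2L
  # restore nail-intensity pixels clipped off the kept nail by the
  # opening (sharp base corners); bounded neighbourhood growth
  if (any(nail_keep)) {
    for (it in seq_len(config$open_radius + 1L)) {
      grow <- cls == 2L & labels == 0L & dilate1(labels == 2L)
      if (!any(grow)) break
      labels[grow] <- 2L
    }
  }
  # remaining dropped pixels: to finger if touching the kept finger
  # component, else background
  dropped <- (finger | nail) & labels == 0L
  if (any(dropped)) {
    labels[dropped & dilate1(labels == 1L)] <- 1L
  }
  seg_mask(labels)
}

#' Bounding box of the dominant foreground region
#'
#' Stand-in for a detection stage: the tight box of the largest
#' 8-connected foreground component, dilated by `margin` pixels and
#' clipped to the image. For a plain image, foreground is everything
#' above a single Otsu threshold; for a `seg_mask`, any non-background
#' label.
#'
#' @param x Image matrix or [seg_mask()].
#' @param margin Box dilation in pixels (default 5).
#' @return List `x_min, y_min, x_max, y_max` (0-based, half-open
#'   `[min, max)`), class `bounding_box`.
#' @export
roi_crop <- function(x, margin = 5) {
  if (inherits(x, "seg_mask")) {
    fg <- x != 0L
  } else {
    img <- normalize_image(x)
    if (stats::sd(img) < 1e-8) {
      stop("detection failure: empty foreground", call. = FALSE)
    }
    thr <- EBImage::otsu(EBImage::Image(t(img)))
    fg <- img > thr
  }
  if (!any(fg)) stop("detection failure: empty foreground", call. = FALSE)
  lab <- label_components(fg)
  keep <- lab == 1L
  rows <- which(rowSums(keep) > 0)
  cols <- which(colSums(keep) > 0)
  h <- nrow(fg); w <- ncol(fg)
  margin <- as.integer(round(margin))
  box <- list(x_min = max(0L, min(cols) - 1L - margin),
              y_min = max(0L, min(rows) - 1L - margin),
              x_max = min(w, max(cols) + margin),
              y_max = min(h, max(rows) + margin))
  structure(box, class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("Bounding box [%d, %d) x [%d, %d)\n",
              x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}

crop_to_box <- function(m, box) {
  m[(box$y_min + 1):box$y_max, (box$x_min + 1):box$x_max, drop = FALSE]
}

#' Validate and wrap a segmenter under the pluggable contract
#'
#' A segmenter is any function `image -> seg_mask` whose output matches
#' the input shape. The pipeline accepts any such callable in place of
#' [baseline_segment()].
#'
#' @param fn A function of one image argument (extra arguments allowed
#'   with defaults).
#' @return `fn`, tagged as a segmenter.
#' @export
as_segmenter <- function(fn) {
  stopifnot(is.function(fn))
  structure(fn, class = c("segmenter", class(fn)))
}

#' Read/write segmentation masks as PNG label images
#'
#' Label convention: gray levels 0, 128, 255 encode background, finger
#' and nail.
#'
#' @param mask A [seg_mask()].
#' @param path PNG file path.
#' @return `read_mask_png` returns a [seg_mask()]; `write_mask_png`
#'   returns `path` invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "seg_mask"))
  img <- matrix(0, nrow(mask), ncol(mask))
  img[mask == 1L] <- 128 / 255
  img[mask == 2L] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  lv <- round(img * 255)
  labels <- matrix(0L, nrow(img), ncol(img))
  labels[lv >= 64 & lv < 192] <- 1L
  labels[lv >= 192] <- 2L
  seg_mask(labels)
}
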