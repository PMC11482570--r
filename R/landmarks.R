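# Landmark extraction: from a segmentation mask to the three Lovibond
# points. The dorsal contour is sampled column-wise in an axis-aligned
# frame (finger principal axis horizontal, tip at +u, dorsal at +v),
# then A, B, C are picked by arc distance along the smoothed contour.

#' Extract the dorsal finger contour from a segmentation mask
#'
#' Aligns the finger with its principal axis (tip towards +u; the tip
#' side is the one holding the nail centroid when a nail is present),
#' chooses the dorsal side as the side of the axis containing the nail
#' centroid (falling back to the upward image direction for nail-free
#' masks), and records, for every axis-aligned column spanned by the
#' digit, the dorsal-most boundary pixel and its class.
#'
#' @param mask A [seg_mask()].
#' @param min_points Minimum number of contour points (default 10).
#' @return A `dorsal_contour`: data.frame with columns `x`, `y`
#'   (original image coordinates), `u`, `v` (axis-aligned coordinates),
#'   `class` ("finger" or "nail"), ordered proximal to distal, with the
#'   alignment frame in attributes.
#' @export
extract_dorsal_contour <- function(mask, min_points = 10L) {
  stopifnot(inherits(mask, "seg_mask"))
  digit <- mask != 0L
  if (!any(mask == 1L)) {
    stop("landmark failure: mask contains no finger component", call. = FALSE)
  }
  idx <- which(digit, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  if (all(c(1, nrow(mask)) %in% idx[, 1]) &&
      all(c(1, ncol(mask)) %in% idx[, 2])) {
    stop("axis estimation failure: finger touches all four image borders",
         call. = FALSE)
  }
  ctr <- colMeans(pts)
  cv <- stats::cov(pts)
  e1 <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  # deterministic sign: tip (+u) towards the nail centroid if any,
  # else positive x (tie: positive y)
  has_nail <- any(mask == 2L)
  if (has_nail) {
    nidx <- which(mask == 2L, arr.ind = TRUE)
    nctr <- c(mean(nidx[, 2] - 1), mean(nidx[, 1] - 1))
    if (sum((nctr - ctr) * e1) < 0) e1 <- -e1
  } else if (e1[1] < 0 || (e1[1] == 0 && e1[2] < 0)) {
    e1 <- -e1
  }
  e2 <- c(-e1[2], e1[1])
  # dorsal side (+v): side of the axis containing the nail centroid;
  # fallback: upward in image coordinates (-y)
  if (has_nail) {
    if (sum((nctr - ctr) * e2) < 0) e2 <- -e2
  } else if (e2[2] > 0) {
    e2 <- -e2
  }
  u <- (pts[, 1] - ctr[1]) * e1[1] + (pts[, 2] - ctr[2]) * e1[2]
  v <- (pts[, 1] - ctr[1]) * e2[1] + (pts[, 2] - ctr[2]) * e2[2]
  cu <- round(u)
  ord <- order(cu, -v)
  first <- !duplicated(cu[ord])
  sel <- ord[first]
  sel <- sel[order(cu[sel])]
  cls <- ifelse(mask[cbind(pts[sel, 2] + 1, pts[sel, 1] + 1)] == 2L,
                "nail", "finger")
  out <- data.frame(x = pts[sel, 1], y = pts[sel, 2],
                    u = u[sel], v = v[sel], class = cls,
                    stringsAsFactors = FALSE)
  # trim end-face artefacts: at the proximal and distal ends of the
  # digit the dorsal-most pixel of a column can sit on the near-vertical
  # end face rather than on the dorsal surface; dorsal slopes of
  # interest stay well below 3 px per column
  slope_cap <- 3
  while (nrow(out) > 2 &&
         abs(out$v[nrow(out)] - out$v[nrow(out) - 1]) > slope_cap) {
    out <- out[-nrow(out), ]
  }
  while (nrow(out) > 2 && abs(out$v[2] - out$v[1]) > slope_cap) {
    out <- out[-1, ]
  }
  if (nrow(out) < min_points) {
    stop("landmark failure: dorsal contour has fewer than ", min_points,
         " points", call. = FALSE)
  }
  attr(out, "centroid") <- ctr
  attr(out, "axis") <- e1
  attr(out, "dorsal") <- e2
  class(out) <- c("dorsal_contour", "data.frame")
  out
}

moving_average <- function(z, window) {
  if (window <= 1) return(z)
  n <- length(z)
  half <- window %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    out[i] <- mean(z[j])
  }
  out
}

#' Landmark-extraction configuration
#'
#' @param nail_span_fraction Arc-length fraction of the nail run from
#'   the nail base A at which C is placed (1 = distal end of the nail).
#' @param fold_offset_fraction Fraction of the nail-run arc length
#'   proximal to A at which the nail-fold point B is placed.
#' @param smooth_window Moving-average window (points) applied to the
#'   contour coordinates before point selection.
#' @param min_nail_points Minimum number of nail-tagged contour points.
#' @return A `landmark_config` list.
#' @export
landmark_config <- function(nail_span_fraction = 1.0,
                            fold_offset_fraction = 0.6,
                            smooth_window = 5L,
                            min_nail_points = 5L) {
  structure(list(nail_span_fraction = nail_span_fraction,
                 fold_offset_fraction = fold_offset_fraction,
                 smooth_window = as.integer(smooth_window),
                 min_nail_points = as.integer(min_nail_points)),
            class = "landmark_config")
}

#' Locate the three Lovibond landmarks on a dorsal contour
#'
#' A is the proximal-most nail-tagged contour point (nail base); C the
#' nail point at arc distance `nail_span_fraction` of the nail-run
#' length distal to A; B the finger-tagged point at arc distance
#' `fold_offset_fraction` of the nail-run length proximal to A.
#' Coordinates are taken from the contour smoothed with a moving
#' average, so the selected points sit on a locally fitted curve rather
#' than on raw pixel corners.
#'
#' @param contour A `dorsal_contour` from [extract_dorsal_contour()].
#' @param mask The source [seg_mask()] (used for the finger centroid).
#' @param config A [landmark_config()].
#' @return List with `triple` ([landmark_triple()]), `dorsal_outward`
#'   (unit vector at A pointing away from the finger), and `provenance`
#'   (contour length, nail-run points and arc length, offsets used).
#' @export
locate_landmarks <- function(contour, mask, config = landmark_config()) {
  stopifnot(inherits(contour, "dorsal_contour"), inherits(mask, "seg_mask"))
  is_nail <- contour$class == "nail"
  if (!any(is_nail)) {
    stop("landmark failure: no nail-tagged contour points", call. = FALSE)
  }
  # longest contiguous nail run
  r <- rle(is_nail)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nail_runs <- which(r$values)
  best <- nail_runs[which.max(r$lengths[nail_runs])]
  i0 <- starts[best]; i1 <- ends[best]
  if (i1 - i0 + 1L < config$min_nail_points) {
    stop("insufficient nail: nail run shorter than ", config$min_nail_points,
         " contour points", call. = FALSE)
  }
  sx <- moving_average(contour$x, config$smooth_window)
  sy <- moving_average(contour$y, config$smooth_window)
  seg <- sqrt(diff(sx)^2 + diff(sy)^2)
  arc <- c(0, cumsum(seg))
  run_len <- arc[i1] - arc[i0]
  # A: nail base
  iA <- i0
  # C: along the nail run at the requested arc fraction from A
  targetC <- arc[iA] + config$nail_span_fraction * run_len
  iC <- i0 + which.min(abs(arc[i0:i1] - targetC)) - 1L
  # B: proximal of A by the requested fraction of the run length,
  # restricted to finger-tagged points
  targetB <- arc[iA] - config$fold_offset_fraction * run_len
  prox <- seq_len(iA - 1L)
  prox <- prox[contour$class[prox] == "finger"]
  if (!length(prox)) {
    stop("landmark failure: no finger-tagged contour proximal to the nail",
         call. = FALSE)
  }
  iB <- prox[which.min(abs(arc[prox] - targetB))]
  triple <- landmark_triple(c(sx[iA], sy[iA]), c(sx[iB], sy[iB]),
                            c(sx[iC], sy[iC]))
  # dorsal-outward normal at A: perpendicular to the local contour
  # tangent, pointing away from the finger centroid
  j0 <- max(1L, iA - 2L); j1 <- min(nrow(contour), iA + 2L)
  tang <- c(sx[j1] - sx[j0], sy[j1] - sy[j0])
  tang <- tang / sqrt(sum(tang^2))
  nrm <- c(-tang[2], tang[1])
  fidx <- which(mask == 1L, arr.ind = TRUE)
  fctr <- c(mean(fidx[, 2] - 1), mean(fidx[, 1] - 1))
  if (sum(nrm * (c(sx[iA], sy[iA]) - fctr)) < 0) nrm <- -nrm
  list(triple = triple,
       dorsal_outward = nrm,
       provenance = list(contour_points = nrow(contour),
                         nail_run_points = i1 - i0 + 1L,
                         nail_run_arc = run_len,
                         nail_span_fraction = config$nail_span_fraction,
                         fold_offset_fraction = config$fold_offset_fraction,
                         smooth_window = config$smooth_window))
}

#' Full landmark extraction from a mask
#'
#' Convenience wrapper: [extract_dorsal_contour()] followed by
#' [locate_landmarks()].
#'
#' @inheritParams locate_landmarks
#' @param mask A [seg_mask()].
#' @return As [locate_landmarks()].
#' @export
extract_landmarks <- function(mask, config = landmark_config()) {
  contour <- extract_dorsal_contour(mask)
  locate_landmarks(contour, mask, config)
}
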