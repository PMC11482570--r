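# Coordinate convention used throughout the package: image coordinates,
# origin at the top-left pixel centre, x = column, y = row, y increases
# DOWNWARD. Angles are degrees at every API boundary; radians internally.

DEG <- 180 / pi

#' Severity levels of digital clubbing
#'
#' The four ordered severity categories used for Lovibond-angle grading,
#' in increasing order of severity.
#'
#' @return Character vector `c("normal", "mild", "moderate", "severe")`.
#' @export
severity_levels <- function() c("normal", "mild", "moderate", "severe")

as_point <- function(p, name) {
  p <- as.numeric(p)
  if (length(p) != 2L || any(!is.finite(p))) {
    stop("point ", name, " must be two finite numbers (x, y)", call. = FALSE)
  }
  names(p) <- c("x", "y")
  p
}

#' Construct a landmark triple A, B, C
#'
#' The three anatomical points of the Lovibond construction in image
#' coordinates (pixels, y increases downward): `A` the nail base (nail
#' matrix), `B` the first phalanx nail fold on the dorsal skin contour
#' proximal to the nail, and `C` a distal point on the dorsal nail-plate
#' edge.
#'
#' @param A,B,C Numeric length-2 vectors `c(x, y)` in pixels.
#' @return An object of class `landmark_triple`: a list with elements
#'   `A`, `B`, `C`.
#' @examples
#' landmark_triple(c(0, 0), c(3, 0), c(0, 4))
#' @export
landmark_triple <- function(A, B, C) {
  tri <- list(A = as_point(A, "A"), B = as_point(B, "B"), C = as_point(C, "C"))
  pairs <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  for (pr in pairs) {
    d <- sqrt(sum((tri[[pr[1]]] - tri[[pr[2]]])^2))
    if (d <= 1e-9) {
      stop("degenerate geometry: points ", pr[1], " and ", pr[2],
           " coincide", call. = FALSE)
    }
  }
  structure(tri, class = "landmark_triple")
}

as_triple <- function(x) {
  if (inherits(x, "landmark_triple")) return(x)
  if (is.list(x) && all(c("A", "B", "C") %in% names(x))) {
    return(landmark_triple(x$A, x$B, x$C))
  }
  stop("expected a landmark_triple or a list with elements A, B, C",
       call. = FALSE)
}

#' @export
print.landmark_triple <- function(x, ...) {
  cat("Landmark triple (image px, y down):\n")
  for (nm in c("A", "B", "C")) {
    cat(sprintf("  %s: (%.3f, %.3f)\n", nm, x[[nm]]["x"], x[[nm]]["y"]))
  }
  invisible(x)
}

#' Side lengths of the landmark triangle
#'
#' Euclidean distances between the three landmark points, i.e. the sides
#' of the triangle used by the severity analysis.
#'
#' @param triple A [landmark_triple()].
#' @return Named numeric vector with elements `AB`, `AC`, `BC` (pixels).
#' @examples
#' side_lengths(landmark_triple(c(0, 0), c(3, 0), c(0, 4)))
#' @export
side_lengths <- function(triple) {
  triple <- as_triple(triple)
  d <- function(p, q) sqrt(sum((p - q)^2))
  c(AB = d(triple$A, triple$B),
    AC = d(triple$A, triple$C),
    BC = d(triple$B, triple$C))
}

#' Interior angles of the landmark triangle (law of cosines)
#'
#' Computes the interior angle at each vertex from the side lengths via
#' the law of cosines, e.g. `thetaA = arccos((AB^2 + AC^2 - BC^2) /
#' (2 AB AC))`. The cosine argument is clamped to `[-1, 1]` so exactly
#' collinear triples yield angles `{180, 0, 0}` instead of an error.
#'
#' @inheritParams side_lengths
#' @return Named numeric vector `c(A=, B=, C=)` of angles in degrees;
#'   the three angles sum to 180 (within 1e-6).
#' @examples
#' triangle_angles(landmark_triple(c(0, 0), c(3, 0), c(0, 4)))
#' @export
triangle_angles <- function(triple) {
  triple <- as_triple(triple)
  s <- side_lengths(triple)
  law <- function(adj1, adj2, opp) {
    arg <- (adj1^2 + adj2^2 - opp^2) / (2 * adj1 * adj2)
    acos(max(-1, min(1, arg))) * DEG
  }
  ang <- c(A = law(s["AB"], s["AC"], s["BC"]),
           B = law(s["AB"], s["BC"], s["AC"]),
           C = law(s["AC"], s["BC"], s["AB"]))
  names(ang) <- c("A", "B", "C")
  ang
}

#' Remaining angle: 360 degrees minus the largest interior angle
#'
#' The severity-analysis transform of the triangle: the largest of the
#' three interior angles is subtracted from 360 degrees. Ties are broken
#' in the fixed order A, B, C.
#'
#' @param angles Named numeric vector as returned by [triangle_angles()],
#'   or a [landmark_triple()] (angles are computed first).
#' @return The remaining angle in degrees; in `(180, 300]` for proper
#'   triangles, exactly 180 for collinear points.
#' @examples
#' remaining_angle(c(A = 90, B = 45, C = 45)) # 270
#' @export
remaining_angle <- function(angles) {
  if (inherits(angles, "landmark_triple") || (is.list(angles) && !is.numeric(angles))) {
    angles <- triangle_angles(angles)
  }
  angles <- as.numeric(angles)
  if (length(angles) != 3L || any(!is.finite(angles)) ||
      any(angles < 0) || any(angles > 180)) {
    stop("angles must be three finite values in [0, 180]", call. = FALSE)
  }
  360 - angles[which.max(angles)]
}

unit2 <- function(v, name = "vector") {
  v <- as.numeric(v)
  if (length(v) != 2L || any(!is.finite(v))) {
    stop(name, " must be two finite numbers", call. = FALSE)
  }
  n <- sqrt(sum(v^2))
  if (n <= 0) stop(name, " must be non-zero", call. = FALSE)
  v / n
}

#' Orientation-resolved profile (Lovibond) angle at the nail base
#'
#' The interior angle `thetaA` of triangle ABC cannot tell a nail plate
#' that dips below the phalanx dorsal line (normal, angle < 180) from one
#' that lifts above it (clubbed, angle > 180): both give the same
#' triangle. `profile_angle` resolves the orientation with a dorsal
#' reference direction: when C lies on the dorsal side of the line
#' through A along A->B the angle wraps around the dorsal side and
#' equals `360 - thetaA`; when C lies ventrally it equals `thetaA`;
#' collinear points give exactly 180.
#'
#' @inheritParams side_lengths
#' @param dorsal_outward Length-2 vector: the outward dorsal direction at
#'   A in image coordinates (unit length not required; it is normalised).
#'   For an upright finger profile with the nail on top this is
#'   `c(0, -1)` (y increases downward).
#' @return The profile angle in degrees, in `(0, 360)`.
#' @examples
#' # nail lifted dorsally: clubbed, > 180
#' profile_angle(landmark_triple(c(0, 0), c(-10, 0), c(10, -3.5)), c(0, -1))
#' # nail dipping ventrally: normal, < 180
#' profile_angle(landmark_triple(c(0, 0), c(-10, 0), c(10, 3.5)), c(0, -1))
#' @export
profile_angle <- function(triple, dorsal_outward) {
  triple <- as_triple(triple)
  d <- unit2(dorsal_outward, "dorsal_outward")
  ab <- triple$B - triple$A
  ac <- triple$C - triple$A
  theta_a <- triangle_angles(triple)[["A"]]
  # perpendicular (to AB) component of AC, signed along the dorsal direction
  ab_u <- ab / sqrt(sum(ab^2))
  perp <- ac - sum(ac * ab_u) * ab_u
  side <- sum(perp * d)
  if (abs(side) < 1e-12) return(180)
  if (side > 0) 360 - theta_a else theta_a
}

#' Grading configuration for Lovibond severity
#'
#' @param normal_max Upper bound (degrees) of the normal class; angles up
#'   to this value grade as normal. Default 160.
#' @param moderate_halfwidth Half-width `eps` (degrees) of the moderate
#'   band around 180; the clinically "exactly straight" profile is
#'   measure-zero for continuous landmarks, so moderate is graded as
#'   `|angle - 180| <= eps`. Default 0.5.
#' @param grading_basis Which angle the composite scorer grades:
#'   `"profile"` (orientation-resolved, default) or `"remaining"`
#'   (the literal 360-minus-largest-angle transform).
#' @return An object of class `grading_config`.
#' @export
grading_config <- function(normal_max = 160, moderate_halfwidth = 0.5,
                           grading_basis = c("profile", "remaining")) {
  grading_basis <- match.arg(grading_basis)
  if (!is.finite(normal_max) || normal_max <= 0 || normal_max >= 180) {
    stop("normal_max must be in (0, 180)", call. = FALSE)
  }
  if (!is.finite(moderate_halfwidth) || moderate_halfwidth < 0 ||
      moderate_halfwidth >= 20) {
    stop("moderate_halfwidth must be in [0, 20)", call. = FALSE)
  }
  structure(list(normal_max = normal_max,
                 moderate_halfwidth = moderate_halfwidth,
                 grading_basis = grading_basis),
            class = "grading_config")
}

#' Grade a Lovibond angle into a severity level
#'
#' Four-level grading of the nail-base profile angle: normal for angles
#' up to `normal_max` (default 160), mild between `normal_max` and the
#' moderate band, moderate within `eps` of 180, severe beyond. The
#' mapping is a total monotone step function of the angle.
#'
#' @param angle Angle in degrees, in `(0, 360)`. Vectorised.
#' @param config A [grading_config()].
#' @return Character vector of severity levels (see [severity_levels()]).
#' @examples
#' grade_severity(c(160, 170, 180, 195))
#' @export
grade_severity <- function(angle, config = grading_config()) {
  stopifnot(inherits(config, "grading_config"))
  angle <- as.numeric(angle)
  if (any(!is.finite(angle)) || any(angle <= 0) || any(angle >= 360)) {
    stop("angle must lie in (0, 360) degrees", call. = FALSE)
  }
  eps <- config$moderate_halfwidth
  out <- character(length(angle))
  out[angle <= config$normal_max] <- "normal"
  out[angle > config$normal_max & angle < 180 - eps] <- "mild"
  out[abs(angle - 180) <= eps] <- "moderate"
  out[angle > 180 + eps] <- "severe"
  out
}

#' Clubbed Finger Severity Analysis of a landmark triple
#'
#' The complete scoring step: side lengths, cosine-law interior angles,
#' the remaining angle (360 minus the largest interior angle), the
#' orientation-resolved profile angle, and the graded severity level.
#' Grading uses the profile angle by default; set
#' `grading_basis = "remaining"` in the config to grade the literal
#' remaining angle instead.
#'
#' @inheritParams profile_angle
#' @param config A [grading_config()].
#' @return An object of class `cfsa_result`: list with `sides`, `angles`,
#'   `remaining_angle`, `profile_angle`, `severity`, `grading_basis`,
#'   `graded_angle`.
#' @examples
#' tri <- landmark_triple(c(0, 0), c(-10, 0), c(10, -3.5))
#' cfsa(tri, dorsal_outward = c(0, -1))
#' @export
cfsa <- function(triple, dorsal_outward = c(0, -1), config = grading_config()) {
  triple <- as_triple(triple)
  stopifnot(inherits(config, "grading_config"))
  sides <- side_lengths(triple)
  angles <- triangle_angles(triple)
  rem <- remaining_angle(angles)
  prof <- profile_angle(triple, dorsal_outward)
  graded_angle <- if (config$grading_basis == "profile") prof else rem
  structure(list(triple = triple,
                 sides = sides,
                 angles = angles,
                 remaining_angle = rem,
                 profile_angle = prof,
                 grading_basis = config$grading_basis,
                 graded_angle = graded_angle,
                 severity = grade_severity(graded_angle, config)),
            class = "cfsa_result")
}

#' @export
print.cfsa_result <- function(x, ...) {
  cat("Clubbed Finger Severity Analysis\n")
  cat(sprintf("  interior angles (deg): A = %.3f, B = %.3f, C = %.3f\n",
              x$angles["A"], x$angles["B"], x$angles["C"]))
  cat(sprintf("  remaining angle: %.3f deg\n", x$remaining_angle))
  cat(sprintf("  profile angle:   %.3f deg\n", x$profile_angle))
  cat(sprintf("  severity (%s basis): %s\n", x$grading_basis, x$severity))
  invisible(x)
}

#' @export
summary.cfsa_result <- function(object, ...) {
  print(object, ...)
}

#' Read/write landmark CSV files
#'
#' Landmark files are CSV with header `point,x,y` and one row per point
#' A, B, C, coordinates in 0-based image pixels (y down).
#'
#' @param path File path.
#' @return `read_landmarks` returns a [landmark_triple()];
#'   `write_landmarks` returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("point", "x", "y") %in% names(df))) {
    stop("landmark file must have columns point,x,y: ", path, call. = FALSE)
  }
  rows <- lapply(c("A", "B", "C"), function(nm) {
    i <- which(df$point == nm)
    if (length(i) != 1L) stop("landmark file needs exactly one row for point ",
                              nm, ": ", path, call. = FALSE)
    c(df$x[i], df$y[i])
  })
  landmark_triple(rows[[1]], rows[[2]], rows[[3]])
}

#' @rdname read_landmarks
#' @param triple A [landmark_triple()] to write.
#' @export
write_landmarks <- function(triple, path) {
  triple <- as_triple(triple)
  df <- data.frame(point = c("A", "B", "C"),
                   x = c(triple$A["x"], triple$B["x"], triple$C["x"]),
                   y = c(triple$A["y"], triple$B["y"], triple$C["y"]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a severity-analysis result to JSON
#'
#' @param result A `cfsa_result` from [cfsa()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
cfsa_to_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "cfsa_result"))
  obj <- list(remaining_angle = result$remaining_angle,
              profile_angle = result$profile_angle,
              severity = result$severity,
              angles = list(A = unname(result$angles["A"]),
                            B = unname(result$angles["B"]),
                            C = unname(result$angles["C"])))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
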