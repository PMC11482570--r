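# End-to-end orchestration: image -> ROI -> segmentation -> landmarks
# -> severity. Per-image content problems are captured in the case
# report, never raised, so one bad image cannot abort a batch.

#' Pipeline configuration
#'
#' Nested configuration for the full severity pipeline, with documented
#' defaults for every field. Serialises to/from YAML losslessly.
#'
#' @param segmentation A [segment_config()].
#' @param landmarks A [landmark_config()].
#' @param grading A [grading_config()] (also fixes the grading basis).
#' @param roi_margin Bounding-box margin in pixels for the ROI stage.
#' @param seed Integer seed used for any stochastic step (noise sweeps).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(segmentation = segment_config(),
                            landmarks = landmark_config(),
                            grading = grading_config(),
                            roi_margin = 5,
                            seed = 1L) {
  structure(list(segmentation = segmentation, landmarks = landmarks,
                 grading = grading, roi_margin = roi_margin,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read/write pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   round-tripping through YAML reproduces the configuration exactly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  config_from_list(raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config` to write.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

config_from_list <- function(raw) {
  base <- pipeline_config()
  merge_pipeline_config(base, raw)
}

#' Merge pipeline-configuration overrides
#'
#' Applies overrides with the precedence command-line flag > config
#' file > built-in default: call once with the file contents, then with
#' the flag values.
#'
#' @param config A `pipeline_config`.
#' @param overrides Named list (possibly nested) of fields to replace.
#' @return The merged `pipeline_config`.
#' @export
merge_pipeline_config <- function(config, overrides) {
  if (is.null(overrides)) return(config)
  for (nm in names(overrides)) {
    if (!nm %in% names(config)) {
      stop("unknown configuration field: ", nm, call. = FALSE)
    }
    if (is.list(config[[nm]]) && is.list(overrides[[nm]])) {
      for (sub in names(overrides[[nm]])) {
        if (!sub %in% names(config[[nm]])) {
          stop("unknown configuration field: ", nm, "$", sub, call. = FALSE)
        }
        config[[nm]][[sub]] <- overrides[[nm]][[sub]]
      }
      # re-validate via the constructor
      ctor <- switch(nm, segmentation = segment_config,
                     landmarks = landmark_config, grading = grading_config,
                     NULL)
      if (!is.null(ctor)) config[[nm]] <- do.call(ctor, unclass(config[[nm]]))
    } else {
      config[[nm]] <- overrides[[nm]]
    }
  }
  config
}

read_image_file <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image file: ", path, call. = FALSE)
  }
  img <- tryCatch(png::readPNG(path), error = function(e) {
    stop("cannot read image file: ", path, " (", conditionMessage(e), ")",
         call. = FALSE)
  })
  normalize_image(img)
}

#' Run the severity pipeline on a single image
#'
#' Executes ROI detection, segmentation, landmark extraction and
#' severity scoring, recording per-stage status. Content-level failures
#' (blank image, missing nail, ...) yield a report with the failing
#' stage and reason and no severity; only unreadable files raise.
#'
#' @param image A file path (PNG), a grayscale matrix, or a `phantom`.
#' @param config A [pipeline_config()].
#' @param segmenter Any function `image -> seg_mask` (the segmenter
#'   contract); defaults to [baseline_segment()].
#' @return A `case_report` list: `input`, `box`, `landmarks`, `result`
#'   (a `cfsa_result`), `severity`, `stages` (named status strings),
#'   `failure` (stage + reason or `NULL`), `timing_s`.
#' @export
run_single <- function(image, config = pipeline_config(),
                       segmenter = baseline_segment) {
  t0 <- proc.time()[["elapsed"]]
  input <- if (is.character(image)) image else "<in-memory>"
  if (is.character(image)) {
    image <- read_image_file(image)
  } else if (inherits(image, "phantom")) {
    image <- image$image
  }
  stages <- c(roi = "pending", segment = "pending", landmarks = "pending",
              cfsa = "pending")
  report <- list(input = input, box = NULL, landmarks = NULL, result = NULL,
                 severity = NULL, stages = stages, failure = NULL)
  fail <- function(stage, e) {
    report$stages[[stage]] <- "failed"
    report$failure <- list(stage = stage, reason = conditionMessage(e))
    report$timing_s <- proc.time()[["elapsed"]] - t0
    structure(report, class = "case_report")
  }
  box <- tryCatch(roi_crop(image, margin = config$roi_margin),
                  error = function(e) e)
  if (inherits(box, "error")) return(fail("roi", box))
  report$box <- box
  report$stages[["roi"]] <- "ok"
  cropped <- crop_to_box(image, box)
  mask <- tryCatch(segmenter(cropped), error = function(e) e)
  if (inherits(mask, "error")) return(fail("segment", mask))
  report$stages[["segment"]] <- "ok"
  lm <- tryCatch(extract_landmarks(mask, config$landmarks),
                 error = function(e) e)
  if (inherits(lm, "error")) return(fail("landmarks", lm))
  # map landmarks from the cropped frame back to image coordinates
  off <- c(box$x_min, box$y_min)
  triple <- landmark_triple(lm$triple$A + off, lm$triple$B + off,
                            lm$triple$C + off)
  report$landmarks <- triple
  report$stages[["landmarks"]] <- "ok"
  res <- tryCatch(cfsa(triple, lm$dorsal_outward, config$grading),
                  error = function(e) e)
  if (inherits(res, "error")) return(fail("cfsa", res))
  report$result <- res
  report$severity <- res$severity
  report$stages[["cfsa"]] <- "ok"
  report$timing_s <- proc.time()[["elapsed"]] - t0
  structure(report, class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat("Case report:", x$input, "\n")
  cat("  stages:", paste(names(x$stages), x$stages, sep = "=",
                         collapse = ", "), "\n")
  if (!is.null(x$failure)) {
    cat("  failure at", x$failure$stage, "-", x$failure$reason, "\n")
  } else {
    cat(sprintf("  profile angle %.2f deg -> %s\n",
                x$result$profile_angle, x$severity))
  }
  invisible(x)
}

eval_cases <- function(images, labels, inputs, config, segmenter,
                       failures_as_errors = FALSE) {
  reports <- vector("list", length(images))
  for (i in seq_along(images)) {
    reports[[i]] <- tryCatch(
      run_single(images[[i]], config, segmenter),
      error = function(e) {
        structure(list(input = inputs[i], box = NULL, landmarks = NULL,
                       result = NULL, severity = NULL,
                       stages = c(roi = "failed"),
                       failure = list(stage = "input",
                                      reason = conditionMessage(e)),
                       timing_s = NA_real_),
                  class = "case_report")
      })
  }
  predicted <- vapply(reports, function(r) {
    if (is.null(r$severity)) NA_character_ else r$severity
  }, character(1))
  ok <- !is.na(predicted)
  n_failed <- sum(!ok)
  if (failures_as_errors) {
    # count failures as misclassifications: assign the (wrong by
    # construction) class farthest from the truth
    predicted[!ok] <- ifelse(labels[!ok] == "severe", "normal", "severe")
    ok <- rep(TRUE, length(ok))
  }
  if (!any(ok)) stop("evaluation error: every case failed", call. = FALSE)
  cm <- confusion_matrix(labels[ok], predicted[ok])
  per_case <- data.frame(input = inputs,
                         label = labels,
                         predicted = vapply(reports, function(r) {
                           if (is.null(r$severity)) NA_character_
                           else r$severity
                         }, character(1)),
                         angle = vapply(reports, function(r) {
                           if (is.null(r$result)) NA_real_
                           else r$result$graded_angle
                         }, numeric(1)),
                         status = vapply(reports, function(r) {
                           if (is.null(r$failure)) "ok"
                           else paste0("failed:", r$failure$stage)
                         }, character(1)),
                         stringsAsFactors = FALSE)
  list(confusion = cm, metrics = ovr_metrics(cm), per_case = per_case,
       n_failed = n_failed, reports = reports)
}

#' Batch evaluation against ground-truth labels
#'
#' Runs [run_single()] on every case and tabulates a severity confusion
#' matrix plus one-vs-rest and micro metrics. Failed cases are excluded
#' from the matrix and reported in `n_failed` (set
#' `failures_as_errors = TRUE` to count them as misclassifications
#' instead).
#'
#' @param x A manifest data.frame with columns `image_path` and `label`,
#'   or a list of `phantom` objects (labels taken from the phantoms).
#' @param config A [pipeline_config()].
#' @param segmenter Segmenter-contract function; default
#'   [baseline_segment()].
#' @param failures_as_errors Count failed cases as errors instead of
#'   excluding them.
#' @return List: `confusion`, `metrics` (`ovr_metrics`), `per_case`
#'   data.frame, `n_failed`, `reports`.
#' @export
run_eval <- function(x, config = pipeline_config(),
                     segmenter = baseline_segment,
                     failures_as_errors = FALSE) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0) stop("input error: empty manifest", call. = FALSE)
    if (!all(c("image_path", "label") %in% names(x))) {
      stop("input error: manifest needs columns image_path and label",
           call. = FALSE)
    }
    images <- as.list(x$image_path)
    labels <- x$label
    inputs <- x$image_path
  } else if (is.list(x) && length(x) && inherits(x[[1]], "phantom")) {
    images <- x
    labels <- vapply(x, function(p) p$severity_label, character(1))
    inputs <- sprintf("phantom_%03d", seq_along(x))
  } else {
    stop("input error: expected a manifest data.frame or a list of phantoms",
         call. = FALSE)
  }
  eval_cases(images, labels, inputs, config, segmenter, failures_as_errors)
}

#' Noise-robustness sweep
#'
#' Corrupts every image with seeded salt-and-pepper noise at each
#' density, re-runs the batch evaluation, and tabulates the four
#' metrics per density. Density 0 reproduces the clean evaluation.
#'
#' @param phantoms List of `phantom` objects (corruption is applied to
#'   copies; the originals stay clean).
#' @param densities Noise densities in `[0, 1]`.
#' @param config A [pipeline_config()]; `config$seed` drives the
#'   per-case noise seeds, so the sweep is reproducible.
#' @param segmenter Segmenter-contract function.
#' @return List with `table` (data.frame: density, micro_accuracy,
#'   macro accuracy/sensitivity/specificity/precision, n_failed) and
#'   `runs` (the per-density [run_eval()] results).
#' @export
noise_sweep <- function(phantoms, densities, config = pipeline_config(),
                        segmenter = baseline_segment) {
  if (any(!is.finite(densities)) || any(densities < 0) || any(densities > 1)) {
    stop("range error: densities must lie in [0, 1]", call. = FALSE)
  }
  runs <- list()
  rows <- list()
  for (k in seq_along(densities)) {
    d <- densities[k]
    cases <- phantoms
    if (d > 0) {
      for (i in seq_along(cases)) {
        cases[[i]]$image <- salt_pepper(
          cases[[i]]$image, d,
          seed = (config$seed + 7919L * k + i) %% .Machine$integer.max)
      }
    }
    ev <- run_eval(cases, config, segmenter)
    runs[[k]] <- ev
    rows[[k]] <- data.frame(density = d,
                            micro_accuracy = ev$metrics$micro_accuracy,
                            macro_accuracy = ev$metrics$macro$accuracy,
                            macro_sensitivity = ev$metrics$macro$sensitivity,
                            macro_specificity = ev$metrics$macro$specificity,
                            macro_precision = ev$metrics$macro$precision,
                            n_failed = ev$n_failed)
  }
  list(table = do.call(rbind, rows), runs = runs)
}
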