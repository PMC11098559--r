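#' Default ROI geometry for synthetic fiber image stacks
#'
#' Three rectangular fiber ROIs along a horizontal fiber band plus one
#' background ROI above the fiber, all disjoint, as logical masks.
#'
#' @param frame_shape `c(rows, cols)` of each frame.
#' @return List with elements `fiber` (list of 3 logical matrices) and
#'   `background` (list of 1 logical matrix).
#' @export
default_roi_geometry <- function(frame_shape = c(64, 64)) {
  nr <- frame_shape[1]; nc <- frame_shape[2]
  mask <- function(rows, cols) {
    m <- matrix(FALSE, nr, nc)
    m[rows, cols] <- TRUE
    m
  }
  band <- seq(round(nr * 0.45), round(nr * 0.65))
  thirds <- split(seq_len(nc), cut(seq_len(nc), 3, labels = FALSE))
  fiber <- lapply(thirds, function(cols) mask(band, cols[-c(1, length(cols))]))
  names(fiber) <- paste0("roi", 1:3)
  bg <- mask(seq(2, round(nr * 0.2)), seq(2, nc - 1))
  list(fiber = fiber, background = list(bg1 = bg))
}

check_roi_geometry <- function(roi, frame_shape) {
  if (!is.list(roi) || is.null(roi$fiber) || is.null(roi$background) ||
      length(roi$fiber) < 1L || length(roi$background) < 1L) {
    abort("`roi_geometry` needs >= 1 fiber ROI and >= 1 background ROI.")
  }
  all_masks <- c(roi$fiber, roi$background)
  for (m in all_masks) {
    if (!is.logical(m) || !identical(dim(m), as.integer(frame_shape))) {
      abort("every ROI mask must be a logical matrix matching `frame_shape`.")
    }
    if (!any(m)) abort("empty ROI mask.")
  }
  overlap <- Reduce(`+`, lapply(all_masks, function(m) m * 1L))
  if (any(overlap > 1L)) abort("ROI masks overlap; they must be disjoint.")
  invisible(roi)
}

#' Render a fluorescence trace as a synthetic image stack
#'
#' Builds one frame per time point in which pixels inside the fiber ROIs
#' have mean equal to the trace's raw fluorescence and all other pixels have
#' mean equal to the background level, plus optional Gaussian pixel noise.
#' Averaging the stack over the ROIs recovers the tabular trace (exactly at
#' zero noise), which is what [extract_roi_traces()] does.
#'
#' @param trace A trace tibble from [simulate_decay()] (columns `time_s`,
#'   `raw_fluor`, `background_fluor`).
#' @param frame_shape `c(rows, cols)` per frame.
#' @param roi_geometry ROI masks as produced by [default_roi_geometry()].
#' @param pixel_noise_sd Gaussian pixel noise SD, arbitrary units.
#' @param seed Optional integer seed.
#' @return List with `stack` (array `frames x rows x cols`), `roi_geometry`,
#'   and `time_s`.
#' @export
simulate_image_stack <- function(trace, frame_shape = c(64, 64),
                                 roi_geometry = default_roi_geometry(frame_shape),
                                 pixel_noise_sd = 0, seed = NULL) {
  assert_columns(trace, c("time_s", "raw_fluor", "background_fluor"), "`trace`")
  check_roi_geometry(roi_geometry, frame_shape)
  assert_number(pixel_noise_sd, "pixel_noise_sd", lower = 0)
  nf <- nrow(trace)
  fiber_union <- Reduce(`|`, roi_geometry$fiber)
  with_seed_or_stream(seed, {
    stack <- array(0, dim = c(nf, frame_shape[1], frame_shape[2]))
    for (i in seq_len(nf)) {
      frame <- matrix(trace$background_fluor[i], frame_shape[1], frame_shape[2])
      frame[fiber_union] <- trace$raw_fluor[i]
      if (pixel_noise_sd > 0) {
        frame <- frame + matrix(rnorm(length(frame), 0, pixel_noise_sd),
                                frame_shape[1], frame_shape[2])
      }
      stack[i, , ] <- frame
    }
    list(stack = stack, roi_geometry = roi_geometry, time_s = trace$time_s)
  })
}
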