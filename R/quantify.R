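#' Default analysis windows
#'
#' `baseline_frames()` returns all frames strictly before `drug_frame`;
#' `fccp_frames_window()` the last `n` frames, when the terminal FCCP pulse
#' used to anchor TMRM normalization is active.  Both return 0-based frame
#' indices.
#'
#' @param stack a [frame_stack()] or [segment_stack()] result.
#' @param n window length in frames.
#' @return integer vector of 0-based frame indices.
#' @export
baseline_frames <- function(stack) {
  if (stack$drug_frame < 1L) abort("No frames precede `drug_frame`; cannot form a baseline window.")
  0:(stack$drug_frame - 1L)
}

#' @rdname baseline_frames
#' @export
fccp_frames_window <- function(stack, n = 3) {
  nT <- n_frames(stack)
  (nT - n):(nT - 1L)
}

#' Define functional ROIs from the baseline TMRM channel
#'
#' Mirrors the assay's manual step of selecting regions with functional,
#' polarized mitochondria from the fluorescence channel before treatment:
#' the baseline frames are time-averaged, thresholded with the automatic
#' between-class-variance (Otsu) criterion, labelled with 8-connectivity,
#' and components below `min_roi_px` are dropped.  ROIs are fixed for the
#' whole movie.
#'
#' @param tmrm_stack TMRM [frame_stack()].
#' @param baseline_window 0-based frame indices to average (default: all
#'   frames before `drug_frame`).  Must precede `drug_frame`.
#' @param min_roi_px smallest ROI kept, pixels.
#' @param dilate optional ROI dilation radius in pixels (default 0 = tight).
#' @return object of class `roi_set`: integer `label_map` (0 = none), with
#'   labels contiguous from 1, `roi_ids`, `source_frames`, `min_roi_px`.
#' @export
define_rois <- function(tmrm_stack, baseline_window = NULL, min_roi_px = 20,
                        dilate = 0) {
  stopifnot(inherits(tmrm_stack, "frame_stack"))
  baseline_window <- baseline_window %||% baseline_frames(tmrm_stack)
  if (any(baseline_window >= tmrm_stack$drug_frame)) {
    abort("`baseline_window` must precede `drug_frame`.")
  }
  ref <- apply(tmrm_stack$pixels[, , f2i(baseline_window), drop = FALSE],
               c(1, 2), mean)
  thr <- guarded_otsu(ref)
  if (is.na(thr)) {
    warn("No ROIs found in the baseline TMRM image.")
    lab <- matrix(0L, nrow(ref), ncol(ref))
  } else {
    mask <- drop_small_components(ref >= thr, min_roi_px)
    if (dilate > 0) {
      mask <- EBImage::dilate(mask * 1,
                              EBImage::makeBrush(2 * dilate + 1, "disc")) > 0
    }
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_roi_px)
    lab[!(lab %in% keep)] <- 0L
    lab[lab > 0L] <- match(lab[lab > 0L], keep)
  }
  structure(list(label_map = lab, roi_ids = seq_len(max(lab)),
                 source_frames = baseline_window, min_roi_px = min_roi_px),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs (min %d px) from baseline frames %d..%d\n",
              length(x$roi_ids), x$min_roi_px, min(x$source_frames),
              max(x$source_frames)))
  invisible(x)
}

roi_pixel_index <- function(roi_set) {
  split(which(roi_set$label_map > 0L), roi_set$label_map[roi_set$label_map > 0L])
}

#' Per-ROI mitochondrial area traces
#'
#' For each ROI and frame, counts the mitochondrion-mask pixels inside the
#' ROI and divides by the ROI's mean over the baseline window, so the
#' baseline of every trace averages exactly 1.  A permeabilization event
#' appears as the fraction collapsing toward 0; in depolarization-only
#' conditions it stays near 1.
#'
#' @param mask_stack a [segment_stack()] result.
#' @param roi_set a [define_rois()] result.
#' @param baseline_window 0-based frames for the baseline mean (default: all
#'   frames before `drug_frame`).
#' @return tibble: `roi_id, frame, time_s, area_px, area_fraction, valid`.
#'   ROIs with zero baseline area are flagged `valid = FALSE` (their
#'   `area_fraction` is `NA`) and are excluded from statistics downstream.
#' @export
area_trace <- function(mask_stack, roi_set, baseline_window = NULL) {
  stopifnot(inherits(mask_stack, "mask_stack"), inherits(roi_set, "roi_set"))
  baseline_window <- baseline_window %||% baseline_frames(mask_stack)
  nT <- dim(mask_stack$masks)[3]
  idx <- roi_pixel_index(roi_set)
  npix <- prod(dim(mask_stack$masks)[1:2])
  counts <- vapply(seq_len(nT), function(k) {
    mk <- mask_stack$masks[, , k]
    vapply(idx, function(px) sum(mk[px]), numeric(1))
  }, numeric(length(idx)))
  counts <- matrix(counts, nrow = length(idx))  # roi x frame
  base_mean <- rowMeans(counts[, f2i(baseline_window), drop = FALSE])
  valid <- base_mean > 0
  if (any(!valid)) {
    warn(sprintf("%d ROI(s) have zero baseline mask area and are flagged invalid.",
                 sum(!valid)))
  }
  frac <- sweep(counts, 1, ifelse(valid, base_mean, NA_real_), "/")
  tibble(
    roi_id = rep(as.integer(names(idx)), times = nT),
    frame = rep(0:(nT - 1L), each = length(idx)),
    time_s = rep((0:(nT - 1L)) * mask_stack$frame_interval, each = length(idx)),
    area_px = as.vector(counts),
    area_fraction = as.vector(frac),
    valid = rep(valid, times = nT)
  ) |> arrange(.data$roi_id, .data$frame)
}

#' Per-ROI mean TMRM intensity traces
#'
#' Arithmetic mean of the TMRM channel over each ROI's pixels, per frame.
#'
#' @param tmrm_stack TMRM [frame_stack()].
#' @param roi_set a [define_rois()] result.
#' @return tibble: `roi_id, frame, time_s, tmrm_raw`.
#' @export
tmrm_trace <- function(tmrm_stack, roi_set) {
  stopifnot(inherits(tmrm_stack, "frame_stack"), inherits(roi_set, "roi_set"))
  nT <- n_frames(tmrm_stack)
  idx <- roi_pixel_index(roi_set)
  means <- vapply(seq_len(nT), function(k) {
    fr <- tmrm_stack$pixels[, , k]
    vapply(idx, function(px) mean(fr[px]), numeric(1))
  }, numeric(length(idx)))
  means <- matrix(means, nrow = length(idx))
  tibble(
    roi_id = rep(as.integer(names(idx)), times = nT),
    frame = rep(0:(nT - 1L), each = length(idx)),
    time_s = rep((0:(nT - 1L)) * tmrm_stack$frame_interval, each = length(idx)),
    tmrm_raw = as.vector(means)
  ) |> arrange(.data$roi_id, .data$frame)
}

#' FCCP-anchored normalization of TMRM traces
#'
#' Rescales each ROI's raw TMRM trace to the dimensionless potential scale
#' using the two in-experiment anchors: the pre-drug baseline (fully
#' polarized, mapped to 1) and the terminal FCCP window (fully depolarized,
#' mapped to 0):
#' \deqn{F_{norm}(t) = (F(t) - \bar F_{FCCP}) / (\bar F_{base} - \bar F_{FCCP})}
#' The result is invariant under positive rescaling of the raw intensities.
#' Traces whose anchor separation falls below `floor_factor` times the
#' trace's noise sd (estimated from first differences of the baseline) are
#' flagged non-normalizable and get `NA`.
#'
#' @param trace tibble with `roi_id, frame, tmrm_raw` (e.g. [tmrm_trace()]).
#' @param baseline_window,fccp_window 0-based frame windows; must not
#'   overlap.
#' @param floor_factor multiple of the noise sd the anchor separation must
#'   exceed (default 3).
#' @return the input tibble with `tmrm_norm` and `normalizable` columns.
#' @export
normalize_tmrm <- function(trace, baseline_window, fccp_window,
                           floor_factor = 3) {
  stopifnot(all(c("roi_id", "frame", "tmrm_raw") %in% names(trace)))
  if (length(intersect(baseline_window, fccp_window)) > 0) {
    abort("`baseline_window` and `fccp_window` must not overlap.")
  }
  trace |>
    group_by(.data$roi_id) |>
    mutate(
      .f_base = mean(.data$tmrm_raw[.data$frame %in% baseline_window]),
      .f_fccp = mean(.data$tmrm_raw[.data$frame %in% fccp_window]),
      .noise = {
        b <- .data$tmrm_raw[.data$frame %in% baseline_window]
        if (length(b) > 2) sd(diff(b)) / sqrt(2) else 0
      },
      normalizable = (.data$.f_base - .data$.f_fccp) > floor_factor * .data$.noise,
      tmrm_norm = ifelse(.data$normalizable,
                         (.data$tmrm_raw - .data$.f_fccp) /
                           (.data$.f_base - .data$.f_fccp),
                         NA_real_)
    ) |>
    ungroup() |>
    select(-".f_base", -".f_fccp", -".noise")
}

#' Full tidy trace table for one movie
#'
#' Convenience wrapper joining [area_trace()], [tmrm_trace()] and
#' [normalize_tmrm()] into one tidy table (one row per ROI x frame).
#'
#' @param mask_stack segmented RI masks ([segment_stack()]).
#' @param tmrm_stack TMRM [frame_stack()].
#' @param roi_set a [define_rois()] result.
#' @param baseline_window,fccp_window 0-based frame windows (defaults: all
#'   pre-drug frames; last 3 frames).
#' @return tibble: `roi_id, frame, time_s, area_px, area_fraction, valid,
#'   tmrm_raw, tmrm_norm, normalizable`.
#' @export
mito_traces <- function(mask_stack, tmrm_stack, roi_set,
                        baseline_window = NULL, fccp_window = NULL) {
  baseline_window <- baseline_window %||% baseline_frames(tmrm_stack)
  fccp_window <- fccp_window %||% fccp_frames_window(tmrm_stack)
  at <- area_trace(mask_stack, roi_set, baseline_window)
  tt <- tmrm_trace(tmrm_stack, roi_set) |>
    normalize_tmrm(baseline_window, fccp_window)
  left_join(at, select(tt, "roi_id", "frame", "tmrm_raw", "tmrm_norm",
                       "normalizable"),
            by = c("roi_id", "frame"))
}
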