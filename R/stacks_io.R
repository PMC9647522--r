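#' Construct a time-lapse frame stack
#'
#' A `frame_stack` holds one channel of a time-lapse experiment: a
#' `H x W x T` array of nonnegative intensities in `[0, 1]` plus the
#' acquisition metadata needed to interpret it.  Frame indices are 0-based
#' throughout the package: frame `k` is acquired at `k * frame_interval`
#' seconds, with frame 0 at `t = 0`.
#'
#' @param pixels numeric array `H x W x T` (a matrix is treated as `T = 1`)
#'   with values in `[0, 1]`; intensities are stored as 16-bit grayscale
#'   on disk.
#' @param channel channel tag, `"RI"` (refractive index) or `"TMRM"`.
#' @param frame_interval seconds between frames (default 15, the assay's
#'   acquisition rate).
#' @param drug_frame 0-based index of the frame at which the compound
#'   (ferutinin or FCCP) is added.
#' @param pixel_size optional pixel size in micrometers.
#' @param provenance free-text metadata.
#'
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(pixels, channel = c("RI", "TMRM"), frame_interval = 15,
                        drug_frame = 0L, pixel_size = NULL, provenance = "") {
  channel <- match.arg(channel)
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    abort("`pixels` must be an H x W x T array (or an H x W matrix).")
  }
  if (any(pixels < 0, na.rm = TRUE)) abort("Intensities must be nonnegative.")
  if (frame_interval <= 0) abort("`frame_interval` must be > 0.")
  nT <- dim(pixels)[3]
  if (nT < 1L) abort("A frame stack needs at least one frame.")
  drug_frame <- as.integer(drug_frame)
  if (drug_frame < 0L || drug_frame >= nT) {
    abort(sprintf("`drug_frame` must lie in [0, %d).", nT))
  }
  structure(
    list(pixels = pixels, channel = channel,
         frame_interval = frame_interval, drug_frame = drug_frame,
         pixel_size = pixel_size, provenance = provenance),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<frame_stack> channel %s: %d frames of %d x %d px, dt = %g s, drug at frame %d (t = %g s)\n",
    x$channel, d[3], d[1], d[2], x$frame_interval, x$drug_frame,
    x$drug_frame * x$frame_interval))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a `frame_stack` or `mask_stack`.
#' @return integer frame count `T`.
#' @export
n_frames <- function(stack) {
  d <- if (inherits(stack, "mask_stack")) dim(stack$masks) else dim(stack$pixels)
  d[3]
}

#' Acquisition times of a stack
#' @param stack a `frame_stack`.
#' @return numeric vector of times in seconds, one per frame.
#' @export
frame_times <- function(stack) {
  (seq_len(n_frames(stack)) - 1) * stack$frame_interval
}

#' Extract one frame as a matrix
#' @param stack a `frame_stack`.
#' @param frame 0-based frame index.
#' @return `H x W` numeric matrix.
#' @export
get_frame <- function(stack, frame) {
  stopifnot(frame >= 0, frame < n_frames(stack))
  stack$pixels[, , f2i(frame)]
}

#' Read a multipage TIFF time-lapse into a frame stack
#'
#' Pages are taken in file order as consecutive frames.  Intensities are
#' returned as stored (16-bit grayscale maps to `[0, 1]` in steps of
#' 1/65535), so a [write_stack()] / `read_stack()` round trip is exact.
#'
#' @param path path to a multipage TIFF with constant page shape.
#' @param channel,frame_interval,drug_frame,pixel_size,provenance metadata
#'   passed to [frame_stack()]; alternatively supply `metadata`, a named list
#'   (e.g. read from a sidecar file) whose entries override these.
#' @param metadata optional named list of metadata overrides.
#' @return a [frame_stack()].
#' @export
read_stack <- function(path, channel = "RI", frame_interval = 15,
                       drug_frame = 0L, pixel_size = NULL, provenance = NULL,
                       metadata = NULL) {
  if (!file.exists(path)) abort(sprintf("Stack file not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      abort(sprintf("Could not read TIFF '%s': %s", path,
                                    conditionMessage(e)))
                    })
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) abort(sprintf("TIFF '%s' contains zero pages.", path))
  shp <- dim(pages[[1]])
  for (k in seq_along(pages)) {
    if (!identical(dim(pages[[k]]), shp)) {
      abort(sprintf("TIFF '%s': page %d has shape %s, expected %s.",
                    path, k, paste(dim(pages[[k]]), collapse = "x"),
                    paste(shp, collapse = "x")))
    }
  }
  px <- array(unlist(pages, use.names = FALSE), dim = c(shp, length(pages)))
  meta <- list(channel = channel, frame_interval = frame_interval,
               drug_frame = drug_frame, pixel_size = pixel_size,
               provenance = provenance %||% basename(path))
  if (!is.null(metadata)) meta <- modifyList(meta, metadata)
  frame_stack(px, channel = meta$channel, frame_interval = meta$frame_interval,
              drug_frame = meta$drug_frame, pixel_size = meta$pixel_size,
              provenance = meta$provenance)
}

#' Write a frame stack to a multipage TIFF
#'
#' One 16-bit grayscale page per frame.  Values are clamped to `[0, 1]` and
#' quantized to 1/65535 steps; data already on that grid round-trips
#' losslessly.
#'
#' @param stack a [frame_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  if (any(stack$pixels < 0)) abort("Negative intensities cannot be written.")
  px <- pmin(stack$pixels, 1)
  pages <- lapply(seq_len(n_frames(stack)), function(k) px[, , k])
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                 error = function(e) {
                   abort(sprintf("Could not write TIFF '%s': %s", path,
                                 conditionMessage(e)))
                 })
  invisible(path)
}

#' Maximum-intensity projection over z
#'
#' Collapses a `Z x H x W` volume (or `H x W x Z` with `z_axis = 3`) to a
#' planar image by the pixelwise maximum over the selected planes — the
#' standard reduction of a holographic z-stack to the 2-D refractive-index
#' image used for segmentation.
#'
#' @param volume 3-D numeric array.
#' @param z_range integer vector of 1-based plane indices to project over
#'   (default: all planes).
#' @param z_axis which array dimension indexes z (1 or 3; default 1).
#' @return `H x W` matrix of pixelwise maxima.
#' @export
max_project <- function(volume, z_range = NULL, z_axis = 1L) {
  if (is.matrix(volume)) return(volume)
  stopifnot(is.array(volume), length(dim(volume)) == 3L, z_axis %in% c(1L, 3L))
  nz <- dim(volume)[z_axis]
  z_range <- z_range %||% seq_len(nz)
  if (length(z_range) == 0L) abort("`z_range` must select at least one plane.")
  if (any(z_range < 1L | z_range > nz)) {
    abort(sprintf("`z_range` out of bounds: volume has %d planes.", nz))
  }
  if (z_axis == 1L) {
    apply(volume[z_range, , , drop = FALSE], c(2, 3), max)
  } else {
    apply(volume[, , z_range, drop = FALSE], c(1, 2), max)
  }
}
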