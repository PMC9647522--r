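#' Label connected components with 8-connectivity
#'
#' Foreground pixels touching edge- or corner-wise belong to one component.
#' Implemented as 4-connected labelling followed by union-find merging of
#' labels that touch diagonally.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of component labels, contiguous from 1.
#' @export
label_components <- function(mask) {
  m <- mask > 0
  lab <- EBImage::bwlabel(m * 1)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  # pairs of 4-connected labels in diagonal contact
  a1 <- lab[-nrow(lab), -ncol(lab)]; b1 <- lab[-1, -1]       # down-right
  a2 <- lab[-nrow(lab), -1]; b2 <- lab[-1, -ncol(lab)]       # down-left
  pa <- c(a1, a2); pb <- c(b1, b2)
  keep <- pa > 0L & pb > 0L & pa != pb
  parent <- seq_len(nl)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (any(keep)) {
    for (j in which(keep)) {
      ra <- find(pa[j]); rb <- find(pb[j])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nl), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# Gaussian blur whose kernel is capped to fit the image (EBImage's brush
# must not exceed the image dimensions).
safe_gblur <- function(x, sigma) {
  max_sigma <- (min(dim(x)) - 3) / 6.5
  EBImage::gblur(x, sigma = min(sigma, max_sigma))
}

#' Multiscale filter bank features for pixel classification
#'
#' Computes one feature plane per `(filter, scale)` pair, the same kind of
#' generic texture/edge features interactive pixel-classification tools use.
#' Supported kinds: `gaussian` (smoothing), `gradient` (Gaussian-gradient
#' magnitude), `laplacian` (Laplacian of Gaussian), `hessian` (largest-
#' magnitude eigenvalue of the Hessian of the smoothed image), `dog`
#' (difference of Gaussians, scale vs `1.6 * scale`).
#'
#' @param frame 2-D numeric matrix.
#' @param feature_spec list of `list(kind, scale)` entries; scales in pixels,
#'   > 0.
#' @return `H x W x n_features` array with dimnames on the feature axis.
#' @export
compute_features <- function(frame, feature_spec = default_feature_spec()) {
  stopifnot(is.matrix(frame), length(feature_spec) >= 1)
  planes <- lapply(feature_spec, function(fs) {
    kind <- fs$kind %||% fs[[1]]
    scale <- fs$scale %||% fs[[2]]
    if (scale <= 0) abort("Feature scales must be > 0.")
    sm <- safe_gblur(frame, sigma = scale)
    switch(kind,
      gaussian = sm,
      gradient = {
        gy <- (rbind(sm[-1, ], sm[nrow(sm), ]) - rbind(sm[1, ], sm[-nrow(sm), ])) / 2
        gx <- (cbind(sm[, -1], sm[, ncol(sm)]) - cbind(sm[, 1], sm[, -ncol(sm)])) / 2
        sqrt(gx^2 + gy^2)
      },
      laplacian = {
        k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
        as.matrix(EBImage::filter2(sm, k))
      },
      hessian = {
        k_yy <- matrix(c(0, 1, 0, 0, -2, 0, 0, 1, 0), 3, 3)
        k_xx <- t(k_yy)
        k_xy <- matrix(c(0.25, 0, -0.25, 0, 0, 0, -0.25, 0, 0.25), 3, 3)
        hyy <- as.matrix(EBImage::filter2(sm, k_yy))
        hxx <- as.matrix(EBImage::filter2(sm, k_xx))
        hxy <- as.matrix(EBImage::filter2(sm, k_xy))
        tr <- hxx + hyy
        disc <- sqrt(pmax((hxx - hyy)^2 / 4 + hxy^2, 0))
        e1 <- tr / 2 + disc
        e2 <- tr / 2 - disc
        ifelse(abs(e1) >= abs(e2), e1, e2)
      },
      dog = sm - safe_gblur(frame, sigma = 1.6 * scale),
      abort(sprintf(
        "Unknown filter kind '%s'. Supported: gaussian, gradient, laplacian, hessian, dog.",
        kind))
    )
  })
  nm <- vapply(feature_spec, function(fs) {
    sprintf("%s_s%g", fs$kind %||% fs[[1]], fs$scale %||% fs[[2]])
  }, character(1))
  out <- array(unlist(planes), dim = c(dim(frame), length(planes)))
  dimnames(out) <- list(NULL, NULL, nm)
  out
}

#' @rdname compute_features
#' @export
default_feature_spec <- function() {
  list(list(kind = "gaussian", scale = 1), list(kind = "gaussian", scale = 2),
       list(kind = "gaussian", scale = 4), list(kind = "gradient", scale = 1),
       list(kind = "gradient", scale = 2), list(kind = "laplacian", scale = 2),
       list(kind = "dog", scale = 2))
}

features_to_df <- function(feat) {
  d <- dim(feat)
  df <- as.data.frame(matrix(feat, d[1] * d[2], d[3]))
  names(df) <- dimnames(feat)[[3]]
  df
}

#' Train a supervised pixel classifier from scribbles
#'
#' Random-forest classifier over the multiscale filter-bank features of
#' [compute_features()], trained from sparse user scribbles — the in-package
#' equivalent of an interactively trained pixel-classification tool.
#'
#' @param frames a single matrix or list of matrices (training frames).
#' @param scribbles matching label matrix/list: 0 = unlabeled, 1 =
#'   mitochondrion, 2 = background.
#' @param feature_spec see [compute_features()].
#' @param seed RNG seed; training is deterministic given the seed.
#' @param holdout_frac fraction of scribble pixels held out to report
#'   accuracy (default 0.2).
#' @param num_trees forest size.
#' @return object of class `pixel_classifier` with a `train_summary` (class
#'   counts, holdout accuracy).
#' @export
train_pixel_classifier <- function(frames, scribbles,
                                   feature_spec = default_feature_spec(),
                                   seed = 1, holdout_frac = 0.2,
                                   num_trees = 100) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.matrix(scribbles)) scribbles <- list(scribbles)
  stopifnot(length(frames) == length(scribbles))
  dfs <- purrr::map2(frames, scribbles, function(fr, sc) {
    stopifnot(identical(dim(fr), dim(sc)))
    idx <- which(sc != 0)
    if (length(idx) == 0) return(NULL)
    feat <- compute_features(fr, feature_spec)
    cbind(features_to_df(feat)[idx, , drop = FALSE],
          .class = c("mito", "background")[sc[idx]])
  })
  train <- dplyr::bind_rows(dfs)
  counts <- table(train$.class)
  if (length(counts) < 2L) {
    abort("Scribbles must label at least one pixel of each class (1 = mito, 2 = background).")
  }
  with_seed(seed, {
    n <- nrow(train)
    hold <- sample.int(n, size = max(1L, floor(holdout_frac * n)))
    fit <- ranger::ranger(
      x = train[-hold, setdiff(names(train), ".class"), drop = FALSE],
      y = factor(train$.class[-hold], levels = c("background", "mito")),
      num.trees = num_trees, probability = TRUE, seed = seed
    )
    pred <- predict(fit, train[hold, setdiff(names(train), ".class"),
                               drop = FALSE])$predictions
    acc <- mean((pred[, "mito"] >= 0.5) == (train$.class[hold] == "mito"))
  })
  structure(
    list(model = fit, feature_spec = feature_spec,
         train_summary = list(class_counts = counts, holdout_accuracy = acc,
                              n_train = nrow(train))),
    class = "pixel_classifier"
  )
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "<pixel_classifier> random forest over %d features; trained on %d px (mito %d / background %d); holdout accuracy %.3f\n",
    length(x$feature_spec), x$train_summary$n_train,
    x$train_summary$class_counts[["mito"]],
    x$train_summary$class_counts[["background"]],
    x$train_summary$holdout_accuracy))
  invisible(x)
}

#' Per-pixel mitochondrion probability map
#'
#' @param classifier a [train_pixel_classifier()] object.
#' @param frame 2-D matrix on the same channel conventions as training.
#' @return `H x W` matrix of probabilities in `[0, 1]`.
#' @export
predict_probability <- function(classifier, frame) {
  stopifnot(inherits(classifier, "pixel_classifier"), is.matrix(frame))
  feat <- compute_features(frame, classifier$feature_spec)
  pred <- predict(classifier$model, features_to_df(feat))$predictions
  matrix(pred[, "mito"], nrow(frame), ncol(frame))
}

#' Binarize a probability map (or raw frame) with a size filter
#'
#' Threshold at `>= threshold`, then remove 8-connected components smaller
#' than `min_object_px` — the equivalent of a make-binary step followed by a
#' particle-size filter.
#'
#' @param x numeric matrix (probability map in `[0, 1]` or raw frame).
#' @param threshold decision threshold; must lie in (0, 1) for probability
#'   maps.
#' @param min_object_px smallest component kept, in pixels.
#' @return logical matrix.
#' @export
binarize <- function(x, threshold = 0.5, min_object_px = 10) {
  stopifnot(is.matrix(x))
  mask <- x >= threshold
  drop_small_components(mask, min_object_px)
}

drop_small_components <- function(mask, min_object_px) {
  if (min_object_px <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_object_px)
  lab %in% keep & mask
}

# Otsu threshold with a separation guard: on a frame with no real foreground
# (e.g. after every organelle has permeabilized) Otsu lands inside the noise
# and would segment about half the pixels.  Require the threshold to clear
# the background mode (pixels below the candidate threshold) by 4 robust
# sds, else return NA (no foreground).
guarded_otsu <- function(frame) {
  rng <- range(frame)
  if (diff(rng) < .Machine$double.eps^0.5) return(NA_real_)
  thr <- EBImage::otsu(EBImage::Image(frame), range = rng)
  bg <- frame[frame < thr]
  if (length(bg) < 2) return(thr)
  spread <- mad(bg)
  if (spread == 0) spread <- sd(bg)
  if (spread == 0) return(thr)  # perfectly clean background
  if (thr < median(bg) + 4 * spread) return(NA_real_)
  thr
}

#' Threshold-based segmentation of a refractive-index frame
#'
#' The classifier-free fallback: large-scale background subtraction
#' (Gaussian, `bg_sigma`), automatic global threshold by the between-class-
#' variance (Otsu) criterion with a separation guard, then the component
#' size filter.  With `invert = TRUE` the frame's contrast is flipped first,
#' so inverted-polarity images give the same mask.
#'
#' @param frame 2-D numeric matrix.
#' @param min_object_px smallest component kept.
#' @param bg_sigma background-smoothing scale in pixels (0 disables
#'   subtraction).
#' @param invert flip contrast polarity before thresholding.
#' @param threshold optional fixed threshold (on the background-subtracted
#'   image); bypasses Otsu.  Used to apply one movie-level threshold to
#'   every frame.
#' @return logical mask.
#' @export
threshold_segment <- function(frame, min_object_px = 10, bg_sigma = 25,
                              invert = FALSE, threshold = NULL) {
  stopifnot(is.matrix(frame))
  if (invert) frame <- max(frame) - frame
  if (diff(range(frame)) < .Machine$double.eps^0.5) {
    warn("Constant frame: returning an empty mask.")
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  work <- if (bg_sigma > 0) frame - safe_gblur(frame, sigma = bg_sigma) else frame
  thr <- threshold %||% guarded_otsu(work)
  if (is.na(thr)) return(matrix(FALSE, nrow(frame), ncol(frame)))
  drop_small_components(work >= thr, min_object_px)
}

#' Segment every frame of an RI stack into a mask stack
#'
#' With a classifier, each frame is scored by [predict_probability()] and
#' binarized at `prob_threshold`.  Without one, a single movie-level Otsu
#' threshold is derived from the mean pre-drug (baseline) frame after
#' background subtraction and applied to every frame — per-frame masks stay
#' independent (no temporal smoothing), but the decision boundary is shared
#' so organelle disappearance is read on a fixed scale.
#'
#' @param stack RI [frame_stack()].
#' @param classifier optional [train_pixel_classifier()] object.
#' @param prob_threshold binarization threshold for probability maps.
#' @param min_object_px component size filter (8-connectivity).
#' @param bg_sigma background-subtraction scale for the threshold method.
#' @return object of class `mask_stack`: logical `H x W x T` array plus the
#'   filter settings and `source` (`"classifier"` or `"threshold"`).
#' @export
segment_stack <- function(stack, classifier = NULL, prob_threshold = 0.5,
                          min_object_px = 10, bg_sigma = 25) {
  stopifnot(inherits(stack, "frame_stack"))
  nT <- n_frames(stack)
  d <- dim(stack$pixels)
  masks <- array(FALSE, d)
  if (!is.null(classifier)) {
    for (k in seq_len(nT)) {
      masks[, , k] <- binarize(predict_probability(classifier, stack$pixels[, , k]),
                               prob_threshold, min_object_px)
    }
    src <- "classifier"
  } else {
    base <- baseline_frames(stack)
    ref <- apply(stack$pixels[, , f2i(base), drop = FALSE], c(1, 2), mean)
    ref_w <- if (bg_sigma > 0) ref - safe_gblur(ref, sigma = bg_sigma) else ref
    thr <- guarded_otsu(ref_w)
    if (is.na(thr)) {
      warn("No foreground detected in the baseline frame; masks are empty.")
      src <- "threshold"
    } else {
      for (k in seq_len(nT)) {
        masks[, , k] <- threshold_segment(stack$pixels[, , k],
                                          min_object_px = min_object_px,
                                          bg_sigma = bg_sigma,
                                          threshold = thr)
      }
      src <- "threshold"
    }
  }
  structure(list(masks = masks, min_object_px = min_object_px, source = src,
                 frame_interval = stack$frame_interval,
                 drug_frame = stack$drug_frame),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("<mask_stack> %d frames of %d x %d px (%s, min object %d px)\n",
              d[3], d[1], d[2], x$source, x$min_object_px))
  invisible(x)
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical masks, and defined as 1 when
#' both masks are empty.
#'
#' @param a,b logical matrices of equal shape.
#' @return numeric in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
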