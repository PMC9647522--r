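#' Track single organelles through the mask stack
#'
#' Greedy frame-to-frame linking of 8-connected mask components by maximal
#' mask overlap: a component in frame `k` is linked to the active track
#' whose last-seen component it overlaps with the highest
#' intersection-over-union, provided `IoU >= min_iou`.  Equal IoU is broken
#' by nearest centroid, then by lowest component label.  A track unmatched
#' for more than `gap_frames` consecutive frames terminates: as
#' `"disappeared"` when its last footprint stays essentially empty to the
#' movie end (the refractive-index signature of permeabilization), else as
#' `"lost"`.  Tracks alive in the final frame terminate as `"movie_end"`.
#'
#' @param mask_stack a [segment_stack()] result.
#' @param min_iou minimum overlap to link (default 0.3).
#' @param gap_frames frames a track may go unmatched before termination
#'   (default 1).
#' @param shrink_containment containment fraction (component-in-footprint)
#'   that links a shrinking component when its IoU falls below `min_iou`
#'   (default 0.6); this keeps a collapsing organelle inside one track.
#' @param reappear_frac fraction of the last footprint that must stay
#'   foreground-free for a termination to count as `"disappeared"`
#'   (default 0.1).
#' @return a tibble of class `mito_tracks`, one row per (track, frame):
#'   `track_id, frame, time_s, y, x, area_px`, with the per-track summary
#'   (`track_id, first_frame, last_seen_frame, termination`) as attribute
#'   `"summary"`, retrievable with [track_summary()].
#' @export
track_organelles <- function(mask_stack, min_iou = 0.3, gap_frames = 1,
                             shrink_containment = 0.6, reappear_frac = 0.1) {
  stopifnot(inherits(mask_stack, "mask_stack"))
  nT <- dim(mask_stack$masks)[3]
  if (nT == 0) abort("Empty mask stack.")
  H <- dim(mask_stack$masks)[1]

  comp_per_frame <- lapply(seq_len(nT), function(k) {
    lab <- label_components(mask_stack$masks[, , k])
    if (max(lab) == 0) return(list())
    px <- split(which(lab > 0L), lab[lab > 0L])
    lapply(px, function(p) {
      list(px = p, area = length(p),
           y = mean((p - 1) %% H + 1), x = mean((p - 1) %/% H + 1))
    })
  })

  tracks <- list()   # each: list(rows = list, last_px, last_y, last_x,
                     #            last_frame(0-based), active, miss, termination)
  next_id <- 1L

  for (k0 in 0:(nT - 1L)) {
    comps <- comp_per_frame[[f2i(k0)]]
    active <- which(vapply(tracks, function(tr) tr$active, logical(1)))
    matched_comp <- rep(FALSE, length(comps))
    if (length(active) > 0 && length(comps) > 0) {
      # candidate (track, component, iou, centroid distance) table
      cand <- list()
      for (ti in active) {
        tr <- tracks[[ti]]
        for (ci in seq_along(comps)) {
          inter <- length(intersect(tr$last_px, comps[[ci]]$px))
          if (inter == 0) next
          iou <- inter / (length(tr$last_px) + comps[[ci]]$area - inter)
          # shrink fallback: a collapsing organelle's remnant can drop below
          # the IoU cut while lying entirely inside the previous footprint;
          # containment keeps the collapse within one track
          contained <- inter / comps[[ci]]$area
          shrinking <- comps[[ci]]$area <= length(tr$last_px)
          if (iou >= min_iou || (shrinking && contained >= shrink_containment)) {
            d <- sqrt((tr$last_y - comps[[ci]]$y)^2 +
                        (tr$last_x - comps[[ci]]$x)^2)
            cand[[length(cand) + 1L]] <- c(ti, ci, iou, d)
          }
        }
      }
      if (length(cand) > 0) {
        cm <- do.call(rbind, cand)
        # greedy: best IoU first; ties by nearest centroid, then lowest label
        ord <- order(-cm[, 3], cm[, 4], cm[, 2])
        used_t <- integer(0); used_c <- integer(0)
        for (r in ord) {
          ti <- cm[r, 1]; ci <- cm[r, 2]
          if (ti %in% used_t || ci %in% used_c) next
          used_t <- c(used_t, ti); used_c <- c(used_c, ci)
          co <- comps[[ci]]
          tracks[[ti]]$rows[[length(tracks[[ti]]$rows) + 1L]] <-
            c(frame = k0, y = co$y, x = co$x, area = co$area)
          tracks[[ti]]$last_px <- co$px
          tracks[[ti]]$last_y <- co$y; tracks[[ti]]$last_x <- co$x
          tracks[[ti]]$last_frame <- k0
          tracks[[ti]]$miss <- 0L
          matched_comp[ci] <- TRUE
        }
      }
    }
    # unmatched active tracks accrue a miss; terminate past the gap
    for (ti in seq_along(tracks)) {
      tr <- tracks[[ti]]
      if (!tr$active || tr$last_frame == k0) next
      tracks[[ti]]$miss <- tr$miss + 1L
      if (tracks[[ti]]$miss > gap_frames) tracks[[ti]]$active <- FALSE
    }
    # unmatched components found new tracks
    for (ci in seq_along(comps)) {
      if (matched_comp[ci]) next
      co <- comps[[ci]]
      tracks[[next_id]] <- list(
        rows = list(c(frame = k0, y = co$y, x = co$x, area = co$area)),
        last_px = co$px, last_y = co$y, last_x = co$x,
        last_frame = k0, active = TRUE, miss = 0L)
      next_id <- next_id + 1L
    }
  }

  # classify terminations
  summ <- purrr::imap(tracks, function(tr, id) {
    first <- tr$rows[[1]]["frame"]
    last <- tr$last_frame
    term <- if (tr$active || last == nT - 1L) {
      "movie_end"
    } else {
      # does foreground reappear in the last footprint after loss?
      later <- (last + 2L):nT  # 1-based slice indices after last seen + gap
      occ <- vapply(later, function(s) {
        mean(mask_stack$masks[, , s][tr$last_px])
      }, numeric(1))
      if (all(occ <= reappear_frac)) "disappeared" else "lost"
    }
    tibble(track_id = id, first_frame = as.integer(first),
           last_seen_frame = as.integer(last), termination = term)
  }) |> bind_rows()

  rows <- purrr::imap(tracks, function(tr, id) {
    m <- do.call(rbind, tr$rows)
    tibble(track_id = id, frame = as.integer(m[, "frame"]),
           time_s = m[, "frame"] * mask_stack$frame_interval,
           y = m[, "y"], x = m[, "x"], area_px = m[, "area"])
  }) |> bind_rows() |> arrange(.data$track_id, .data$frame)

  structure(rows, class = c("mito_tracks", class(rows)),
            summary = summ, n_frames = nT,
            frame_interval = mask_stack$frame_interval,
            drug_frame = mask_stack$drug_frame)
}

#' @rdname track_organelles
#' @param tracks a `mito_tracks` object.
#' @export
track_summary <- function(tracks) attr(tracks, "summary")

#' Detect the depolarization onset in a normalized TMRM trace
#'
#' First frame `k >= drug_frame` at which the normalized potential falls
#' below `1 - onset_drop` and stays below for `sustain_frames` consecutive
#' frames.  The scan stops before `search_end` (default: the start of the
#' terminal FCCP window), since the normalization pulse itself collapses
#' the potential in every condition.
#'
#' @param tmrm_norm numeric vector, one value per frame (frame 0 first).
#' @param drug_frame 0-based frame of compound addition.
#' @param onset_drop fractional drop defining the onset (default 0.1).
#' @param sustain_frames consecutive frames the drop must persist
#'   (default 3).
#' @param search_end 0-based exclusive end of the scan (default: trace end).
#' @return 0-based onset frame, or `NA` if never satisfied.
#' @export
detect_depolarization_onset <- function(tmrm_norm, drug_frame,
                                        onset_drop = 0.1, sustain_frames = 3,
                                        search_end = NULL) {
  nT <- length(tmrm_norm)
  if (nT < sustain_frames) {
    abort("Trace shorter than the sustain window.")
  }
  search_end <- search_end %||% nT
  below <- tmrm_norm < (1 - onset_drop)
  below[is.na(below)] <- FALSE
  for (k in drug_frame:(search_end - 1L)) {
    run <- f2i(k):min(f2i(k) + sustain_frames - 1L, nT)
    if (length(run) < sustain_frames) break
    if (all(below[run])) return(k)
  }
  NA_integer_
}

#' Detect permeabilization (organelle disappearance) in a track
#'
#' First frame at which the organelle's mask area falls below
#' `area_floor_fraction` of its pre-drug mean area and stays below through
#' `sustain_frames` frames (or the movie end).  Frames after a track's last
#' detection count as area 0.  Tracks terminating as `"lost"` return `NA`
#' (they are never counted as permeabilized); tracks with no pre-drug
#' frames are rejected.
#'
#' @param areas numeric vector of per-frame areas over the whole movie
#'   (0 where the organelle is absent), frame 0 first.
#' @param drug_frame 0-based drug-addition frame.
#' @param area_floor_fraction collapse threshold relative to the pre-drug
#'   mean area (default 0.2).
#' @param sustain_frames consecutive frames the collapse must persist
#'   (default 3).
#' @return 0-based frame of permeabilization, or `NA`.
#' @export
detect_permeabilization <- function(areas, drug_frame,
                                    area_floor_fraction = 0.2,
                                    sustain_frames = 3) {
  nT <- length(areas)
  pre <- areas[f2i(0:(drug_frame - 1L))]
  if (drug_frame < 1L || all(pre == 0)) {
    abort("Track has no pre-drug frames; cannot define a reference area.")
  }
  floor_px <- area_floor_fraction * mean(pre)
  below <- areas < floor_px
  for (k in drug_frame:(nT - 1L)) {
    run <- f2i(k):min(f2i(k) + sustain_frames - 1L, nT)
    if (all(below[run]) && (length(run) == sustain_frames || run[length(run)] == nT)) {
      return(k)
    }
  }
  NA_integer_
}

# densify a track's areas to one value per movie frame (0 when absent)
track_area_series <- function(tracks, id, nT) {
  tr <- tracks[tracks$track_id == id, ]
  areas <- numeric(nT)
  areas[f2i(tr$frame)] <- tr$area_px
  areas
}

# match each track to the ROI its baseline centroid falls in (3x3 fallback)
match_track_roi <- function(tracks, roi_set) {
  summ <- track_summary(tracks)
  lab <- roi_set$label_map
  H <- nrow(lab); W <- ncol(lab)
  vapply(summ$track_id, function(id) {
    tr <- tracks[tracks$track_id == id, ][1, ]
    y <- round(tr$y); x <- round(tr$x)
    hit <- lab[max(1, min(H, y)), max(1, min(W, x))]
    if (hit == 0L) {
      ys <- max(1, y - 1):min(H, y + 1)
      xs <- max(1, x - 1):min(W, x + 1)
      nb <- lab[ys, xs]
      nb <- nb[nb > 0L]
      hit <- if (length(nb) > 0) as.integer(names(sort(table(nb),
                                                       decreasing = TRUE))[1])
             else 0L
    }
    as.integer(hit)
  }, integer(1))
}

#' Per-organelle event records
#'
#' Combines tracking and the two detectors into the single-organelle
#' statistics of the assay: for each track matched to a normalized TMRM
#' ROI trace, the depolarization-onset time, the permeabilization time,
#' the residual normalized potential at the permeabilization frame, and
#' the onset-to-permeabilization delay
#' `delay_s = (perm_frame - onset_frame) * frame_interval`.  Records
#' missing either event carry `NA` in the derived fields.  Negative delays
#' are reported as computed (they flag detection pathology rather than
#' being clipped).
#'
#' @param tracks a [track_organelles()] result.
#' @param traces a [mito_traces()] (or [normalize_tmrm()]) table with
#'   `roi_id, frame, tmrm_norm`.
#' @param roi_set the [define_rois()] result the traces were measured on.
#' @param onset_params,perm_params named lists of detector overrides
#'   (`onset_drop`, `sustain_frames`, `search_end`; `area_floor_fraction`,
#'   `sustain_frames`).
#' @return tibble of class `mito_events`: `track_id, roi_id, termination,
#'   onset_frame, onset_s, perm_frame, perm_s, residual_potential, delay_s`.
#' @export
summarize_events <- function(tracks, traces, roi_set,
                             onset_params = list(), perm_params = list()) {
  stopifnot(inherits(tracks, "mito_tracks"))
  summ <- track_summary(tracks)
  nT <- attr(tracks, "n_frames")
  dt <- attr(tracks, "frame_interval")
  drug <- attr(tracks, "drug_frame")
  roi_of <- match_track_roi(tracks, roi_set)

  drop <- roi_of == 0L
  if (any(drop)) {
    warn(sprintf("%d track(s) matched no ROI and were excluded.", sum(drop)))
  }

  recs <- purrr::map(which(!drop), function(j) {
    id <- summ$track_id[j]
    roi <- roi_of[j]
    tn <- traces$tmrm_norm[traces$roi_id == roi][order(traces$frame[traces$roi_id == roi])]
    onset <- do.call(detect_depolarization_onset,
                     c(list(tmrm_norm = tn, drug_frame = drug), onset_params))
    areas <- track_area_series(tracks, id, nT)
    # lost tracks and tracks born after the drug are never scored as
    # permeabilized (no pre-drug reference area exists for the latter)
    perm <- if (summ$termination[j] == "lost" ||
                drug < 1L || all(areas[f2i(0:(drug - 1L))] == 0)) {
      NA_integer_
    } else {
      do.call(detect_permeabilization,
              c(list(areas = areas, drug_frame = drug), perm_params))
    }
    residual <- if (!is.na(perm)) tn[f2i(perm)] else NA_real_
    tibble(track_id = id, roi_id = roi, termination = summ$termination[j],
           onset_frame = onset, onset_s = onset * dt,
           perm_frame = perm, perm_s = perm * dt,
           residual_potential = ifelse(!is.na(onset) & !is.na(perm),
                                       residual, NA_real_),
           delay_s = (perm - onset) * dt)
  })
  out <- bind_rows(recs)
  structure(out, class = c("mito_events", class(out)))
}
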