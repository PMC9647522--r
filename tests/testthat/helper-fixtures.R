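# Shared seeded fixtures, built once per test run.  Unit-test movies are
# deliberately small (5 organelles, 50-60 frames); full-size cohorts live in
# the acceptance tests.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

wt_small <- function() {
  fixture("wt_small", function() {
    simulate_experiment("WT_FERUTININ", n_mito = 5, n_frames = 60,
                        drug_frame = 8, seed = 42)
  })
}

wt_small_analysis <- function() {
  fixture("wt_small_analysis", function() {
    sim <- wt_small()
    analyze_movie(sim$ri, sim$tmrm)
  })
}

noise_free_overrides <- list(noise = list(ri_sd = 0, tmrm_sd = 0))

# independent oracle: walk the TIFF IFD chain by hand and count directories
# (classic little-endian TIFF as written by this package)
count_tiff_pages <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 4)
  stopifnot(rawToChar(hdr[1:2]) == "II")
  offset <- readBin(con, "integer", 1, size = 4, endian = "little")
  n <- 0L
  while (offset != 0L) {
    seek(con, offset)
    n_entries <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                         endian = "little")
    seek(con, offset + 2 + n_entries * 12)
    offset <- readBin(con, "integer", 1, size = 4, endian = "little")
    n <- n + 1L
  }
  n
}

# independent oracle for binarize(): recursive flood fill (8-neighbour) with
# explicit stack, then size filter
floodfill_binarize <- function(x, threshold, min_object_px) {
  mask <- x >= threshold
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j] || seen[i, j]) next
    comp <- list(); stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      comp[[length(comp) + 1]] <- p
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            mask[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          stack[[length(stack) + 1]] <- c(ni, nj)
        }
      }
    }
    if (length(comp) >= min_object_px) {
      for (p in comp) out[p[1], p[2]] <- TRUE
    }
  }
  out
}

# independent oracle for the onset detector: literal linear scan of the rule
scan_onset <- function(tmrm_norm, drug_frame, onset_drop = 0.1,
                       sustain_frames = 3, search_end = length(tmrm_norm)) {
  for (k in drug_frame:(search_end - 1)) {
    if (k + sustain_frames > length(tmrm_norm)) break
    ok <- TRUE
    for (j in k:(k + sustain_frames - 1)) {
      v <- tmrm_norm[j + 1]
      if (is.na(v) || v >= 1 - onset_drop) { ok <- FALSE; break }
    }
    if (ok) return(k)
  }
  NA_integer_
}

# independent oracle for the permeabilization detector
scan_perm <- function(areas, drug_frame, area_floor_fraction = 0.2,
                      sustain_frames = 3) {
  floor_px <- area_floor_fraction * mean(areas[1:drug_frame])
  nT <- length(areas)
  for (k in drug_frame:(nT - 1)) {
    last <- min(k + sustain_frames - 1, nT - 1)
    ok <- all(areas[(k:last) + 1] < floor_px)
    full <- (last - k + 1) == sustain_frames || last == nT - 1
    if (ok && full) return(k)
  }
  NA_integer_
}
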