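make_mask_stack <- function(masks, drug_frame = 3, frame_interval = 15) {
  structure(list(masks = masks, min_object_px = 1, source = "threshold",
                 frame_interval = frame_interval, drug_frame = drug_frame),
            class = "mask_stack")
}

test_that("a static blob yields a single movie-end track", {
  m <- array(FALSE, c(20, 20, 10))
  m[5:9, 5:9, ] <- TRUE
  tr <- track_organelles(make_mask_stack(m))
  summ <- track_summary(tr)
  expect_equal(nrow(summ), 1)
  expect_equal(summ$termination, "movie_end")
  expect_equal(nrow(tr), 10)
  expect_true(all(tr$area_px == 25))
})

test_that("a blob vanishing at frame 5 terminates as disappeared at frame 4", {
  m <- array(FALSE, c(20, 20, 10))
  m[5:9, 5:9, 1:5] <- TRUE  # frames 0..4
  tr <- track_organelles(make_mask_stack(m), gap_frames = 1)
  summ <- track_summary(tr)
  expect_equal(summ$termination, "disappeared")
  expect_equal(summ$last_seen_frame, 4L)
})

test_that("a blob that blinks out past the gap but returns is lost, not disappeared", {
  m <- array(FALSE, c(20, 20, 12))
  m[5:9, 5:9, c(1:4, 9:12)] <- TRUE  # absent frames 4..7 (gap > 1)
  tr <- track_organelles(make_mask_stack(m), gap_frames = 1)
  summ <- track_summary(tr)
  expect_equal(summ$termination[summ$track_id == 1], "lost")
  expect_equal(nrow(summ), 2)  # reappearance founds a new track
})

test_that("two separated blobs track independently with stable ids", {
  m <- array(FALSE, c(30, 30, 8))
  m[3:7, 3:7, ] <- TRUE
  m[20:26, 20:26, ] <- TRUE
  tr <- track_organelles(make_mask_stack(m))
  summ <- track_summary(tr)
  expect_equal(nrow(summ), 2)
  expect_true(all(summ$termination == "movie_end"))
  expect_equal(as.integer(table(tr$track_id)), c(8L, 8L))
})

test_that("onset detector matches its rule on forced and random traces", {
  expect_true(is.na(detect_depolarization_onset(rep(1, 30), drug_frame = 5)))
  step <- c(rep(1, 20), rep(0.5, 20))
  expect_equal(detect_depolarization_onset(step, drug_frame = 5), 20L)
  expect_error(detect_depolarization_onset(c(1, 1), drug_frame = 0,
                                           sustain_frames = 3), "shorter")
  set.seed(31)
  for (rep in 1:100) {
    tr <- 1 - cumsum(runif(40, -0.05, 0.12))
    drug <- sample(0:10, 1)
    drop <- runif(1, 0.05, 0.3)
    sus <- sample(1:4, 1)
    expect_identical(
      detect_depolarization_onset(tr, drug, onset_drop = drop,
                                  sustain_frames = sus),
      scan_onset(tr, drug, onset_drop = drop, sustain_frames = sus))
  }
})

test_that("permeabilization detector matches its rule on forced and random traces", {
  areas <- c(50, 50, 50, 4, 0, 0, 0, 0)
  expect_equal(detect_permeabilization(areas, drug_frame = 3,
                                       area_floor_fraction = 0.2), 3L)
  expect_true(is.na(detect_permeabilization(rep(40, 10), drug_frame = 3)))
  expect_error(detect_permeabilization(c(0, 0, 10, 10), drug_frame = 2),
               "pre-drug")
  set.seed(32)
  for (rep in 1:100) {
    pre <- sample(30:60, 1)
    areas <- c(rep(pre, 5), pmax(0, pre - cumsum(sample(0:25, 25, TRUE))))
    floor_frac <- runif(1, 0.1, 0.4)
    sus <- sample(1:4, 1)
    expect_identical(
      detect_permeabilization(areas, 5, area_floor_fraction = floor_frac,
                              sustain_frames = sus),
      scan_perm(areas, 5, area_floor_fraction = floor_frac,
                sustain_frames = sus))
  }
})

test_that("event summary arithmetic and WT ground-truth recovery", {
  sim <- wt_small()
  ana <- wt_small_analysis()
  ev <- ana$events
  gt <- sim$ground_truth$organelles

  # every organelle permeabilizes and delay = (perm - onset) * 15 exactly
  expect_equal(nrow(ev), 5)
  expect_true(all(!is.na(ev$perm_frame)))
  expect_equal(ev$delay_s, (ev$perm_frame - ev$onset_frame) * 15)

  # detected disappearance count equals ground-truth permeabilization count
  summ <- track_summary(ana$tracks)
  expect_equal(sum(summ$termination == "disappeared"),
               sum(!is.na(gt$perm_s)))

  # detected perm frame within one frame of the ground-truth crossing,
  # matched per organelle through the ROI label map
  lab_gt <- ground_truth_labels(sim$scenario)
  for (i in seq_len(nrow(gt))) {
    roi <- unique(ana$rois$label_map[lab_gt == i & ana$rois$label_map > 0])
    got <- ev$perm_frame[ev$roi_id == roi]
    expect_lte(abs(got - ceiling(gt$perm_s[i] / 15)), 1)
  }
})

test_that("depolarization precedes permeabilization in every WT record", {
  ev <- wt_small_analysis()$events
  both <- dplyr::filter(ev, !is.na(onset_s), !is.na(perm_s))
  expect_gt(nrow(both), 0)
  expect_true(all(both$perm_s >= both$onset_s))
})

test_that("no false events across a seeded cyclosporin-A cohort", {
  onsets <- 0L; perms <- 0L; total <- 0L
  for (seed in 1:20) {
    sim <- simulate_experiment("WT_FERUTININ_CSA", n_mito = 4, n_frames = 50,
                               drug_frame = 6, seed = 100 + seed)
    ev <- analyze_movie(sim$ri, sim$tmrm)$events
    onsets <- onsets + sum(!is.na(ev$onset_frame))
    perms <- perms + sum(!is.na(ev$perm_frame))
    total <- total + nrow(ev)
  }
  expect_equal(total, 80)
  expect_equal(onsets, 0)
  expect_equal(perms, 0)
})

test_that("lost tracks are never scored as permeabilized", {
  m <- array(FALSE, c(20, 20, 12))
  m[5:9, 5:9, c(1:4, 9:12)] <- TRUE
  ms <- make_mask_stack(m)
  lab <- matrix(0L, 20, 20); lab[5:9, 5:9] <- 1L
  rois <- structure(list(label_map = lab, roi_ids = 1L, source_frames = 0:2,
                         min_roi_px = 1), class = "roi_set")
  traces <- tibble::tibble(roi_id = 1L, frame = 0:11,
                           tmrm_norm = c(rep(1, 4), rep(0.1, 8)))
  tr <- track_organelles(ms)
  ev <- summarize_events(tr, traces, rois)
  lost <- dplyr::filter(ev, termination == "lost")
  expect_true(all(is.na(lost$perm_frame)))
})
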