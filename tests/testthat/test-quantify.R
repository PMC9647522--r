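test_that("baseline ROI definition recovers one ROI per separated organelle", {
  sim <- wt_small()
  rois <- define_rois(sim$tmrm)
  expect_equal(length(rois$roi_ids), sim$scenario$n_mito)
  expect_equal(sort(unique(as.vector(rois$label_map))),
               0:sim$scenario$n_mito)
  # every ROI sits on exactly one ground-truth organelle
  gt <- ground_truth_labels(sim$scenario)
  for (r in rois$roi_ids) {
    covered <- gt[rois$label_map == r]
    expect_equal(length(setdiff(unique(covered), 0L)), 1)
  }
})

test_that("ROI definition rejects post-drug windows and warns on empty channels", {
  sim <- wt_small()
  expect_error(define_rois(sim$tmrm, baseline_window = 0:10), "precede")
  flat <- frame_stack(array(0.05 + abs(rnorm(30 * 30 * 10, 0, 0.01)),
                            c(30, 30, 10)),
                      channel = "TMRM", drug_frame = 5)
  expect_warning(rois <- define_rois(flat), "No ROIs")
  expect_equal(length(rois$roi_ids), 0)
})

test_that("overlapping organelles merge into a single ROI", {
  geom <- tibble::tibble(id = 1:2, cy = c(20, 24), cx = c(20, 26),
                         ry = c(4, 4), rx = c(7, 7), theta = c(0, 0))
  attr(geom, "height") <- 44; attr(geom, "width") <- 44
  sim <- simulate_experiment("WT_FERUTININ", n_mito = 2, n_frames = 40,
                             drug_frame = 6, seed = 2,
                             overrides = list(geometry = geom))
  rois <- define_rois(sim$tmrm)
  expect_equal(length(rois$roi_ids), 1)
})

test_that("area traces are baseline-normalized with invalid ROIs flagged", {
  sim <- wt_small()
  ana <- wt_small_analysis()
  at <- area_trace(ana$masks, ana$rois)
  base <- dplyr::filter(at, frame < 8)
  means <- tapply(base$area_fraction, base$roi_id, mean)
  expect_equal(as.numeric(means), rep(1, length(means)), tolerance = 1e-12)
  # constant mask over time gives area_fraction identically 1
  const_masks <- ana$masks
  for (k in seq_len(dim(const_masks$masks)[3])) {
    const_masks$masks[, , k] <- ana$masks$masks[, , 1]
  }
  atc <- area_trace(const_masks, ana$rois)
  expect_true(all(abs(atc$area_fraction - 1) < 1e-12))
  # an ROI with zero baseline mask area is flagged invalid
  rois2 <- ana$rois
  lm <- rois2$label_map
  lm[lm == 0L][1:30] <- 99L  # fake ROI off any organelle
  rois2$label_map <- lm
  rois2$roi_ids <- sort(unique(lm[lm > 0]))
  expect_warning(at2 <- area_trace(ana$masks, rois2), "invalid")
  bad <- dplyr::filter(at2, roi_id == 99L)
  expect_true(all(!bad$valid))
  expect_true(all(is.na(bad$area_fraction)))
})

test_that("TMRM traces equal a brute-force per-pixel loop", {
  set.seed(5)
  px <- array(runif(12 * 12 * 6), c(12, 12, 6))
  st <- frame_stack(px, channel = "TMRM", drug_frame = 2)
  lab <- matrix(0L, 12, 12)
  lab[2:4, 2:4] <- 1L
  lab[8, 8] <- 2L  # single-pixel ROI
  rois <- structure(list(label_map = lab, roi_ids = 1:2,
                         source_frames = 0:1, min_roi_px = 1),
                    class = "roi_set")
  tt <- tmrm_trace(st, rois)
  for (k in 0:5) {
    acc <- 0; cnt <- 0
    for (i in 2:4) for (j in 2:4) { acc <- acc + px[i, j, k + 1]; cnt <- cnt + 1 }
    expect_equal(tt$tmrm_raw[tt$roi_id == 1 & tt$frame == k], acc / cnt)
    expect_equal(tt$tmrm_raw[tt$roi_id == 2 & tt$frame == k], px[8, 8, k + 1])
  }
})

test_that("FCCP normalization maps its anchors to 1 and 0 exactly", {
  # forced arithmetic: baseline 200, fccp 50, value 80 -> 0.2
  tr <- tibble::tibble(roi_id = 1L, frame = 0:9,
                       tmrm_raw = c(200, 200, 80, 80, 80, 80, 80, 80, 50, 50))
  nt <- normalize_tmrm(tr, baseline_window = 0:1, fccp_window = 8:9)
  expect_equal(nt$tmrm_norm[nt$frame == 2], 0.2)
  expect_equal(mean(nt$tmrm_norm[nt$frame %in% 0:1]), 1)
  expect_equal(mean(nt$tmrm_norm[nt$frame %in% 8:9]), 0)

  sim <- wt_small()
  rois <- define_rois(sim$tmrm)
  tt <- tmrm_trace(sim$tmrm, rois)
  bw <- 0:7; fw <- 57:59
  nt2 <- normalize_tmrm(tt, bw, fw)
  for (r in unique(nt2$roi_id)) {
    v <- nt2[nt2$roi_id == r, ]
    expect_equal(mean(v$tmrm_norm[v$frame %in% bw]), 1, tolerance = 1e-12)
    expect_equal(mean(v$tmrm_norm[v$frame %in% fw]), 0, tolerance = 1e-12)
  }
  # invariance under positive rescaling of the raw intensities
  tt_scaled <- dplyr::mutate(tt, tmrm_raw = tmrm_raw * 37.5)
  nt3 <- normalize_tmrm(tt_scaled, bw, fw)
  expect_equal(nt3$tmrm_norm, nt2$tmrm_norm, tolerance = 1e-12)
})

test_that("flat traces are flagged non-normalizable and windows must not overlap", {
  tr <- tibble::tibble(roi_id = 1L, frame = 0:9,
                       tmrm_raw = 100 + rnorm(10, 0, 1))
  nt <- normalize_tmrm(tr, baseline_window = 0:3, fccp_window = 8:9)
  expect_false(any(nt$normalizable))
  expect_true(all(is.na(nt$tmrm_norm)))
  expect_error(normalize_tmrm(tr, baseline_window = 0:5, fccp_window = 5:9),
               "overlap")
})

test_that("normalized potential at the true permeabilization frame is near the threshold", {
  sim <- wt_small()
  ana <- wt_small_analysis()
  gt <- sim$ground_truth$organelles
  lab_gt <- ground_truth_labels(sim$scenario)
  for (i in seq_len(nrow(gt))) {
    perm_frame <- ceiling(gt$perm_s[i] / 15)
    # find this organelle's ROI via the ground-truth label map
    roi <- unique(ana$rois$label_map[lab_gt == i & ana$rois$label_map > 0])
    expect_length(roi, 1)
    v <- ana$traces$tmrm_norm[ana$traces$roi_id == roi &
                                ana$traces$frame == perm_frame]
    expect_lt(abs(v - 0.15), 0.05)
  }
})
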