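test_that("scenarios are deterministic and validate their inputs", {
  a <- make_scenario("WT_FERUTININ", 10, n_frames = 80, drug_frame = 10, seed = 1)
  b <- make_scenario("WT_FERUTININ", 10, n_frames = 80, drug_frame = 10, seed = 1)
  expect_identical(a, b)
  expect_true(a$kinetics$perm_enabled)
  expect_equal(a$kinetics$v_basal, 1)
  ko <- make_scenario("KO_FERUTININ", 5, n_frames = 80, drug_frame = 10, seed = 1)
  expect_false(ko$kinetics$perm_enabled)
  expect_lt(ko$kinetics$v_basal, 1)
  expect_error(make_scenario("BAD_CONDITION", 5), "Valid conditions")
  expect_error(make_scenario("WT_FERUTININ", 5, overrides = list(nope = 1)),
               "Unknown override")
  expect_error(kinetic_params(perm_threshold = 1.2), "perm_threshold")
  expect_error(kinetic_params(v_basal = 0), "v_basal")
})

test_that("kinetics honour the condition logic of the four archetypes", {
  onsets <- list()
  for (cond in mito_conditions) {
    sc <- make_scenario(cond, 8, n_frames = 80, drug_frame = 10, seed = 3)
    gt <- simulate_kinetics(sc)
    if (cond == "WT_FERUTININ") {
      expect_true(all(!is.na(gt$organelles$perm_s)))
      expect_true(all(gt$organelles$perm_s >= gt$organelles$onset_s))
    } else {
      expect_true(all(is.na(gt$organelles$perm_s)))
      expect_equal(gt$ri_contrast, matrix(1, 8, 80))
    }
    if (cond == "WT_FERUTININ_CSA") {
      # potential stays at basal until the terminal FCCP anchor
      pre_fccp <- seq_len(80 - sc$fccp_frames)
      expect_true(all(gt$potential[, pre_fccp] == sc$kinetics$v_basal))
      expect_true(all(is.na(gt$organelles$onset_s)))
    } else {
      expect_true(all(!is.na(gt$organelles$onset_s)))
    }
  }
})

test_that("noise-free potential is nonincreasing from the onset", {
  for (cond in c("WT_FERUTININ", "KO_FERUTININ", "FCCP_ONLY")) {
    sc <- make_scenario(cond, 6, n_frames = 60, drug_frame = 8, seed = 9)
    gt <- simulate_kinetics(sc)
    for (i in 1:6) {
      post <- which(gt$times >= gt$organelles$onset_s[i])
      expect_true(all(diff(gt$potential[i, post]) <= 1e-12))
    }
  }
})

test_that("threshold crossing follows the closed form tau * log(1/theta)", {
  # zero jitter, zero lag: perm - onset = tau_depol * log(1/perm_threshold)
  sc <- make_scenario("WT_FERUTININ", 5, n_frames = 80, drug_frame = 10,
                      seed = 2,
                      overrides = list(kinetics = list(onset_jitter_sd = 0)))
  gt <- simulate_kinetics(sc)
  expected <- 79 * log(1 / 0.15)
  expect_equal(gt$organelles$perm_s - gt$organelles$onset_s,
               rep(expected, 5), tolerance = 1e-10)
  expect_lt(abs(expected - 150), sc$frame_interval)
  # potential at the crossing equals the threshold fraction of basal
  for (i in 1:5) {
    v_at <- sc$kinetics$v_basal *
      exp(-(gt$organelles$perm_s[i] - gt$organelles$onset_s[i]) / 79)
    expect_equal(v_at, 0.15, tolerance = 1e-10)
  }
  # and a custom tau scales the crossing accordingly
  sc2 <- make_scenario("WT_FERUTININ", 3, n_frames = 80, drug_frame = 10,
                       seed = 2,
                       overrides = list(kinetics = list(onset_jitter_sd = 0,
                                                        tau_depol = 40)))
  gt2 <- simulate_kinetics(sc2)
  expect_equal(unique(gt2$organelles$perm_s - gt2$organelles$onset_s),
               40 * log(1 / 0.15), tolerance = 1e-10)
})

test_that("truncated Gaussian lag delays permeabilization but never precedes the crossing", {
  sc <- make_scenario("WT_FERUTININ", 20, n_frames = 120, drug_frame = 10,
                      seed = 5,
                      overrides = list(kinetics = list(perm_lag_mean = 10,
                                                       perm_lag_sd = 20)))
  gt <- simulate_kinetics(sc)
  crossing <- gt$organelles$onset_s + 79 * log(1 / 0.15)
  expect_true(all(gt$organelles$perm_s >= crossing - 1e-9))
})

test_that("rendering is deterministic and static before the drug when noise-free", {
  sim1 <- simulate_experiment("WT_FERUTININ", n_mito = 3, n_frames = 40,
                              drug_frame = 6, seed = 5)
  sim2 <- simulate_experiment("WT_FERUTININ", n_mito = 3, n_frames = 40,
                              drug_frame = 6, seed = 5)
  expect_identical(sim1$ri$pixels, sim2$ri$pixels)
  expect_identical(sim1$tmrm$pixels, sim2$tmrm$pixels)

  nf <- simulate_experiment("WT_FERUTININ", n_mito = 3, n_frames = 40,
                            drug_frame = 6, seed = 5,
                            overrides = noise_free_overrides)
  for (k in 1:5) {
    expect_identical(nf$ri$pixels[, , k], nf$ri$pixels[, , 1])
  }
})

test_that("FCCP-only movies keep RI organelles while TMRM collapses", {
  sim <- simulate_experiment("FCCP_ONLY", n_mito = 4, n_frames = 50,
                             drug_frame = 6, seed = 8,
                             overrides = noise_free_overrides)
  sc <- sim$scenario
  gt_mask <- ground_truth_labels(sc) > 0
  last_ri <- get_frame(sim$ri, 49)
  last_tmrm <- get_frame(sim$tmrm, 49)
  # organelle pixels keep full RI contrast ...
  expect_gt(mean(last_ri[gt_mask]) - mean(last_ri[!gt_mask]), 0.2)
  # ... while TMRM is at background everywhere
  expect_lt(mean(last_tmrm[gt_mask]) - mean(last_tmrm[!gt_mask]), 1e-3)
})

test_that("WT organelles vanish from the RI channel after permeabilization", {
  sim <- simulate_experiment("WT_FERUTININ", n_mito = 4, n_frames = 60,
                             drug_frame = 6, seed = 8)
  sc <- sim$scenario
  gt_mask <- ground_truth_labels(sc) > 0
  # analytic residual contrast at the last frame is far below the noise sd
  last_perm <- max(sim$ground_truth$organelles$perm_s)
  t_end <- (60 - 1) * sc$frame_interval
  residual <- sc$optics$ri_amplitude *
    exp(-(t_end - last_perm) / sc$kinetics$tau_ri_collapse)
  expect_lt(residual, sc$noise$ri_sd)
  last_ri <- get_frame(sim$ri, 59)
  expect_lt(abs(mean(last_ri[gt_mask]) - mean(last_ri[!gt_mask])),
            2 * sc$noise$ri_sd)
})

test_that("degenerate zero-area ellipses are rejected at render time", {
  sc <- make_scenario("WT_FERUTININ", 2, n_frames = 40, drug_frame = 6, seed = 1)
  sc$geometry$rx[1] <- 0
  expect_error(render_movie(sc), "Degenerate")
})

test_that("write_simulation emits both channels, metadata and ground truth", {
  sim <- wt_small()
  dir <- withr::local_tempdir()
  files <- write_simulation(sim, dir)
  expect_equal(nrow(files), 4)
  expect_true(all(file.exists(files$path)))
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  expect_equal(meta$condition, "WT_FERUTININ")
  expect_equal(meta$drug_frame, 8)
  gt <- read.table(file.path(dir, "ground_truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(gt), 5)
  expect_true(all(c("onset_s", "perm_s", "cy", "cx", "ry", "rx") %in% names(gt)))
})
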