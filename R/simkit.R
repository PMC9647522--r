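#' Experimental condition archetypes
#'
#' The four archetypes the simulator reproduces:
#' \describe{
#'   \item{WT_FERUTININ}{wild-type cells + ferutinin: gradual depolarization
#'     followed by permeability-transition-pore opening; organelles vanish
#'     from the refractive-index channel.}
#'   \item{WT_FERUTININ_CSA}{ferutinin in the presence of cyclosporin A:
#'     both depolarization and permeabilization are blocked.}
#'   \item{FCCP_ONLY}{protonophore uncoupler alone: rapid depolarization,
#'     no permeabilization — organelles stay visible in the RI channel.}
#'   \item{KO_FERUTININ}{ATP-synthase- or ANT-deficient cells + ferutinin:
#'     lower basal potential, CSA-sensitive depolarization, but no
#'     high-conductance permeabilization.}
#' }
#' @export
mito_conditions <- c("WT_FERUTININ", "WT_FERUTININ_CSA", "FCCP_ONLY",
                     "KO_FERUTININ")

#' Phenomenological kinetic parameters of the simulator
#'
#' Depolarization after a jittered onset is single-exponential; if the
#' condition permits permeabilization, the organelle permeabilizes when its
#' potential falls to `perm_threshold` of the basal level (plus an optional
#' nonnegative lag), after which its refractive-index contrast decays with
#' `tau_ri_collapse`.  A terminal FCCP pulse collapses the potential of all
#' organelles over the last frames of the movie (the normalization anchor);
#' in the FCCP_ONLY condition the drug itself is FCCP, applied at
#' `drug_frame`.
#'
#' Defaults are calibrated so the wild-type archetype has a ground-truth
#' residual potential fraction of 0.15 and a mean onset-to-permeabilization
#' delay of `tau_depol * log(1 / perm_threshold) = 79 * log(1/0.15) = 149.9`
#' seconds.
#'
#' @param v_basal basal potential level in `(0, 1]` (dimensionless; the
#'   knockout archetype uses a reduced value).
#' @param tau_depol depolarization decay constant, seconds.
#' @param onset_jitter_sd per-organelle spread of the depolarization onset
#'   after drug addition, seconds (onsets are `t_drug + |N(0, sd)|`).
#' @param perm_threshold fraction of the basal potential at which
#'   permeabilization triggers, in `(0, 1)`.
#' @param perm_lag_mean,perm_lag_sd mean and sd (seconds) of the Gaussian
#'   lag between threshold crossing and RI collapse; draws are truncated
#'   at 0.
#' @param tau_ri_collapse decay constant of the RI contrast after
#'   permeabilization, seconds.
#' @param tau_fccp decay constant of the potential under FCCP, seconds.
#' @param bleach_rate per-frame fluorescence bleaching fraction (0 = none).
#' @param depol_enabled,perm_enabled condition switches (set by
#'   [make_scenario()]; cyclosporin A disables both, the uncoupler and the
#'   knockouts disable permeabilization only).
#' @return a list of class `kinetic_params`.
#' @export
kinetic_params <- function(v_basal = 1, tau_depol = 79, onset_jitter_sd = 30,
                           perm_threshold = 0.15, perm_lag_mean = 0,
                           perm_lag_sd = 0, tau_ri_collapse = 10,
                           tau_fccp = 5, bleach_rate = 0,
                           depol_enabled = TRUE, perm_enabled = TRUE) {
  stopifnot(tau_depol > 0, tau_ri_collapse > 0, tau_fccp > 0,
            onset_jitter_sd >= 0, perm_lag_sd >= 0,
            bleach_rate >= 0, bleach_rate < 1)
  if (!(v_basal > 0 && v_basal <= 1)) abort("`v_basal` must lie in (0, 1].")
  if (!(perm_threshold > 0 && perm_threshold < 1)) {
    abort("`perm_threshold` must lie in (0, 1).")
  }
  structure(
    list(v_basal = v_basal, tau_depol = tau_depol,
         onset_jitter_sd = onset_jitter_sd, perm_threshold = perm_threshold,
         perm_lag_mean = perm_lag_mean, perm_lag_sd = perm_lag_sd,
         tau_ri_collapse = tau_ri_collapse, tau_fccp = tau_fccp,
         bleach_rate = bleach_rate, depol_enabled = depol_enabled,
         perm_enabled = perm_enabled),
    class = "kinetic_params"
  )
}

condition_kinetics <- function(condition) {
  switch(condition,
    WT_FERUTININ     = kinetic_params(),
    WT_FERUTININ_CSA = kinetic_params(depol_enabled = FALSE,
                                      perm_enabled = FALSE),
    FCCP_ONLY        = kinetic_params(onset_jitter_sd = 0,
                                      perm_enabled = FALSE),
    KO_FERUTININ     = kinetic_params(v_basal = 0.6, perm_enabled = FALSE)
  )
}

default_noise <- function() {
  list(ri_sd = 0.02, tmrm_sd = 0.02, background_gradient = 0)
}

default_optics <- function() {
  # image formation constants: cytosol background, organelle amplitudes,
  # edge smoothing in px
  list(ri_background = 0.15, ri_amplitude = 0.45,
       tmrm_background = 0.08, tmrm_amplitude = 0.55, edge_sigma = 0.8)
}

# Jittered-grid ellipse geometry: one organelle per grid cell keeps default
# scenarios non-overlapping, so ROI counts equal organelle counts.
make_geometry <- function(n_mito, cell = 30, margin = 8) {
  ncol_g <- ceiling(sqrt(n_mito))
  nrow_g <- ceiling(n_mito / ncol_g)
  height <- nrow_g * cell + 2 * margin
  width <- ncol_g * cell + 2 * margin
  idx <- seq_len(n_mito) - 1L
  gy <- idx %/% ncol_g
  gx <- idx %% ncol_g
  tibble(
    id = seq_len(n_mito),
    cy = margin + (gy + 0.5) * cell + runif(n_mito, -4, 4),
    cx = margin + (gx + 0.5) * cell + runif(n_mito, -4, 4),
    ry = runif(n_mito, 3, 5),
    rx = runif(n_mito, 5, 8),
    theta = runif(n_mito, 0, pi)
  ) |>
    (\(g) structure(g, height = height, width = width))()
}

#' Build a simulation scenario
#'
#' Assembles the full description of one simulated experiment: condition,
#' organelle geometry (ellipses on a jittered grid), kinetic parameters,
#' noise levels and the RNG seed that fully determines the output.
#'
#' @param condition one of [mito_conditions].
#' @param n_mito number of organelles (>= 1).
#' @param n_frames number of movie frames.
#' @param drug_frame 0-based frame of compound addition.
#' @param seed integer RNG seed; the same call with the same seed returns an
#'   identical scenario, and all downstream draws (onset jitter, lags, pixel
#'   noise) are derived from it in a documented order.
#' @param fccp_frames number of terminal frames over which the FCCP
#'   normalization pulse acts (also the default normalization window).
#' @param overrides named list overriding scenario fields (`kinetics`,
#'   `noise`, `optics`, `geometry`, `frame_interval`, `fccp_frames`).
#'   Unknown names are an error.
#' @return a list of class `mito_scenario`.
#' @export
make_scenario <- function(condition, n_mito = 10, n_frames = 80,
                          drug_frame = 10, seed = 1, fccp_frames = 5,
                          overrides = list()) {
  if (!is.character(condition) || length(condition) != 1 ||
      !condition %in% mito_conditions) {
    abort(sprintf("Unknown condition %s. Valid conditions: %s.",
                  deparse(condition), paste(mito_conditions, collapse = ", ")))
  }
  stopifnot(n_mito >= 1, n_frames >= 2, drug_frame >= 0,
            drug_frame < n_frames)
  allowed <- c("kinetics", "noise", "optics", "geometry", "frame_interval",
               "fccp_frames")
  bad <- setdiff(names(overrides), allowed)
  if (length(bad) > 0) {
    abort(sprintf("Unknown override field(s): %s. Allowed: %s.",
                  paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  }
  kin <- condition_kinetics(condition)
  if (!is.null(overrides$kinetics)) {
    kin <- do.call(kinetic_params, modifyList(unclass(kin), overrides$kinetics))
  }
  noise <- modifyList(default_noise(), overrides$noise %||% list())
  optics <- modifyList(default_optics(), overrides$optics %||% list())
  geometry <- overrides$geometry %||%
    with_seed(seed, make_geometry(n_mito))
  fccp_frames <- overrides$fccp_frames %||% fccp_frames
  stopifnot(fccp_frames >= 1, drug_frame + 1 < n_frames - fccp_frames)
  structure(
    list(condition = condition, n_mito = as.integer(n_mito),
         n_frames = as.integer(n_frames), drug_frame = as.integer(drug_frame),
         frame_interval = overrides$frame_interval %||% 15,
         fccp_frames = as.integer(fccp_frames),
         height = attr(geometry, "height") %||% max(ceiling(geometry$cy + geometry$ry + 8)),
         width = attr(geometry, "width") %||% max(ceiling(geometry$cx + geometry$rx + 8)),
         geometry = geometry, kinetics = kin, noise = noise, optics = optics,
         seed = as.integer(seed)),
    class = "mito_scenario"
  )
}

#' @export
print.mito_scenario <- function(x, ...) {
  cat(sprintf(
    "<mito_scenario> %s: %d organelles, %d frames (dt = %g s), drug at frame %d, seed %d\n",
    x$condition, x$n_mito, x$n_frames, x$frame_interval, x$drug_frame, x$seed))
  invisible(x)
}

# 0-based frame at which the terminal FCCP pulse starts
fccp_start_frame <- function(scenario) scenario$n_frames - scenario$fccp_frames

#' Simulate per-organelle kinetics (ground truth)
#'
#' Produces the noise-free potential and RI-contrast curves plus the event
#' times that constitute the simulation's ground truth.  Per organelle `i`,
#' the depolarization onset is `o_i = t_drug + |jitter_i|`; the potential is
#' `v_basal` before the onset and `v_basal * exp(-(t - o_i)/tau_depol)`
#' after.  Where the condition permits permeabilization, the threshold
#' crossing is the closed form `o_i + tau_depol * log(1/perm_threshold)` and
#' the permeabilization time adds a nonnegative lag draw; the RI contrast is
#' 1 until then and decays exponentially with `tau_ri_collapse` afterwards.
#' Cyclosporin A holds the potential at `v_basal` (no onset); FCCP collapses
#' it from `drug_frame` with `tau_fccp`.  All conditions end with the
#' terminal FCCP pulse used as the normalization anchor.
#'
#' @param scenario a [make_scenario()] object.
#' @return a list of class `mito_ground_truth` with elements `organelles`
#'   (tibble: id, onset_s, perm_s), `potential` and `ri_contrast`
#'   (`n_mito x n_frames` matrices), and `times` (seconds).
#' @export
simulate_kinetics <- function(scenario) {
  stopifnot(inherits(scenario, "mito_scenario"))
  kin <- scenario$kinetics
  n <- scenario$n_mito
  times <- (seq_len(scenario$n_frames) - 1) * scenario$frame_interval
  t_drug <- scenario$drug_frame * scenario$frame_interval
  t_fccp <- fccp_start_frame(scenario) * scenario$frame_interval

  draws <- with_seed(scenario$seed + 1L, list(
    jitter = abs(rnorm(n, 0, kin$onset_jitter_sd)),
    lag = pmax(0, rnorm(n, kin$perm_lag_mean, kin$perm_lag_sd))
  ))

  fccp_only <- scenario$condition == "FCCP_ONLY"
  csa <- scenario$condition == "WT_FERUTININ_CSA"

  onset <- if (csa) rep(NA_real_, n)
           else if (fccp_only) rep(t_drug, n)
           else t_drug + draws$jitter
  tau <- if (fccp_only) kin$tau_fccp else kin$tau_depol

  perm <- rep(NA_real_, n)
  if (kin$perm_enabled) {
    perm <- onset + tau * log(1 / kin$perm_threshold) + draws$lag
  }

  potential <- matrix(kin$v_basal, n, scenario$n_frames)
  ri <- matrix(1, n, scenario$n_frames)
  for (i in seq_len(n)) {
    v <- rep(kin$v_basal, length(times))
    if (!is.na(onset[i])) {
      post <- times >= onset[i]
      v[post] <- kin$v_basal * exp(-(times[post] - onset[i]) / tau)
    }
    # terminal FCCP pulse: accelerated collapse from the potential reached
    # at the pulse start (a no-op when the drug itself was FCCP)
    if (!fccp_only) {
      post_f <- times >= t_fccp
      v_at <- v[which(post_f)[1]]
      v[post_f] <- v_at * exp(-(times[post_f] - t_fccp) / kin$tau_fccp)
    }
    potential[i, ] <- v
    if (!is.na(perm[i])) {
      post_p <- times >= perm[i]
      ri[i, post_p] <- exp(-(times[post_p] - perm[i]) / kin$tau_ri_collapse)
    }
  }

  structure(
    list(organelles = tibble(id = seq_len(n), onset_s = onset, perm_s = perm),
         potential = potential, ri_contrast = ri, times = times),
    class = "mito_ground_truth"
  )
}

# Smoothed indicator image of one ellipse (binary inside-test then Gaussian
# blur), plus the binary ground-truth mask itself.
ellipse_mask <- function(height, width, cy, cx, ry, rx, theta) {
  if (ry <= 0 || rx <= 0) abort("Degenerate zero-area ellipse rejected.")
  y <- matrix(seq_len(height), height, width)
  x <- matrix(seq_len(width), height, width, byrow = TRUE)
  dy <- y - cy
  dx <- x - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / rx)^2 + (v / ry)^2 <= 1
}

organelle_indicators <- function(scenario, smooth = TRUE) {
  sig <- scenario$optics$edge_sigma
  lapply(seq_len(scenario$n_mito), function(i) {
    g <- scenario$geometry[i, ]
    m <- ellipse_mask(scenario$height, scenario$width,
                      g$cy, g$cx, g$ry, g$rx, g$theta)
    if (sum(m) == 0) abort("Degenerate zero-area ellipse rejected.")
    if (smooth) EBImage::gblur(m * 1, sigma = sig) else m * 1
  })
}

#' Ground-truth organelle label map
#'
#' Binary/label image of the simulated organelles before any
#' permeabilization, for scoring segmentation (Dice) and ROI recovery.
#'
#' @param scenario a [make_scenario()] object.
#' @return integer `H x W` matrix; 0 = background, `i` = organelle `i`.
#' @export
ground_truth_labels <- function(scenario) {
  lab <- matrix(0L, scenario$height, scenario$width)
  for (i in seq_len(scenario$n_mito)) {
    g <- scenario$geometry[i, ]
    m <- ellipse_mask(scenario$height, scenario$width,
                      g$cy, g$cx, g$ry, g$rx, g$theta)
    lab[m] <- i
  }
  lab
}

#' Render the dual-channel movie
#'
#' Converts a scenario plus its ground truth into the two image stacks the
#' analysis pipeline consumes.  Each RI frame is the cytosol background plus
#' the sum of smoothed organelle ellipses weighted by their RI-contrast
#' curve; each TMRM frame is background plus ellipses weighted by the
#' potential curve (times a cumulative bleach factor if enabled).  Additive
#' Gaussian pixel noise is seeded and reproducible; an optional linear
#' background gradient can be added to both channels.
#'
#' @param scenario a [make_scenario()] object.
#' @param ground_truth the matching [simulate_kinetics()] result (computed
#'   if missing).
#' @return list with elements `ri` and `tmrm`, both [frame_stack()]s, and
#'   `ground_truth`.
#' @export
render_movie <- function(scenario, ground_truth = NULL) {
  stopifnot(inherits(scenario, "mito_scenario"))
  gt <- ground_truth %||% simulate_kinetics(scenario)
  H <- scenario$height; W <- scenario$width; nT <- scenario$n_frames
  ind <- organelle_indicators(scenario)
  opt <- scenario$optics; nz <- scenario$noise

  grad <- if (nz$background_gradient != 0) {
    matrix(seq(0, nz$background_gradient, length.out = W), H, W, byrow = TRUE)
  } else 0

  bleach <- (1 - scenario$kinetics$bleach_rate)^(seq_len(nT) - 1)

  ri_px <- array(0, c(H, W, nT))
  tm_px <- array(0, c(H, W, nT))
  with_seed(scenario$seed + 2L, {
    for (k in seq_len(nT)) {
      ri_f <- matrix(opt$ri_background, H, W) + grad
      tm_f <- matrix(opt$tmrm_background, H, W) + grad
      for (i in seq_len(scenario$n_mito)) {
        ri_f <- ri_f + opt$ri_amplitude * gt$ri_contrast[i, k] * ind[[i]]
        tm_f <- tm_f + opt$tmrm_amplitude * gt$potential[i, k] * bleach[k] * ind[[i]]
      }
      if (nz$ri_sd > 0) ri_f <- ri_f + rnorm(H * W, 0, nz$ri_sd)
      if (nz$tmrm_sd > 0) tm_f <- tm_f + rnorm(H * W, 0, nz$tmrm_sd)
      ri_px[, , k] <- pmax(pmin(ri_f, 1), 0)
      tm_px[, , k] <- pmax(pmin(tm_f, 1), 0)
    }
  })

  list(
    ri = frame_stack(ri_px, channel = "RI",
                     frame_interval = scenario$frame_interval,
                     drug_frame = scenario$drug_frame,
                     provenance = sprintf("simulated %s seed %d",
                                          scenario$condition, scenario$seed)),
    tmrm = frame_stack(tm_px, channel = "TMRM",
                       frame_interval = scenario$frame_interval,
                       drug_frame = scenario$drug_frame,
                       provenance = sprintf("simulated %s seed %d",
                                            scenario$condition, scenario$seed)),
    ground_truth = gt
  )
}

#' Simulate a full experiment in one call
#'
#' Convenience wrapper: [make_scenario()] then [simulate_kinetics()] then
#' [render_movie()].
#'
#' @inheritParams make_scenario
#' @return list with `scenario`, `ri`, `tmrm`, `ground_truth`.
#' @export
simulate_experiment <- function(condition, n_mito = 10, n_frames = 80,
                                drug_frame = 10, seed = 1,
                                overrides = list()) {
  sc <- make_scenario(condition, n_mito = n_mito, n_frames = n_frames,
                      drug_frame = drug_frame, seed = seed,
                      overrides = overrides)
  mov <- render_movie(sc)
  c(list(scenario = sc), mov)
}

#' Write a simulated experiment to disk
#'
#' Writes both channel TIFFs, a flat YAML metadata sidecar (condition,
#' drug_frame, frame_interval, fccp_frames, seed, image size) and the
#' ground-truth table (one row per organelle: id, onset_s, perm_s, ellipse
#' geometry) as tab-delimited text.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return tibble of the four file paths written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- sim$scenario
  paths <- c(ri = file.path(dir, "ri.tif"),
             tmrm = file.path(dir, "tmrm.tif"),
             metadata = file.path(dir, "metadata.yaml"),
             ground_truth = file.path(dir, "ground_truth.tsv"))
  write_stack(sim$ri, paths[["ri"]])
  write_stack(sim$tmrm, paths[["tmrm"]])
  yaml::write_yaml(list(condition = sc$condition, n_mito = sc$n_mito,
                        n_frames = sc$n_frames, drug_frame = sc$drug_frame,
                        frame_interval = sc$frame_interval,
                        fccp_frames = sc$fccp_frames, seed = sc$seed,
                        height = sc$height, width = sc$width),
                   paths[["metadata"]])
  gt_tab <- dplyr::left_join(sim$ground_truth$organelles, sc$geometry,
                             by = "id")
  write.table(gt_tab, paths[["ground_truth"]], sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(tibble(file = names(paths), path = unname(paths)))
}
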