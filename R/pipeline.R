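#' End-to-end analysis of one dual-channel movie
#'
#' Runs the full pipeline on a matched pair of stacks: segmentation of the
#' RI channel (pixel classifier if supplied, movie-level threshold
#' otherwise), baseline ROI definition on the TMRM channel, area and
#' normalized-potential traces, organelle tracking and event detection.
#'
#' @param ri_stack RI [frame_stack()].
#' @param tmrm_stack matched TMRM [frame_stack()] (same frame count and
#'   drug frame).
#' @param classifier optional [train_pixel_classifier()] object.
#' @param fccp_frame 0-based frame at which the terminal FCCP normalization
#'   pulse was added (default: 5 frames before the movie end, the standard
#'   protocol).  The onset scan stops here, so the pulse — which collapses
#'   the potential in every condition — is never read as a depolarization
#'   onset.
#' @param fccp_window 0-based frames of the fully collapsed FCCP anchor
#'   used for normalization (default: last 3 frames).
#' @param min_object_px,min_roi_px size filters for masks and ROIs.
#' @param onset_params,perm_params detector overrides, see
#'   [summarize_events()].
#' @return list of class `mito_analysis`: `masks`, `rois`, `traces`,
#'   `tracks`, `events`.
#' @export
analyze_movie <- function(ri_stack, tmrm_stack, classifier = NULL,
                          fccp_frame = NULL, fccp_window = NULL,
                          min_object_px = 10, min_roi_px = 20,
                          onset_params = list(), perm_params = list()) {
  stopifnot(inherits(ri_stack, "frame_stack"),
            inherits(tmrm_stack, "frame_stack"))
  if (n_frames(ri_stack) != n_frames(tmrm_stack)) {
    abort("RI and TMRM stacks have different frame counts.")
  }
  if (ri_stack$drug_frame != tmrm_stack$drug_frame) {
    abort("RI and TMRM stacks disagree on `drug_frame`.")
  }
  fccp_frame <- fccp_frame %||% (n_frames(tmrm_stack) - 5L)
  fccp_window <- fccp_window %||% fccp_frames_window(tmrm_stack)
  onset_search_end <- fccp_frame
  masks <- segment_stack(ri_stack, classifier = classifier,
                         min_object_px = min_object_px)
  rois <- define_rois(tmrm_stack, min_roi_px = min_roi_px)
  if (length(rois$roi_ids) == 0) {
    warn("No ROIs; returning an empty analysis.")
    return(structure(list(masks = masks, rois = rois, traces = tibble(),
                          tracks = NULL, events = tibble()),
                     class = "mito_analysis"))
  }
  traces <- mito_traces(masks, tmrm_stack, rois, fccp_window = fccp_window)
  tracks <- track_organelles(masks)
  onset_params <- modifyList(list(search_end = onset_search_end),
                             onset_params)
  events <- summarize_events(tracks, traces, rois,
                             onset_params = onset_params,
                             perm_params = perm_params)
  structure(list(masks = masks, rois = rois, traces = traces,
                 tracks = tracks, events = events),
            class = "mito_analysis")
}

#' @export
print.mito_analysis <- function(x, ...) {
  cat(sprintf(
    "<mito_analysis> %d ROIs, %d tracks, %d events (%d with permeabilization)\n",
    length(x$rois$roi_ids),
    if (is.null(x$tracks)) 0L else nrow(track_summary(x$tracks)),
    nrow(x$events), sum(!is.na(x$events$perm_frame))))
  invisible(x)
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("Config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  config
}

write_config_echo <- function(config, out_dir) {
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
}

#' Pipeline commands: simulate, analyze, report
#'
#' Thin orchestration layer over the package functions, driven by a flat
#' YAML config (or an equivalent named list).  Every command writes its
#' outputs as delimited text plus a `resolved_config.yaml` echoing the
#' exact parameters used, so runs are reproducible from the output
#' directory alone.
#'
#' `cmd_simulate` needs `condition`, `out_dir` and optionally `n_mito`,
#' `n_frames`, `drug_frame`, `seed`.  `cmd_analyze` needs `ri`, `tmrm`
#' (TIFF paths), `drug_frame`, `out_dir`, optionally `frame_interval`,
#' `min_object_px`, `min_roi_px`.  `cmd_report` needs `inputs` (named list
#' or vector: group label -> directory written by `cmd_analyze`) and
#' `out_dir`.
#'
#' @param config path to a YAML file or a named list.
#' @return tibble of output paths (`cmd_simulate`, `cmd_analyze`) or a list
#'   of summary tables (`cmd_report`), invisibly.
#' @export
cmd_simulate <- function(config) {
  cfg <- read_config(config)
  if (is.null(cfg$condition) || is.null(cfg$out_dir)) {
    abort("`cmd_simulate` config needs `condition` and `out_dir`.")
  }
  sim <- simulate_experiment(
    cfg$condition,
    n_mito = cfg$n_mito %||% 10, n_frames = cfg$n_frames %||% 80,
    drug_frame = cfg$drug_frame %||% 10, seed = cfg$seed %||% 1,
    overrides = cfg$overrides %||% list())
  files <- write_simulation(sim, cfg$out_dir)
  write_config_echo(cfg, cfg$out_dir)
  inform(sprintf("Simulated %s: %d organelles, %d frames -> %s",
                 cfg$condition, sim$scenario$n_mito, sim$scenario$n_frames,
                 cfg$out_dir))
  invisible(files)
}

#' @rdname cmd_simulate
#' @export
cmd_analyze <- function(config) {
  cfg <- read_config(config)
  for (f in c("ri", "tmrm", "out_dir")) {
    if (is.null(cfg[[f]])) abort(sprintf("`cmd_analyze` config needs `%s`.", f))
  }
  if (!file.exists(cfg$tmrm)) abort(sprintf("TMRM stack not found: %s", cfg$tmrm))
  if (!file.exists(cfg$ri)) abort(sprintf("RI stack not found: %s", cfg$ri))
  meta_path <- file.path(dirname(cfg$ri), "metadata.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  drug_frame <- cfg$drug_frame %||% meta$drug_frame
  if (is.null(drug_frame)) abort("`drug_frame` missing (config or metadata sidecar).")
  dt <- cfg$frame_interval %||% meta$frame_interval %||% 15
  ri <- read_stack(cfg$ri, channel = "RI", frame_interval = dt,
                   drug_frame = drug_frame)
  tmrm <- read_stack(cfg$tmrm, channel = "TMRM", frame_interval = dt,
                     drug_frame = drug_frame)
  fccp_frame <- cfg$fccp_frame %||%
    (n_frames(ri) - (meta$fccp_frames %||% 5L))
  ana <- analyze_movie(ri, tmrm, fccp_frame = fccp_frame,
                       min_object_px = cfg$min_object_px %||% 10,
                       min_roi_px = cfg$min_roi_px %||% 20)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(traces = file.path(cfg$out_dir, "traces.tsv"),
             tracks = file.path(cfg$out_dir, "tracks.tsv"),
             events = file.path(cfg$out_dir, "events.tsv"))
  write.table(ana$traces, paths[["traces"]], sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(as.data.frame(ana$tracks), paths[["tracks"]], sep = "\t",
              row.names = FALSE, quote = FALSE)
  ev <- ana$events
  if (!is.null(cfg$condition)) ev$condition <- cfg$condition
  write.table(as.data.frame(ev), paths[["events"]], sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_config_echo(cfg, cfg$out_dir)
  inform(sprintf("Analyzed %s: %d ROIs, %d tracks, %d events",
                 cfg$ri, length(ana$rois$roi_ids),
                 nrow(track_summary(ana$tracks)), nrow(ana$events)))
  invisible(tibble(file = names(paths), path = unname(paths)))
}

#' @rdname cmd_simulate
#' @export
cmd_report <- function(config) {
  cfg <- read_config(config)
  if (is.null(cfg$inputs) || length(cfg$inputs) == 0) {
    abort("`cmd_report` config needs `inputs` (group -> analysis directory).")
  }
  if (is.null(cfg$out_dir)) abort("`cmd_report` config needs `out_dir`.")
  inputs <- unlist(cfg$inputs)
  groups <- names(inputs) %||% basename(inputs)
  dat <- purrr::map2(inputs, groups, function(dir, grp) {
    tp <- file.path(dir, "traces.tsv")
    ep <- file.path(dir, "events.tsv")
    if (!file.exists(tp)) abort(sprintf("No traces.tsv in %s", dir))
    traces <- as_tibble(read.table(tp, header = TRUE, sep = "\t"))
    events <- if (file.exists(ep)) {
      as_tibble(read.table(ep, header = TRUE, sep = "\t"))
    } else tibble()
    ra <- remaining_area(traces) |> mutate(group = grp, dir = dir)
    list(remaining = ra, events = mutate(events, group = grp))
  })
  remaining <- bind_rows(purrr::map(dat, "remaining"))
  events <- bind_rows(purrr::map(dat, "events"))
  summ <- group_summary(remaining, remaining_area, group)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(summ, file.path(cfg$out_dir, "remaining_area_summary.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  tests <- NULL
  if (length(unique(remaining$group)) >= 2) {
    tst <- compare_groups(remaining, remaining_area, group,
                          test = if (length(unique(remaining$group)) == 2)
                            "t_test" else "one_way_anova")
    tests <- tidy(tst)
    write.table(tests, file.path(cfg$out_dir, "tests.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  } else {
    inform("Single group: summaries only, tests skipped.")
  }
  write_config_echo(cfg, cfg$out_dir)
  invisible(list(remaining_area = remaining, summary = summ, tests = tests,
                 events = events))
}
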