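# Seeded full-scale cohorts shared by the acceptance tests: 10-organelle,
# 80-frame movies at default parameters, run through the complete pipeline.

run_cohort <- function(condition, seeds, n_mito = 10, n_frames = 80,
                       drug_frame = 10) {
  purrr::map(seeds, function(s) {
    sim <- simulate_experiment(condition, n_mito = n_mito,
                               n_frames = n_frames, drug_frame = drug_frame,
                               seed = s)
    ana <- suppressWarnings(analyze_movie(sim$ri, sim$tmrm))
    list(seed = s,
         events = dplyr::mutate(ana$events, seed = s, condition = condition),
         remaining = dplyr::mutate(remaining_area(ana$traces), seed = s,
                                   condition = condition),
         ground_truth = sim$ground_truth$organelles)
  })
}

wt_cohort_full <- function() {
  fixture("wt_cohort_full", function() run_cohort("WT_FERUTININ", 1:20))
}

condition_cohorts <- function() {
  fixture("condition_cohorts", function() {
    list(
      WT_FERUTININ = wt_cohort_full()[1:10],
      WT_FERUTININ_CSA = run_cohort("WT_FERUTININ_CSA", 21:30),
      FCCP_ONLY = run_cohort("FCCP_ONLY", 31:40),
      KO_FERUTININ = run_cohort("KO_FERUTININ", 41:50)
    )
  })
}

cohort_events <- function(cohort) dplyr::bind_rows(purrr::map(cohort, "events"))
cohort_remaining <- function(cohort) dplyr::bind_rows(purrr::map(cohort, "remaining"))
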