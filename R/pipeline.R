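#' Run one simulated cone assay end to end
#'
#' Chains the full pipeline on one cohort: simulate truth, render the
#' video, detect movement, and aggregate activity.  This is the package's
#' one-call version of a video cone test.
#'
#' @param params A [behavior_params()].
#' @param geometry A [cone_geometry()].
#' @param n_agents,duration,dt Assay design, as in [simulate_cohort()].
#' @param blob_radius,agent_intensity,noise_sd Rendering, as in
#'   [render_video()].
#' @param vision A [mog_params()].
#' @param min_area,max_area Blob filter.
#' @param assay_id,strain,net Metadata carried into the profile.
#' @param keep_frames Keep the rendered array in the result (off by
#'   default; frame stacks are large).
#' @return A list with `truth`, `series`, `profile`, `scans` and
#'   `total_activity`.
#' @export
run_assay <- function(params, geometry, n_agents = 5, duration = 180,
                      dt = 0.1, blob_radius = 3, agent_intensity = 40,
                      noise_sd = 4, vision = mog_params(), min_area = 6,
                      max_area = 400, assay_id = "assay",
                      strain = NA_character_, net = NA_character_,
                      keep_frames = FALSE) {
  truth <- simulate_cohort(params, geometry, n_agents = n_agents,
                           duration = duration, dt = dt)
  frames <- render_video(truth, geometry, blob_radius = blob_radius,
                         agent_intensity = agent_intensity,
                         noise_sd = noise_sd)
  series <- analyze_recording(frames, fps = 1 / dt, interval = dt,
                              duration = duration, params = vision,
                              min_area = min_area, max_area = max_area)
  profile <- aggregate_bins(series, geometry, assay_id = assay_id,
                            strain = strain, net = net)
  scans <- scan_sample(truth, interval = 5)
  out <- list(truth = truth, series = series, profile = profile,
              scans = scans, total_activity = profile$total_activity)
  if (keep_frames) out$frames <- frames
  out
}

#' Scaled-down cone geometry for simulation studies
#'
#' A 40 x 30 px frame with the same cone proportions as the default
#' geometry.  Used for repeated-pipeline experiments (e.g.
#' [power_study()]) where many full assays must be rendered and analyzed;
#' the behavioural model is resolution-independent, only pixel sizes
#' shrink.
#'
#' @return A [cone_geometry()].
#' @export
study_geometry <- function() {
  cone_geometry(frame_width = 40, frame_height = 30, apex_y = 3,
                base_y = 27, apex_halfwidth = 3, base_halfwidth = 16)
}

#' Total-activity group comparison through the full pipeline
#'
#' Simulates `n_per_arm` complete assays per arm under two behavioural
#' parameterisations, runs each through render -> detect -> activity, and
#' compares the arms' total activity with [welch_t()].
#'
#' @param params_a,params_b Arm parameterisations ([behavior_params()]).
#' @param geometry A [cone_geometry()] (default [study_geometry()]).
#' @param n_per_arm Assays per arm.
#' @param duration,dt Assay design.
#' @param blob_radius,noise_sd,min_area,max_area Rendering/detection
#'   settings scaled to the geometry.
#' @return A list with `p`, `t`, `df`, `d` (observed standardised
#'   effect), `totals_a`, `totals_b`.
#' @export
compare_arms <- function(params_a, params_b, geometry = study_geometry(),
                         n_per_arm = 10, duration = 180, dt = 0.1,
                         blob_radius = 2, noise_sd = 4, min_area = 3,
                         max_area = 120) {
  one_arm <- function(params) {
    vapply(seq_len(n_per_arm), function(i) {
      run_assay(params, geometry, duration = duration, dt = dt,
                blob_radius = blob_radius, noise_sd = noise_sd,
                min_area = min_area, max_area = max_area)$total_activity
    }, numeric(1))
  }
  ta <- one_arm(params_a)
  tb <- one_arm(params_b)
  ga <- group_summary(ta, label = "arm_a")
  gb <- group_summary(tb, label = "arm_b")
  wt <- welch_t(ga, gb)
  d <- cohens_d(ga, gb)
  list(p = wt$p, t = wt$t, df = wt$df, d = d$d, totals_a = ta,
       totals_b = tb)
}

#' Default arm parameterisations for the discrimination study
#'
#' Two irritancy settings -- a strongly irritant surface versus a weakly
#' irritant one -- calibrated once by simulation so the standardised
#' effect on pipeline-measured total activity is about 2.5 under the
#' [study_geometry()] design with 10 assays per arm (the scale of the
#' resistant-strain contrast the platform is meant to resolve).
#'
#' @return A named list with elements `a` and `b`
#'   ([behavior_params()] objects).
#' @export
study_arms <- function() {
  list(a = net_presets("irritant", flight_speed = 20),
       b = net_presets("weak_irritant", flight_speed = 20))
}

#' Repeated-pipeline discrimination study
#'
#' Repeats [compare_arms()] `n_reps` times and reports how often the full
#' simulate -> render -> detect -> activity -> Welch chain flags the
#' between-arm difference at `alpha`.  With arms of standardised effect
#' around 2.5 and 10 assays per arm the chain should flag nearly every
#' repetition at `alpha = 0.01`.
#'
#' @param params_a,params_b Arm parameterisations (default
#'   [study_arms()]).
#' @param n_reps Number of repetitions.
#' @param alpha Significance threshold.
#' @param seed Optional seed for the whole study.
#' @param ... Passed to [compare_arms()].
#' @return A list with `reject_rate`, `p_values`, `d_values`.
#' @export
power_study <- function(params_a = study_arms()$a,
                        params_b = study_arms()$b, n_reps = 100,
                        alpha = 0.01, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ps <- numeric(n_reps)
  ds <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    res <- compare_arms(params_a, params_b, ...)
    ps[r] <- res$p
    ds[r] <- res$d
  }
  list(reject_rate = mean(ps < alpha), p_values = ps, d_values = ds)
}
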