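#' Behavioural parameters for the cone assay simulator
#'
#' Transition hazards between the four behavioural states observed in cone
#' assays: contacting the net (N), flying within the cone (F), resting on
#' the cone surface (C) and knocked down (K).  Hazards are per second;
#' transition probabilities on the simulation grid are
#' `1 - exp(-rate * dt)`.
#'
#' Irritancy (excito-repellency) is modelled as a multiplier
#' `1 + irritancy_gain * contact_time` on the N->F and C->F rates, so
#' accumulated exposure to an irritant net surface drives activity up.
#' Knockdown is delayed toxicity: the per-second hazard at any instant is
#' `toxicity_hazard * cumulative_contact_time`, so knockdowns accumulate
#' late in the assay.  `toxicity_hazard = 0` guarantees zero knockdowns.
#'
#' @param rate_C_to_F,rate_F_to_C,rate_F_to_N,rate_N_to_F Per-second
#'   transition hazards (all >= 0).
#' @param irritancy_gain Dimensionless gain per contact-second (>= 0).
#' @param toxicity_hazard Knockdown hazard per second per contact-second
#'   (>= 0).
#' @param flight_speed Flight speed in pixels per second.
#' @param rng_seed Optional integer seed used by [simulate_cohort()]; if
#'   `NULL` the current RNG stream is used.
#' @return An object of class `behavior_params`.
#' @seealso [net_presets()] for ready-made parameter sets.
#' @export
behavior_params <- function(rate_C_to_F = 0.08, rate_F_to_C = 0.15,
                            rate_F_to_N = 0.06, rate_N_to_F = 0.10,
                            irritancy_gain = 0, toxicity_hazard = 0,
                            flight_speed = 60, rng_seed = NULL) {
  rates <- c(rate_C_to_F, rate_F_to_C, rate_F_to_N, rate_N_to_F,
             irritancy_gain, toxicity_hazard)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all hazards and gains must be finite and non-negative")
  stopifnot(is.finite(flight_speed), flight_speed > 0)
  p <- list(rate_C_to_F = rate_C_to_F, rate_F_to_C = rate_F_to_C,
            rate_F_to_N = rate_F_to_N, rate_N_to_F = rate_N_to_F,
            irritancy_gain = irritancy_gain,
            toxicity_hazard = toxicity_hazard,
            flight_speed = flight_speed, rng_seed = rng_seed)
  class(p) <- "behavior_params"
  p
}

#' Preset behavioural parameter sets
#'
#' Qualitative presets emulating the characteristic activity shapes of cone
#' assays: a `control` (untreated) net with stable low-to-moderate activity;
#' an `irritant_toxic` net producing the susceptible-strain response (a
#' pronounced rise in activity that declines in the second half as
#' knockdowns accumulate); an `irritant` net producing a sustained rise
#' without knockdown (the resistant-strain response to a bioavailable
#' surface); and `weak_irritant`, the attenuated response to a surface with
#' poor insecticide bioavailability (prolonged net contact, little activity
#' rise).  Rates were chosen once to reproduce
#' these shapes; they are illustrative, not estimates of any real strain.
#'
#' @param name One of `"control"`, `"irritant"`, `"weak_irritant"`,
#'   `"irritant_toxic"`.
#' @param ... Overrides passed on to [behavior_params()].
#' @return A `behavior_params` object.
#' @export
net_presets <- function(name = c("control", "irritant", "weak_irritant",
                                 "irritant_toxic"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    control = list(),
    irritant = list(rate_F_to_N = 0.12, rate_N_to_F = 0.25,
                    irritancy_gain = 0.20),
    weak_irritant = list(rate_F_to_N = 0.12, rate_N_to_F = 0.13,
                         irritancy_gain = 0.02),
    irritant_toxic = list(rate_F_to_N = 0.12, rate_N_to_F = 0.25,
                          irritancy_gain = 0.20, toxicity_hazard = 4e-4))
  do.call(behavior_params, utils::modifyList(base, list(...)))
}

#' Simulate a mosquito cohort in a WHO cone assay
#'
#' Agent-based simulation of `n_agents` mosquitoes confined under a cone
#' for `duration` seconds, on a time grid of step `dt`.  All agents start
#' in flight at uniform positions in the cone interior.  Flying agents
#' follow a correlated random walk clipped to the cone silhouette; agents
#' contacting the net sit on the net edge; resting agents sit on the cone
#' wall; knocked-down agents drop to the base and stay there (K is
#' absorbing).
#'
#' @param params A [behavior_params()].
#' @param geometry A [cone_geometry()].
#' @param n_agents Cohort size (the WHO cone assay uses 5).
#' @param duration Assay duration in seconds.
#' @param dt Time step in seconds; must divide `duration`.
#' @return A `truth_log`: a data frame with one row per (frame, agent) and
#'   columns `frame_index` (0-based), `time_s`, `agent_id`, `state`
#'   (`"N"`, `"F"`, `"C"`, `"K"`), `x`, `y`,
#'   `cumulative_contact_time`.  The geometry, parameters and grid are
#'   attached as attributes.
#' @examples
#' truth <- simulate_cohort(behavior_params(rng_seed = 1), cone_geometry(),
#'                          duration = 10)
#' table(truth$state[truth$frame_index == 100])
#' @export
simulate_cohort <- function(params, geometry, n_agents = 5, duration = 180,
                            dt = 0.1) {
  stopifnot(inherits(params, "behavior_params"),
            inherits(geometry, "cone_geometry"),
            n_agents >= 1, duration > 0, dt > 0)
  nstep <- duration / dt
  if (abs(nstep - round(nstep)) > 1e-8)
    stop("`dt` must divide `duration` into a whole number of steps")
  nstep <- as.integer(round(nstep))

  if (!is.null(params$rng_seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(params$rng_seed)
  }

  sim <- simulate_cohort_cpp(
    n_agents = as.integer(n_agents), nstep = nstep, dt = dt,
    rate_C_to_F = params$rate_C_to_F, rate_F_to_C = params$rate_F_to_C,
    rate_F_to_N = params$rate_F_to_N, rate_N_to_F = params$rate_N_to_F,
    irritancy_gain = params$irritancy_gain,
    toxicity_hazard = params$toxicity_hazard,
    flight_speed = params$flight_speed, turn_sd = 0.6,
    cx = geometry$center_x, apex_y = geometry$apex_y,
    base_y = geometry$base_y, apex_hw = geometry$apex_halfwidth,
    base_hw = geometry$base_halfwidth)

  nt <- nstep + 1L
  codes <- c("N", "F", "C", "K")
  truth <- data.frame(
    frame_index = rep(0:nstep, each = n_agents),
    time_s = rep(round((0:nstep) * dt, 6), each = n_agents),
    agent_id = rep(seq_len(n_agents), times = nt),
    state = codes[as.vector(t(sim$state))],
    x = as.vector(t(sim$x)),
    y = as.vector(t(sim$y)),
    cumulative_contact_time = round(as.vector(t(sim$contact)), 6),
    stringsAsFactors = FALSE)
  structure(truth, class = c("truth_log", "data.frame"),
            geometry = geometry, params = params, n_agents = n_agents,
            duration = duration, dt = dt)
}

#' Write / read a truth log as CSV
#'
#' The on-disk layout is one row per (frame, agent) with columns
#' `frame_index, time_s, agent_id, state, x, y, cumulative_contact_time`.
#' Grid metadata (`dt`, `duration`, `n_agents`) is recovered from the data
#' on read.
#'
#' @param truth A `truth_log` from [simulate_cohort()].
#' @param path File path.
#' @return `write_truth_csv()` returns `path` invisibly;
#'   `read_truth_csv()` returns a `truth_log` data frame.
#' @export
write_truth_csv <- function(truth, path) {
  write.csv(as.data.frame(truth), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  truth <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "time_s", "agent_id", "state", "x", "y",
            "cumulative_contact_time")
  if (!all(need %in% names(truth)))
    stop("not a truth log CSV; missing columns: ",
         paste(setdiff(need, names(truth)), collapse = ", "))
  n_agents <- length(unique(truth$agent_id))
  dt <- if (max(truth$frame_index) > 0)
    max(truth$time_s) / max(truth$frame_index) else NA_real_
  structure(truth, class = c("truth_log", "data.frame"),
            n_agents = n_agents, duration = max(truth$time_s), dt = dt)
}
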