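# Shared fixtures: everything is generated in code at test time.

# mid-size geometry for module tests (cheap to render, uncrowded)
test_geometry <- function() {
  cone_geometry(frame_width = 64, frame_height = 48, apex_y = 4,
                base_y = 44, apex_halfwidth = 5, base_halfwidth = 26)
}

# a hand-built truth log (no simulator) for tests that need exact states
manual_truth <- function(states, x, y, dt = 0.1) {
  n_agents <- ncol(states)
  nt <- nrow(states)
  truth <- data.frame(
    frame_index = rep(0:(nt - 1), each = n_agents),
    time_s = rep(round((0:(nt - 1)) * dt, 6), each = n_agents),
    agent_id = rep(seq_len(n_agents), times = nt),
    state = as.vector(t(states)),
    x = as.vector(t(x)),
    y = as.vector(t(y)),
    cumulative_contact_time = 0)
  structure(truth, class = c("truth_log", "data.frame"),
            n_agents = n_agents, duration = (nt - 1) * dt, dt = dt)
}

# detection series built directly (bypassing the vision stage)
manual_series <- function(counts, blob_x, blob_y, interval = 0.1,
                          burnin_frames = 0) {
  n <- length(counts)
  frames <- data.frame(frame_index = 0:(n - 1),
                       time_s = round((0:(n - 1)) * interval, 6),
                       count = counts,
                       burnin = seq_len(n) <= burnin_frames)
  blobs <- data.frame(
    frame_index = rep(frames$frame_index, counts),
    x = blob_x, y = blob_y,
    area = rep(10, sum(counts)))
  structure(list(frames = frames, blobs = blobs, interval = interval,
                 duration = n * interval,
                 burnin = burnin_frames * interval),
            class = "detection_series")
}
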