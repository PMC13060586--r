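#' Score a detection series against simulator ground truth
#'
#' The simulator's truth log is the oracle for the vision stage.  The
#' detector counts *moving* mosquitoes, so the truth "moving" set at an
#' analyzed frame is the agents whose position changed by more than
#' `min_displacement` pixels since the previous frame (flying agents every
#' frame, plus single-frame relocations such as landing on the net or
#' dropping at knockdown).  Detections are matched one-to-one to truth
#' agent positions greedily by increasing distance, accepted within
#' `radius` pixels.  Recall is the fraction of truth movers matched by a
#' detection; precision is the fraction of detections that fall on *any*
#' real mosquito (a detection on a mosquito that has just stopped moving
#' is model-adaptation lag, not a phantom -- only detections matching no
#' agent, e.g. ghosts at vacated positions or noise clusters, count as
#' false alarms); `frame_agreement` is the fraction of frames whose
#' detected count is within 1 of the truth moving count.
#'
#' @param series A `detection_series` from [analyze_recording()].
#' @param truth The `truth_log` the recording was rendered from.
#' @param radius Match radius in pixels (typically the rendered blob
#'   radius).
#' @param min_displacement Per-frame displacement above which an agent
#'   counts as moving.
#' @return A list with `recall`, `precision`, `frame_agreement`, and the
#'   underlying tallies `n_truth`, `n_detected`, `n_matched` (detections
#'   matched to movers) and `n_on_agent` (detections matched to any
#'   agent).
#' @export
score_detections <- function(series, truth, radius,
                             min_displacement = 0.25) {
  stopifnot(inherits(series, "detection_series"),
            inherits(truth, "truth_log"), radius > 0)
  n_agents <- length(unique(truth$agent_id))
  nt <- nrow(truth) / n_agents
  X <- matrix(truth$x, nrow = nt, ncol = n_agents, byrow = TRUE)
  Y <- matrix(truth$y, nrow = nt, ncol = n_agents, byrow = TRUE)
  moved <- rbind(FALSE,
                 sqrt(diff(X)^2 + diff(Y)^2) > min_displacement)

  fr <- series$frames[!series$frames$burnin, , drop = FALSE]
  blobs <- split(series$blobs, factor(series$blobs$frame_index,
                                      levels = fr$frame_index))
  n_truth <- 0L
  n_det <- 0L
  n_match <- 0L
  agree <- 0L
  n_on_agent <- 0L
  for (i in seq_len(nrow(fr))) {
    fi <- fr$frame_index[i]
    mv <- moved[fi + 1L, ]
    tx <- X[fi + 1L, ]
    ty <- Y[fi + 1L, ]
    bl <- blobs[[i]]
    n_truth <- n_truth + sum(mv)
    n_det <- n_det + nrow(bl)
    if (abs(nrow(bl) - sum(mv)) <= 1) agree <- agree + 1L
    if (!nrow(bl)) next
    d <- outer(seq_len(nrow(bl)), seq_len(n_agents), function(a, b)
      sqrt((bl$x[a] - tx[b])^2 + (bl$y[a] - ty[b])^2))
    used_b <- logical(nrow(bl))
    used_t <- logical(n_agents)
    for (k in order(d)) {
      if (d[k] > radius) break
      a <- (k - 1) %% nrow(bl) + 1
      b <- (k - 1) %/% nrow(bl) + 1
      if (used_b[a] || used_t[b]) next
      used_b[a] <- TRUE
      used_t[b] <- TRUE
      n_on_agent <- n_on_agent + 1L
      if (mv[b]) n_match <- n_match + 1L
    }
  }
  list(recall = if (n_truth) n_match / n_truth else NA_real_,
       precision = if (n_det) n_on_agent / n_det else NA_real_,
       frame_agreement = agree / nrow(fr),
       n_truth = n_truth, n_detected = n_det, n_matched = n_match,
       n_on_agent = n_on_agent)
}
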