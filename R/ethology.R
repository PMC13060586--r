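#' Scan-sample behavioural states from a truth log
#'
#' Emulates manual scan sampling of a cone-assay recording: at every
#' `interval` seconds (t = 0 through t = duration inclusive) the number of
#' mosquitoes in each behavioural state is recorded.  A 180-s assay at 5-s
#' intervals yields 37 time points.
#'
#' @param truth A `truth_log` from [simulate_cohort()] or
#'   [read_truth_csv()].
#' @param interval Scan interval in seconds.
#' @return A data frame with columns `time_point_s`, `n_N`, `n_F`, `n_C`,
#'   `n_K`; rows sum to the cohort size.
#' @export
scan_sample <- function(truth, interval = 5) {
  stopifnot(inherits(truth, "truth_log"), interval > 0)
  times <- sort(unique(truth$time_s))
  points <- seq(0, max(times), by = interval)
  missing <- points[!points %in% times]
  if (length(missing))
    stop("truth grid is missing scan instants: ",
         paste(head(missing, 3), collapse = ", "))
  out <- do.call(rbind, lapply(points, function(tp) {
    st <- truth$state[truth$time_s == tp]
    data.frame(time_point_s = tp,
               n_N = sum(st == "N"), n_F = sum(st == "F"),
               n_C = sum(st == "C"), n_K = sum(st == "K"))
  }))
  rownames(out) <- NULL
  out
}

#' Summarise behavioural states across replicates
#'
#' Per-time-point arithmetic mean and t-based confidence interval of the
#' count in each state across replicate assays.  Because the per-replicate
#' counts sum to the cohort size at every time point, so do the means.
#'
#' @param scans A list of scan-record data frames from [scan_sample()] with
#'   aligned time points.
#' @param level Confidence level.
#' @return A data frame with columns `time_point_s`, `state`, `mean`,
#'   `ci_lo`, `ci_hi`.
#' @export
summarize_states <- function(scans, level = 0.95) {
  stopifnot(length(scans) >= 2)
  tp <- scans[[1]]$time_point_s
  for (s in scans[-1]) {
    if (!identical(s$time_point_s, tp))
      stop("replicates have misaligned time grids")
  }
  n <- length(scans)
  tcrit <- qt(1 - (1 - level) / 2, n - 1)
  out <- do.call(rbind, lapply(c("N", "F", "C", "K"), function(st) {
    col <- paste0("n_", st)
    m <- vapply(scans, function(s) s[[col]], numeric(length(tp)))
    mu <- rowMeans(m)
    se <- apply(m, 1, sd) / sqrt(n)
    data.frame(time_point_s = tp, state = st, mean = mu,
               ci_lo = mu - tcrit * se, ci_hi = mu + tcrit * se)
  }))
  rownames(out) <- NULL
  out
}

#' Read / write scan records in tidy CSV form
#'
#' The expected external layout (e.g. exported from an ethology-coding
#' tool) is tidy: one row per (assay, time point, state) with columns
#' `assay_id, time_point_s, state, count`, where `state` is one of
#' `N`, `F`, `C`, `K`.  `read_scan_csv()` converts that layout to one
#' wide scan-record data frame per assay.
#'
#' @param path CSV path.
#' @return A named list of scan-record data frames, one per `assay_id`.
#' @export
read_scan_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("assay_id", "time_point_s", "state", "count")
  if (!all(need %in% names(tab)))
    stop("expected tidy columns: ", paste(need, collapse = ", "))
  if (!all(tab$state %in% c("N", "F", "C", "K")))
    stop("states must be N, F, C or K")
  lapply(split(tab, tab$assay_id), function(d) {
    wide <- do.call(rbind, lapply(sort(unique(d$time_point_s)), function(tp) {
      cnt <- function(st) {
        v <- d$count[d$time_point_s == tp & d$state == st]
        if (length(v)) sum(v) else 0L
      }
      data.frame(time_point_s = tp, n_N = cnt("N"), n_F = cnt("F"),
                 n_C = cnt("C"), n_K = cnt("K"))
    }))
    rownames(wide) <- NULL
    wide
  })
}

#' @param scans A named list of scan-record data frames (as returned by
#'   [read_scan_csv()] or built from [scan_sample()]).
#' @rdname read_scan_csv
#' @export
write_scan_csv <- function(scans, path) {
  if (is.data.frame(scans)) scans <- list(assay = scans)
  tidy <- do.call(rbind, lapply(names(scans), function(id) {
    s <- scans[[id]]
    do.call(rbind, lapply(c("N", "F", "C", "K"), function(st) {
      data.frame(assay_id = id, time_point_s = s$time_point_s, state = st,
                 count = s[[paste0("n_", st)]])
    }))
  }))
  tidy <- tidy[order(tidy$assay_id, tidy$time_point_s, tidy$state), ]
  write.csv(tidy, path, row.names = FALSE)
  invisible(path)
}
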