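#' Aggregate a detection series into an activity profile
#'
#' Converts per-frame detections into the per-assay behavioural summary:
#' total activity (the number of movements detected during the assay,
#' excluding burn-in frames) and counts in half-open 5-s bins `[t, t+5)`
#' split by upper/lower cone region.  Every detection falls in exactly one
#' region and one bin, so per-bin top + bottom counts sum to the total.
#'
#' @param series A `detection_series` from [analyze_recording()].
#' @param geometry The [cone_geometry()] used for the upper/lower split.
#' @param bin_width Bin width in seconds (must divide the assay duration).
#' @param assay_id Optional identifier carried into the profile.
#' @param strain,net Optional replicate metadata labels.
#' @return An `activity_profile`: list with `assay_id`, `strain`, `net`,
#'   `total_activity` and `bins` (data frame `bin_start_s`, `count_top`,
#'   `count_bottom`).
#' @export
aggregate_bins <- function(series, geometry, bin_width = 5,
                           assay_id = "assay", strain = NA_character_,
                           net = NA_character_) {
  stopifnot(inherits(series, "detection_series"),
            inherits(geometry, "cone_geometry"))
  fr <- series$frames
  n_expected <- series$duration / series$interval
  if (nrow(fr) != round(n_expected))
    stop(sprintf("incomplete detection series: %d frames, expected %d",
                 nrow(fr), round(n_expected)))
  n_bins <- series$duration / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-8)
    stop("`bin_width` must divide the assay duration")
  n_bins <- as.integer(round(n_bins))
  starts <- (0:(n_bins - 1L)) * bin_width

  live <- fr$frame_index[!fr$burnin]
  blobs <- series$blobs[series$blobs$frame_index %in% live, , drop = FALSE]
  top <- integer(n_bins)
  bottom <- integer(n_bins)
  if (nrow(blobs)) {
    t_s <- blobs$frame_index * series$interval
    bin <- pmin(floor(t_s / bin_width), n_bins - 1) + 1L
    region <- assign_region(blobs$x, blobs$y, geometry)
    for (b in seq_len(n_bins)) {
      in_b <- bin == b
      top[b] <- sum(in_b & region == "top")
      bottom[b] <- sum(in_b & region == "bottom")
    }
  }
  total <- sum(fr$count[!fr$burnin])
  structure(list(assay_id = assay_id, strain = strain, net = net,
                 total_activity = total,
                 bins = data.frame(bin_start_s = starts, count_top = top,
                                   count_bottom = bottom)),
            class = "activity_profile")
}

#' Cross-replicate mean activity profile with confidence band
#'
#' Per-bin arithmetic mean and t-based 95% confidence interval across
#' replicate assays, separately for the top and bottom cone regions (the
#' quantity behind stacked mean-activity-over-time plots).
#'
#' @param profiles A list of `activity_profile` objects with identical
#'   binning.
#' @param level Confidence level.
#' @return A data frame with columns `bin_start_s`, `region`, `mean`,
#'   `ci_lo`, `ci_hi`.
#' @export
mean_profile <- function(profiles, level = 0.95) {
  stopifnot(length(profiles) >= 2,
            all(vapply(profiles, inherits, TRUE, "activity_profile")))
  starts <- profiles[[1]]$bins$bin_start_s
  for (p in profiles[-1]) {
    if (!identical(p$bins$bin_start_s, starts))
      stop("profiles have heterogeneous binning")
  }
  n <- length(profiles)
  tcrit <- qt(1 - (1 - level) / 2, n - 1)
  one_region <- function(col, label) {
    m <- vapply(profiles, function(p) p$bins[[col]], numeric(length(starts)))
    mu <- rowMeans(m)
    se <- apply(m, 1, sd) / sqrt(n)
    data.frame(bin_start_s = starts, region = label, mean = mu,
               ci_lo = mu - tcrit * se, ci_hi = mu + tcrit * se)
  }
  out <- rbind(one_region("count_top", "top"),
               one_region("count_bottom", "bottom"))
  rownames(out) <- NULL
  out
}

#' Write / read an activity profile as CSV
#'
#' One row per bin plus header metadata encoded as columns, matching a
#' "one row per cone test bin" layout; [profile_summary_row()] gives the
#' one-row-per-assay layout consumed by the statistics stage.
#'
#' @param profile An `activity_profile`.
#' @param path File path.
#' @return `write_profile_csv()` returns `path` invisibly;
#'   `read_profile_csv()` an `activity_profile`.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "activity_profile"))
  out <- cbind(assay_id = profile$assay_id, strain = profile$strain,
               net = profile$net, total_activity = profile$total_activity,
               profile$bins)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("assay_id", "total_activity", "bin_start_s", "count_top",
            "count_bottom")
  if (!all(need %in% names(tab))) stop("not an activity profile CSV")
  structure(list(assay_id = tab$assay_id[1], strain = tab$strain[1],
                 net = tab$net[1], total_activity = tab$total_activity[1],
                 bins = tab[, c("bin_start_s", "count_top", "count_bottom")]),
            class = "activity_profile")
}

#' One-row-per-assay summary of an activity profile
#'
#' @param profile An `activity_profile`.
#' @return A one-row data frame with `assay_id`, `strain`, `net`,
#'   `total_activity`.
#' @export
profile_summary_row <- function(profile) {
  data.frame(assay_id = profile$assay_id, strain = profile$strain,
             net = profile$net, total_activity = profile$total_activity,
             stringsAsFactors = FALSE)
}
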