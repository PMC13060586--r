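#' Plot a cross-replicate mean activity profile
#'
#' Mean activity over time in the top and bottom cone regions with the
#' confidence band, one panel per region stacked in one plot.
#'
#' @param mp A data frame from [mean_profile()].
#' @param main Plot title.
#' @export
plot_mean_profile <- function(mp, main = "Mean activity over time") {
  stopifnot(all(c("bin_start_s", "region", "mean") %in% names(mp)))
  cols <- c(top = "#3366AA", bottom = "#DDAA33")
  ylim <- c(0, max(mp$ci_hi, mp$mean) * 1.05)
  plot(NULL, xlim = range(mp$bin_start_s), ylim = ylim,
       xlab = "time (s)", ylab = "mean detections per 5-s bin",
       main = main)
  for (reg in unique(mp$region)) {
    d <- mp[mp$region == reg, ]
    graphics::polygon(c(d$bin_start_s, rev(d$bin_start_s)),
                      c(pmax(d$ci_lo, 0), rev(d$ci_hi)),
                      col = grDevices::adjustcolor(cols[[reg]], 0.25),
                      border = NA)
    graphics::lines(d$bin_start_s, d$mean, col = cols[[reg]], lwd = 2)
  }
  graphics::legend("topright", legend = names(cols), col = cols, lwd = 2,
                   bty = "n")
  invisible(mp)
}

#' Plot behavioural-state means over time
#'
#' Mean number of mosquitoes per state at each scan point with confidence
#' bands, in the conventional state colours (net contact, flying,
#' knocked down, resting).
#'
#' @param summary A data frame from [summarize_states()].
#' @param cohort Cohort size used for the y-axis.
#' @param main Plot title.
#' @export
plot_state_summary <- function(summary, cohort = 5,
                               main = "Behavioural states over time") {
  stopifnot(all(c("time_point_s", "state", "mean") %in% names(summary)))
  cols <- c(N = "#7B3294", F = "#008837", K = "#0571B0", C = "#CA0020")
  plot(NULL, xlim = range(summary$time_point_s), ylim = c(0, cohort),
       xlab = "time (s)", ylab = "mean mosquitoes", main = main)
  for (st in names(cols)) {
    d <- summary[summary$state == st, ]
    if (!nrow(d)) next
    graphics::polygon(c(d$time_point_s, rev(d$time_point_s)),
                      c(pmax(d$ci_lo, 0), rev(pmin(d$ci_hi, cohort))),
                      col = grDevices::adjustcolor(cols[[st]], 0.2),
                      border = NA)
    graphics::lines(d$time_point_s, d$mean, col = cols[[st]], lwd = 2)
  }
  graphics::legend("topright", legend = names(cols), col = cols, lwd = 2,
                   bty = "n")
  invisible(summary)
}
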