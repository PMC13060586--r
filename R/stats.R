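#' Group summary (n, mean, SD)
#'
#' The sufficient statistics for the two-group comparisons used throughout
#' the package: group size, mean and sample SD (n - 1 denominator).  Can be
#' built from raw values or from published summary numbers.
#'
#' @param x Either a numeric vector of raw values, or the group mean when
#'   `n` and `sd` are supplied directly.
#' @param n,sd Group size and sample SD when constructing from summaries.
#' @param label Group label.
#' @return An object of class `group_summary`.
#' @examples
#' group_summary(3628.3, n = 40, sd = 1014.209, label = "treated")
#' group_summary(rnorm(10), label = "raw")
#' @export
group_summary <- function(x, n = NULL, sd = NULL, label = "") {
  if (is.null(n) && is.null(sd)) {
    stopifnot(is.numeric(x), length(x) >= 2)
    out <- list(label = label, n = length(x), mean = mean(x),
                sd = stats::sd(x))
  } else {
    stopifnot(length(x) == 1, n >= 2, sd >= 0)
    out <- list(label = label, n = as.integer(n), mean = x, sd = sd)
  }
  class(out) <- "group_summary"
  out
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, mean = %.4g, sd = %.4g\n",
              if (nzchar(x$label)) x$label else "group", x$n, x$mean, x$sd))
  invisible(x)
}

new_stat_report <- function(...) structure(list(...), class = "stat_report")

#' @export
print.stat_report <- function(x, ...) {
  cat(x$method, "\n")
  for (nm in setdiff(names(x), c("method", "emmeans", "contrasts",
                                 "anova_table"))) {
    v <- x[[nm]]
    if (is.numeric(v) && length(v) <= 2)
      cat(sprintf("  %s: %s\n", nm, paste(signif(v, 6), collapse = " to ")))
  }
  if (!is.null(x$anova_table)) { cat("\n"); print(x$anova_table) }
  if (!is.null(x$emmeans)) { cat("\nEstimated marginal means:\n")
    for (e in x$emmeans) print(e) }
  if (!is.null(x$contrasts)) { cat("\nTukey-adjusted contrasts:\n")
    for (e in x$contrasts) print(e) }
  invisible(x)
}

#' Welch's two-sample t test from group summaries
#'
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value.  Operating on summaries
#' allows published results to be reproduced without raw data.
#'
#' @param a,b [group_summary()] objects.
#' @param level Confidence level for the difference CI.
#' @return A `stat_report` with `t`, `df`, `p`, `estimate` (mean
#'   difference) and `conf_int`.
#' @examples
#' a <- group_summary(3628.3, n = 40, sd = 1014.209)
#' b <- group_summary(3211.655, n = 55, sd = 830.311)
#' welch_t(a, b)   # t = 2.130, df = 73.649
#' @export
welch_t <- function(a, b, level = 0.95) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$sd == 0 && b$sd == 0)
    stop("both groups have zero variance; t is undefined")
  v1 <- a$sd^2 / a$n
  v2 <- b$sd^2 / b$n
  se <- sqrt(v1 + v2)
  t <- (a$mean - b$mean) / se
  df <- (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1))
  p <- 2 * pt(-abs(t), df)
  tcrit <- qt(1 - (1 - level) / 2, df)
  new_stat_report(method = "Welch two-sample t test (from summaries)",
                  t = t, df = df, p = p, estimate = a$mean - b$mean,
                  conf_int = c(a$mean - b$mean - tcrit * se,
                               a$mean - b$mean + tcrit * se),
                  groups = list(a = a, b = b))
}

#' Cohen's d with confidence interval
#'
#' Pooled-SD standardised mean difference,
#' `d = (m1 - m2) / s_p` with
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)`.  The CI uses the
#' large-sample variance `(n1+n2)/(n1 n2) + d^2 / (2 (n1+n2))` with a t
#' quantile on `n1+n2-2` df, the convention that reproduces the published
#' interval widths this package targets.
#'
#' @param a,b [group_summary()] objects with `n >= 2`.
#' @param level Confidence level.
#' @return A `stat_report` with `d` and `conf_int`.
#' @export
cohens_d <- function(a, b, level = 0.95) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"),
            a$n >= 2, b$n >= 2)
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (sp2 == 0) stop("pooled SD is zero; d is undefined")
  d <- (a$mean - b$mean) / sqrt(sp2)
  se <- sqrt((a$n + b$n) / (a$n * b$n) + d^2 / (2 * (a$n + b$n)))
  tcrit <- qt(1 - (1 - level) / 2, a$n + b$n - 2)
  new_stat_report(method = "Cohen's d (pooled SD)", d = d,
                  conf_int = c(d - tcrit * se, d + tcrit * se))
}

#' t-based confidence interval for a group mean
#'
#' `mean +/- t(1-alpha/2, n-1) * sd / sqrt(n)`.
#'
#' @param s A [group_summary()].
#' @param level Confidence level.
#' @return Numeric vector `c(lo, hi)`.
#' @export
ci_mean <- function(s, level = 0.95) {
  stopifnot(inherits(s, "group_summary"), s$n >= 2)
  half <- qt(1 - (1 - level) / 2, s$n - 1) * s$sd / sqrt(s$n)
  c(lo = s$mean - half, hi = s$mean + half)
}

#' Recover a group size from a printed mean, SD and CI bound
#'
#' Inverts [ci_mean()]: finds the integer `n` whose t-based CI upper bound
#' matches the printed value at its printed (2-decimal) precision.  Errors
#' unless the solution is unique -- this is the oracle used to pin down
#' unpublished group sizes from published summaries.
#'
#' @param mean,sd Printed group mean and SD.
#' @param ci_hi Printed CI upper bound.
#' @param level Confidence level of the printed interval.
#' @param n_max Largest group size considered.
#' @return The unique integer `n`.
#' @export
infer_n_from_ci <- function(mean, sd, ci_hi, level = 0.95, n_max = 500) {
  ns <- 2:n_max
  hi <- mean + qt(1 - (1 - level) / 2, ns - 1) * sd / sqrt(ns)
  hits <- ns[abs(hi - ci_hi) < 0.005]
  if (length(hits) == 0) stop("no group size reproduces the printed CI")
  if (length(hits) > 1)
    stop("printed CI is consistent with several group sizes: ",
         paste(hits, collapse = ", "))
  hits
}

#' Levene's test for homogeneity of variance
#'
#' Classical (mean-centred) Levene test: a one-way ANOVA on absolute
#' deviations from the group means, appropriate when group sizes are
#' unequal.  Thin wrapper around [car::leveneTest()].
#'
#' @param values Numeric response vector.
#' @param group Grouping factor (>= 2 groups of >= 2 values).
#' @param center `"mean"` (classical) or `"median"` (Brown-Forsythe).
#' @return A `stat_report` with `F`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(values, group, center = c("mean", "median")) {
  center <- match.arg(center)
  group <- factor(group)
  stopifnot(nlevels(group) >= 2, all(table(group) >= 2))
  if (all(tapply(values, group, function(v) all(v == v[1]))))
    stop("all values equal within groups; deviations are degenerate")
  fun <- if (center == "mean") base::mean else stats::median
  tab <- car::leveneTest(values ~ group, center = fun)
  new_stat_report(method = sprintf("Levene's test (%s-centred)", center),
                  F = tab[1, "F value"], df1 = tab[1, "Df"],
                  df2 = tab[2, "Df"], p = tab[1, "Pr(>F)"])
}

#' Two-way factorial ANOVA with marginal means and Tukey contrasts
#'
#' Fits `response ~ A * B` by least squares with sum-to-zero contrasts and
#' Type-III sums of squares (so results are invariant to imbalance and the
#' marginal means are unweighted over the other factor's levels, matching
#' the estimated-marginal-means convention), reports per-effect F tests
#' with partial eta squared and its one-sided 95% CI (noncentral-F
#' inversion, upper bound 1), tests residual normality with Shapiro-Wilk,
#' and returns estimated marginal means and Tukey-adjusted pairwise
#' contrasts per factor via the emmeans machinery.
#'
#' @param data A data frame.
#' @param response,factor_a,factor_b Column names.
#' @return A `stat_report` with `anova_table` (`effect`, `df`, `df_res`,
#'   `F`, `p`, `partial_eta_sq`, `eta_ci_lo`, `eta_ci_hi`), `shapiro_w`,
#'   `shapiro_p`, `emmeans` and `contrasts` (lists per factor, plus the
#'   simple effects of `factor_b` within `factor_a`).
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  stopifnot(is.data.frame(data),
            all(c(response, factor_a, factor_b) %in% names(data)))
  data[[factor_a]] <- factor(data[[factor_a]])
  data[[factor_b]] <- factor(data[[factor_b]])
  if (nlevels(data[[factor_a]]) < 2 || nlevels(data[[factor_b]]) < 2)
    stop("each factor needs at least 2 levels")
  cells <- table(data[[factor_a]], data[[factor_b]])
  if (any(cells < 2))
    stop("empty or singleton design cell: every strain x net cell needs ",
         ">= 2 observations")
  form <- reformulate(sprintf("%s * %s", factor_a, factor_b), response)
  contr <- setNames(list("contr.sum", "contr.sum"), c(factor_a, factor_b))
  fit <- lm(form, data = data, contrasts = contr)
  at <- car::Anova(fit, type = 3)
  keep <- !rownames(at) %in% c("(Intercept)", "Residuals")
  ss_res <- at["Residuals", "Sum Sq"]
  df_res <- at["Residuals", "Df"]
  eta <- at[keep, "Sum Sq"] / (at[keep, "Sum Sq"] + ss_res)
  ci <- t(vapply(which(keep), function(i)
    partial_eta_ci(at[i, "F value"], at[i, "Df"], df_res), numeric(2)))
  tab <- data.frame(effect = rownames(at)[keep], df = at[keep, "Df"],
                    df_res = df_res, F = at[keep, "F value"],
                    p = at[keep, "Pr(>F)"], partial_eta_sq = eta,
                    eta_ci_lo = ci[, 1], eta_ci_hi = ci[, 2],
                    row.names = NULL)
  sw <- shapiro.test(residuals(fit))
  # emmeans notes that factor-level means average over the interaction;
  # that is exactly the unweighted-margin convention wanted here
  emm_a <- suppressMessages(emmeans::emmeans(fit, factor_a))
  emm_b <- suppressMessages(emmeans::emmeans(fit, factor_b))
  emm_ab <- suppressMessages(emmeans::emmeans(fit, specs = factor_b,
                                              by = factor_a))
  new_stat_report(
    method = "Two-way ANOVA (Type III, sum-to-zero contrasts)",
    anova_table = tab, shapiro_w = unname(sw$statistic),
    shapiro_p = sw$p.value,
    emmeans = list(summary(emm_a), summary(emm_b)),
    contrasts = list(
      summary(emmeans::contrast(emm_a, "pairwise", adjust = "tukey")),
      summary(emmeans::contrast(emm_b, "pairwise", adjust = "tukey")),
      summary(emmeans::contrast(emm_ab, "pairwise", by = factor_a,
                                adjust = "tukey"))),
    model = fit)
}

# One-sided CI for partial eta^2 by inverting the noncentral F CDF
# (lower bound at the level, upper bound fixed at 1, the convention used
# for effect-size reporting alongside ANOVA tables).
partial_eta_ci <- function(F, df1, df2, level = 0.95) {
  if (!is.finite(F) || F <= 0) return(c(0, 1))
  g <- function(ncp) pf(F, df1, df2, ncp) - level
  if (g(0) < 0) return(c(0, 1))
  upper <- 4 * (df1 * F + df1 + df2)
  while (g(upper) > 0) upper <- upper * 2
  ncp_lo <- uniroot(g, c(0, upper))$root
  c(ncp_lo / (ncp_lo + df1 + df2 + 1), 1)
}

#' Bioassay endpoint rates per swatch and per arm
#'
#' Pools replicate cone assays into per-swatch knockdown (60 min) and
#' mortality (24 h) percentages over all exposed mosquitoes (5 replicates
#' x 5 mosquitoes = 25 per swatch in the standard design), plus per-arm
#' aggregates.  Replicates with `n_exposed != 5` are flagged, not
#' rejected.
#'
#' @param outcomes Data frame with columns `swatch_id`, `replicate_id`,
#'   `n_exposed`, `n_kd_60min`, `n_dead_24h`, `arm` (`"treated"` /
#'   `"control"`); optional `strain`, `net`.
#' @return A list with `per_swatch` and `per_arm` data frames.
#' @export
endpoint_rates <- function(outcomes) {
  need <- c("swatch_id", "replicate_id", "n_exposed", "n_kd_60min",
            "n_dead_24h", "arm")
  stopifnot(all(need %in% names(outcomes)))
  with(outcomes, stopifnot(all(n_kd_60min >= 0 & n_kd_60min <= n_exposed),
                           all(n_dead_24h >= 0 & n_dead_24h <= n_exposed)))
  per_swatch <- do.call(rbind, lapply(split(outcomes, outcomes$swatch_id),
                                      function(d) {
    data.frame(swatch_id = d$swatch_id[1], arm = d$arm[1],
               n_replicates = nrow(d), n_exposed = sum(d$n_exposed),
               kd_pct = 100 * sum(d$n_kd_60min) / sum(d$n_exposed),
               mortality_pct = 100 * sum(d$n_dead_24h) / sum(d$n_exposed),
               nonstandard_exposure = any(d$n_exposed != 5))
  }))
  rownames(per_swatch) <- NULL
  per_arm <- do.call(rbind, lapply(split(outcomes, outcomes$arm),
                                   function(d) {
    data.frame(arm = d$arm[1], n_exposed = sum(d$n_exposed),
               kd_pct = 100 * sum(d$n_kd_60min) / sum(d$n_exposed),
               mortality_pct = 100 * sum(d$n_dead_24h) / sum(d$n_exposed))
  }))
  rownames(per_arm) <- NULL
  list(per_swatch = per_swatch, per_arm = per_arm)
}

#' Abbott control correction of a treated-arm percentage
#'
#' `100 * (treated - control) / (100 - control)`, floored at 0, following
#' the WHO convention: no adjustment when control mortality is at most 5%,
#' adjustment when it lies in (5%, 20%], and an invalid-assay flag when it
#' exceeds 20%.
#'
#' @param treated_pct,control_pct Percentages in `[0, 100]`;
#'   `control_pct < 100`.
#' @return A list with `adjusted` (`NA` when the assay is invalid),
#'   `applied` (was the formula applied?) and `valid`.
#' @examples
#' abbott_adjust(60, 10)   # 55.56
#' abbott_adjust(56, 0)    # unadjusted 56
#' @export
abbott_adjust <- function(treated_pct, control_pct) {
  stopifnot(treated_pct >= 0, treated_pct <= 100, control_pct >= 0)
  if (control_pct >= 100)
    stop("control mortality of 100% leaves the correction undefined")
  if (control_pct > 20)
    return(list(adjusted = NA_real_, applied = FALSE, valid = FALSE))
  if (control_pct <= 5)
    return(list(adjusted = treated_pct, applied = FALSE, valid = TRUE))
  adj <- 100 * (treated_pct - control_pct) / (100 - control_pct)
  list(adjusted = max(adj, 0), applied = TRUE, valid = TRUE)
}
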