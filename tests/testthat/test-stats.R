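# Published summary groups used across the statistical tests: total
# movement activity of a susceptible and a resistant strain on two net
# formulations (group sizes recovered by CI inversion, see
# infer_n_from_ci).
ks_pos <- group_summary(3628.3, n = 40, sd = 1014.209, label = "KS+")
ks_neg <- group_summary(3211.655, n = 55, sd = 830.311, label = "KS-")
ts_pos <- group_summary(3804, n = 10, sd = 531.208, label = "TS+")
ts_neg <- group_summary(2141.6, n = 10, sd = 738.529, label = "TS-")

test_that("summary-based Welch t matches t.test on raw data", {
  set.seed(1)
  for (i in 1:5) {
    a <- rnorm(7 + i, mean = 10, sd = 2)
    b <- rnorm(12, mean = 8, sd = 4)
    ref <- t.test(a, b)
    got <- welch_t(group_summary(a), group_summary(b))
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_equal(got$conf_int, as.numeric(ref$conf.int), tolerance = 1e-12)
  }
})

test_that("Welch t reproduces the published strain contrasts", {
  ks <- welch_t(ks_pos, ks_neg)
  expect_equal(round(ks$t, 3), 2.130)
  expect_equal(round(ks$df, 3), 73.649)
  expect_equal(round(ks$p, 3), 0.036)
  ts <- welch_t(ts_pos, ts_neg)
  expect_equal(ts$t, 5.778, tolerance = 1e-3)
  expect_equal(round(ts$df, 3), 16.346)
  expect_lt(ts$p, 0.001)
  # identical groups give t = 0; two degenerate groups are rejected
  same <- group_summary(5, n = 10, sd = 1)
  expect_equal(welch_t(same, same)$t, 0)
  flat <- group_summary(5, n = 10, sd = 0)
  expect_error(welch_t(flat, flat), "undefined")
})

test_that("Cohen's d and its CI reproduce the published effect sizes", {
  ks <- cohens_d(ks_pos, ks_neg)
  expect_equal(round(ks$d, 3), 0.457)
  expect_equal(round(ks$conf_int, 3), c(0.039, 0.875))
  ts <- cohens_d(ts_pos, ts_neg)
  expect_equal(round(ts$d, 3), 2.584)
  expect_equal(round(ts$conf_int, 3), c(1.312, 3.857))
  expect_equal(cohens_d(group_summary(4, n = 8, sd = 2),
                        group_summary(4, n = 9, sd = 3))$d, 0)
})

test_that("mean CIs reproduce the published bounds and invert to n", {
  expect_equal(round(ci_mean(ks_pos), 2), c(lo = 3303.94, hi = 3952.66))
  expect_equal(round(ci_mean(ts_neg), 2), c(lo = 1613.29, hi = 2669.91))
  expect_equal(unname(ci_mean(group_summary(7, n = 5, sd = 0))),
               c(7, 7))
  # the CI-inversion oracle recovers a unique n for all four groups
  expect_equal(infer_n_from_ci(3628.30, 1014.209, 3952.66), 40)
  expect_equal(infer_n_from_ci(3211.655, 830.311, 3436.12), 55)
  expect_equal(infer_n_from_ci(3804.00, 531.208, 4184.00), 10)
  expect_equal(infer_n_from_ci(2141.60, 738.529, 2669.91), 10)
})

test_that("Levene's test equals a hand-rolled ANOVA on absolute deviations", {
  vals <- c(1, 2, 3, 10, 20, 30)
  grp <- rep(c("a", "b"), each = 3)
  got <- levene_test(vals, grp)
  # independent oracle: one-way ANOVA on |x - group mean|
  dev <- abs(vals - ave(vals, grp))
  ref <- anova(lm(dev ~ factor(grp)))
  expect_equal(got$F, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(got$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(got$df1, 1)
  expect_error(levene_test(rep(c(1, 2), each = 3), rep(c("a", "b"),
                                                       each = 3)),
               "degenerate")
})

test_that("balanced two-way ANOVA equals the classical SS decomposition", {
  d <- expand.grid(strain = c("S", "R"), net = c("A", "B", "C"),
                   rep = 1:4)
  set.seed(3)
  d$y <- 10 + 2 * (d$strain == "R") + 3 * (d$net == "B") + rnorm(nrow(d))
  got <- two_way_anova(d, "y", "strain", "net")
  ref <- anova(lm(y ~ strain * net, data = d))  # Type I == III if balanced
  tab <- got$anova_table
  expect_equal(tab$F, ref$`F value`[1:3], tolerance = 1e-10)
  expect_equal(tab$p, ref$`Pr(>F)`[1:3], tolerance = 1e-10)
  # partial eta^2 from the same SS decomposition
  expect_equal(tab$partial_eta_sq,
               ref$`Sum Sq`[1:3] / (ref$`Sum Sq`[1:3] + ref$`Sum Sq`[4]),
               tolerance = 1e-10)
  # marginal means on a balanced design are the cell-mean averages
  emm <- got$emmeans[[2]]
  hand <- tapply(d$y, d$net, mean)
  expect_equal(emm$emmean, as.numeric(hand[as.character(emm$net)]),
               tolerance = 1e-10)
  expect_true(got$shapiro_p > 0.01)
})

test_that("a 2x2 hand dataset matches hand-computed F values", {
  # cells: a1b1 = (1,2), a1b2 = (5,6), a2b1 = (3,4), a2b2 = (11,12)
  d <- data.frame(A = rep(c("a1", "a2"), each = 4),
                  B = rep(c("b1", "b2", "b1", "b2"), each = 2),
                  y = c(1, 2, 5, 6, 3, 4, 11, 12))
  got <- two_way_anova(d, "y", "A", "B")$anova_table
  # closed-form balanced decomposition
  gm <- mean(d$y)
  ssA <- 4 * sum((tapply(d$y, d$A, mean) - gm)^2)
  ssB <- 4 * sum((tapply(d$y, d$B, mean) - gm)^2)
  cell <- tapply(d$y, list(d$A, d$B), mean)
  ssAB <- 2 * sum((cell - outer(tapply(d$y, d$A, mean),
                                tapply(d$y, d$B, mean), `+`) + gm)^2)
  sse <- sum((d$y - cell[cbind(d$A, d$B)])^2)
  expect_equal(got$F, c(ssA, ssB, ssAB) / (sse / 4), tolerance = 1e-10)
  expect_error(two_way_anova(d[-(1:2), ], "y", "A", "B"), "cell")
})

test_that("endpoint rates pool replicates into per-swatch percentages", {
  outcomes <- data.frame(
    swatch_id = rep(c("s1", "s2"), each = 5),
    replicate_id = rep(1:5, 2),
    n_exposed = 5,
    n_kd_60min = c(rep(5, 5), 0:4),
    n_dead_24h = c(rep(5, 5), 0:4),
    arm = rep(c("treated", "treated"), each = 5))
  rates <- endpoint_rates(outcomes)
  expect_equal(rates$per_swatch$n_exposed, c(25, 25))  # 5 x 5 = 25
  expect_equal(rates$per_swatch$mortality_pct[1], 100)
  expect_equal(rates$per_swatch$mortality_pct[2], 40)  # 10 / 25
  expect_false(any(rates$per_swatch$nonstandard_exposure))
  outcomes$n_exposed[1] <- 4
  outcomes$n_kd_60min[1] <- 4
  outcomes$n_dead_24h[1] <- 4
  expect_true(endpoint_rates(outcomes)$per_swatch$nonstandard_exposure[1])
})

test_that("Abbott correction follows the WHO control windows", {
  expect_equal(abbott_adjust(56, 0)$adjusted, 56)    # no adjustment <= 5%
  expect_false(abbott_adjust(56, 0)$applied)
  expect_equal(abbott_adjust(100, 15)$adjusted, 100)
  a <- abbott_adjust(60, 10)
  expect_true(a$applied)
  expect_equal(a$adjusted, 100 * (60 - 10) / 90)
  expect_equal(round(a$adjusted, 2), 55.56)
  inv <- abbott_adjust(60, 25)
  expect_false(inv$valid)
  expect_true(is.na(inv$adjusted))
  expect_equal(abbott_adjust(5, 10)$adjusted, 0)     # floored at zero
  expect_error(abbott_adjust(50, 100), "undefined")
})
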