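test_that("pearson_r_p matches brute-force formulas and cor.test", {
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(14); y <- rnorm(14)
    out <- pearson_r_p(x, y)
    r_direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(out$r, r_direct, tolerance = 1e-12)
    ct <- cor.test(x, y)
    expect_equal(out$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(out$p, ct$p.value, tolerance = 1e-12)
  }
  perfect <- pearson_r_p(1:10, 2 * (1:10) + 1)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p, 1e-12)
  expect_error(pearson_r_p(rep(1, 10), rnorm(10)),
               class = "pitchpri_undefined_correlation")
})

test_that("the n = 14 significance boundary sits at |r| = 0.5324", {
  expect_equal(critical_r(14), 0.5324, tolerance = 1e-4)
  expect_lt(pearson_p_from_r(0.533, 14), 0.05)
  expect_gt(pearson_p_from_r(0.530, 14), 0.05)
  # cross-check against the t-quantile
  tq <- qt(0.975, 12)
  expect_equal(critical_r(14), tq / sqrt(tq^2 + 12), tolerance = 1e-12)
})

test_that("p-values are uniform under the null", {
  set.seed(9)
  p <- replicate(500, pearson_r_p(rnorm(14), rnorm(14))$p)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("per-pitcher aggregation uses sample SD and exact arithmetic", {
  st <- make_single_trial()
  t1 <- st$trial; t2 <- st$trial
  t1$release_params$theta1_deg <- 1
  t2$release_params$theta1_deg <- 3
  agg <- aggregate_trials(list(t1, t2), "X")
  expect_equal(agg$release$mean[agg$release$parameter == "theta1_deg"], 2)
  expect_equal(agg$sd_theta1_deg, sqrt(2))
  # identical trials: all SDs exactly zero
  same <- aggregate_trials(rep(list(st$trial), 5), "Y")
  expect_equal(same$release$sd, rep(0, 6))
  expect_equal(max(abs(same$pri_sd)), 0)
  expect_error(aggregate_trials(list(st$trial)),
               class = "pitchpri_insufficient_trials")
  # un-mirrored left-handers are rejected
  lh <- st$trial; lh$handedness <- "left"; lh$mirror_applied <- FALSE
  expect_error(aggregate_trials(list(lh, lh)),
               class = "pitchpri_invalid_metadata")
})

test_that("aggregates match a direct formula oracle on a simulated pitcher", {
  co <- make_small_cohort()
  p <- names(co$trials)[1]
  agg <- co$aggregates[[p]]
  speeds <- vapply(co$trials[[p]], function(tr) tr$release_params$speed,
                   numeric(1))
  expect_equal(agg$release$mean[agg$release$parameter == "speed"],
               mean(speeds), tolerance = 1e-12)
  expect_equal(agg$release$sd[agg$release$parameter == "speed"], sd(speeds),
               tolerance = 1e-12)
  z25 <- vapply(co$trials[[p]],
                function(tr) tr$pri$series$middle[16, "z"], numeric(1))
  expect_equal(agg$pri_mean[16, "middle", "z"], mean(z25), tolerance = 1e-12)
  expect_equal(agg$pri_sd[16, "middle", "z"], sd(z25), tolerance = 1e-12)
})

test_that("correlation scan recovers the planted sign and dies under shuffling", {
  co <- make_small_cohort()
  scan <- correlation_scan(co$aggregates)
  expect_true(all(abs(scan$r) <= 1))
  expect_true(all(scan$p >= 0 & scan$p <= 1))
  expect_equal(unique(scan$n), 5)
  expect_equal(nrow(scan), 41 * 2 * 2 * 2 * 2)
  # shuffling pitcher labels on one side centers r at 0: oracle by direct
  # recomputation over permutations
  sub <- scan[scan$pairing == "Mean_z_middle_x_SDtheta1", ]
  z25 <- vapply(co$aggregates, function(a) a$pri_mean[16, "middle", "z"],
                numeric(1))
  s1 <- vapply(co$aggregates, function(a) a$sd_theta1_deg, numeric(1))
  expect_equal(sub$r[sub$time_ms == -25], pearson_r_p(z25, s1)$r,
               tolerance = 1e-12)
  set.seed(31)
  perm_r <- replicate(200, pearson_r_p(z25, sample(s1))$r)
  expect_lt(abs(mean(perm_r)), 0.15)
  expect_error(correlation_scan(co$aggregates[1:2]),
               class = "pitchpri_insufficient_trials")
})

test_that("significant windows are maximal contiguous runs of p < alpha", {
  scan <- data.frame(pairing = "X", time_ms = -10:0,
                     p = c(0.5, 0.01, 0.02, 0.5, 0.5, 0.01, 0.5, 0.5, 0.03,
                           0.02, 0.01))
  w <- significant_windows(scan)
  expect_equal(nrow(w), 3)
  expect_equal(w$start_ms, c(-9, -5, -2))
  expect_equal(w$end_ms, c(-8, -5, 0))
  none <- significant_windows(data.frame(pairing = "X", time_ms = -5:0,
                                         p = rep(0.5, 6)))
  expect_equal(nrow(none), 0)
  single <- significant_windows(data.frame(pairing = "X", time_ms = -5:0,
                                           p = c(1, 1, 0.01, 1, 1, 1)))
  expect_equal(single$start_ms, single$end_ms)
})

test_that("cohort summary reproduces two-pitcher and degenerate cases", {
  df <- data.frame(pitcher = c("A", "B"),
                   speed_mean = c(30, 32), speed_sd = c(0.5, 0.6),
                   theta1_deg_mean = c(1, 3), theta1_deg_sd = c(1, 1),
                   theta2_deg_mean = c(-5, -3), theta2_deg_sd = c(1, 1),
                   x_mean = c(0.4, 0.5), x_sd = c(0.02, 0.02),
                   y_mean = c(1.5, 1.6), y_sd = c(0.03, 0.03),
                   z_mean = c(1.6, 1.7), z_sd = c(0.02, 0.02))
  out <- summarize_release_parameters(df)
  ov <- out[out$pitcher == "Mean", ]
  expect_equal(ov$speed_mean, 31)
  expect_equal(ov$speed_sd, sd(c(30, 32)))
  expect_equal(ov$theta1_deg_mean, 2)
  # one pitcher duplicated: zero across-pitcher SD
  dup <- summarize_release_parameters(df[c(1, 1), ])
  expect_equal(dup$speed_sd[dup$pitcher == "Mean"], 0)
})
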