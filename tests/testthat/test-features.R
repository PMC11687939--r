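test_that("section statistics match direct computation", {
  const <- make_signal(rep(100, 1201))
  st <- section_stats(const, "sap", "A")
  expect_equal(st$min, 100); expect_equal(st$max, 100)
  expect_equal(st$mean, 100); expect_equal(st$var, 0)

  # three-sample section: min/max with earliest-tie times
  sig <- make_signal(c(100, 90, 80), t_keep = 0:2)
  st3 <- section_stats(sig, "sap", "B")
  expect_equal(st3$min, 80); expect_equal(st3$t_min, 2)
  expect_equal(st3$max, 100); expect_equal(st3$t_max, 0)

  expect_error(section_stats(make_signal(rep(1, 3), t_keep = 0:2), "sap", "A"),
               "empty section")
})

test_that("section statistics agree with a brute-force scan oracle", {
  set.seed(11)
  for (rep_i in 1:10) {
    x <- runif(1201, 60, 180)
    sig <- make_signal(x)
    sec <- sample(c("A", "B", "C"), 1)
    idx <- if (sec == "A") sig$t >= -300 & sig$t < 0 else
           if (sec == "B") sig$t >= 0 & sig$t < 300 else sig$t >= 0
    st <- section_stats(sig, "sap", sec)
    v <- x[idx]; tt <- sig$t[idx]
    best_min <- Inf; best_max <- -Inf; t_min <- NA; t_max <- NA
    for (i in seq_along(v)) {            # explicit earliest-attaining scan
      if (v[i] < best_min) { best_min <- v[i]; t_min <- tt[i] }
      if (v[i] > best_max) { best_max <- v[i]; t_max <- tt[i] }
    }
    expect_equal(st$min, best_min); expect_equal(st$t_min, t_min)
    expect_equal(st$max, best_max); expect_equal(st$t_max, t_max)
    expect_equal(st$mean, sum(v) / length(v), tolerance = 1e-12)
    expect_equal(st$var, sum((v - mean(v))^2) / (length(v) - 1),
                 tolerance = 1e-12)
  }
})

test_that("slope series is the central difference in mmHg/min", {
  lin <- make_signal(seq(1500, 300, length.out = 1201))  # -1 mmHg/s
  s <- slope_series(lin, "sap")
  expect_equal(s[2:1200], rep(-60, 1199), tolerance = 1e-9)
  expect_true(is.na(s[1]) && is.na(s[1201]))

  flat <- make_signal(rep(100, 1201))
  expect_equal(slope_series(flat, "sap")[2:1200], rep(0, 1199))

  set.seed(3)
  x <- runif(1201, 80, 160)
  s2 <- slope_series(make_signal(x), "sap")
  i <- sample(2:1200, 50)
  expect_equal(s2[i], (x[i + 1] - x[i - 1]) / 2 * 60, tolerance = 1e-12)
})

test_that("mean negative slope averages only the declining samples", {
  lin <- make_signal(seq(1500, 300, length.out = 1201))
  expect_equal(mean_negative_slope(lin, "sap"), -60,
               ignore_attr = TRUE, tolerance = 1e-9)

  rise <- make_signal(seq(300, 1500, length.out = 1201))
  mns <- mean_negative_slope(rise, "sap")
  expect_equal(as.numeric(mns), 0)
  expect_true(attr(mns, "no_negative_slope"))

  set.seed(5)
  x <- 120 + cumsum(rnorm(1201))
  sig <- make_signal(x)
  s <- slope_series(sig, "sap")
  inw <- sig$t >= -150 & sig$t <= 150 & !is.na(s) & s < 0
  expect_equal(as.numeric(mean_negative_slope(sig, "sap")),
               mean(s[inw]), tolerance = 1e-12)
})

test_that("steepest-slope deciles use linear-interpolation percentiles", {
  # constant decline: every slope identical
  lin <- make_signal(seq(1500, 300, length.out = 1201))
  ss <- steepest_slopes(lin, "sap")
  expect_equal(ss$steepest, -60, tolerance = 1e-9)
  expect_equal(ss$d1, -60, tolerance = 1e-9)
  expect_equal(ss$d2, -60, tolerance = 1e-9)

  # enumerated slope set -1..-100 mmHg/min, each once
  want <- -(1:100)
  x <- numeric(102); x[1] <- 500; x[2] <- 500
  for (i in 2:101) x[i + 1] <- x[i - 1] + 2 * want[i - 1] / 60
  sig <- make_signal(x[1:102], t_keep = 0:101)
  ss2 <- steepest_slopes(sig, "sap")
  expect_equal(ss2$steepest, -100, tolerance = 1e-9)
  expect_equal(ss2$d1, -90.1, tolerance = 1e-6)
  expect_equal(ss2$d2, -80.2, tolerance = 1e-6)

  # all-positive slopes: steepest is the smallest rise, flagged
  rise <- make_signal(seq(300, 1500, length.out = 1201))
  ss3 <- steepest_slopes(rise, "sap")
  expect_equal(ss3$steepest, 60, tolerance = 1e-9)
  expect_true(attr(ss3, "no_downward_slope"))
})

test_that("cross-section deltas subtract the section-A baseline", {
  a <- list(min = 1, max = 2, mean = 150, var = 4)
  b <- list(min = 0, max = 1, mean = 110, var = 5)
  d <- cross_section_deltas(a, b, a)
  expect_equal(unname(d$A_to_B["mean"]), -40)
  expect_equal(unname(d$A_to_C), rep(0, 4))
})

test_that("the default registry enumerates exactly 98 uniquely named features", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 98)
  expect_equal(anyDuplicated(reg$name), 0L)
  expect_equal(sum(reg$family == "section_stat"), 60)   # 54 + 6 PP
  expect_equal(sum(reg$family == "delta"), 26)          # 24 + 2 PP
})

test_that("featurize is deterministic and fails loudly on masked sections", {
  rec <- generate_record(cohort_config(), "unstable", seed = 21)
  sig <- preprocess_record(rec)$signal
  f1 <- featurize(sig); f2 <- featurize(sig)
  expect_identical(f1, f2)
  expect_length(f1, 98)
  expect_true(all(is.finite(f1)))

  masked_a <- sig
  masked_a$mask[masked_a$t < 0] <- FALSE
  expect_error(featurize(masked_a), "section A")
})

test_that("features are equivariant under a pressure shift", {
  rec <- generate_record(cohort_config(), "stable", seed = 31,
                         artifacts = FALSE)
  sig <- preprocess_record(rec)$signal
  shifted <- sig
  for (ch in c("sap", "map", "dap")) shifted[[ch]] <- shifted[[ch]] + 25
  shifted$pp <- shifted$sap - shifted$dap
  f0 <- featurize(sig); f1 <- featurize(shifted)
  reg <- feature_registry()
  loc <- reg$family == "section_stat" & reg$stat %in% c("min", "max", "mean") &
    reg$signal != "pp"
  expect_equal(unname(f1[loc] - f0[loc]), rep(25, sum(loc)), tolerance = 1e-9)
  expect_equal(f1[!loc], f0[!loc], tolerance = 1e-9)
})

test_that("time reversal negates and reverses the slope series", {
  set.seed(13)
  x <- 150 - cumsum(abs(rnorm(1201, 0.05, 0.02)))   # monotone decline
  s_fwd <- slope_series(make_signal(x), "sap")
  s_rev <- slope_series(make_signal(rev(x)), "sap")
  expect_equal(s_rev[2:1200], -rev(s_fwd[2:1200]), tolerance = 1e-9)
  expect_true(all(s_fwd[2:1200] < 0))
})

test_that("cohort featurization keeps ids aligned and drops excluded records", {
  cfg <- cohort_config(n = 6, seed = 17)
  coh <- generate_cohort(cfg)
  fc <- featurize_cohort(coh$records)
  expect_equal(nrow(fc$features), sum(fc$included))
  expect_equal(fc$features$id,
               vapply(coh$records[fc$included], `[[`, "", "patient_id"))
  expect_equal(ncol(fc$features), 99)   # id + 98
})
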