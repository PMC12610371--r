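# Builds bare alignment results directly so component arithmetic can be
# checked against hand computation.
fake_alignment <- function(shifts, d, nr = 50) {
  hsbtw:::.alignment_result(shifts, d, sum(d), nr, alignment_params())
}

test_that("posture component subtracts the minimum pair distance", {
  ar <- fake_alignment(c(0, 0, 0), c(0.2, 0.5, 0.8))
  pc <- posture_component(ar)
  expect_equal(pc$M_anthro, 0.2)
  expect_equal(pc$DP, (0 + 0.3 + 0.6) / 3)

  # identical sequences
  ar0 <- fake_alignment(c(0, 0, 0), c(0, 0, 0))
  expect_equal(posture_component(ar0), list(DP = 0, M_anthro = 0))

  # a pure anthropometric offset leaves DP at zero
  arc <- fake_alignment(c(0, 1, 1), rep(0.37, 3))
  expect_equal(posture_component(arc)$DP, 0)
  expect_equal(posture_component(arc)$M_anthro, 0.37)
})

test_that("adding a constant to every pair distance leaves DP unchanged", {
  set.seed(5)
  d <- runif(20)
  ar1 <- fake_alignment(rep(0, 20), d)
  ar2 <- fake_alignment(rep(0, 20), d + 0.123)
  expect_equal(posture_component(ar2)$DP, posture_component(ar1)$DP,
               tolerance = 1e-12)
  expect_equal(posture_component(ar2)$M_anthro,
               posture_component(ar1)$M_anthro + 0.123, tolerance = 1e-12)
})

test_that("dynamics component is the total variation of the shifts over Nb", {
  expect_equal(dynamics_component(fake_alignment(c(2, 2, 2, 2), rep(0, 4))), 0)
  expect_equal(dynamics_component(fake_alignment(c(0, 0, 2, 2), rep(0, 4))),
               2 / 4)
  set.seed(6)
  v <- cumsum(sample(-1:2, 15, replace = TRUE))
  ar <- fake_alignment(v, runif(15))
  expect_equal(dynamics_component(ar), sum(abs(diff(v))) / 15,
               tolerance = 1e-12)
})

test_that("intensity-augmented dynamics adds beta times the intensity gap", {
  ar <- fake_alignment(c(0, 0, 2, 2), rep(0, 4))  # base DT = 0.5
  expect_equal(dynamics_with_intensity(ar, 0.1, 0.3, beta = 0),
               dynamics_component(ar))
  expect_equal(dynamics_with_intensity(ar, 0.3, 0.3, beta = 5),
               dynamics_component(ar))
  expect_equal(dynamics_with_intensity(ar, 0.25, 0.3, beta = 2), 0.6)
  expect_error(dynamics_with_intensity(ar, 0.4, 0.3, beta = 1), "exceeds")
})

test_that("combine and project obey their closed forms", {
  expect_equal(combine_score(0.3, 0.5, 0), 0.3)
  expect_equal(combine_score(0.3, 0.5, 0.2), 0.4)
  expect_equal(project_score(0.3, 0.5, 0), 0.3)
  expect_equal(project_score(0.3, 0.5, 45), (0.3 + 0.5) / sqrt(2),
               tolerance = 1e-12)
  expect_error(project_score(0.3, 0.5, 90), "\\[0, 90\\)")
  expect_error(combine_score(1, 1, -0.1), "alpha")
})

test_that("projection at phi and combination at tan(phi) rank records alike", {
  set.seed(7)
  DP <- runif(30); DT <- runif(30)
  for (phi in c(0, 13, 45, 80)) {
    o1 <- order(project_score(DP, DT, phi))
    o2 <- order(combine_score(DP, DT, tanpi(phi / 180)))
    expect_identical(o1, o2)
  }
})

test_that("self-comparison and pure delay yield zero posture and dynamics", {
  ins <- generate_instructor(exercise_template("sitting"))
  sc <- compare_records(ins, ins)
  expect_lt(sc$DP, 1e-12)
  expect_equal(sc$DT, 0)
  delayed <- degrade(ins, impairment_profile(start_delay = 6, level = "good"))
  sc2 <- compare_records(ins, delayed)
  expect_lt(sc2$DP, 1e-12)
  expect_equal(sc2$DT, 0)
})

test_that("attenuated amplitude produces strictly positive posture error", {
  ins <- generate_instructor(exercise_template("standing"))
  weak <- degrade(ins, impairment_profile(amplitude_factor = 0.5, level = "bad"))
  sc <- compare_records(ins, weak)
  expect_gt(sc$DP, 1e-4)
})

test_that("a uniform limb rescale is absorbed by the anthropometric chain", {
  ins <- generate_instructor(exercise_template("standing"))
  ref <- compare_records(ins, degrade(ins, impairment_profile(
    amplitude_factor = 0.7, level = "intermediate")))
  for (s in c(0.8, 1.25)) {
    scaled <- compare_records(ins, degrade(ins, impairment_profile(
      amplitude_factor = 0.7, anthropometric_scale = s, level = "intermediate")))
    expect_lt(abs(scaled$DP - ref$DP), 1e-6)
  }
})

test_that("stage failures are labeled with the failing stage", {
  ins <- generate_instructor(exercise_template("standing"))
  static <- ins
  static$coords[] <- rep(static$coords[1, , ], each = nframes(ins))
  expect_error(compare_records(static, ins), "attention weights")
})

test_that("legacy uncorrected scoring keeps the raw mean and total variation", {
  ins <- generate_instructor(exercise_template("standing"))
  pat <- degrade(ins, impairment_profile(amplitude_factor = 0.6,
                                         tempo_factor = 0.9, level = "bad"))
  sc <- compare_records(ins, pat, legacy_uncorrected = TRUE)
  scc <- compare_records(ins, pat)
  expect_equal(sc$M_anthro, 0)
  expect_equal(sc$DP, scc$DP + scc$M_anthro, tolerance = 1e-12)
  expect_equal(sc$DT, scc$DT * scc$n_base, tolerance = 1e-12)
})

test_that("group scaling keeps the reference at the origin", {
  df <- data.frame(
    DP = c(0, 0.2, 0.4, 0, 0.1, 0.5), DT = c(0, 0.1, 0.3, 0, 0.2, 0.4),
    position = rep(c("sitting", "standing"), each = 3),
    label = rep(c("reference", "good", "bad"), 2))
  sc <- scale_scores(df)
  expect_equal(sc$DP_scaled[c(1, 4)], c(0, 0))
  expect_equal(sc$DT_scaled[c(1, 4)], c(0, 0))
  # scaling is per group: each group's axis variance becomes 1
  expect_equal(sd(sc$DP_scaled[1:3]), 1, tolerance = 1e-12)
  expect_equal(sd(sc$DP_scaled[4:6]), 1, tolerance = 1e-12)
  # plot helper runs headless to a file
  f <- withr::local_tempfile(fileext = ".png")
  plot_score_plane(df, file = f, phi = 13)
  expect_true(file.exists(f) && file.size(f) > 0)
})
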