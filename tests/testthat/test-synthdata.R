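test_that("templates require motion and a minimum span", {
  tmpl <- exercise_template("standing")
  zero <- tmpl$moves
  zero$amplitude <- 0
  expect_error(motion_template(tmpl$base_pose, zero), "nonzero-amplitude")
  expect_error(motion_template(tmpl$base_pose, tmpl$moves, duration = 0.5,
                               fps = 10), "at least 10 frames")
  bad <- tmpl$moves
  bad$joint[1] <- 17
  expect_error(motion_template(tmpl$base_pose, bad), "invalid joint")
})

test_that("the instructor recording is deterministic harmonic motion", {
  tmpl <- exercise_template("standing")
  a <- generate_instructor(tmpl)
  b <- generate_instructor(tmpl)
  expect_identical(a$coords, b$coords)
  expect_equal(nframes(a), round(tmpl$duration * tmpl$fps))
  expect_identical(a$meta$label, "reference")

  # single-harmonic template: sample variance of the moving coordinate is
  # amplitude^2 / 2 (closed form for a sampled sinusoid over whole cycles)
  one <- motion_template(tmpl$base_pose,
                         data.frame(joint = 7, coord = "y", amplitude = 0.3,
                                    frequency = 0.5, phase = 0),
                         duration = 8, fps = 10)
  s <- generate_instructor(one)
  v <- s$coords[, 8, 2]
  expect_equal(var(v) * (length(v) - 1) / length(v), 0.3^2 / 2,
               tolerance = 0.05 * 0.3^2 / 2)
})

test_that("an identity profile degrades to the identical sequence", {
  ins <- generate_instructor(exercise_template("sitting"))
  out <- degrade(ins, impairment_profile(level = "good"))
  expect_identical(out$coords, ins$coords)
  expect_identical(out$meta$label, "good")
})

test_that("tempo resampling changes length and delay prepends the first pose", {
  ins <- generate_instructor(exercise_template("standing"))
  slow <- degrade(ins, impairment_profile(tempo_factor = 0.8, level = "bad"))
  expect_equal(nframes(slow), round(nframes(ins) / 0.8))
  late <- degrade(ins, impairment_profile(start_delay = 4, level = "good"))
  expect_equal(nframes(late), nframes(ins) + 4)
  for (i in 1:5) {
    expect_equal(late$coords[i, , ], ins$coords[1, , ], tolerance = 1e-15)
  }
  expect_warning(degrade(ins, impairment_profile(start_delay = 8),
                         window = 10), "exceeds half")
})

test_that("amplitude attenuation shrinks displacement about the mean pose", {
  ins <- generate_instructor(exercise_template("standing"))
  weak <- degrade(ins, impairment_profile(amplitude_factor = 0.5, level = "bad"))
  mu <- colMeans(ins$coords, dims = 1)
  dev_ins <- sweep(ins$coords, c(2, 3), mu)
  dev_weak <- sweep(weak$coords, c(2, 3), colMeans(weak$coords, dims = 1))
  expect_equal(dev_weak, dev_ins * 0.5, tolerance = 1e-12)
})

test_that("noise is seeded and reproducible", {
  ins <- generate_instructor(exercise_template("standing"))
  p <- impairment_profile(pose_noise_sd = 0.001, level = "bad")
  a <- degrade(ins, p, seed = 5)
  b <- degrade(ins, p, seed = 5)
  c <- degrade(ins, p, seed = 6)
  expect_identical(a$coords, b$coords)
  expect_false(identical(a$coords, c$coords))
})

test_that("preset profiles keep the monotone-degradation ordering", {
  pr <- impairment_presets()
  expect_named(pr$levels, c("good", "intermediate", "bad"))
  amp <- vapply(pr$levels, `[[`, numeric(1), "amplitude_factor")
  noise <- vapply(pr$levels, `[[`, numeric(1), "pose_noise_sd")
  expect_true(amp["good"] > amp["intermediate"] &&
              amp["intermediate"] > amp["bad"])
  expect_true(noise["good"] < noise["intermediate"] &&
              noise["intermediate"] < noise["bad"])
})

test_that("mean intensity is ordered good > intermediate > bad across seeds", {
  for (seed in 1:3) {
    st <- generate_study(n_participants = 4, seed = 100 + seed)
    E <- vapply(st$records,
                function(r) intensity(normalize_sequence(r)), numeric(1))
    lab <- vapply(st$records, function(r) r$meta$label, character(1))
    m <- tapply(E, lab, mean)
    expect_gt(m[["good"]], m[["intermediate"]])
    expect_gt(m[["intermediate"]], m[["bad"]])
  }
})

test_that("study size follows the protocol arithmetic", {
  st1 <- generate_study(n_participants = 1, positions = "sitting", seed = 2)
  expect_length(st1$records, 3)
  expect_length(st1$instructors, 1)
  st <- generate_study(n_participants = 3, seed = 4)
  expect_length(st$records, 3 * 2 * 3)
  expect_length(st$instructors, 2)
  expect_equal(nrow(st$manifest), 18)
  expect_setequal(unique(st$manifest$label), c("good", "intermediate", "bad"))
})

test_that("studies are reproducible and survive a directory round trip", {
  a <- generate_study(n_participants = 2, seed = 9)
  b <- generate_study(n_participants = 2, seed = 9)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$records[[5]]$coords, b$records[[5]]$coords)

  dir <- withr::local_tempdir()
  write_study(a, dir)
  r <- load_study(dir)
  expect_equal(length(r$records), length(a$records))
  expect_identical(r$records[[3]]$coords, a$records[[3]]$coords)
  expect_identical(r$instructors$sitting$coords, a$instructors$sitting$coords)
  expect_identical(r$records[[7]]$meta$person_record_id,
                   a$records[[7]]$meta$person_record_id)
})

test_that("an instructor repeat lands near the origin of the score plane", {
  st <- generate_study(n_participants = 1, positions = "standing", seed = 12,
                       instructor_repeat = TRUE)
  rep_rec <- st$records[[length(st$records)]]
  expect_identical(rep_rec$meta$person, "instructor_repeat")
  sc <- compare_records(st$instructors$standing, rep_rec)
  expect_lt(sc$DP, 1e-3)
  expect_equal(sc$DT, 0)
})
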