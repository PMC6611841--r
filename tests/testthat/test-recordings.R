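test_that("dICP is the channel difference over the sensor separation", {
  n <- 100
  rec <- icp_recording(time = (0:(n - 1)) / 10, icp_iv = rep(10, n),
                       icp_sd_or_par = rep(10, n), sampling_rate = 10,
                       sensor_distance_L = 0.06)
  expect_true(all(compute_dicp(rec) == 0))
  rec2 <- icp_recording(time = (0:(n - 1)) / 10, icp_iv = rep(10, n),
                        icp_sd_or_par = rep(10.12, n), sampling_rate = 10,
                        sensor_distance_L = 0.06)
  expect_equal(compute_dicp(rec2), rep(2.0, n), tolerance = 1e-12)
  expect_error(icp_recording(time = 1:3 / 10, icp_iv = 1:3,
                             icp_sd_or_par = 1:4, sampling_rate = 10,
                             sensor_distance_L = 0.06), "equal length")
})

test_that("dICP recovers the synthetic ground-truth gradient", {
  sp <- synthetic_spec(duration = 20, sampling_rate = 50,
                       cardiac_grad_amplitude = 2.1, cardiac_freq = 1.2,
                       resp_grad_amplitude = 0.6, resp_freq = 0.3,
                       noise_sd = 0)
  rec <- generate_recording(sp)
  truth <- 2.1 * sin(2 * pi * 1.2 * rec$time) +
    0.6 * sin(2 * pi * 0.3 * rec$time)
  expect_equal(compute_dicp(rec), truth, tolerance = 1e-10)
})

test_that("constant-difference recording splits into fully accepted windows", {
  fs <- 10
  n <- 1080 * fs + 55                    # trailing partial window discarded
  rec <- icp_recording(time = (0:(n - 1)) / fs, icp_iv = rep(12, n),
                       icp_sd_or_par = rep(12.5, n), sampling_rate = fs,
                       sensor_distance_L = 0.06, start_clock = "13:00:00")
  wins <- extract_windows(rec)
  expect_length(wins, 3L)
  expect_true(all(vapply(wins, `[[`, TRUE, "accepted")))
  expect_true(all(vapply(wins, function(w) abs(mean(w$dicp)), 1) < 1e-10))
  expect_equal(vapply(wins, `[[`, 1, "start_offset"), c(0, 360, 720))
})

test_that("a 2.5 mmHg step rejects only the window containing it", {
  fs <- 10
  sp <- synthetic_spec(duration = 1080, sampling_rate = fs,
                       cardiac_grad_amplitude = 1.0, resp_grad_amplitude = 0.3,
                       noise_sd = 0, artifact_times = 500,
                       artifact_steps = 2.5)
  wins <- extract_windows(generate_recording(sp))
  expect_identical(vapply(wins, `[[`, TRUE, "accepted"),
                   c(TRUE, FALSE, TRUE))
  expect_gt(wins[[2]]$raw_difference_range, 2)
})

test_that("acceptance uses the raw mmHg difference with a strict 2 mmHg bound", {
  fs <- 20
  t <- (0:(360 * fs - 1)) / fs
  # peak-to-peak 1.9 mmHg difference: accepted
  rec <- icp_recording(time = t, icp_iv = rep(0, length(t)),
                       icp_sd_or_par = 0.95 * sin(2 * pi * 1.0 * t),
                       sampling_rate = fs, sensor_distance_L = 0.06)
  expect_true(extract_windows(rec)[[1]]$accepted)
  # exactly 2.0 mmHg range: rejected (strict inequality)
  rec2 <- icp_recording(time = t, icp_iv = rep(0, length(t)),
                        icp_sd_or_par = c(0, 2, rep(1, length(t) - 2)),
                        sampling_rate = fs, sensor_distance_L = 0.06)
  expect_false(extract_windows(rec2)[[1]]$accepted)
  # missing samples: rejected
  ch <- rep(1, length(t)); ch[100] <- NA
  rec3 <- icp_recording(time = t, icp_iv = rep(0, length(t)),
                        icp_sd_or_par = ch, sampling_rate = fs,
                        sensor_distance_L = 0.06)
  expect_false(extract_windows(rec3)[[1]]$accepted)
})

test_that("acceptance is invariant to a common-mode shift of both channels", {
  fs <- 10
  sp <- synthetic_spec(duration = 720, sampling_rate = fs,
                       cardiac_grad_amplitude = 1.4, resp_grad_amplitude = 0.5,
                       noise_sd = 0.05, seed = 11L)
  rec <- generate_recording(sp)
  shifted <- rec
  shifted$icp_iv <- rec$icp_iv + 37.5
  shifted$icp_sd_or_par <- rec$icp_sd_or_par + 37.5
  w1 <- extract_windows(rec)
  w2 <- extract_windows(shifted)
  expect_identical(vapply(w1, `[[`, TRUE, "accepted"),
                   vapply(w2, `[[`, TRUE, "accepted"))
  expect_equal(vapply(w1, `[[`, 1, "raw_difference_range"),
               vapply(w2, `[[`, 1, "raw_difference_range"), tolerance = 1e-9)
})

test_that("recordings shorter than one window yield an empty list", {
  fs <- 10
  rec <- icp_recording(time = (0:(100 * fs - 1)) / fs,
                       icp_iv = rep(0, 100 * fs),
                       icp_sd_or_par = rep(0, 100 * fs),
                       sampling_rate = fs, sensor_distance_L = 0.06)
  expect_length(extract_windows(rec), 0L)
})

test_that("the zero-mean shift preserves spectral amplitudes at f > 0", {
  w <- make_window(function(t) 1.5 * sin(2 * pi * 1.1 * t) + 3.7)
  sp <- amplitude_spectrum(w)
  k <- which.max(sp$amplitude)
  expect_equal(sp$amplitude[k], 1.5, tolerance = 1e-9)
})

test_that("circadian labelling uses the half-open midnight-to-06:00 interval", {
  expect_identical(categorize_state("03:00:00"), "sleeping")
  expect_identical(categorize_state("23:59:00"), "awake")
  expect_identical(categorize_state("06:00:00"), "awake")
  expect_identical(categorize_state("05:59:59"), "sleeping")
  expect_identical(categorize_state("00:00:00"), "sleeping")
  expect_identical(categorize_state(NULL), "unknown")
  # offsets roll the window start across midnight
  expect_identical(categorize_state("23:00:00", offset_s = 2 * 3600),
                   "sleeping")
})

test_that("the window index table reports one vetted row per window", {
  fs <- 10
  sp <- synthetic_spec(duration = 1080, sampling_rate = fs, noise_sd = 0,
                       artifact_times = 500, artifact_steps = 3,
                       patient_id = "px", start_clock = "23:48:00")
  wins <- extract_windows(generate_recording(sp))
  tab <- window_index_table(wins)
  expect_equal(nrow(tab), 3L)
  expect_identical(tab$accepted, c(TRUE, FALSE, TRUE))
  expect_identical(tab$state, c("awake", "awake", "sleeping"))
  expect_identical(tab$patient_id, rep("px", 3))
})
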