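test_that("extremum detection matches analytic sinusoid extrema", {
  fs <- 30
  t <- (0:899) / fs                       # 30 s at 40 bpm
  x <- 2 + 1.5 * sin(2 * pi * (40 / 60) * t)
  ext <- detect_extrema(x, window = 33)
  # analytic extrema: maxima at t = (k + 1/4) * 1.5 s, minima at (k + 3/4)
  true_max <- (0:19 + 0.25) * 1.5 * fs + 1
  true_min <- (0:19 + 0.75) * 1.5 * fs + 1
  # compare over the region where the detection window is complete
  interior <- function(i) i[i > 17 & i < 884]
  got_max <- interior(ext$index[ext$type == "max"])
  got_min <- interior(ext$index[ext$type == "min"])
  expect_length(got_max, length(interior(true_max)))
  expect_length(got_min, length(interior(true_min)))
  expect_true(all(abs(got_max - interior(true_max)) <= 1))
  expect_true(all(abs(got_min - interior(true_min)) <= 1))
  # types strictly alternate
  expect_true(all(ext$type[-1] != ext$type[-nrow(ext)]))
})

test_that("monotone and constant signals yield no interior extrema", {
  ramp <- detect_extrema(seq(0, 10, length.out = 100), window = 33)
  expect_true(all(ramp$index %in% c(1, 100)))
  expect_equal(nrow(detect_extrema(rep(1, 100), window = 33)), 0)
  expect_error(detect_extrema(1:10, window = 33), "shorter")
})

test_that("plateaus resolve to the earliest sample", {
  x <- c(seq(0, 1, length.out = 40), rep(2, 5), seq(1, 0, length.out = 40))
  ext <- detect_extrema(x, window = 33)
  expect_true(41 %in% ext$index[ext$type == "max"])
  expect_false(any(c(42, 43, 44, 45) %in% ext$index))
})

test_that("breath segmentation pairs min-max-min triples sharing the
           boundary minimum", {
  ext <- data.frame(index = c(10, 30, 55, 80, 100),
                    type = c("min", "max", "min", "max", "min"))
  br <- segment_breaths(ext)
  expect_equal(nrow(br), 2)
  expect_equal(br$i_min1, c(10, 55))
  expect_equal(br$i_min2, c(55, 100))

  expect_equal(nrow(segment_breaths(
    data.frame(index = c(10, 30), type = c("min", "max")))), 0)
  # leading maximum is skipped, breaths start at the first minimum
  ext2 <- data.frame(index = c(5, 10, 30, 55),
                     type = c("max", "min", "max", "min"))
  expect_equal(segment_breaths(ext2)$i_min1, 10)
})

test_that("rate and amplitude follow the breath definitions", {
  v <- rep(0, 200)
  v[c(50, 140)] <- c(3.2, 0.2)
  br <- data.frame(i_min1 = 5, i_max = 50, i_min2 = 140)
  got <- breath_parameters(v, br, fs = 30)
  expect_equal(got$rr, 60 * 30 / 135)
  expect_equal(got$a, 3.0)

  br45 <- breath_parameters(v, data.frame(i_min1 = 1, i_max = 20,
                                          i_min2 = 46), fs = 30)
  expect_equal(br45$rr, 40)
  br90 <- breath_parameters(v, data.frame(i_min1 = 1, i_max = 45,
                                          i_min2 = 91), fs = 30)
  expect_equal(br90$rr, 20)
})

test_that("the Lissajous phase matches its analytic identity and a
           cross-spectral oracle", {
  fs <- 30
  t <- seq(0, 1.5, length.out = 46)[-46]  # one 40 bpm breath
  mk <- function(delay_deg, amp = 1) {
    ph <- delay_deg * pi / 180
    list(rc = 1 - cos(2 * pi * (40 / 60) * t),
         ab = amp * (1 - cos(2 * pi * (40 / 60) * t - ph)))
  }
  expect_equal(lissajous_phase(mk(0)$rc, mk(0)$rc), 0)
  expect_equal(abs(lissajous_phase(mk(90)$rc, mk(90)$ab)), 90,
               tolerance = 2)
  # |sin(theta)| = m/s identity for equal-amplitude sinusoids
  for (d in c(10, 30, 45, 60, 120, 150)) {
    s <- mk(d)
    expect_equal(lissajous_phase(s$rc, s$ab), d, tolerance = 2)
    # ab leading instead of lagging flips the sign
    expect_equal(lissajous_phase(s$ab, s$rc), -d, tolerance = 2)
  }
  # independent oracle on a long record
  tl <- (0:899) / fs
  for (d in c(30, 60)) {
    rc <- 1 - cos(2 * pi * 0.6 * tl)
    ab <- 1 - cos(2 * pi * 0.6 * tl - d * pi / 180)
    one <- 2:51  # one full period
    expect_equal(lissajous_phase(rc[one], ab[one]),
                 cross_spectral_phase(rc, ab), tolerance = 2)
  }
  # paradoxical motion
  s <- mk(0)
  expect_equal(abs(lissajous_phase(s$rc, 2 - s$rc)), 180)
  # degenerate range
  expect_true(is.na(lissajous_phase(s$rc, rep(1, length(s$rc)))))
})

test_that("scaling both signals leaves the phase unchanged and scales the
           amplitude", {
  sim_t <- seq(0, 1.5, length.out = 46)[-46]
  rc <- 1 - cos(2 * pi * (40 / 60) * sim_t)
  ab <- 1 - cos(2 * pi * (40 / 60) * sim_t - pi / 4)
  th1 <- lissajous_phase(rc, ab)
  th2 <- lissajous_phase(3 * rc, 3 * ab)
  expect_equal(th1, th2, tolerance = 1e-9)

  v <- abs(sin(seq(0, 2 * pi, length.out = 91)))
  br <- data.frame(i_min1 = 1, i_max = 23, i_min2 = 46)
  a1 <- breath_parameters(v, br, fs = 30)$a
  a3 <- breath_parameters(3 * v, br, fs = 30)$a
  expect_equal(a3, 3 * a1)
})

test_that("recording summaries report mean, sample SD and counts", {
  mk_sig <- function(v) breathing_signal(v, 30)
  sim <- run_condition(amp = 3, rr = 60, phase = 0, cycles = 2, seed = 21)
  summ <- summarize_recording(sim$bt)
  expect_setequal(summ$metric,
                  c("rr_rc_bpm", "rr_ab_bpm", "a_rc_mm", "a_ab_mm",
                    "theta_deg"))
  # summary recomputable from the breath rows
  expect_equal(summ$mean[summ$metric == "rr_rc_bpm"], mean(sim$bt$rc$rr),
               tolerance = 1e-9)
  expect_equal(summ$sd[summ$metric == "a_ab_mm"], sd(sim$bt$ab$a),
               tolerance = 1e-9)

  # direct-formula cases
  bt <- sim$bt
  bt$rc <- bt$rc[1, , drop = FALSE]
  bt$theta <- bt$theta[1, , drop = FALSE]
  one <- summarize_recording(bt)
  expect_equal(one$sd[one$metric == "rr_rc_bpm"], 0)
  expect_false(one$sd_defined[one$metric == "rr_rc_bpm"])

  bt2 <- bt
  bt2$rc <- data.frame(i_min1 = c(1, 4, 7), i_max = c(2, 5, 8),
                       i_min2 = c(4, 7, 10), t_start_s = 0,
                       rr = c(40, 40, 40), a = c(30, 50, 40))
  s2 <- summarize_recording(bt2)
  expect_equal(s2$mean[s2$metric == "rr_rc_bpm"], 40)
  expect_equal(s2$sd[s2$metric == "rr_rc_bpm"], 0)
  bt2$rc$rr <- c(30, 50, NA)
  s3 <- summarize_recording(bt2)
  expect_equal(s3$mean[s3$metric == "rr_rc_bpm"], 40)
  expect_equal(s3$sd[s3$metric == "rr_rc_bpm"], 14.142136,
               tolerance = 1e-6)
  expect_equal(s3$n[s3$metric == "rr_rc_bpm"], 2)
})
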