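test_that("AP detection finds planted events and ignores flat traces", {
  expect_equal(nrow(detect_aps(flat_sweep())), 0)

  s <- template_sweep(c(100, 110, 125))
  ev <- detect_aps(s)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$threshold_time, c(100, 110, 125))
  expect_equal(ev$threshold_voltage, rep(-45, 3))
  expect_equal(ev$peak_voltage, rep(40, 3), tolerance = 1e-9)
  expect_true(all(ev$threshold_time < ev$peak_time))
  expect_true(all(ev$peak_time < ev$ahp_time))
})

test_that("a double-peaked rise yields one event with the global maximum", {
  ## two local maxima above threshold within one excursion
  t <- seq(0, 700, by = 0.05)
  v <- rep(-75, length(t))
  v[t >= 100 & t <= 600] <- -45
  seg <- function(from, to, v0, v1) {
    sel <- t >= from & t < to
    v[sel] <<- v0 + (v1 - v0) * (t[sel] - from) / (to - from)
  }
  seg(200, 200.5, -45, 30)    # first local max
  seg(200.5, 201, 30, 10)     # dip, still above threshold
  seg(201, 201.5, 10, 40)     # global max
  seg(201.5, 202, 40, -55)    # fall through threshold to AHP
  seg(202, 204, -55, -45)
  s <- sweep_recording(t, v, 300, 100, 600)
  ev <- detect_aps(s)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_voltage, 40, tolerance = 1e-9)
  expect_equal(ev$ahp_voltage, -55, tolerance = 1e-9)
})

test_that("HHW matches analytic crossing times on linear templates", {
  t <- seq(0, 20, by = 0.05)
  tri <- function(rise, fall, peak = 40) {
    v <- numeric(length(t))
    up <- t >= 5 & t < 5 + rise
    v[up] <- peak * (t[up] - 5) / rise
    dn <- t >= 5 + rise & t < 5 + rise + fall
    v[dn] <- peak * (1 - (t[dn] - 5 - rise) / fall)
    sweep_recording(t, v, 300, 1, 19)
  }
  ev <- function(rise, fall, peak = 40)
    data.frame(threshold_time = 5, threshold_voltage = 0,
               peak_time = 5 + rise, peak_voltage = peak,
               ahp_time = 5 + rise + fall, ahp_voltage = 0)

  ## symmetric triangle: crossings at 0.5 and 1.5 ms after threshold
  tol <- 2 * 2 / 999  # two interpolation steps over a 2 ms event
  expect_equal(compute_hhw(tri(1, 1), ev(1, 1)), 1.0, tolerance = tol)
  ## amplitude scaling about threshold leaves HHW unchanged
  expect_equal(compute_hhw(tri(1, 1, peak = 80), ev(1, 1, peak = 80)), 1.0,
               tolerance = tol)
  ## sawtooth 1.5 up / 0.5 down: crossings at 0.75 and 1.75 ms
  expect_equal(compute_hhw(tri(1.5, 0.5), ev(1.5, 0.5)), 1.0, tolerance = tol)

  ## time translation invariance
  s <- template_sweep(200, rise = 0.5, fall = 0.5)
  s2 <- template_sweep(300, rise = 0.5, fall = 0.5)
  e1 <- detect_aps(s); e2 <- detect_aps(s2)
  expect_equal(compute_hhw(s, e1[1, ]), compute_hhw(s2, e2[1, ]),
               tolerance = 1e-9)

  ## malformed event: trace never recrosses the half level
  flat <- flat_sweep()
  bad <- data.frame(threshold_time = 200, threshold_voltage = -75,
                    peak_time = 201, peak_voltage = -75, ahp_time = 202,
                    ahp_voltage = -75)
  expect_error(compute_hhw(flat, bad), "malformed")
})

test_that("train features derive from consecutive threshold times", {
  ev <- data.frame(threshold_time = c(100, 110, 125))
  f <- compute_train_features(ev)
  expect_equal(f$isi_ms, c(10, 15))
  expect_equal(f$iff_hz, c(100, 1000 / 15))
  expect_equal(f$mff_hz, 100)
  ## IFF * ISI is exactly 1000 pairwise, and MFF >= mean IFF
  expect_equal(f$iff_hz * f$isi_ms, rep(1000, 2))
  expect_gte(f$mff_hz, f$mean_iff_hz)

  uniform <- compute_train_features(data.frame(threshold_time = c(0, 10, 20)))
  expect_equal(uniform$mean_iff_hz, 100)

  single <- compute_train_features(data.frame(threshold_time = 100))
  expect_false(single$defined)
  expect_true(is.na(single$mff_hz))
})

test_that("passive properties follow Ohm's law on ideal traces", {
  t <- seq(0, 700, by = 0.05)
  mk <- function(current, dv) {
    v <- rep(-75, length(t))
    v[t >= 100 & t <= 600] <- -75 + dv
    sweep_recording(t, v, current, 100, 600)
  }
  p <- compute_passive(list(mk(-100, -10), mk(-200, -20)))
  expect_equal(p$input_resistance_MOhm, 100, tolerance = 1e-9)
  expect_equal(p$rmp_mV, -75)

  expect_error(compute_passive(list(mk(0, 0))), "sweeps")
  expect_error(compute_passive(list(mk(0, 0), mk(0, 0))), "identical")
})

test_that("planted input resistance is recovered within 1%", {
  p <- generation_params("SPN")  # planted R_in 117.7 MOhm
  sw <- generate_sweeps(p)
  hyper <- Filter(function(s) s$current_pA < 0, sw$sweeps)
  pp <- compute_passive(hyper)
  expect_equal(pp$input_resistance_MOhm, 117.7, tolerance = 0.01)
  expect_equal(pp$rmp_mV, p$rmp_mV, tolerance = 1e-6)
})

test_that("classification separates fast thin spikes from slow wide ones", {
  expect_equal(classify_cell(0.4043, 75.21), "FSI")
  expect_equal(classify_cell(1.282, 26.47), "SPN")
  expect_equal(classify_cell(0.4, 20), "AMBIGUOUS")
  expect_equal(classify_cell(0.4, 75, steady_state = FALSE), "AMBIGUOUS")
})

test_that("steady-state check uses the CV of the last half of ISIs", {
  uniform <- data.frame(threshold_time = seq(100, 200, by = 10))
  expect_true(steady_state_check(uniform))

  ## ISIs doubling each interval: CV of last half well above 0.2
  doubling <- data.frame(threshold_time = 100 + cumsum(c(0, 2^(0:5))))
  isi <- diff(doubling$threshold_time)
  last <- isi[(floor(length(isi) / 2) + 1):length(isi)]
  expect_gte(sd(last) / mean(last), 0.2)
  expect_false(steady_state_check(doubling, cv_cut = 0.2))

  few <- steady_state_check(data.frame(threshold_time = c(1, 2, 3)))
  expect_false(few)
  expect_match(attr(few, "reason"), "too few")
})
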