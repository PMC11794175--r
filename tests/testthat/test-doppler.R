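half_sine_trace <- function(vmax = 4, t_ej = 0.3, dt = 0.001, pad = 0.2,
                            cycles = 1, period = 0.8) {
  total <- pad + cycles * period
  tt <- seq(dt / 2, total, by = dt)
  v <- numeric(length(tt))
  for (k in seq_len(cycles)) {
    ph <- tt - pad - (k - 1) * period
    on <- ph >= 0 & ph <= t_ej
    v[on] <- vmax * sin(pi * ph[on] / t_ej)
  }
  velocity_trace(tt, pmax(v, 0))
}

test_that("half-sine measurements match the closed forms within 1%", {
  tr <- half_sine_trace(vmax = 4, t_ej = 0.3, dt = 0.001)
  w <- detect_ejection_windows(tr)
  expect_equal(nrow(w), 1)
  m <- measure_spectral(tr, w)
  expect_equal(m$vmax, 4.00, tolerance = 0.01)
  expect_equal(m$mpg, 32.0, tolerance = 0.01 * 32)   # mean of 4 v^2 = 2 Vmax^2
  expect_equal(m$vti, 76.39, tolerance = 0.01 * 76.39) # (2/pi) Vmax T * 100
})

test_that("constant-velocity window gives rectangle integrals", {
  tt <- seq(0.0005, 0.4, by = 0.001)
  v <- ifelse(tt > 0.05 & tt <= 0.35, 1, 0)
  tr <- velocity_trace(tt, v)
  w <- detect_ejection_windows(tr)
  m <- measure_spectral(tr, w)
  expect_equal(m$vmax, 1)
  expect_equal(m$mpg, 4, tolerance = 0.01)
  expect_equal(m$vti, 30, tolerance = 0.01 * 30)
})

test_that("scaling a trace by k scales Vmax and VTI by k and mPG by k^2", {
  set.seed(31)
  for (i in 1:100) {
    vmax <- runif(1, 0.8, 5)
    tr <- half_sine_trace(vmax = vmax, t_ej = runif(1, 0.2, 0.35),
                          dt = 0.002)
    w <- detect_ejection_windows(tr)
    m1 <- measure_spectral(tr, w)
    k <- runif(1, 0.3, 2.5)
    tr2 <- velocity_trace(tr$times, tr$velocities * k)
    m2 <- measure_spectral(tr2, w)
    expect_equal(m2$vmax, k * m1$vmax, tolerance = 1e-10)
    expect_equal(m2$vti, k * m1$vti, tolerance = 1e-10)
    expect_equal(m2$mpg, k^2 * m1$mpg, tolerance = 1e-10)
  }
})

test_that("ejection-window detection counts cycles and filters duration", {
  tr3 <- half_sine_trace(cycles = 3)
  expect_equal(nrow(detect_ejection_windows(tr3)), 3)

  flat <- velocity_trace(seq(0.001, 1, by = 0.001), numeric(1000))
  expect_equal(nrow(detect_ejection_windows(flat)), 0)

  short <- half_sine_trace(t_ej = 0.05)
  expect_equal(nrow(detect_ejection_windows(short, min_duration = 0.1)), 0)

  expect_error(detect_ejection_windows(tr3, threshold_frac = 1.5), "threshold")
})

test_that("trace extraction from a mask uses distance from the baseline", {
  img <- matrix(0, 70, 3)
  spec <- doppler_spectrum(img, velocity_per_row = 0.02, time_per_col = 0.01,
                           baseline_row = 10, flow_side = "below")
  mask <- matrix(0, 70, 3)
  mask[11:60, 2] <- 1            # 50 rows below baseline
  tr <- trace_from_mask(mask, spec)
  expect_equal(tr$velocities, c(0, 1.0, 0))
  expect_false(tr$flagged)

  empty <- trace_from_mask(matrix(0, 70, 3), spec)
  expect_true(empty$flagged)
  expect_equal(sum(empty$velocities), 0)
})

test_that("trapezoid VTI is refinement-stable on smooth traces", {
  m1 <- measure_spectral(half_sine_trace(dt = 0.002),
                         data.frame(start = 0.2, end = 0.5))
  m2 <- measure_spectral(half_sine_trace(dt = 0.001),
                         data.frame(start = 0.2, end = 0.5))
  expect_lt(abs(m2$vti - m1$vti) / m2$vti, 0.005)
})

test_that("threshold provider recovers the truth envelope on clean phantoms", {
  sp <- phantom_spec("X", "moderate", 3.5, noise_level = 0)
  rd <- render_doppler(sp)
  prob <- segment_envelope(rd$spectrum, "threshold")
  expect_gte(dice_score(prob, rd$truth_mask), 0.95)

  blank <- doppler_spectrum(matrix(0, 40, 50), 0.02, 0.01, 5)
  expect_true(all(segment_envelope(blank, "threshold") <= 0.5))
})

test_that("oracle pipeline recovers analytic truth within 2% at noise 0", {
  mid_v <- c(normal = 1.6, sclerosis = 1.7, mild = 2.6, moderate = 3.6,
             severe = 4.9)
  for (st in names(mid_v)) {
    sp <- phantom_spec("X", st, mid_v[[st]], noise_level = 0)
    tr <- analytic_truth(sp)
    q <- quantify_doppler(render_doppler(sp)$spectrum)
    expect_equal(q$vmax, tr$vmax, tolerance = 0.02 * tr$vmax)
    expect_equal(q$mpg, tr$mpg, tolerance = 0.02 * tr$mpg)
    expect_equal(q$vti, tr$av_vti, tolerance = 0.02 * tr$av_vti)
    # LVOT signal too
    ql <- quantify_doppler(render_doppler(sp, "lvot")$spectrum)
    expect_equal(ql$vti, tr$lvot_vti, tolerance = 0.02 * tr$lvot_vti)
  }
})

test_that("learned envelope segmenter generalises to held-out phantoms", {
  model <- get_doppler_segmenter()
  held_out <- sample_cohort(8, rep(0.2, 5), seed = 77)
  dices <- vapply(held_out, function(sp) {
    rd <- render_doppler(sp)
    prob <- segment_envelope(rd$spectrum, "learned", model)
    dice_score(prob, rd$truth_mask)
  }, numeric(1))
  expect_gte(mean(dices), 0.8)
})

test_that("no windows propagates as unavailable, not as numbers", {
  tr <- velocity_trace(seq(0.001, 0.5, 0.001), numeric(500))
  m <- measure_spectral(tr, detect_ejection_windows(tr))
  expect_true(is.na(m$vmax) && is.na(m$mpg) && is.na(m$vti))
})
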