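test_that("cohort sampling honours the class mix and stays concordant", {
  specs <- sample_cohort(100, rep(0.2, 5), seed = 7)
  stages <- vapply(specs, `[[`, character(1), "true_stage")
  expect_equal(unname(table(factor(stages, asckit:::AS_STAGES))),
               rep(20L, 5), ignore_attr = TRUE)
  # every sampled spec stages concordantly as its own true stage
  for (sp in specs) {
    s <- stage_from_measurements(analytic_truth(sp))
    expect_true(s$concordant)
    expect_equal(s$stage, sp$true_stage)
  }
})

test_that("single-stage mix yields only that stage inside its band", {
  specs <- sample_cohort(5, c(1, 0, 0, 0, 0), seed = 3)
  expect_length(specs, 5)
  for (sp in specs) {
    expect_equal(sp$true_stage, "normal")
    expect_lt(sp$true_vmax, 2)
    expect_false(sp$calcified)
  }
})

test_that("cohort sampling is deterministic in the seed and validates the mix", {
  a <- sample_cohort(20, rep(0.2, 5), seed = 12)
  b <- sample_cohort(20, rep(0.2, 5), seed = 12)
  expect_identical(a, b)
  c <- sample_cohort(20, rep(0.2, 5), seed = 13)
  expect_false(identical(a, c))
  expect_error(sample_cohort(10, c(0.5, 0.5, 0.5, 0, 0)), "sum to 1")
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec("X", "mild", 3.5), "band")
  expect_error(phantom_spec("X", "severe", 4.5, ejection_duration = 1.2,
                            heart_rate = 80), "cardiac cycle")
  expect_error(phantom_spec("X", "mild", 2.5, noise_level = 2), "noise_level")
  expect_false(phantom_spec("X", "normal", 1.5)$calcified)
  expect_true(phantom_spec("X", "sclerosis", 1.5)$calcified)
})

test_that("analytic truth follows the half-sine closed forms", {
  sp <- phantom_spec("X", "severe", 4.0, ejection_duration = 0.3,
                     true_lvot_diameter = 2.0, true_lvot_vti = 20)
  tr <- analytic_truth(sp)
  expect_equal(tr$mpg, 32)                          # 2 * 4^2
  expect_equal(tr$av_vti, (2 / pi) * 4 * 0.3 * 100, tolerance = 1e-12)
  expect_equal(tr$ava, pi * 1^2 * 20 / tr$av_vti)
  expect_equal(round(compute_ava_continuity(2.0, 20, 80), 3), 0.785)
})

test_that("leaflet excursion decreases strictly with stage ordinal", {
  mid_v <- c(normal = 1.5, sclerosis = 1.5, mild = 2.5, moderate = 3.5,
             severe = 4.7)
  exc <- vapply(names(mid_v), function(st) {
    sp <- phantom_spec("X", st, mid_v[[st]], noise_level = 0, seed = 5)
    rv <- render_views(sp, resolution = 96)
    leaflet_excursion(rv$truth$label_map_truth, rv$truth$pixel_spacing)
  }, numeric(1))
  expect_true(all(diff(exc) < 0))
})

test_that("calcified leaflets render brighter inside the leaflet box", {
  mean_leaflet <- function(st) {
    sp <- phantom_spec("X", st, 1.5, noise_level = 0, seed = 5)
    rv <- render_views(sp, resolution = 96)
    b <- rv$truth$leaflet_box
    sel <- rv$truth$label_map_truth == 8L
    mean(rv$plax$frames[sel])
  }
  expect_gt(mean_leaflet("sclerosis"), mean_leaflet("normal"))
})

test_that("rendering is a pure function of the spec", {
  sp <- phantom_spec("X", "moderate", 3.5, noise_level = 0.4, seed = 9)
  a <- render_views(sp, resolution = 64)
  b <- render_views(sp, resolution = 64)
  expect_identical(a$plax$frames, b$plax$frames)
  expect_identical(a$psax$frames, b$psax$frames)
  expect_error(render_views(sp, resolution = 16), "resolution")
  expect_error(render_views(sp, n_frames = 4), "n_frames")
})

test_that("doppler rendering matches its closed-form truth", {
  sp <- phantom_spec("X", "severe", 4.0, ejection_duration = 0.3,
                     noise_level = 0)
  rd <- render_doppler(sp)
  w <- detect_ejection_windows(rd$truth)
  m <- measure_spectral(rd$truth, w)
  expect_equal(m$vmax, 4.0, tolerance = 0.01)
  expect_equal(m$mpg, 32.0, tolerance = 0.01 * 32)
  expect_equal(m$vti, 76.39, tolerance = 0.01 * 76.39)
  # velocity axis must contain the jet
  expect_error(render_doppler(sp, v_axis_max = 3.5), "exceeds")
})

test_that("noiseless envelope top inverts to the truth trace within one row", {
  sp <- phantom_spec("X", "moderate", 3.4, noise_level = 0)
  rd <- render_doppler(sp)
  tr <- trace_from_mask(rd$truth_mask * 1, rd$spectrum)
  expect_lte(max(abs(tr$velocities - rd$truth$velocities)),
             rd$spectrum$velocity_per_row)
})

test_that("cohort table carries one concordant row per patient", {
  specs <- sample_cohort(10, rep(0.2, 5), seed = 2)
  tab <- cohort_table(specs)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$mpg, 2 * tab$vmax^2, tolerance = 1e-12)
  staged <- stage_table(tab)
  expect_equal(staged$stage, tab$stage)
  expect_true(all(staged$concordant))
})
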