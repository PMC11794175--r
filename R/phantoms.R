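# Seeded phantom generator: echo-like PLAX/PSAX videos with anatomical label
# maps, spectral-Doppler spectrograms and cohort tables, all with closed-form
# ground truth.  The ejection velocity profile is a half-sine, which gives
# exact VTI and mean-gradient oracles:
#   VTI = (2/pi) * Vmax * T_ej * 100  (cm),   mPG = 2 * Vmax^2  (mmHg).

PLAX_CLASSES <- c("background", "LV", "septum", "posterior_wall", "LA",
                  "RV", "aorta", "MV", "AV")

# field of view in cm; pixel_spacing = FOV / resolution (0.05 cm/px at 128)
PHANTOM_FOV <- 6.4

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Vmax sampling bands (m/s).  Two trims keep every sampled patient
# concordant by construction:
# (1) the generator's mPG identity 2*Vmax^2 must stay inside the stage's mPG
#     band (below 3.17 m/s the half-sine mean gradient drops under 20 mmHg
#     and below 4.48 m/s under 40 mmHg), mirroring the exclusion of
#     discordant cases from training labels;
# (2) a small interior margin keeps quantised measurements (velocity axis
#     resolution 0.02 m/s per row) from crossing a band boundary.
VMAX_SAMPLING_BANDS <- list(
  normal    = c(1.00, 1.97), sclerosis = c(1.00, 1.97),
  mild      = c(2.03, 2.87), moderate  = c(3.19, 3.88),
  severe    = c(4.49, 5.50))

# nominal bands used to place a Vmax within its stage for rendering
VMAX_NOMINAL_BANDS <- list(
  normal    = c(1.0, 2.0), sclerosis = c(1.0, 2.0),
  mild      = c(2.0, 3.0), moderate  = c(3.0, 4.0),
  severe    = c(4.0, 5.5))

# AVA targets per stage; interior margins keep pipeline-measured AVA (LVOT
# diameter is pixel-quantised, ~3% worst case) inside the stage band
AVA_SAMPLING_BANDS <- list(
  normal    = c(2.50, 4.00), sclerosis = c(2.50, 4.00),
  mild      = c(1.60, 2.45), moderate = c(1.10, 1.42),
  severe    = c(0.60, 0.95))

#' Phantom patient specification
#'
#' Generative ground truth for one synthetic patient.  Invariants are
#' enforced: `true_vmax` must lie in the stage's Vmax band, `calcified` is
#' true exactly for stages at or beyond sclerosis, and the ejection must fit
#' inside the cardiac cycle.
#'
#' @param patient_id Character id.
#' @param true_stage One of `"normal"`, `"sclerosis"`, `"mild"`,
#'   `"moderate"`, `"severe"`.
#' @param true_vmax Peak AV jet velocity (m/s).
#' @param ejection_duration Systolic ejection time (s).
#' @param heart_rate Beats per minute.
#' @param true_lvot_diameter LVOT diameter (cm).
#' @param true_lvot_vti LVOT velocity-time integral (cm); by default solved
#'   so the continuity-equation AVA sits mid-band for the stage, keeping the
#'   spec concordant.
#' @param noise_level Speckle noise amplitude in `[0, 1]`.
#' @param seed Integer seed controlling all rendering randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(patient_id, true_stage, true_vmax,
                         ejection_duration = 0.3, heart_rate = 72,
                         true_lvot_diameter = 2.0, true_lvot_vti = NULL,
                         noise_level = 0.2, seed = 1L) {
  true_stage <- match.arg(true_stage, AS_STAGES)
  if (is.null(true_lvot_vti)) {
    ava_mid <- mean(AVA_SAMPLING_BANDS[[true_stage]])
    av_vti <- (2 / pi) * true_vmax * ejection_duration * 100
    true_lvot_vti <- ava_mid * av_vti / (pi * (true_lvot_diameter / 2)^2)
  }
  band <- VMAX_NOMINAL_BANDS[[true_stage]]
  out_of_band <- if (true_stage == "severe")
    true_vmax < band[1] || true_vmax > band[2]
  else true_vmax < band[1] || true_vmax >= band[2]
  if (out_of_band)
    stop("true_vmax ", true_vmax, " outside the ", true_stage,
         " band [", band[1], ", ", band[2], ")")
  if (ejection_duration >= 60 / heart_rate)
    stop("ejection_duration must be shorter than the cardiac cycle")
  if (any(c(true_vmax, ejection_duration, heart_rate, true_lvot_diameter,
            true_lvot_vti) <= 0))
    stop("all physical fields must be > 0")
  if (noise_level < 0 || noise_level > 1) stop("noise_level must be in [0,1]")
  structure(list(
    patient_id = as.character(patient_id), true_stage = true_stage,
    true_vmax = true_vmax, ejection_duration = ejection_duration,
    heart_rate = heart_rate, true_lvot_diameter = true_lvot_diameter,
    true_lvot_vti = true_lvot_vti,
    calcified = true_stage != "normal",
    noise_level = noise_level, seed = as.integer(seed)),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom %s: %s, Vmax %.2f m/s, D_LVOT %.2f cm, noise %.2f\n",
              x$patient_id, x$true_stage, x$true_vmax, x$true_lvot_diameter,
              x$noise_level))
  invisible(x)
}

#' Analytic measurement truth for a phantom
#'
#' Closed-form conventional measurements implied by the half-sine ejection
#' profile: `mPG = 2 Vmax^2`, `VTI_AV = (2/pi) Vmax T_ej * 100`, and AVA from
#' the continuity equation.
#'
#' @param spec A [phantom_spec()].
#' @return An [as_measurements()] object.
#' @export
analytic_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  av_vti <- (2 / pi) * spec$true_vmax * spec$ejection_duration * 100
  as_measurements(
    vmax = spec$true_vmax,
    mpg = 2 * spec$true_vmax^2,
    ava = compute_ava_continuity(spec$true_lvot_diameter, spec$true_lvot_vti,
                                 av_vti),
    av_vti = av_vti,
    lvot_vti = spec$true_lvot_vti,
    lvot_diameter = spec$true_lvot_diameter,
    calcified = spec$calcified)
}

#' Sample a concordant phantom cohort
#'
#' Stage counts follow `class_mix` by largest-remainder rounding.  Vmax is
#' uniform inside the stage's (concordance-trimmed) band; the LVOT VTI is
#' solved so that the continuity-equation AVA lands inside the stage's AVA
#' band, so every sampled patient stages concordantly by construction.
#'
#' @param n Number of patients.
#' @param class_mix Numeric length-5 proportions over
#'   (normal, sclerosis, mild, moderate, severe); must sum to 1.
#' @param seed Integer seed.
#' @param noise_level Speckle noise level shared by the cohort.
#' @return List of [phantom_spec()] objects.
#' @export
sample_cohort <- function(n, class_mix = rep(0.2, 5), seed = 1L,
                          noise_level = 0.2) {
  if (n < 1) stop("n must be >= 1")
  if (length(class_mix) != 5L) stop("class_mix must have 5 entries")
  if (abs(sum(class_mix) - 1) > 1e-6) stop("class_mix must sum to 1")
  raw <- n * class_mix
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  stages <- rep(AS_STAGES, times = counts)
  with_seed(seed, {
    lapply(seq_along(stages), function(i) {
      st <- stages[i]
      vb <- VMAX_SAMPLING_BANDS[[st]]
      ab <- AVA_SAMPLING_BANDS[[st]]
      vmax <- runif(1, vb[1], vb[2])
      t_ej <- runif(1, 0.27, 0.33)
      hr <- runif(1, 60, 90)
      d <- runif(1, 1.8, 2.4)
      ava <- runif(1, ab[1], ab[2])
      av_vti <- (2 / pi) * vmax * t_ej * 100
      lvot_vti <- ava * av_vti / (pi * (d / 2)^2)
      phantom_spec(
        patient_id = sprintf("P%04d", i), true_stage = st, true_vmax = vmax,
        ejection_duration = t_ej, heart_rate = hr, true_lvot_diameter = d,
        true_lvot_vti = lvot_vti, noise_level = noise_level,
        seed = (as.integer(seed) %% 100000L) * 10000L + i)
    })
  })
}

#' Cohort ground-truth table
#'
#' @param specs List of [phantom_spec()] objects.
#' @return Data frame with one row per patient (id, stage and analytic
#'   measurements).
#' @export
cohort_table <- function(specs) {
  rows <- lapply(specs, function(sp) {
    tr <- analytic_truth(sp)
    data.frame(patient_id = sp$patient_id, stage = sp$true_stage,
               vmax = tr$vmax, mpg = tr$mpg, ava = tr$ava,
               av_vti = tr$av_vti, lvot_vti = tr$lvot_vti,
               lvot_diameter = tr$lvot_diameter, calcified = tr$calcified,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- rendering helpers -----------------------------------------------------

# pixel-centre coordinate grids in cm for a resolution
coord_grids <- function(res) {
  sp <- PHANTOM_FOV / res
  cc <- (seq_len(res) - 0.5) * sp
  list(x = matrix(cc, res, res, byrow = TRUE),
       y = matrix(cc, res, res), spacing = sp)
}

rect_mask <- function(g, x0, x1, y0, y1)
  g$x >= x0 & g$x <= x1 & g$y >= y0 & g$y <= y1

disk_mask <- function(g, cx, cy, r) (g$x - cx)^2 + (g$y - cy)^2 <= r^2

# thick line segment from (x0,y0) to (x1,y1), half-width w/2
segment_mask <- function(g, x0, y0, x1, y1, w) {
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- max(dx^2 + dy^2, 1e-9)
  tt <- pmin(pmax(((g$x - x0) * dx + (g$y - y0) * dy) / len2, 0), 1)
  px <- x0 + tt * dx; py <- y0 + tt * dy
  (g$x - px)^2 + (g$y - py)^2 <= (w / 2)^2
}

# opening fraction schedule over the cycle; returns function of time
opening_schedule <- function(spec) {
  t_cyc <- 60 / spec$heart_rate
  t0 <- 0.08 * t_cyc
  o_min <- 0.04
  band <- VMAX_NOMINAL_BANDS[[spec$true_stage]]
  frac <- min(max((spec$true_vmax - band[1]) / (band[2] - band[1]), 0), 1)
  s <- stage_ordinal(spec$true_stage) + 0.8 * frac
  o_max <- 0.93 - 0.165 * s
  function(t) {
    tt <- t %% t_cyc
    inside <- tt >= t0 & tt <= t0 + spec$ejection_duration
    ifelse(inside,
           o_min + (o_max - o_min) * sin(pi * (tt - t0) / spec$ejection_duration),
           o_min)
  }
}

render_plax_frame <- function(spec, g, opening) {
  res <- nrow(g$x)
  img <- matrix(0.02, res, res)
  lab <- matrix(0L, res, res)
  paint <- function(mask, intensity, label) {
    img[mask] <<- intensity
    lab[mask] <<- label
  }
  D <- spec$true_lvot_diameter
  y_c <- 3.0; x_a <- 4.2
  paint(rect_mask(g, 0.3, 4.0, 0.22, 0.48), 0.7, 0L)          # RV free wall
  paint(rect_mask(g, 0.5, 3.9, 0.5, 1.1), 0.08, 5L)           # RV cavity
  paint(rect_mask(g, 0.3, x_a, 1.15, 1.65), 0.8, 2L)          # septum
  paint(rect_mask(g, 0.5, x_a - 0.001, 1.7, 4.35), 0.08, 1L)  # LV cavity
  paint(rect_mask(g, 0.3, 4.4, 4.4, 4.9), 0.8, 3L)            # posterior wall
  paint(rect_mask(g, x_a, 6.35, y_c - D / 2 - 0.25, y_c - D / 2 - 0.001),
        0.75, 0L)                                             # ant. aortic wall
  paint(rect_mask(g, x_a, 6.35, y_c + D / 2 + 0.001, y_c + D / 2 + 0.25),
        0.75, 0L)                                             # post. aortic wall
  paint(rect_mask(g, x_a, 6.35, y_c - D / 2, y_c + D / 2), 0.08, 6L) # aorta
  paint(rect_mask(g, 4.5, 6.1, y_c + D / 2 + 0.3, 5.9), 0.08, 4L)    # LA
  paint(segment_mask(g, x_a - 0.05, y_c + D / 2 + 0.35, 3.3, 4.15, 0.12),
        0.5, 7L)                                              # mitral leaflet
  # AV leaflets: hinges at the annulus corners, tips move with opening
  leaf_b <- 0.55 + 0.28 * spec$calcified
  leaf_w <- 0.12 + 0.06 * spec$calcified
  x_h <- x_a + 0.15
  L <- D / 2
  for (side in c(-1, 1)) {
    hy <- y_c + side * (D / 2 - 0.02)
    tip_y <- y_c + side * opening * (D / 2) * 0.95
    drop <- abs(hy - tip_y)
    tip_x <- x_h + sqrt(max(L^2 - drop^2, 0.01^2))
    paint(segment_mask(g, x_h, hy, tip_x, tip_y, leaf_w), leaf_b, 8L)
  }
  list(img = img, lab = lab)
}

render_psax_frame <- function(spec, g, opening) {
  res <- nrow(g$x)
  img <- matrix(0.02, res, res)
  lab <- matrix(0L, res, res)
  cx <- 3.2; cy <- 3.2; R <- 1.5
  ring <- disk_mask(g, cx, cy, R + 0.3) & !disk_mask(g, cx, cy, R)
  img[ring] <- 0.7
  lumen <- disk_mask(g, cx, cy, R)
  img[lumen] <- 0.08; lab[lumen] <- 6L
  leaf_b <- 0.55 + 0.28 * spec$calcified
  leaf_w <- 0.12 + 0.06 * spec$calcified
  r_tip <- 0.02 + (R - 0.37) * opening
  for (ang in c(90, 210, 330) * pi / 180) {
    x0 <- cx + (R - 0.05) * cos(ang); y0 <- cy + (R - 0.05) * sin(ang)
    x1 <- cx + r_tip * cos(ang); y1 <- cy + r_tip * sin(ang)
    m <- segment_mask(g, x0, y0, x1, y1, leaf_w)
    img[m] <- leaf_b; lab[m] <- 8L
  }
  list(img = img, lab = lab)
}

add_speckle <- function(frames, noise_level) {
  if (noise_level <= 0) return(frames)
  n <- length(frames)
  out <- frames * (1 + 0.35 * noise_level * rnorm(n)) +
    0.12 * noise_level * abs(rnorm(n))
  array(pmin(pmax(out, 0), 1), dim = dim(frames))
}

echo_video <- function(frames, view, frame_rate, pixel_spacing, patient_id) {
  structure(list(frames = frames, view = view, frame_rate = frame_rate,
                 pixel_spacing = pixel_spacing, patient_id = patient_id),
            class = "echo_video")
}

#' @export
print.echo_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("echo_video %s: %dx%d px, %d frames @ %.1f fps, %.3f cm/px\n",
              x$view, d[1], d[2], d[3], x$frame_rate, x$pixel_spacing))
  invisible(x)
}

#' Render PLAX and PSAX phantom videos
#'
#' Draws a stylised parasternal long-axis (chambers, septum, aorta, mitral
#' valve, two AV leaflets) and short-axis (aortic root, three leaflets) view.
#' The systolic leaflet opening excursion decreases strictly with stage
#' ordinal and leaflet brightness/thickness increase when calcified.  Speckle
#' is seeded from the spec, so rendering is a pure function of the spec.
#'
#' @param spec A [phantom_spec()].
#' @param resolution Frame edge length in pixels (>= 32). The field of view
#'   is fixed at 6.4 cm, so `pixel_spacing = 6.4 / resolution`.
#' @param n_frames Number of frames covering one cardiac cycle (>= 8).
#' @return List with `plax` and `psax` ([echo_video] objects) and `truth`
#'   (class `phantom_truth`: analytic measurements, per-frame PLAX/PSAX label
#'   maps, the PLAX leaflet bounding box in pixels, and the peak-opening
#'   frame index).
#' @export
render_views <- function(spec, resolution = 64, n_frames = 16) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (resolution < 32) stop("resolution must be >= 32")
  if (n_frames < 8) stop("n_frames must be >= 8")
  g <- coord_grids(resolution)
  t_cyc <- 60 / spec$heart_rate
  times <- (seq_len(n_frames) - 1) * t_cyc / n_frames
  osched <- opening_schedule(spec)
  o <- osched(times)
  plax <- array(0, c(resolution, resolution, n_frames))
  psax <- array(0, c(resolution, resolution, n_frames))
  lab_plax <- array(0L, c(resolution, resolution, n_frames))
  lab_psax <- array(0L, c(resolution, resolution, n_frames))
  for (f in seq_len(n_frames)) {
    fr <- render_plax_frame(spec, g, o[f])
    plax[, , f] <- fr$img; lab_plax[, , f] <- fr$lab
    fr <- render_psax_frame(spec, g, o[f])
    psax[, , f] <- fr$img; lab_psax[, , f] <- fr$lab
  }
  with_seed(spec$seed, {
    plax <- add_speckle(plax, spec$noise_level)
    psax <- add_speckle(psax, spec$noise_level)
  })
  av <- which(apply(lab_plax == 8L, c(1, 2), any), arr.ind = TRUE)
  box <- c(row_min = max(min(av[, 1]) - 1L, 1L),
           row_max = min(max(av[, 1]) + 1L, resolution),
           col_min = max(min(av[, 2]) - 1L, 1L),
           col_max = min(max(av[, 2]) + 1L, resolution))
  t0 <- 0.08 * t_cyc
  peak_frame <- which.min(abs(times - (t0 + spec$ejection_duration / 2)))
  fps <- n_frames / t_cyc
  truth <- structure(list(
    measurements = analytic_truth(spec),
    label_map_truth = lab_plax, psax_label_map = lab_psax,
    leaflet_box = box, peak_frame = peak_frame,
    opening = o, pixel_spacing = g$spacing), class = "phantom_truth")
  list(plax = echo_video(plax, "PLAX", fps, g$spacing, spec$patient_id),
       psax = echo_video(psax, "PSAX", fps, g$spacing, spec$patient_id),
       truth = truth)
}

#' Leaflet opening excursion from truth label maps
#'
#' Maximum systolic gap (cm) between the two AV leaflet components in a PLAX
#' truth label-map stack; the generator's observable encoding of severity.
#'
#' @param label_maps Integer array `H x W x T` of PLAX class labels.
#' @param pixel_spacing cm per pixel.
#' @return Excursion in cm (0 if leaflets never separate).
#' @export
leaflet_excursion <- function(label_maps, pixel_spacing) {
  gaps <- vapply(seq_len(dim(label_maps)[3]), function(f) {
    idx <- which(label_maps[, , f] == 8L, arr.ind = TRUE)
    if (nrow(idx) < 2) return(0)
    rows <- sort(unique(idx[, 1]))
    jump <- diff(rows)
    if (all(jump == 1)) return(0)
    max(jump - 1) * pixel_spacing
  }, numeric(1))
  max(gaps)
}

# ---- spectral Doppler ------------------------------------------------------

#' Doppler spectrogram container
#'
#' @param intensity Matrix, rows = velocity bins, cols = time bins, in `[0,1]`.
#' @param velocity_per_row m/s per row of distance from the baseline.
#' @param time_per_col Seconds per column.
#' @param baseline_row Row index of the zero-velocity baseline.
#' @param flow_side `"below"` or `"above"`: side of the baseline carrying the
#'   jet.
#' @param modality `"CW"` or `"PW"`.
#' @param view_tag Free-text tag, e.g. `"AV_CW"` or `"LVOT_PW"`.
#' @return Object of class `doppler_spectrum`.
#' @export
doppler_spectrum <- function(intensity, velocity_per_row, time_per_col,
                             baseline_row, flow_side = c("below", "above"),
                             modality = c("CW", "PW"), view_tag = "AV_CW") {
  flow_side <- match.arg(flow_side)
  modality <- match.arg(modality)
  if (velocity_per_row <= 0 || time_per_col <= 0)
    stop("calibrations must be > 0")
  if (baseline_row < 1 || baseline_row > nrow(intensity))
    stop("baseline_row outside image")
  structure(list(intensity = intensity, velocity_per_row = velocity_per_row,
                 time_per_col = time_per_col, baseline_row = baseline_row,
                 flow_side = flow_side, modality = modality,
                 view_tag = view_tag), class = "doppler_spectrum")
}

#' @export
print.doppler_spectrum <- function(x, ...) {
  cat(sprintf("doppler_spectrum %s (%s): %dx%d, %.3f m/s/row, %.4f s/col\n",
              x$view_tag, x$modality, nrow(x$intensity), ncol(x$intensity),
              x$velocity_per_row, x$time_per_col))
  invisible(x)
}

#' Render a phantom spectral-Doppler spectrogram
#'
#' The envelope follows `v(t) = Vmax sin(pi t / T_ej)` inside each ejection
#' window and is zero elsewhere; the area below the envelope on the flow side
#' is filled.  The AV signal uses the spec's `true_vmax` (CW); the LVOT
#' signal uses the peak velocity implied by `true_lvot_vti` (PW).
#'
#' @param spec A [phantom_spec()].
#' @param signal `"av"` or `"lvot"`.
#' @param velocity_per_row m/s per row (default 0.02).
#' @param time_per_col s per column (default 1/256).
#' @param v_axis_max Velocity axis range below baseline (m/s); must exceed
#'   the signal's peak velocity.
#' @param n_cycles Number of cardiac cycles rendered.
#' @return List with `spectrum` (a [doppler_spectrum()]), `truth` (a
#'   [velocity_trace()] at column resolution), `windows` (true ejection
#'   windows, data frame of start/end seconds) and `truth_mask` (logical
#'   matrix: the noiseless filled-envelope region).
#' @export
render_doppler <- function(spec, signal = c("av", "lvot"),
                           velocity_per_row = 0.02, time_per_col = 1 / 256,
                           v_axis_max = 6.0, n_cycles = 3) {
  stopifnot(inherits(spec, "phantom_spec"))
  signal <- match.arg(signal)
  vmax <- switch(signal,
                 av = spec$true_vmax,
                 lvot = spec$true_lvot_vti * pi / (2 * spec$ejection_duration * 100))
  if (vmax <= 0) stop("degenerate phantom: peak velocity must be > 0")
  if (vmax > v_axis_max)
    stop("peak velocity ", vmax, " m/s exceeds the velocity axis range ",
         v_axis_max, " m/s")
  t_cyc <- 60 / spec$heart_rate
  t0 <- 0.1 * t_cyc
  dur <- n_cycles * t_cyc
  n_col <- round(dur / time_per_col)
  n_below <- ceiling(v_axis_max / velocity_per_row)
  baseline <- 8L
  n_row <- baseline + n_below
  tt <- (seq_len(n_col) - 0.5) * time_per_col
  phase <- (tt - t0) %% t_cyc
  v <- ifelse(phase >= 0 & phase <= spec$ejection_duration,
              vmax * sin(pi * phase / spec$ejection_duration), 0)
  v[v < 0] <- 0
  img <- matrix(0, n_row, n_col)
  env_rows <- round(v / velocity_per_row)
  for (j in seq_len(n_col)) {
    if (env_rows[j] >= 1)
      img[(baseline + 1):(baseline + env_rows[j]), j] <- 0.7
  }
  truth_mask <- img > 0.5
  with_seed(spec$seed + switch(signal, av = 7001L, lvot = 7002L), {
    if (spec$noise_level > 0) {
      img <- img + 0.3 * spec$noise_level * abs(matrix(rnorm(n_row * n_col),
                                                       n_row, n_col))
      img <- pmin(pmax(img, 0), 1)
    }
  })
  starts <- t0 + (seq_len(n_cycles) - 1) * t_cyc
  windows <- data.frame(start = starts, end = starts + spec$ejection_duration)
  windows <- windows[windows$end <= dur, , drop = FALSE]
  list(spectrum = doppler_spectrum(img, velocity_per_row, time_per_col,
                                   baseline, "below",
                                   if (signal == "av") "CW" else "PW",
                                   if (signal == "av") "AV_CW" else "LVOT_PW"),
       truth = velocity_trace(tt, v), windows = windows,
       truth_mask = truth_mask)
}
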