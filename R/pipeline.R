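# Study bundles (disk layout + round trip), the per-patient dual-pathway
# orchestration and cohort-level evaluation.

#' Study bundle
#'
#' @param patient_id Character id.
#' @param videos List of [echo_video] objects (views PLAX/PSAX).
#' @param spectra List of [doppler_spectrum()] objects.
#' @param ground_truth Optional list with `stage` and `measurements`
#'   ([as_measurements()]).
#' @param truth_labels Optional PLAX truth label-map array (oracle
#'   segmentation provider).
#' @return Object of class `study_bundle`.
#' @export
study_bundle <- function(patient_id, videos = list(), spectra = list(),
                         ground_truth = NULL, truth_labels = NULL) {
  if (!length(videos) && !length(spectra))
    stop("a study bundle needs at least one video or spectrum")
  views <- vapply(videos, `[[`, character(1), "view")
  if (!all(views %in% c("PLAX", "PSAX")))
    stop("unsupported view tag: ", paste(setdiff(views, c("PLAX", "PSAX")),
                                         collapse = ", "))
  structure(list(patient_id = patient_id, videos = videos, spectra = spectra,
                 ground_truth = ground_truth, truth_labels = truth_labels),
            class = "study_bundle")
}

#' Render a phantom into a study bundle
#'
#' @param spec A [phantom_spec()].
#' @param resolution,n_frames Passed to [render_views()].
#' @return A [study_bundle()] carrying PLAX + PSAX videos, AV CW and LVOT PW
#'   spectra, the generative truth and the PLAX truth label maps.
#' @export
phantom_bundle <- function(spec, resolution = 128, n_frames = 16) {
  rv <- render_views(spec, resolution = resolution, n_frames = n_frames)
  av <- render_doppler(spec, "av")
  lv <- render_doppler(spec, "lvot")
  study_bundle(spec$patient_id, list(rv$plax, rv$psax),
               list(av$spectrum, lv$spectrum),
               ground_truth = list(stage = spec$true_stage,
                                   measurements = rv$truth$measurements,
                                   leaflet_box = rv$truth$leaflet_box),
               truth_labels = rv$truth$label_map_truth)
}

# ---- disk round trip -------------------------------------------------------

#' Write a study bundle to disk
#'
#' One directory per patient: `meta.json` sidecar (views, calibrations,
#' ground truth), videos and spectra as `.rds` arrays, per-frame 8-bit PNG
#' label maps and a spectrogram PNG for inspection.
#'
#' @param bundle A [study_bundle()].
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_study_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(patient_id = bundle$patient_id, videos = list(),
               spectra = list())
  for (v in bundle$videos) {
    fn <- sprintf("video_%s.rds", v$view)
    saveRDS(v$frames, file.path(path, fn))
    meta$videos[[length(meta$videos) + 1]] <-
      list(file = fn, view = v$view, frame_rate = v$frame_rate,
           pixel_spacing = v$pixel_spacing)
  }
  for (s in bundle$spectra) {
    fn <- sprintf("spectrum_%s.rds", s$view_tag)
    saveRDS(s$intensity, file.path(path, fn))
    png::writePNG(s$intensity, file.path(path, sprintf("spectrum_%s.png",
                                                       s$view_tag)))
    meta$spectra[[length(meta$spectra) + 1]] <-
      list(file = fn, view_tag = s$view_tag, modality = s$modality,
           flow_side = s$flow_side, baseline_row = s$baseline_row,
           velocity_per_row = s$velocity_per_row,
           time_per_col = s$time_per_col)
  }
  if (!is.null(bundle$truth_labels)) {
    d <- dim(bundle$truth_labels)
    for (f in seq_len(d[3]))
      png::writePNG(bundle$truth_labels[, , f] / 255,
                    file.path(path, sprintf("label_PLAX_%02d.png", f)))
    meta$truth_label_frames <- d[3]
  }
  if (!is.null(bundle$ground_truth)) {
    gt <- bundle$ground_truth
    meta$ground_truth <- list(
      stage = gt$stage,
      measurements = unclass(gt$measurements),
      leaflet_box = as.list(gt$leaflet_box))
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a study bundle from disk
#'
#' @param path Bundle directory written by [write_study_bundle()].
#' @return A [study_bundle()].
#' @export
read_study_bundle <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("missing sidecar meta.json in ", path)
  meta <- jsonlite::read_json(mf)
  videos <- lapply(meta$videos, function(v) {
    for (f in c("file", "view", "frame_rate", "pixel_spacing"))
      if (is.null(v[[f]])) stop("bundle sidecar missing video field \"", f, "\"")
    echo_video(readRDS(file.path(path, v$file)), v$view, v$frame_rate,
               v$pixel_spacing, meta$patient_id)
  })
  spectra <- lapply(meta$spectra, function(s) {
    for (f in c("file", "velocity_per_row", "time_per_col", "baseline_row",
                "flow_side", "modality"))
      if (is.null(s[[f]])) stop("bundle sidecar missing spectrum field \"", f, "\"")
    doppler_spectrum(readRDS(file.path(path, s$file)), s$velocity_per_row,
                     s$time_per_col, s$baseline_row, s$flow_side, s$modality,
                     s$view_tag)
  })
  truth_labels <- NULL
  if (!is.null(meta$truth_label_frames)) {
    fr <- lapply(seq_len(meta$truth_label_frames), function(f)
      round(png::readPNG(file.path(path, sprintf("label_PLAX_%02d.png", f))) * 255))
    truth_labels <- array(as.integer(unlist(fr)),
                          c(dim(fr[[1]]), length(fr)))
  }
  gt <- NULL
  if (!is.null(meta$ground_truth)) {
    g <- meta$ground_truth
    m <- g$measurements
    gt <- list(stage = g$stage,
               measurements = as_measurements(
                 vmax = m$vmax %||% NA_real_, mpg = m$mpg %||% NA_real_,
                 ava = m$ava %||% NA_real_, av_vti = m$av_vti %||% NA_real_,
                 lvot_vti = m$lvot_vti %||% NA_real_,
                 lvot_diameter = m$lvot_diameter %||% NA_real_,
                 calcified = m$calcified %||% NA),
               leaflet_box = unlist(g$leaflet_box))
  }
  study_bundle(meta$patient_id, videos, spectra, gt, truth_labels)
}

# ---- dual-pathway orchestration --------------------------------------------

#' Automated calcification call
#'
#' Mean intensity of AV-labelled pixels across frames against a fixed
#' brightness threshold (calcified leaflets render markedly brighter).
#'
#' @param video A PLAX [echo_video].
#' @param maps Per-frame label maps (list of [plax_label_map()]).
#' @param threshold Intensity threshold (default 0.68).
#' @return Logical, or `NA` when no AV pixels are found.
#' @export
detect_calcification <- function(video, maps, threshold = 0.68) {
  vals <- unlist(lapply(seq_along(maps), function(f) {
    sel <- maps[[f]]$labels == 8L
    if (!any(sel)) return(NULL)
    video$frames[, , f][sel]
  }))
  if (!length(vals)) return(NA)
  mean(vals) > threshold
}

#' Run the dual pathway for one patient
#'
#' The continuum pathway scores every PLAX/PSAX video and is always
#' attempted.  The conventional pathway (Doppler quantification, LVOT
#' diameter, continuity-equation AVA, guideline staging) runs when spectra
#' and a PLAX video are present and the uncertainty gate allows it; halted
#' or missing measurements propagate as unavailable, never as numbers.
#'
#' @param bundle A [study_bundle()].
#' @param scorer A trained `asc_scorer` (or `NULL` to skip the continuum
#'   pathway).
#' @param cutoffs A [cutoff_set()] for score classification.
#' @param gate_cfg A [gate_config()].
#' @param providers List: `doppler` (`"threshold"`/`"learned"`), `plax`
#'   (`"truth"`/`"learned"`), and models `doppler_model`, `plax_model` for
#'   the learned providers.
#' @return Object of class `patient_report`.
#' @export
run_patient <- function(bundle, scorer = NULL, cutoffs = default_cutoffs(),
                        gate_cfg = gate_config(),
                        providers = list(doppler = "threshold",
                                         plax = "truth")) {
  stopifnot(inherits(bundle, "study_bundle"))
  dli <- NULL
  predicted_stage <- NA_character_
  scorable <- Filter(function(v) v$view %in% c("PLAX", "PSAX"), bundle$videos)
  if (!is.null(scorer) && length(scorable)) {
    sc <- data.frame(view = vapply(scorable, `[[`, character(1), "view"),
                     score = vapply(scorable, function(v)
                       score_video(scorer, v), numeric(1)))
    dli <- aggregate_patient(sc)
    predicted_stage <- classify_by_cutoffs(dli$dli_asc, cutoffs)
  }

  # conventional pathway
  gate_rep <- uncertainty_report(0, 0, 0, "proceed")
  meas <- as_measurements()
  plax_video <- Filter(function(v) v$view == "PLAX", bundle$videos)
  av_spec <- Filter(function(s) s$modality == "CW", bundle$spectra)
  lvot_spec <- Filter(function(s) s$modality == "PW", bundle$spectra)

  if (identical(providers$plax, "learned") ||
      identical(providers$doppler, "learned")) {
    ent <- 0
    if (identical(providers$plax, "learned") && length(plax_video)) {
      mid <- dim(plax_video[[1]]$frames)[3] %/% 2
      r <- assess_uncertainty(providers$plax_model,
                              plax_video[[1]]$frames[, , mid], gate_cfg)
      ent <- max(ent, r$predictive_entropy)
      gate_rep <- r
    }
    if (identical(providers$doppler, "learned") && length(av_spec)) {
      r <- assess_uncertainty(providers$doppler_model,
                              av_spec[[1]]$intensity, gate_cfg, seed = 2L)
      if (r$predictive_entropy > ent) { ent <- r$predictive_entropy; gate_rep <- r }
    }
    gate_rep$gate <- gate_measurement(gate_rep, gate_cfg)
  }

  if (gate_rep$gate == "proceed") {
    vmax <- mpg <- av_vti <- lvot_vti <- d_lvot <- ava <- NA_real_
    calc <- NA
    if (length(av_spec)) {
      q <- quantify_doppler(av_spec[[1]], providers$doppler %||% "threshold",
                            providers$doppler_model)
      vmax <- q$vmax; mpg <- q$mpg; av_vti <- q$vti
    }
    if (length(lvot_spec)) {
      q <- quantify_doppler(lvot_spec[[1]], providers$doppler %||% "threshold",
                            providers$doppler_model)
      lvot_vti <- q$vti
    }
    plax_provider <- providers$plax %||% "truth"
    plax_ready <- length(plax_video) &&
      ((plax_provider == "truth" && !is.null(bundle$truth_labels)) ||
         (plax_provider == "learned" && !is.null(providers$plax_model)))
    if (plax_ready) {
      maps <- segment_plax(plax_video[[1]], plax_provider,
                           model = providers$plax_model,
                           truth_labels = bundle$truth_labels)
      d_lvot <- tryCatch(measure_lvot_diameter(maps)$value,
                         error = function(e) NA_real_)
      calc <- detect_calcification(plax_video[[1]], maps)
    }
    if (!is.na(d_lvot) && !is.na(lvot_vti) && !is.na(av_vti) && av_vti > 0)
      ava <- compute_ava_continuity(d_lvot, lvot_vti, av_vti)
    meas <- as_measurements(vmax = vmax, mpg = mpg, ava = ava,
                            av_vti = av_vti, lvot_vti = lvot_vti,
                            lvot_diameter = d_lvot, calcified = calc)
  }
  auto_stage <- if (any(!is.na(c(meas$vmax, meas$mpg, meas$ava))))
    stage_from_measurements(meas)
  else as_stage("indeterminate", FALSE, "insufficient_data")

  structure(list(patient_id = bundle$patient_id, dli_asc = dli,
                 predicted_stage_by_cutoffs = predicted_stage,
                 auto_measurements = meas, auto_stage = auto_stage,
                 gate = gate_rep), class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat("patient", x$patient_id, "\n")
  if (!is.null(x$dli_asc))
    cat(sprintf("  DLi-ASc %.1f -> %s\n", x$dli_asc$dli_asc,
                x$predicted_stage_by_cutoffs))
  cat(sprintf("  conventional: %s (gate %s)\n", x$auto_stage$stage,
              x$gate$gate))
  invisible(x)
}

# ---- cohort evaluation -----------------------------------------------------

auc_or_na <- function(labels, scores) {
  if (length(unique(labels)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(FALSE, TRUE))))
}

binary_metrics <- function(truth, pred) {
  tp <- sum(truth & pred); tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = tp / (tp + fp), npv = tn / (tn + fn),
    f1 = 2 * tp / (2 * tp + fp + fn),
    accuracy = (tp + tn) / length(truth))
}

#' Evaluate a cohort of patient reports against ground truth
#'
#' Computes the discrimination of DLi-ASc for the three nested severity
#' tiers (any AS = mild or worse, significant AS = moderate or worse, severe
#' AS), staging agreement of the conventional pathway, and Spearman r / MAE
#' between automated and true measurements.
#'
#' @param reports List of `patient_report` objects.
#' @param truth Data frame with `patient_id`, `stage` and optionally `vmax`,
#'   `mpg`, `ava` columns.
#' @param cutoffs [cutoff_set()] used for operating-point metrics.
#' @return List with `auc` (per tier), `operating` (sens/spec/PPV/NPV/F1 per
#'   tier at the cutoffs), `staging` (confusion matrix + accuracy) and
#'   `measurements` (per-parameter Spearman r, MAE, n).
#' @export
evaluate_cohort <- function(reports, truth, cutoffs = default_cutoffs()) {
  ids <- vapply(reports, `[[`, character(1), "patient_id")
  truth <- truth[match(ids, truth$patient_id), ]
  ord <- stage_ordinal(truth$stage)
  dli <- vapply(reports, function(r)
    if (is.null(r$dli_asc)) NA_real_ else r$dli_asc$dli_asc, numeric(1))
  tiers <- list(any_as = ord >= 2, significant_as = ord >= 3,
                severe_as = ord >= 4)
  has <- !is.na(dli)
  auc <- vapply(tiers, function(tr) auc_or_na(tr[has], dli[has]), numeric(1))
  cutvals <- c(any_as = cutoffs$mild, significant_as = cutoffs$moderate,
               severe_as = cutoffs$severe)
  operating <- t(vapply(names(tiers), function(nm)
    binary_metrics(tiers[[nm]][has], dli[has] >= cutvals[nm]),
    numeric(6)))

  auto_stage <- vapply(reports, function(r) r$auto_stage$stage, character(1))
  measurable <- auto_stage %in% AS_STAGES
  confusion <- table(truth = factor(truth$stage, AS_STAGES),
                     auto = factor(auto_stage, AS_STAGES))
  staging_acc <- mean(auto_stage[measurable] == truth$stage[measurable])

  meas <- NULL
  for (p in c("vmax", "mpg", "ava")) {
    if (!p %in% names(truth)) next
    est <- vapply(reports, function(r) r$auto_measurements[[p]], numeric(1))
    ok <- !is.na(est) & !is.na(truth[[p]])
    meas <- rbind(meas, data.frame(
      parameter = p, n = sum(ok),
      spearman_r = if (sum(ok) > 2) cor(est[ok], truth[[p]][ok],
                                        method = "spearman") else NA_real_,
      mae = if (any(ok)) mean(abs(est[ok] - truth[[p]][ok])) else NA_real_))
  }
  list(auc = auc, operating = operating,
       staging = list(confusion = confusion, accuracy = staging_acc,
                      n_measured = sum(measurable)),
       measurements = meas)
}
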