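# PLAX anatomy segmentation (desk-scale) and LVOT diameter measurement.

#' PLAX label map
#'
#' @param probabilities `H x W x 9` per-pixel class probability stack
#'   (classes in [PLAX_CLASSES] order, background first).
#' @param pixel_spacing cm per pixel.
#' @return Object of class `plax_label_map` with `labels` (0-based argmax
#'   class image), the probability stack and the spacing.
#' @export
plax_label_map <- function(probabilities, pixel_spacing) {
  s <- apply(probabilities, c(1, 2), sum)
  if (max(abs(s - 1)) > 1e-5)
    stop("probabilities must sum to 1 per pixel")
  labels <- apply(probabilities, c(1, 2), which.max) - 1L
  structure(list(labels = labels, probabilities = probabilities,
                 pixel_spacing = pixel_spacing), class = "plax_label_map")
}

# build a label map from hard labels (oracle/identity provider)
label_map_from_truth <- function(labels, pixel_spacing) {
  k <- 9L
  prob <- array(1e-6 / (k - 1), c(nrow(labels), ncol(labels), k))
  idx <- cbind(c(row(labels)), c(col(labels)), c(labels) + 1L)
  prob[idx] <- 1 - 1e-6
  plax_label_map(prob / 1, pixel_spacing)
}

#' Segment a PLAX video
#'
#' Per-frame anatomical label maps.  Providers: `"learned"` (the small
#' encoder-decoder from [train_plax_segmenter()]) or `"truth"` (identity
#' oracle: requires `truth_labels`, the generator's label-map stack).
#'
#' @param video An [echo_video] with view tag `"PLAX"`.
#' @param provider `"learned"` or `"truth"`.
#' @param model An `asc_segmenter` (learned provider).
#' @param truth_labels `H x W x T` label array (truth provider).
#' @return List of [plax_label_map()] objects, one per frame.
#' @export
segment_plax <- function(video, provider = c("learned", "truth"),
                         model = NULL, truth_labels = NULL) {
  stopifnot(inherits(video, "echo_video"))
  if (!identical(video$view, "PLAX"))
    stop("segment_plax requires a PLAX view, got ", video$view)
  provider <- match.arg(provider)
  n <- dim(video$frames)[3]
  if (provider == "truth") {
    if (is.null(truth_labels)) stop("truth provider requires truth_labels")
    return(lapply(seq_len(n), function(f)
      label_map_from_truth(matrix(truth_labels[, , f], dim(truth_labels)[1]),
                           video$pixel_spacing)))
  }
  if (is.null(model)) stop("learned provider requires a trained model")
  lapply(seq_len(n), function(f)
    plax_label_map(predict_segmenter(model, video$frames[, , f]),
                   video$pixel_spacing))
}

# pixel gap between the two AV leaflet groups (0 when closed/absent)
av_opening_px <- function(labels) {
  idx <- which(labels == 8L, arr.ind = TRUE)
  if (nrow(idx) < 2) return(0)
  rows <- sort(unique(idx[, 1]))
  jump <- diff(rows)
  if (!length(jump) || all(jump == 1)) return(0)
  max(jump - 1)
}

#' Select the mid-systolic frame
#'
#' Returns the frame index with the widest AV leaflet opening; ties break to
#' the lowest index.
#'
#' @param maps List of [plax_label_map()] objects.
#' @return Integer frame index (1-based).
#' @export
select_midsystolic_frame <- function(maps) {
  if (!length(maps)) stop("no frames given")
  gaps <- vapply(maps, function(m) av_opening_px(m$labels), numeric(1))
  has_av <- vapply(maps, function(m) any(m$labels == 8L), logical(1))
  if (!any(has_av)) stop("no AV pixels in any frame: study unmeasurable")
  which.max(gaps)
}

#' Linear measurement
#'
#' @param value Length in cm.
#' @param endpoints 2x2 matrix of (row, col) endpoints.
#' @param frame_index Frame the measurement was taken on.
#' @return Object of class `linear_measurement`.
#' @export
linear_measurement <- function(value, endpoints, frame_index) {
  structure(list(value = value, endpoints = endpoints,
                 frame_index = frame_index), class = "linear_measurement")
}

#' @export
print.linear_measurement <- function(x, ...) {
  cat(sprintf("linear_measurement: %.2f cm (frame %d)\n", x$value,
              x$frame_index))
  invisible(x)
}

measure_lvot_single <- function(map, offset_cm = 0) {
  labels <- map$labels
  if (!any(labels == 1L)) stop("unmeasurable: no LV class in label map")
  if (!any(labels == 6L)) stop("unmeasurable: no aorta class in label map")
  ao <- which(labels == 6L, arr.ind = TRUE)
  lv_px <- which(labels == 1L, arr.ind = TRUE)
  # outflow axis = LV centroid -> aorta centroid direction (robust to the
  # aorta region being nearly isotropic, unlike its principal axis)
  ctr <- colMeans(ao)
  axis <- ctr - colMeans(lv_px)
  axis <- axis / sqrt(sum(axis^2))
  perp <- c(-axis[2], axis[1])
  # annulus = LV pixels 4-adjacent to an aorta pixel
  lv <- labels == 1L
  aom <- labels == 6L
  h <- nrow(labels); w <- ncol(labels)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
    out[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  touch <- lv & (shift(aom, 1, 0) | shift(aom, -1, 0) |
                 shift(aom, 0, 1) | shift(aom, 0, -1))
  ann <- which(touch, arr.ind = TRUE)
  if (nrow(ann) < 2) stop("unmeasurable: LV-aorta interface not found")
  pts <- ann
  if (offset_cm != 0) {
    # slide the annulus points into the LVOT along the outflow axis, towards
    # the LV side, and keep those that still land in LV cavity
    step <- offset_cm / map$pixel_spacing
    dir <- if (sum((ctr - colMeans(ann)) * axis) > 0) -1 else 1
    cand <- sweep(ann, 2, round(dir * step * axis), "+")
    keep <- cand[, 1] >= 1 & cand[, 1] <= h & cand[, 2] >= 1 & cand[, 2] <= w
    cand <- cand[keep, , drop = FALSE]
    inlv <- lv[cand]
    if (sum(inlv) >= 2) pts <- cand[inlv, , drop = FALSE]
  }
  proj <- as.numeric(pts %*% perp)
  i0 <- which.min(proj); i1 <- which.max(proj)
  value <- (max(proj) - min(proj) + 1) * map$pixel_spacing
  linear_measurement(value, rbind(pts[i0, ], pts[i1, ]), 1L)
}

#' Measure the LVOT diameter
#'
#' Locates the annulus plane (LV pixels touching the aorta class), takes the
#' inner-edge to inner-edge extent perpendicular to the outflow axis (the
#' LV-to-aorta centroid direction) and converts by the pixel spacing.
#' Given a frame sequence, the median over the three most-open frames is
#' returned.  `offset_cm` moves the measurement plane from the annulus into
#' the LVOT.
#'
#' @param maps A [plax_label_map()] or a list of them (a frame sequence).
#' @param offset_cm Distance below the annulus (cm, default 0).
#' @return A [linear_measurement()].
#' @export
measure_lvot_diameter <- function(maps, offset_cm = 0) {
  if (inherits(maps, "plax_label_map"))
    return(measure_lvot_single(maps, offset_cm))
  gaps <- vapply(maps, function(m) av_opening_px(m$labels), numeric(1))
  pick <- order(gaps, decreasing = TRUE)[seq_len(min(3, length(maps)))]
  ms <- lapply(pick, function(f) {
    m <- measure_lvot_single(maps[[f]], offset_cm)
    m$frame_index <- f
    m
  })
  vals <- vapply(ms, `[[`, numeric(1), "value")
  best <- ms[[which.min(abs(vals - median(vals)))]]
  best$value <- median(vals)
  best
}
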