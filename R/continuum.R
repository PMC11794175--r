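# The deep-learning continuum pathway: ordered-label targets, combined
# Bernoulli + multi-task loss, desk-scale (2+1)D video network training,
# DLi-ASc scoring, patient aggregation, cutoffs, Grad-CAM saliency.

#' Ordinal continuum target for a stage
#'
#' Maps the five severity stages to equally spaced targets on `[0, 1]`:
#' normal 0, sclerosis 0.25, mild 0.5, moderate 0.75, severe 1.
#'
#' @param stage Character vector of stage names.
#' @return Numeric vector in `{0, 0.25, 0.5, 0.75, 1}`.
#' @export
ordinal_target <- function(stage) stage_ordinal(stage) / 4

#' Negative Bernoulli log-likelihood with soft targets
#'
#' `-(y log p + (1 - y) log(1 - p))` with `p` clamped to
#' `[1e-7, 1 - 1e-7]`.  For fractional ordered targets this is soft-target
#' cross-entropy, minimised at `p = y`.
#'
#' @param p Predicted probability.
#' @param y Target in `[0, 1]`.
#' @return Loss (non-negative up to the entropy floor of the soft target).
#' @export
loss_bernoulli <- function(p, y) {
  if (any(y < 0 | y > 1)) stop("ordinal target must lie in [0, 1]")
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Combined continuum + auxiliary loss
#'
#' `L = L_Bernoulli + lambda * sum over unmasked auxiliary tasks of the
#' squared residual` (per-sample; averaging over a batch recovers the
#' per-task MSE).  Targets and predictions are expected on the normalised
#' (z-scored) scale.
#'
#' @param p,y As in [loss_bernoulli()].
#' @param aux_preds,aux_targets Numeric length-3 vectors (Vmax, mPG, AVA).
#' @param aux_mask 0/1 availability mask; masked tasks contribute nothing.
#' @param lambda_weight Non-negative weighting of the auxiliary terms.
#' @return Scalar loss.
#' @export
loss_combined <- function(p, y, aux_preds = numeric(3),
                          aux_targets = numeric(3), aux_mask = rep(1, 3),
                          lambda_weight = 1) {
  if (lambda_weight < 0) stop("lambda_weight must be >= 0")
  res <- (aux_preds - aux_targets) * aux_mask
  loss_bernoulli(p, y) + lambda_weight * sum(res^2)
}

#' Model configuration for the continuum scorer
#'
#' @param lambda_weight Auxiliary loss weight (>= 0, default 1).
#' @param frames Frames per clip (temporal length).
#' @param resolution Frame edge in pixels.
#' @param epochs Maximum training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param channels Channel widths of the four (2+1)D blocks.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param seed Integer seed controlling initialisation and shuffling.
#' @return Object of class `asc_model_config`.
#' @export
asc_model_config <- function(lambda_weight = 1, frames = 16, resolution = 64,
                             epochs = 60, lr = 5e-3, batch_size = 8,
                             channels = c(8, 16, 24, 32), patience = 15,
                             seed = 1L) {
  if (lambda_weight < 0) stop("lambda_weight must be >= 0")
  structure(list(lambda_weight = lambda_weight, frames = frames,
                 resolution = resolution, epochs = epochs, lr = lr,
                 batch_size = batch_size, channels = channels,
                 patience = patience, seed = as.integer(seed)),
            class = "asc_model_config")
}

# resample a video to the configured grid (bilinear space, uniform time)
conform_video <- function(video, config) {
  fr <- if (inherits(video, "echo_video")) video$frames else video
  d <- dim(fr)
  fidx <- round(seq(1, d[3], length.out = config$frames))
  out <- array(0, c(config$resolution, config$resolution, config$frames))
  for (k in seq_along(fidx)) {
    f <- fr[, , fidx[k]]
    out[, , k] <- if (d[1] == config$resolution && d[2] == config$resolution)
      f else resize_img(f, config$resolution, config$resolution)
  }
  out
}

#' Train the desk-scale continuum scorer
#'
#' A small (2+1)D convolutional network (factorised spatial/temporal blocks,
#' global average pooling) with a sigmoid continuum head and three linear
#' auxiliary heads (Vmax, mPG, AVA on the z-scored scale), trained with the
#' combined Bernoulli + lambda * MSE loss by Adam, early-stopped on the
#' validation combined loss.  Fully seeded: identical inputs give identical
#' loss trajectories.
#'
#' @param videos List of [echo_video] objects (or raw arrays).
#' @param labels Data frame with columns `stage` and (optionally) `vmax`,
#'   `mpg`, `ava`; `NA` auxiliary entries are masked out of their MSE terms.
#' @param config An [asc_model_config()].
#' @param val_idx Indices of the validation subset; default: every fifth
#'   sample per stage (deterministic stratified split).
#' @param return_best Return the weights of the best validation epoch
#'   (default) rather than the final epoch.
#' @return Object of class `asc_scorer` (weights, config, auxiliary
#'   normalisation, training history).
#' @export
train_continuum_model <- function(videos, labels, config = asc_model_config(),
                                  val_idx = NULL, return_best = TRUE) {
  stopifnot(inherits(config, "asc_model_config"))
  n <- length(videos)
  if (nrow(labels) != n) stop("labels must have one row per video")
  if (length(unique(labels$stage)) < 2)
    stop("training requires at least two severity classes")
  y <- ordinal_target(labels$stage)
  aux_raw <- cbind(vmax = labels$vmax %||% rep(NA_real_, n),
                   mpg = labels$mpg %||% rep(NA_real_, n),
                   ava = labels$ava %||% rep(NA_real_, n))
  if (is.null(val_idx)) {
    ord <- order(labels$stage, seq_len(n))
    val_idx <- ord[seq_along(ord) %% 5 == 0]
    if (!length(val_idx)) val_idx <- n
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  mask <- (!is.na(aux_raw)) * 1
  mu <- colMeans(aux_raw[tr_idx, , drop = FALSE], na.rm = TRUE)
  sdv <- apply(aux_raw[tr_idx, , drop = FALSE], 2, sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
  mu[!is.finite(mu)] <- 0
  aux <- sweep(sweep(aux_raw, 2, mu), 2, sdv, "/")
  aux[is.na(aux)] <- 0

  cubes <- lapply(videos, conform_video, config = config)
  params <- vnet_init(config$channels, config$frames, seed = config$seed)
  weights <- params[c("blocks", "wp", "bp", "Wa", "ba")]
  state <- adam_init(weights)
  history <- data.frame()
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      sched <- sample(tr_idx)
      tr_loss <- 0
      for (start in seq(1, length(sched), by = config$batch_size)) {
        bi <- sched[start:min(start + config$batch_size - 1, length(sched))]
        acc <- NULL
        for (i in bi) {
          g <- vnet_grad(params, cubes[[i]], y[i], aux[i, ], mask[i, ],
                         config$lambda_weight)
          acc <- grad_accumulate(acc, g$grads)
          tr_loss <- tr_loss + g$loss
        }
        upd <- adam_step(weights, grad_scale(acc, 1 / length(bi)), state,
                         config$lr)
        weights <- upd$params; state <- upd$state
        params[c("blocks", "wp", "bp", "Wa", "ba")] <- weights
      }
      val <- vapply(val_idx, function(i) {
        fw <- vnet_forward(params, cubes[[i]])
        loss_combined(fw$p, y[i], fw$aux, aux[i, ], mask[i, ],
                      config$lambda_weight)
      }, numeric(1))
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = tr_loss / length(tr_idx),
        val_loss = mean(val)))
      if (mean(val) < best$loss - 1e-6) {
        best <- list(loss = mean(val), weights = weights, epoch = ep)
      } else if (ep - best$epoch >= config$patience) break
    }
  })
  if (return_best) params[c("blocks", "wp", "bp", "Wa", "ba")] <- best$weights
  structure(list(params = params, config = config,
                 aux_norm = list(mean = mu, sd = sdv),
                 history = history, val_idx = val_idx),
            class = "asc_scorer")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.asc_scorer <- function(x, ...) {
  cat(sprintf(
    "asc_scorer: (2+1)D net [%s ch], %d frames @ %dpx, %d epochs (best val %.4f)\n",
    paste(x$config$channels, collapse = ","), x$config$frames,
    x$config$resolution, nrow(x$history), min(x$history$val_loss)))
  invisible(x)
}

#' Score one video on the AS continuum
#'
#' DLi-ASc = 100 x the continuum head probability, range 0-100.
#'
#' @param scorer A trained `asc_scorer`.
#' @param video An [echo_video] with view `"PLAX"` or `"PSAX"`.
#' @return Score in `[0, 100]`.
#' @export
score_video <- function(scorer, video) {
  stopifnot(inherits(scorer, "asc_scorer"))
  if (inherits(video, "echo_video") && !video$view %in% c("PLAX", "PSAX"))
    stop("unsupported view: ", video$view)
  fw <- vnet_forward(scorer$params, conform_video(video, scorer$config))
  100 * fw$p
}

#' Predicted auxiliary parameters for a video
#'
#' Auxiliary head outputs de-normalised to clinical units.
#'
#' @inheritParams score_video
#' @return Named numeric vector (vmax, mpg, ava).
#' @export
predict_aux <- function(scorer, video) {
  fw <- vnet_forward(scorer$params, conform_video(video, scorer$config))
  setNames(fw$aux * scorer$aux_norm$sd + scorer$aux_norm$mean,
           c("vmax", "mpg", "ava"))
}

#' Aggregate per-video scores into a patient score
#'
#' Scores are averaged within each view type; the final DLi-ASc is the mean
#' of the available view-type means (a single available view type is used
#' directly).
#'
#' @param scores Data frame with columns `view` and `score`.
#' @return Object of class `patient_score` with `per_video`,
#'   `per_view_mean` and `dli_asc`.
#' @export
aggregate_patient <- function(scores) {
  if (is.null(scores) || nrow(scores) == 0) stop("no scores to aggregate")
  if (any(scores$score < 0 | scores$score > 100))
    stop("scores must lie in [0, 100]")
  vm <- tapply(scores$score, scores$view, mean)
  structure(list(per_video = scores,
                 per_view_mean = as.list(vm),
                 dli_asc = mean(unlist(vm))), class = "patient_score")
}

#' @export
print.patient_score <- function(x, ...) {
  cat(sprintf("DLi-ASc %.1f (%s)\n", x$dli_asc,
              paste(sprintf("%s %.1f", names(x$per_view_mean),
                            unlist(x$per_view_mean)), collapse = ", ")))
  invisible(x)
}

#' Derive stage cutoffs from score distributions
#'
#' Each cutoff is the midpoint between the mean scores of consecutive
#' severity categories.
#'
#' @param scores Numeric patient-level DLi-ASc values.
#' @param stages Character true stages, same length.
#' @return Object of class `cutoff_set`: named numeric
#'   (sclerosis, mild, moderate, severe), strictly increasing.
#' @export
derive_cutoffs <- function(scores, stages) {
  missing <- setdiff(AS_STAGES, unique(stages))
  if (length(missing))
    stop("cannot derive cutoffs; absent categories: ",
         paste(missing, collapse = ", "))
  means <- tapply(scores, factor(stages, levels = AS_STAGES), mean)
  cuts <- (means[-1] + means[-5]) / 2
  cutoff_set(cuts[1], cuts[2], cuts[3], cuts[4])
}

#' Cutoff set
#'
#' Score thresholds for entering each stage.  `default_cutoffs()` ships the
#' clinically derived reference values 24.6 / 45.4 / 53.7 / 69.7.
#'
#' @param sclerosis,mild,moderate,severe Thresholds on the 0-100 scale,
#'   strictly increasing.
#' @return Object of class `cutoff_set`.
#' @export
cutoff_set <- function(sclerosis, mild, moderate, severe) {
  v <- c(sclerosis = unname(sclerosis), mild = unname(mild),
         moderate = unname(moderate), severe = unname(severe))
  if (any(diff(v) <= 0)) stop("cutoffs must be strictly increasing")
  structure(as.list(v), class = "cutoff_set")
}

#' @rdname cutoff_set
#' @export
default_cutoffs <- function() cutoff_set(24.6, 45.4, 53.7, 69.7)

#' Classify a score by cutoffs
#'
#' Returns the stage of the highest cutoff at or below the score (boundary
#' inclusive upward); scores under the sclerosis cutoff are normal.
#'
#' @param score DLi-ASc in `[0, 100]` (vectorised).
#' @param cutoffs A [cutoff_set()].
#' @return Character stage vector.
#' @export
classify_by_cutoffs <- function(score, cutoffs = default_cutoffs()) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  if (any(score < 0 | score > 100)) stop("score must lie in [0, 100]")
  cuts <- unlist(cutoffs)
  vapply(score, function(s) AS_STAGES[1 + sum(s >= cuts)], character(1))
}

#' Grad-CAM saliency for a video
#'
#' Gradient-weighted activation map of the last convolutional stage.  With a
#' global-average-pooled linear head the channel weights equal the head
#' gradient, so the map is `relu(sum_c w_c A_c)`, max-normalised and
#' upsampled to the frame grid.
#'
#' @inheritParams score_video
#' @return `H x W x T` array in `[0, 1]` on the model's input grid (all-zero
#'   when no channel activates positively).
#' @export
saliency_map <- function(scorer, video) {
  stopifnot(inherits(scorer, "asc_scorer"))
  cube <- conform_video(video, scorer$config)
  fw <- vnet_forward(scorer$params, cube)
  T <- scorer$config$frames
  C <- dim(fw$acts)[3] / T
  hw <- dim(fw$acts)[1]
  cam_small <- array(0, c(hw, hw, T))
  w <- as.numeric(scorer$params$wp)
  for (t in seq_len(T)) {
    acc <- matrix(0, hw, hw)
    for (c in seq_len(C)) acc <- acc + w[c] * fw$acts[, , (c - 1) * T + t]
    cam_small[, , t] <- pmax(acc, 0)
  }
  res <- scorer$config$resolution
  cam <- array(0, c(res, res, T))
  for (t in seq_len(T)) cam[, , t] <- resize_img(cam_small[, , t], res, res)
  cam[cam < 0] <- 0
  m <- max(cam)
  if (m > 0) cam <- cam / m
  cam
}

#' Penultimate features and 2-D embedding for a set of videos
#'
#' Extracts the global-average-pooled features (the scorer's penultimate
#' layer) for every video and projects them to 2-D with the neighbour
#' embedding of [neighbor_embedding()] (15 nearest neighbours, minimum
#' distance 0.1, Euclidean metric, seeded).
#'
#' @param scorer A trained `asc_scorer`.
#' @param videos List of [echo_video] objects (>= 16).
#' @param n_neighbors,min_dist,seed Embedding parameters.
#' @return List with `features` (n x C matrix) and `embedding` (n x 2).
#' @export
embed_features <- function(scorer, videos, n_neighbors = 15, min_dist = 0.1,
                           seed = 42L) {
  stopifnot(inherits(scorer, "asc_scorer"))
  if (length(videos) < 16) stop("need at least 16 videos to embed")
  if (length(videos) <= n_neighbors)
    stop("need more videos than neighbours (", n_neighbors, ")")
  feats <- t(vapply(videos, function(v)
    vnet_forward(scorer$params, conform_video(v, scorer$config))$features,
    numeric(utils::tail(scorer$config$channels, 1))))
  emb <- neighbor_embedding(feats, n_neighbors = n_neighbors,
                            min_dist = min_dist, seed = seed)
  list(features = feats, embedding = emb)
}
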