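# Desk-scale learned segmentation providers: one small fully-convolutional
# encoder-decoder class, trained on phantom (image, truth-mask) pairs, used
# for the Doppler envelope (2 classes) and PLAX anatomy (9 classes).

asc_segmenter <- function(params, classes, train_size, dropout_rate = 0.25) {
  structure(list(params = params, classes = classes, train_size = train_size,
                 dropout_rate = dropout_rate), class = "asc_segmenter")
}

#' @export
print.asc_segmenter <- function(x, ...) {
  cat(sprintf("asc_segmenter: %d classes, trained at %dx%d\n",
              length(x$classes), x$train_size[1], x$train_size[2]))
  invisible(x)
}

segnet_train <- function(samples, k_classes, steps, lr, batch, seed, hidden) {
  params <- segnet_init(k_classes, hidden = hidden, seed = seed)
  weights <- params[c("W1", "b1", "W2", "b2", "W3", "b3")]
  state <- adam_init(weights)
  with_seed(seed + 1L, {
    for (s in seq_len(steps)) {
      pick <- sample.int(length(samples), min(batch, length(samples)))
      acc <- NULL
      for (i in pick) {
        g <- segnet_grad(params, samples[[i]]$img, samples[[i]]$lab)
        acc <- grad_accumulate(acc, g$grads)
      }
      upd <- adam_step(weights, grad_scale(acc, 1 / length(pick)), state, lr)
      weights <- upd$params; state <- upd$state
      params[names(weights)] <- weights
    }
  })
  params
}

# resize an image (bilinear) or label map (nearest) to h x w
resize_img <- function(img, h, w) {
  EBImage::imageData(EBImage::resize(EBImage::Image(img), w = h, h = w))
}
resize_lab <- function(lab, h, w) {
  ri <- pmin(pmax(round(seq(1, nrow(lab), length.out = h)), 1), nrow(lab))
  ci <- pmin(pmax(round(seq(1, ncol(lab), length.out = w)), 1), ncol(lab))
  lab[ri, ci, drop = FALSE]
}

#' Train the Doppler envelope segmenter
#'
#' Trains the small encoder-decoder on phantom (spectrogram, truth-mask)
#' pairs rendered from `specs`, downsampled to `size` for training; at
#' prediction time inputs are resized to the trained scale and probabilities
#' resized back, so the provider is resolution-agnostic.
#'
#' @param specs List of [phantom_spec()] objects (training cohort).
#' @param size Training grid `c(rows, cols)` (even numbers).
#' @param steps Adam steps.
#' @param lr Learning rate.
#' @param seed Integer seed.
#' @return An `asc_segmenter` with classes `(background, envelope)`.
#' @export
train_doppler_segmenter <- function(specs, size = c(64, 128), steps = 250,
                                    lr = 5e-3, seed = 1L) {
  samples <- lapply(specs, function(sp) {
    rd <- render_doppler(sp)
    list(img = resize_img(rd$spectrum$intensity, size[1], size[2]),
         lab = matrix(as.integer(resize_lab(rd$truth_mask * 1L, size[1],
                                            size[2])), size[1], size[2]))
  })
  params <- segnet_train(samples, 2L, steps, lr, batch = 4L, seed = seed,
                         hidden = 12L)
  asc_segmenter(params, c("background", "envelope"), size)
}

#' Train the PLAX anatomy segmenter
#'
#' @param specs List of [phantom_spec()] objects.
#' @param resolution Training frame edge (even).
#' @param frames_per_spec Frames sampled per phantom.
#' @param steps Adam steps.
#' @param lr Learning rate.
#' @param seed Integer seed.
#' @return An `asc_segmenter` over the nine PLAX classes.
#' @export
train_plax_segmenter <- function(specs, resolution = 64, frames_per_spec = 3,
                                 steps = 300, lr = 5e-3, seed = 1L) {
  samples <- list()
  with_seed(seed + 2L, {
    for (sp in specs) {
      rv <- render_views(sp, resolution = resolution)
      fidx <- unique(c(rv$truth$peak_frame,
                       sample.int(dim(rv$plax$frames)[3],
                                  frames_per_spec - 1)))
      for (f in fidx)
        samples[[length(samples) + 1]] <-
          list(img = rv$plax$frames[, , f],
               lab = matrix(rv$truth$label_map_truth[, , f],
                            resolution, resolution))
    }
  })
  params <- segnet_train(samples, 9L, steps, lr, batch = 4L, seed = seed,
                         hidden = 16L)
  asc_segmenter(params, PLAX_CLASSES, c(resolution, resolution))
}

#' Predict per-pixel class probabilities
#'
#' @param model An `asc_segmenter`.
#' @param img Image matrix in `[0,1]` (any size; resized internally).
#' @param dropout `TRUE` for a stochastic Monte-Carlo dropout pass.
#' @return Array `H x W x K` of class probabilities on the input grid.
#' @export
predict_segmenter <- function(model, img, dropout = FALSE) {
  stopifnot(inherits(model, "asc_segmenter"))
  h <- nrow(img); w <- ncol(img)
  ts <- model$train_size
  scaled <- if (h == ts[1] && w == ts[2]) img else resize_img(img, ts[1], ts[2])
  mask <- NULL
  if (dropout) {
    keep <- stats::rbinom(model$params$hidden, 1, 1 - model$dropout_rate)
    mask <- keep / (1 - model$dropout_rate)
  }
  prob <- segnet_probs(model$params, scaled, mask)
  if (h == ts[1] && w == ts[2]) return(prob)
  out <- array(0, c(h, w, dim(prob)[3]))
  for (c in seq_len(dim(prob)[3])) out[, , c] <- resize_img(prob[, , c], h, w)
  # renormalize after interpolation
  s <- apply(out, c(1, 2), sum)
  for (c in seq_len(dim(out)[3])) out[, , c] <- out[, , c] / s
  out
}

#' Dice coefficient between two binary masks
#'
#' @param a,b Logical or 0/1 matrices.
#' @return Dice score in `[0,1]` (1 when both masks are empty).
#' @export
dice_score <- function(a, b) {
  a <- a > 0.5; b <- b > 0.5
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
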