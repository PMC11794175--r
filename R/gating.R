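# Predictive-entropy uncertainty quantification for segmentation outputs and
# the halt/proceed gate guarding automated measurements.

#' Mean predictive entropy of a probability map
#'
#' Mean over pixels of `-sum_c p_c log p_c` (nats).
#'
#' @param prob_map `H x W x K` array of per-pixel class probabilities
#'   (must sum to 1 per pixel, tolerance 1e-5).
#' @return Entropy in nats.
#' @export
predictive_entropy <- function(prob_map) {
  if (length(dim(prob_map)) != 3) stop("prob_map must be H x W x K")
  s <- apply(prob_map, c(1, 2), sum)
  if (max(abs(s - 1)) > 1e-5) stop("probabilities must sum to 1 per pixel")
  p <- pmax(prob_map, 1e-12)
  mean(apply(-p * log(p), c(1, 2), sum))
}

#' Decompose uncertainty over Monte-Carlo passes
#'
#' Given probability maps from stochastic forward passes (e.g. Monte-Carlo
#' dropout): aleatoric = mean over passes of the per-pass entropy;
#' epistemic = entropy of the mean map minus aleatoric (the mutual
#' information between prediction and parameters).
#'
#' @param prob_maps List of `H x W x K` probability arrays on the same grid.
#' @return List with `aleatoric`, `epistemic` and `predictive` entropies
#'   (nats, means over pixels).
#' @export
mc_decompose <- function(prob_maps) {
  if (!length(prob_maps)) stop("need at least one probability map")
  d <- dim(prob_maps[[1]])
  if (any(!vapply(prob_maps, function(m) identical(dim(m), d), logical(1))))
    stop("all probability maps must share the same shape")
  aleatoric <- mean(vapply(prob_maps, predictive_entropy, numeric(1)))
  mean_map <- Reduce(`+`, prob_maps) / length(prob_maps)
  predictive <- predictive_entropy(mean_map)
  list(aleatoric = aleatoric,
       epistemic = max(predictive - aleatoric, 0),
       predictive = predictive)
}

#' Uncertainty report
#'
#' @param predictive_entropy Total predictive entropy (nats).
#' @param aleatoric Aleatoric component (nats).
#' @param epistemic Epistemic component (nats).
#' @param gate `"proceed"` or `"halt"`.
#' @return Object of class `uncertainty_report`.
#' @export
uncertainty_report <- function(predictive_entropy, aleatoric = NA_real_,
                               epistemic = NA_real_, gate = "proceed") {
  if (!is.na(aleatoric) && !is.na(epistemic) &&
      abs(predictive_entropy - (aleatoric + epistemic)) > 1e-6)
    stop("predictive entropy must equal aleatoric + epistemic")
  structure(list(predictive_entropy = predictive_entropy,
                 aleatoric = aleatoric, epistemic = epistemic, gate = gate),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("uncertainty: predictive %.3f nats (aleatoric %.3f, epistemic %.3f) -> %s\n",
              x$predictive_entropy, x$aleatoric, x$epistemic, x$gate))
  invisible(x)
}

#' Gate configuration
#'
#' @param entropy_threshold Halt threshold in nats (> 0).
#' @param mc_samples Number of stochastic passes for the decomposition.
#' @return Object of class `gate_config`.
#' @export
gate_config <- function(entropy_threshold = 0.5, mc_samples = 8L) {
  if (entropy_threshold <= 0) stop("entropy_threshold must be > 0")
  if (mc_samples < 1) stop("mc_samples must be >= 1")
  structure(list(entropy_threshold = entropy_threshold,
                 mc_samples = as.integer(mc_samples)), class = "gate_config")
}

#' Halt or proceed with automated measurement
#'
#' Halts when the predictive entropy reaches the threshold (tie halts:
#' conservative rule).  Halted measurements propagate as unavailable, never
#' as numbers.
#'
#' @param report An [uncertainty_report()] (or a bare entropy value).
#' @param config A [gate_config()].
#' @return `"halt"` or `"proceed"`.
#' @export
gate_measurement <- function(report, config) {
  stopifnot(inherits(config, "gate_config"))
  h <- if (inherits(report, "uncertainty_report"))
    report$predictive_entropy else as.numeric(report)
  if (h >= config$entropy_threshold) "halt" else "proceed"
}

#' Calibrate the gate threshold on clean phantoms
#'
#' Sets the halt threshold at the given quantile (default 95th percentile)
#' of the predictive entropies the segmenter produces on noise-free
#' validation images, so clean studies almost always proceed.
#'
#' @param model An `asc_segmenter`.
#' @param images List of validation image matrices.
#' @param quantile_level Quantile of the entropy distribution (default 0.95).
#' @param config A [gate_config()] whose `mc_samples` is reused.
#' @param seed Seed for the dropout passes.
#' @return A [gate_config()] with the calibrated threshold.
#' @export
calibrate_gate_threshold <- function(model, images, quantile_level = 0.95,
                                     config = gate_config(), seed = 1L) {
  ent <- vapply(seq_along(images), function(i)
    assess_uncertainty(model, images[[i]], config, seed = seed + i)$predictive_entropy,
    numeric(1))
  gate_config(max(stats::quantile(ent, quantile_level), 1e-6) * 1.0,
              config$mc_samples)
}

#' Uncertainty report for a segmenter on an image
#'
#' Runs `mc_samples` Monte-Carlo dropout passes of the segmenter, decomposes
#' the uncertainty and applies the gate.
#'
#' @param model An `asc_segmenter`.
#' @param img Image matrix.
#' @param config A [gate_config()].
#' @param seed Seed for the dropout passes.
#' @return An [uncertainty_report()].
#' @export
assess_uncertainty <- function(model, img, config = gate_config(),
                               seed = 1L) {
  maps <- with_seed(seed, lapply(seq_len(config$mc_samples), function(i)
    predict_segmenter(model, img, dropout = TRUE)))
  dec <- mc_decompose(maps)
  rep <- uncertainty_report(dec$aleatoric + dec$epistemic, dec$aleatoric,
                            dec$epistemic, "proceed")
  rep$gate <- gate_measurement(rep, config)
  rep
}
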