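# 2-D nonlinear neighbour embedding of the UMAP family: fuzzy k-NN graph
# with locally adaptive bandwidths, spectral initialisation, then batch
# gradient descent on the attraction/repulsion cross-entropy with the
# standard (a, b) low-dimensional kernel fitted from min_dist.

# fit 1/(1 + a d^(2b)) to the target curve exp(-(d - min_dist)) for
# d > min_dist (1 below), as in the reference embedding
fit_ab <- function(min_dist, spread = 1) {
  d <- seq(0, 3 * spread, length.out = 300)
  target <- ifelse(d <= min_dist, 1, exp(-(d - min_dist) / spread))
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    sum((1 / (1 + a * d^(2 * b)) - target)^2)
  }
  p <- stats::optim(c(log(1.5), log(1)), obj)$par
  c(a = exp(p[1]), b = exp(p[2]))
}

# fuzzy simplicial weights for one point's k-NN distances
smooth_knn_weights <- function(dists, k) {
  rho <- min(dists[dists > 0], Inf)
  if (!is.finite(rho)) rho <- 0
  target <- log2(k)
  lo <- 1e-4; hi <- 1e3
  for (it in 1:50) {
    sigma <- (lo + hi) / 2
    val <- sum(exp(-pmax(dists - rho, 0) / sigma))
    if (abs(val - target) < 1e-5) break
    if (val > target) hi <- sigma else lo <- sigma
  }
  exp(-pmax(dists - rho, 0) / sigma)
}

#' 2-D neighbour embedding
#'
#' Projects feature vectors to 2-D preserving local neighbourhood structure:
#' a fuzzy 15-nearest-neighbour graph (Euclidean metric, locally adaptive
#' bandwidths), spectral initialisation, and gradient descent balancing
#' attraction along graph edges against repulsion from sampled non-edges.
#' `min_dist` sets how tightly neighbours pack in the plane.  Fully seeded.
#'
#' @param x Numeric matrix (rows = observations).
#' @param n_neighbors Neighbourhood size (default 15).
#' @param min_dist Minimum embedding distance (default 0.1).
#' @param n_epochs Gradient-descent epochs.
#' @param seed Integer seed.
#' @return n x 2 matrix of embedding coordinates.
#' @export
neighbor_embedding <- function(x, n_neighbors = 15, min_dist = 0.1,
                               n_epochs = 150, seed = 42L) {
  n <- nrow(x)
  if (n <= n_neighbors) stop("need more observations than neighbours")
  D <- as.matrix(stats::dist(x))
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(n_neighbors + 1)]
    P[i, nb] <- smooth_knn_weights(D[i, nb], n_neighbors)
  }
  P <- P + t(P) - P * t(P)       # fuzzy union
  ab <- fit_ab(min_dist)
  a <- ab["a"]; b <- ab["b"]

  # spectral initialisation from the symmetric normalised Laplacian
  deg <- pmax(rowSums(P), 1e-12)
  L <- diag(n) - diag(1 / sqrt(deg)) %*% P %*% diag(1 / sqrt(deg))
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  Y <- ev$vectors[, n - c(1, 2)]
  Y <- 10 * Y / max(abs(Y))

  edges <- which(P > 0 & upper.tri(P), arr.ind = TRUE)
  w <- P[edges]
  with_seed(seed, {
    for (ep in seq_len(n_epochs)) {
      alpha <- 1 * (1 - (ep - 1) / n_epochs)
      dy <- Y[edges[, 1], ] - Y[edges[, 2], ]
      d2 <- rowSums(dy^2)
      # attraction along edges
      ga <- (2 * a * b * d2^(b - 1)) / (1 + a * d2^b)
      ga <- pmin(ga, 4) * w
      push <- ga * dy
      G <- matrix(0, n, 2)
      G[, 1] <- -tapply2(push[, 1], edges[, 1], n) + tapply2(push[, 1], edges[, 2], n)
      G[, 2] <- -tapply2(push[, 2], edges[, 1], n) + tapply2(push[, 2], edges[, 2], n)
      # repulsion from sampled non-neighbours (5 per edge endpoint)
      neg <- sample.int(n, length(w) * 5, replace = TRUE)
      src <- rep(edges[, 1], 5)
      dyn <- Y[src, ] - Y[neg, ]
      d2n <- pmax(rowSums(dyn^2), 1e-3)
      gr <- (2 * b) / ((0.001 + d2n) * (1 + a * d2n^b))
      gr <- pmin(gr, 4)
      pull <- gr * dyn
      G[, 1] <- G[, 1] + tapply2(pull[, 1], src, n) - tapply2(pull[, 1], neg, n)
      G[, 2] <- G[, 2] + tapply2(pull[, 2], src, n) - tapply2(pull[, 2], neg, n)
      Y <- Y + alpha * 0.05 * G
    }
  })
  colnames(Y) <- c("dim1", "dim2")
  Y
}

# fast grouped sum into a length-n vector
tapply2 <- function(v, idx, n) {
  out <- numeric(n)
  s <- rowsum(v, idx)
  out[as.integer(rownames(s))] <- s
  out
}
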