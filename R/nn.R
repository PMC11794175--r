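# Internal training engine shared by the video scorer and the segmentation
# networks.  Parameters and gradients are nested lists of numeric arrays;
# Adam walks the structure recursively.  All convolutions run in C++
# (src/nn.cpp); frame stacks are H x W x (C*T) arrays, slice c*T + t.

nested_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(x) nested_map(f, x)))
  f(a)
}
nested_map2 <- function(f, a, b) {
  if (is.list(a)) return(Map(function(x, y) nested_map2(f, x, y), a, b))
  f(a, b)
}

adam_init <- function(params) {
  list(m = nested_map(function(x) x * 0, params),
       v = nested_map(function(x) x * 0, params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nested_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                         state$m, grads)
  state$v <- nested_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                         state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  upd <- nested_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                     state$m, state$v)
  list(params = nested_map2(`-`, params, upd), state = state)
}

grad_accumulate <- function(acc, g) {
  if (is.null(acc)) return(g)
  nested_map2(`+`, acc, g)
}
grad_scale <- function(g, s) nested_map(function(x) x * s, g)

he_mat <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)),
                                          nr, nc)

relu <- function(x) { x[x < 0] <- 0; x }

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- (2+1)D video network --------------------------------------------------

# 4 factorized blocks: spatial 3x3 stride-2 conv then temporal 3-tap conv,
# ReLU after each; global average pooling; sigmoid continuum head + 3 linear
# auxiliary heads.
vnet_init <- function(channels = c(8, 16, 24, 32), n_frames = 16, seed = 1L) {
  with_seed(seed, {
    cin <- 1
    blocks <- lapply(channels, function(co) {
      b <- list(Ws = he_mat(9 * cin, co, 9 * cin), bs = numeric(co),
                Wt = he_mat(co, 3 * co, 3 * co), bt = numeric(co))
      cin <<- co
      b
    })
    cf <- channels[length(channels)]
    list(blocks = blocks,
         wp = matrix(rnorm(cf, sd = 1 / sqrt(cf)), cf, 1), bp = 0,
         Wa = he_mat(3, cf, cf), ba = numeric(3),
         channels = channels, n_frames = n_frames)
  })
}

# channel-wise global average pooling of an H x W x (C*T) cube
gap_features <- function(x, T) {
  C <- dim(x)[3] / T
  vapply(seq_len(C), function(c) mean(x[, , ((c - 1) * T + 1):(c * T)]),
         numeric(1))
}

vnet_forward <- function(params, video) {
  fw <- vnet_forward_cpp(video, params$blocks, params$wp, params$bp,
                         params$Wa, params$ba, params$n_frames)
  fw$aux <- as.numeric(fw$aux)
  fw$features <- as.numeric(fw$features)
  fw
}

vnet_grad <- function(params, video, y, aux_t, aux_mask, lambda) {
  g <- vnet_grad_cpp(video, params$blocks, params$wp, params$bp, params$Wa,
                     params$ba, params$n_frames, y, aux_t, aux_mask, lambda)
  g$aux <- as.numeric(g$aux)
  for (bi in seq_along(g$grads$blocks)) {
    g$grads$blocks[[bi]]$bs <- as.numeric(g$grads$blocks[[bi]]$bs)
    g$grads$blocks[[bi]]$bt <- as.numeric(g$grads$blocks[[bi]]$bt)
  }
  g$grads$ba <- as.numeric(g$grads$ba)
  g$grads$bp <- as.numeric(g$grads$bp)
  g
}

# reference implementation (layer-by-layer in R); kept as the independent
# oracle for gradient checks
vnet_forward_r <- function(params, video, keep = FALSE) {
  T <- params$n_frames
  x <- video - 0.5
  cache <- list()
  for (b in params$blocks) {
    s <- sconv_fwd(x, b$Ws, b$bs, T, 2L)
    sr <- relu(s)
    t <- tconv_fwd(sr, b$Wt, b$bt, T)
    tr <- relu(t)
    if (keep) cache[[length(cache) + 1]] <- list(x = x, s = s, sr = sr, t = t)
    x <- tr
  }
  f <- gap_features(x, T)
  logit <- sum(params$wp * f) + params$bp
  list(p = sigmoid(logit), aux = as.numeric(params$Wa %*% f + params$ba),
       features = f, acts = x, cache = cache)
}

# loss and gradients for one video; y in [0,1]; aux_t normalized targets,
# aux_mask in {0,1}^3; lambda weights the auxiliary MSE terms
vnet_grad_r <- function(params, video, y, aux_t, aux_mask, lambda) {
  T <- params$n_frames
  fw <- vnet_forward_r(params, video, keep = TRUE)
  p <- min(max(fw$p, 1e-7), 1 - 1e-7)
  res <- (fw$aux - aux_t) * aux_mask
  loss <- -(y * log(p) + (1 - y) * log(1 - p)) + lambda * sum(res^2)
  dlogit <- fw$p - y
  daux <- 2 * lambda * res
  df <- as.numeric(params$wp) * dlogit + as.numeric(t(params$Wa) %*% daux)
  g <- list(blocks = vector("list", length(params$blocks)),
            wp = matrix(fw$features * dlogit), bp = dlogit,
            Wa = outer(daux, fw$features), ba = daux)
  # spread GAP gradient over activations
  x <- fw$acts
  C <- dim(x)[3] / T
  dx <- array(0, dim(x))
  hw <- dim(x)[1] * dim(x)[2]
  for (c in seq_len(C))
    dx[, , ((c - 1) * T + 1):(c * T)] <- df[c] / (hw * T)
  for (bi in rev(seq_along(params$blocks))) {
    b <- params$blocks[[bi]]
    cc <- fw$cache[[bi]]
    dx[cc$t < 0] <- 0
    tb <- tconv_bwd(cc$sr, b$Wt, dx, T)
    ds <- tb$dx
    ds[cc$s < 0] <- 0
    sb <- sconv_bwd(cc$x, b$Ws, ds, T, 2L)
    g$blocks[[bi]] <- list(Ws = sb$dW, bs = as.numeric(sb$db),
                           Wt = tb$dW, bt = as.numeric(tb$db))
    dx <- sb$dx
  }
  list(loss = loss, bernoulli = -(y * log(p) + (1 - y) * log(1 - p)),
       grads = g[c("blocks", "wp", "bp", "Wa", "ba")], p = fw$p,
       aux = fw$aux)
}

# ---- small fully-convolutional segmenter -----------------------------------

# encoder-decoder: 3x3 stride-2 conv -> 3x3 conv (dropout site) -> 2x nearest
# upsample -> 3x3 conv to K class logits; inputs are intensity + normalized
# x/y coordinate channels.
segnet_init <- function(k_classes, hidden = 12, seed = 1L) {
  with_seed(seed, list(
    W1 = he_mat(9 * 3, hidden, 27), b1 = numeric(hidden),
    W2 = he_mat(9 * hidden, hidden, 9 * hidden), b2 = numeric(hidden),
    W3 = he_mat(9 * hidden, k_classes, 9 * hidden), b3 = numeric(k_classes),
    hidden = hidden, k = k_classes))
}

segnet_input <- function(img) {
  h <- nrow(img); w <- ncol(img)
  xg <- matrix(seq_len(w) / w - 0.5, h, w, byrow = TRUE)
  yg <- matrix(seq_len(h) / h - 0.5, h, w)
  x <- array(0, c(h, w, 3))
  x[, , 1] <- img - 0.5; x[, , 2] <- xg; x[, , 3] <- yg
  x
}

segnet_forward <- function(params, img, dropout_mask = NULL, keep = FALSE) {
  x <- segnet_input(img)
  s1 <- sconv_fwd(x, params$W1, params$b1, 1L, 2L); h1 <- relu(s1)
  s2 <- sconv_fwd(h1, params$W2, params$b2, 1L, 1L); h2 <- relu(s2)
  if (!is.null(dropout_mask))
    for (c in seq_len(dim(h2)[3])) h2[, , c] <- h2[, , c] * dropout_mask[c]
  u <- upsample2_fwd(h2)
  logits <- sconv_fwd(u, params$W3, params$b3, 1L, 1L)
  out <- list(logits = logits)
  if (keep) out <- c(out, list(x = x, s1 = s1, h1 = h1, s2 = s2, h2 = h2,
                               u = u, dropout_mask = dropout_mask))
  out
}

# pixel-wise softmax over slices of an H x W x K logits cube
softmax_cube <- function(logits) {
  k <- dim(logits)[3]
  mx <- apply(logits, c(1, 2), max)
  e <- array(0, dim(logits))
  for (c in seq_len(k)) e[, , c] <- exp(logits[, , c] - mx)
  s <- apply(e, c(1, 2), sum)
  for (c in seq_len(k)) e[, , c] <- e[, , c] / s
  e
}

# mean pixel cross-entropy loss + gradients; labels are 0-based class ints
segnet_grad <- function(params, img, labels, dropout_mask = NULL) {
  fw <- segnet_forward(params, img, dropout_mask, keep = TRUE)
  prob <- softmax_cube(fw$logits)
  n <- length(labels)
  k <- params$k
  onehot <- array(0, dim(prob))
  idx <- cbind(c(row(labels)), c(col(labels)), c(labels) + 1L)
  onehot[idx] <- 1
  pick <- pmax(prob[idx], 1e-12)
  loss <- -mean(log(pick))
  dlogits <- (prob - onehot) / n
  b3 <- sconv_bwd(fw$u, params$W3, dlogits, 1L, 1L)
  dh2 <- upsample2_bwd(b3$dx)
  if (!is.null(fw$dropout_mask))
    for (c in seq_len(dim(dh2)[3])) dh2[, , c] <- dh2[, , c] * fw$dropout_mask[c]
  dh2[fw$s2 < 0] <- 0
  b2 <- sconv_bwd(fw$h1, params$W2, dh2, 1L, 1L)
  dh1 <- b2$dx
  dh1[fw$s1 < 0] <- 0
  b1 <- sconv_bwd(fw$x, params$W1, dh1, 1L, 2L)
  list(loss = loss,
       grads = list(W1 = b1$dW, b1 = as.numeric(b1$db),
                    W2 = b2$dW, b2 = as.numeric(b2$db),
                    W3 = b3$dW, b3 = as.numeric(b3$db)))
}

# pad an image to even dimensions (replicating edges), run the net, crop back
segnet_probs <- function(params, img, dropout_mask = NULL) {
  h <- nrow(img); w <- ncol(img)
  hp <- h + h %% 2; wp <- w + w %% 2
  if (hp != h || wp != w) {
    pad <- matrix(0, hp, wp)
    pad[1:h, 1:w] <- img
    if (hp != h) pad[hp, 1:w] <- img[h, ]
    if (wp != w) pad[1:h, wp] <- img[, w]
    img <- pad
  }
  prob <- softmax_cube(segnet_forward(params, img, dropout_mask)$logits)
  prob[1:h, 1:w, , drop = FALSE]
}
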