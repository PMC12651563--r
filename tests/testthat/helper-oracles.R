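# Independent brute-force oracles used across the block/attention tests.
# These deliberately share no code with the package's compute kernels.

# Direct 2-D convolution with same padding, stride and dilation, computed
# by explicit summation.  x: (H, W, Cin, N); w: (kh, kw, Cin, Cout).
brute_conv <- function(x, w, b = NULL, stride = 1L, dil = 1L) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  if (is.null(b)) b <- numeric(Cout)
  Ho <- as.integer(ceiling(H / stride)); Wo <- as.integer(ceiling(W / stride))
  pt <- max(0L, (Ho - 1L) * stride + (kh - 1L) * dil + 1L - H) %/% 2L
  pl <- max(0L, (Wo - 1L) * stride + (kw - 1L) * dil + 1L - W) %/% 2L
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- b[co]
    for (ci in 1:Cin) for (ih in 1:kh) for (iw in 1:kw) {
      hi <- (ho - 1L) * stride - pt + (ih - 1L) * dil + 1L
      wi <- (wo - 1L) * stride - pl + (iw - 1L) * dil + 1L
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[hi, wi, ci, n] * w[ih, iw, ci, co]
    }
    y[ho, wo, co, n] <- acc
  }
  y
}

# Explicit channel-attention oracle: pooling by apply(), matrix products,
# sigmoid -- mirrors the definition, not the implementation.
brute_channel_weights <- function(f, w1, b1, w2, b2) {
  d <- dim(f)
  out <- matrix(0, d[3], d[4])
  for (n in seq_len(d[4])) {
    avg <- apply(f[, , , n, drop = FALSE], 3, mean)
    mx <- apply(f[, , , n, drop = FALSE], 3, max)
    mlp <- function(p) w2 %*% pmax(w1 %*% p + b1, 0) + b2
    out[, n] <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
  }
  out
}

# Connected components of a binary matrix (8-neighbourhood flood fill).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  nbrs <- expand.grid(dr = -1:1, dc = -1:1)
  nbrs <- nbrs[!(nbrs$dr == 0 & nbrs$dc == 0), ]
  for (start in which(mask == 1)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1L) %% h + 1L; cc <- (p - 1L) %/% h + 1L
      for (k in seq_len(nrow(nbrs))) {
        rr <- r + nbrs$dr[k]; ccc <- cc + nbrs$dc[k]
        if (rr >= 1 && rr <= h && ccc >= 1 && ccc <= w) {
          q <- rr + h * (ccc - 1L)
          if (mask[q] == 1 && lab[q] == 0L) {
            lab[q] <- nxt
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# Random binary mask pair of a given size.
random_masks <- function(n = 6L, p = 0.4) {
  list(a = matrix(rbinom(n * n, 1, p), n, n),
       b = matrix(rbinom(n * n, 1, p), n, n))
}
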