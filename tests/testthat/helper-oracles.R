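# Scalar brute-force oracles, written independently of the implementation
# paths they check: explicit loops, no shared convolution or resize code.

# same-size cross-correlation with a 3x3 kernel, replicate padding
oracle_conv3x3 <- function(grid, K) {
  h <- nrow(grid); w <- ncol(grid)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      s <- 0
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- min(max(r + dr, 1), h)
          cc <- min(max(c + dc, 1), w)
          s <- s + K[dr + 2, dc + 2] * grid[rr, cc]
        }
      }
      out[r, c] <- s
    }
  }
  out
}

oracle_mse <- function(a, b) {
  s <- 0
  for (r in seq_len(nrow(a)))
    for (c in seq_len(ncol(a)))
      s <- s + (a[r, c] - b[r, c])^2
  s / (nrow(a) * ncol(a))
}

oracle_edge_loss <- function(output, lum, K) {
  oracle_mse(oracle_conv3x3(output, K), oracle_conv3x3(lum, K))
}

# bilinear value at a single 0-based output pixel under half-pixel centers
oracle_bilinear_at <- function(v, m, i, j) {
  h <- nrow(v); w <- ncol(v)
  sr <- min(max((i + 0.5) / m - 0.5, 0), h - 1)
  sc <- min(max((j + 0.5) / m - 0.5, 0), w - 1)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  r1 <- min(r0 + 1, h - 1); c1 <- min(c0 + 1, w - 1)
  (1 - fr) * (1 - fc) * v[r0 + 1, c0 + 1] +
    fr * (1 - fc) * v[r1 + 1, c0 + 1] +
    (1 - fr) * fc * v[r0 + 1, c1 + 1] +
    fr * fc * v[r1 + 1, c1 + 1]
}

oracle_block_mean <- function(v, m) {
  h <- nrow(v) / m; w <- ncol(v) / m
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      s <- 0
      for (a in seq_len(m))
        for (b in seq_len(m))
          s <- s + v[(r - 1) * m + a, (c - 1) * m + b]
      out[r, c] <- s / m^2
    }
  }
  out
}

# hand simulation of the cumulative "total counts of loss increase" rule
oracle_early_stop <- function(values, patience) {
  best <- Inf; counter <- 0L; halt_at <- NA_integer_
  best_index <- NA_integer_
  for (i in seq_along(values)) {
    if (values[i] < best) {
      best <- values[i]
      best_index <- i
    } else {
      counter <- counter + 1L
    }
    if (counter >= patience) {
      halt_at <- i
      break
    }
  }
  list(halt_at = halt_at, counter = counter, best = best,
       best_index = best_index)
}

oracle_luminance <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  out <- matrix(0, h, w)
  for (r in seq_len(h))
    for (c in seq_len(w))
      out[r, c] <- 0.299 * img[r, c, 1] + 0.587 * img[r, c, 2] +
        0.114 * img[r, c, 3]
  out
}

# closed-form parameter count of the residual network from the declared
# channel plan (3x3 main convs, 1x1 skips, one bias per output channel)
oracle_residual_param_count <- function(channels = c(3, 64, 32, 1)) {
  n <- 3 * 3 * channels[1] * channels[2] + channels[2]  # init block
  for (i in 2:(length(channels) - 1)) {
    cin <- channels[i]; cout <- channels[i + 1]
    n <- n + 3 * 3 * cin * cout + cout   # convA
    n <- n + 3 * 3 * cout * cout + cout  # convB
    n <- n + 1 * 1 * cin * cout + cout   # 1x1 skip
  }
  n
}

oracle_plain_param_count <- function(channels = c(3, 64, 32, 1)) {
  n <- 0
  for (i in seq_len(length(channels) - 1))
    n <- n + 3 * 3 * channels[i] * channels[i + 1] + channels[i + 1]
  n
}
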