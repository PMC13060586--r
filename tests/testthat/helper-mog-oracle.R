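# Brute-force straight-line reference implementation of the per-pixel
# mixture-of-Gaussians update equations.  Written independently of the
# compiled code and kept deliberately naive (explicit loops, one pixel at
# a time); the package implementation must agree with it bit-for-bit in
# float64.

mog_oracle_pixel <- function(x, w, mu, v, p) {
  K <- p$n_components
  # stable insertion sort of component indices by weight, descending
  ord <- seq_len(K)
  for (i in seq_len(K)[-1]) {
    key <- ord[i]
    j <- i - 1
    while (j >= 1 && w[ord[j]] < w[key]) {
      ord[j + 1] <- ord[j]
      j <- j - 1
    }
    ord[j + 1] <- key
  }
  # background set: shortest top-weight prefix covering T
  cum <- 0
  nB <- 0
  for (i in seq_len(K)) {
    cum <- cum + w[ord[i]]
    nB <- nB + 1
    if (cum >= p$background_threshold) break
  }
  # decision on the pre-update state
  fg <- TRUE
  for (i in seq_len(nB)) {
    k <- ord[i]
    if (abs(x - mu[k]) <= p$match_sd * sqrt(v[k])) {
      fg <- FALSE
      break
    }
  }
  # first matching component over all K, in sorted order
  m <- -1L
  for (i in seq_len(K)) {
    k <- ord[i]
    if (abs(x - mu[k]) <= p$match_sd * sqrt(v[k])) {
      m <- k
      break
    }
  }
  if (m > 0) {
    for (k in seq_len(K)) w[k] <- (1 - p$learning_rate) * w[k]
    w[m] <- w[m] + p$learning_rate
    d <- x - mu[m]
    mu[m] <- mu[m] + p$learning_rate * d
    d2 <- x - mu[m]
    v[m] <- (1 - p$learning_rate) * v[m] + p$learning_rate * (d2 * d2)
    if (v[m] < p$var_floor) v[m] <- p$var_floor
  } else {
    k0 <- ord[K]
    mu[k0] <- x
    v[k0] <- p$init_var
    w[k0] <- p$new_weight
    s <- w[1]
    for (k in seq_len(K)[-1]) s <- s + w[k]
    for (k in seq_len(K)) w[k] <- w[k] / s
  }
  list(fg = fg, w = w, mu = mu, v = v)
}

mog_oracle_run <- function(frames, p) {
  H <- dim(frames)[1]
  W <- dim(frames)[2]
  Tn <- dim(frames)[3]
  K <- p$n_components
  w <- array(0, c(H, W, K))
  mu <- array(0, c(H, W, K))
  v <- array(p$init_var, c(H, W, K))
  w[, , 1] <- 1
  mu[, , 1] <- frames[, , 1]
  masks <- array(FALSE, c(H, W, Tn))
  for (t in seq_len(Tn)) {
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        res <- mog_oracle_pixel(frames[i, j, t], w[i, j, ], mu[i, j, ],
                                v[i, j, ], p)
        masks[i, j, t] <- res$fg
        w[i, j, ] <- res$w
        mu[i, j, ] <- res$mu
        v[i, j, ] <- res$v
      }
    }
  }
  list(masks = masks, w = w, mu = mu, v = v)
}

# a small noisy crop with a jumping dark disk, shared by the oracle tests
oracle_fixture_frames <- function(H = 20, W = 20, Tn = 40, seed = 5) {
  set.seed(seed)
  frames <- array(150 + round(rnorm(H * W * Tn, 0, 4)), c(H, W, Tn))
  for (t in seq_len(Tn)) {
    r <- 5 + (t %% 10)
    frames[r:(r + 2), 8:10, t] <- 40
  }
  frames
}
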