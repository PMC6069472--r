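# Independent brute-force oracles and tiny fixture builders.
# Everything here is deliberately naive (loops, per-definition formulas) so
# that agreement with the package implementations is meaningful.

# --- fixtures -----------------------------------------------------------

# a frame with all 68 points at a single location
constant_frame <- function(x = 0, y = 0) {
  landmark_frame(matrix(c(x, y), 68, 2, byrow = TRUE))
}

# template frame with selected points overridden: idx -> c(x, y)
toy_frame <- function(overrides = list()) {
  pts <- template_face()
  for (nm in names(overrides)) pts[as.integer(nm), ] <- overrides[[nm]]
  landmark_frame(pts)
}

# short sequence of jittered template frames
toy_sequence <- function(n = 6, fs = 30, seed = 1) {
  set.seed(seed)
  frames <- lapply(seq_len(n), function(i) {
    template_face() + matrix(rnorm(136, sd = 0.5), 68, 2)
  })
  landmark_sequence(frames, fs = fs)
}

# --- LBP-TOP oracle -----------------------------------------------------

naive_uniform_bin <- function(code) {
  bits <- as.integer(intToBits(code)[1:8])
  trans <- sum(bits != c(bits[-1], bits[1]))
  uniform_codes <- Filter(function(k) {
    b <- as.integer(intToBits(k)[1:8])
    sum(b != c(b[-1], b[1])) <= 2
  }, 0:255)
  if (trans <= 2) match(code, uniform_codes) else 59L
}

# LBP code of pixel (i, j) of a matrix, neighbour order CCW from the
# positive column direction, bit set when neighbour >= centre
naive_lbp_code <- function(m, i, j) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  code <- 0L
  for (k in seq_along(offs)) {
    nb <- m[i + offs[[k]][1], j + offs[[k]][2]]
    if (nb >= m[i, j]) code <- code + 2L^(k - 1L)
  }
  code
}

naive_plane_hist <- function(slices) {
  h <- numeric(59)
  for (m in slices) {
    if (nrow(m) < 3 || ncol(m) < 3) next
    for (i in 2:(nrow(m) - 1)) {
      for (j in 2:(ncol(m) - 1)) {
        b <- naive_uniform_bin(naive_lbp_code(m, i, j))
        h[b] <- h[b] + 1
      }
    }
  }
  h
}

naive_lbp_top <- function(vol, normalize = FALSE) {
  d <- dim(vol)
  xy <- naive_plane_hist(lapply(seq_len(d[3]), function(t) vol[, , t]))
  xt <- naive_plane_hist(lapply(seq_len(d[1]), function(y) vol[y, , ]))
  yt <- naive_plane_hist(lapply(seq_len(d[2]), function(x) vol[, x, ]))
  if (normalize) {
    l1 <- function(h) if (sum(h) > 0) h / sum(h) else h
    xy <- l1(xy); xt <- l1(xt); yt <- l1(yt)
  }
  c(xy, xt, yt)
}

# --- Sobel oracle -------------------------------------------------------

naive_sobel_mean <- function(m) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dx (columns)
  ky <- t(kx)                                                 # d/dy (rows)
  r <- nrow(m); c <- ncol(m)
  clamp <- function(v, hi) pmin(pmax(v, 1), hi)
  total <- 0
  for (i in 1:r) {
    for (j in 1:c) {
      gx <- 0; gy <- 0
      for (a in -1:1) {
        for (b in -1:1) {
          px <- m[clamp(i + a, r), clamp(j + b, c)]
          gx <- gx + kx[a + 2, b + 2] * px
          gy <- gy + ky[a + 2, b + 2] * px
        }
      }
      total <- total + sqrt(gx^2 + gy^2)
    }
  }
  total / (r * c)
}

# --- descriptor oracle --------------------------------------------------

naive_quantile <- function(x, p) {
  xs <- sort(x); n <- length(xs)
  h <- (n - 1) * p
  lo <- floor(h)
  xs[lo + 1] + (h - lo) * (xs[min(lo + 2, n)] - xs[lo + 1])
}

naive_describe <- function(x, fs) {
  n <- length(x)
  med <- naive_quantile(x, 0.5)
  mu <- sum(x) / n
  mn <- min(x); mx <- max(x)
  count_runs <- function(keep) {
    runs <- 0
    prev <- FALSE
    for (k in keep) {
      if (k && !prev) runs <- runs + 1
      prev <- k
    }
    runs
  }
  area <- sum(x - mn) / fs
  c(max = mx, min = mn, mean = mu, median = med,
    range = mx - mn,
    sd = if (n > 1) sqrt(sum((x - mu)^2) / (n - 1)) else 0,
    iqr = naive_quantile(x, 0.75) - naive_quantile(x, 0.25),
    idr = naive_quantile(x, 0.9) - naive_quantile(x, 0.1),
    mad = naive_quantile(abs(x - med), 0.5),
    t_peak = (which(x == mx)[1] - 1) / fs,
    dur_mean = sum(x > mu) / fs,
    dur_mid = sum(x > (mu + mn) / 2) / fs,
    seg_mean = count_runs(x > mu),
    seg_mid = count_runs(x > (mu + mn) / 2),
    area = area,
    area_quot = if (mx > mn) area / (mx - mn) else 0)
}

# --- voting and AUC oracles ---------------------------------------------

naive_majority <- function(votes, confs) {
  counts <- sapply(unique(votes), function(v) sum(votes == v))
  winners <- names(counts)[counts > length(votes) / 2]
  if (length(winners) == 1) winners else votes[which.max(confs)]
}

naive_auc <- function(scores, labels) {
  pos <- which(labels == "pain"); neg <- which(labels != "pain")
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}

# --- SLPP oracle pieces -------------------------------------------------

# naive supervised adjacency + Laplacian matrices from pre-projected data
naive_slpp_system <- function(U, y, k, t_) {
  n <- nrow(U)
  D2 <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D2[i, j] <- sum((U[i, ] - U[j, ])^2)
  W <- matrix(0, n, n)
  for (i in 1:n) {
    nn <- order(D2[i, -i])  # indices into the vector without i
    others <- (1:n)[-i]
    for (j in others[nn[seq_len(min(k, n - 1))]]) {
      W[i, j] <- exp(-D2[i, j] / t_)
    }
  }
  W <- pmax(W, t(W))
  for (i in 1:n) for (j in 1:n) if (y[i] != y[j]) W[i, j] <- 0
  diag(W) <- 0
  dvec <- rowSums(W)
  list(A = t(U) %*% (diag(dvec) - W) %*% U, B = t(U) %*% (dvec * U),
       W = W)
}
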