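# Brute-force binary erosion oracle: pixelwise neighbourhood test, applied
# sequentially with the same structuring-element sequence as the
# implementation under test. Deliberately naive (double loop).
brute_force_erode <- function(mask, iterations, connectivity = "alternating") {
  offsets <- function(conn) {
    if (conn == 4) {
      list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1), c(0, 0))
    } else {
      out <- list()
      for (dr in -1:1) for (dc in -1:1) out[[length(out) + 1]] <- c(dr, dc)
      out
    }
  }
  out <- mask
  for (k in seq_len(iterations)) {
    conn <- switch(connectivity,
      alternating = if (k %% 2 == 1) 4 else 8,
      four = 4,
      eight = 8
    )
    offs <- offsets(conn)
    prev <- out
    for (i in seq_len(nrow(prev))) {
      for (j in seq_len(ncol(prev))) {
        keep <- TRUE
        for (off in offs) {
          r <- i + off[1]
          c <- j + off[2]
          inside <- r >= 1 && r <= nrow(prev) && c >= 1 && c <= ncol(prev)
          if (!inside || !prev[r, c]) {
            keep <- FALSE
            break
          }
        }
        out[i, j] <- keep
      }
    }
  }
  out
}

# Random blob-ish binary mask: thresholded sum of a few random discs.
random_mask <- function(n = 32, n_discs = 3) {
  m <- matrix(FALSE, n, n)
  for (k in seq_len(n_discs)) {
    cr <- runif(1, 4, n - 3)
    cc <- runif(1, 4, n - 3)
    rad <- runif(1, 3, n / 3)
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    m <- m | ((rows - cr)^2 + (cols - cc)^2 <= rad^2)
  }
  m
}

# Analytic derivative maximum of the power logistic (p > 1):
# at u* = ((p-1)/(p+1))^(1/p), t* = x0 u*.
power_kmax_analytic <- function(a1, a2, x0, p) {
  stopifnot(p > 1)
  u <- ((p - 1) / (p + 1))^(1 / p)
  t_star <- x0 * u
  k <- (a2 - a1) * p * u^p / (t_star * (1 + u^p)^2)
  c(k_max = k, t_at_kmax = t_star)
}

# Small noiseless imaging setup shared by several tests.
noiseless_spec <- function() {
  imaging_noise(background_level = 0, read_noise_sd = 0, shot_noise = FALSE)
}
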