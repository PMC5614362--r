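# Brute-force dense oracles, deliberately independent of the package's
# separable/C++ implementations: direct summation with explicit index
# arithmetic. Only usable on small grids.

reflect_i <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# dense 3D convolution with a separable Gaussian kernel, reflect boundary
brute_gauss3 <- function(x, sigma, order = c(0, 0, 0)) {
  r <- max(1L, ceiling(4 * sigma))
  off <- (-r):r
  g <- exp(-off^2 / (2 * sigma^2))
  g <- g / sum(g)
  k1 <- function(ord) switch(as.character(ord),
    "0" = g, "1" = -off / sigma^2 * g,
    "2" = {
      k <- (off^2 / sigma^4 - 1 / sigma^2) * g
      k - sum(k) / length(k) # zero-sum sampled second derivative
    })
  kz <- k1(order[1]); ky <- k1(order[2]); kx <- k1(order[3])
  d <- dim(x)
  out <- array(0, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (xx in 1:d[3]) {
    acc <- 0
    for (a in seq_along(off)) for (b in seq_along(off)) {
      zz <- reflect_i(z + off[a], d[1])
      yy <- reflect_i(y + off[b], d[2])
      row <- 0
      for (cc in seq_along(off))
        row <- row + kx[cc] * x[zz, yy, reflect_i(xx + off[cc], d[3])]
      acc <- acc + kz[a] * ky[b] * row
    }
    out[z, y, xx] <- acc
  }
  out
}

# brute-force ball dilation by explicit offset enumeration
brute_dilate <- function(mask, radius) {
  d <- dim(mask)
  r <- ceiling(radius)
  out <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  off <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  off <- off[off$dz^2 + off$dy^2 + off$dx^2 <= radius^2 + 1e-9, ]
  for (i in seq_len(nrow(idx))) {
    z <- idx[i, 1] + off$dz; y <- idx[i, 2] + off$dy; x <- idx[i, 3] + off$dx
    ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    out[cbind(z[ok], y[ok], x[ok])] <- TRUE
  }
  out
}

# a small annotated two-phase workspace used by several training tests
two_phase_workspace <- function(size = 32, seed = 5, noise_sd = 0.1) {
  ph <- make_multiregion(size = size, n_regions = 2, noise_sd = noise_sd,
                         seed = seed, layout = "slabs")
  ws <- new_workspace(ph$volume)
  compute_channel(ws, "tv", "total_variation",
                  params = list(lambda = 1, n_iter = 60))
  compute_supervoxels(ws, "tv", shape = c(8, 8, 8), compactness = 30)
  lvl <- add_level(ws)
  l1 <- add_label(ws, lvl, "phase1")
  l2 <- add_label(ws, lvl, "phase2")
  q <- round(size / 4)
  annotate(ws, lvl, l1, rbind(c(q, q, q), c(size - q, q, size - q)),
           mode = "supervoxel")
  annotate(ws, lvl, l2, rbind(c(q, size - q, q),
                              c(size - q, size - q, size - q)),
           mode = "supervoxel")
  list(ws = ws, ph = ph, level = lvl, labels = c(l1, l2))
}
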