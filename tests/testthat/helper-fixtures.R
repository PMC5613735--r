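# Shared fixture builders and independent oracles.

# small deterministic stack spec used across suites
small_spec <- function(seed = 7, ...) {
  stack_spec(n_slices = 8, width = 96, height = 96, seed = seed, ...)
}

rgb_from_channels <- function(r, g, b) {
  rgb_section(array(c(r, g, b), dim = c(dim(r), 3)), slice_index = 0)
}

random_label_volume <- function(ny, nx, nz, p = c(0.5, 0.35, 0.15)) {
  labels <- array(sample(0:2, ny * nx * nz, replace = TRUE, prob = p),
                  dim = c(ny, nx, nz))
  label_volume(labels)
}

# --- independent oracles -------------------------------------------------

# connected component containing the seed, by iterative mask dilation
# (array shifting) rather than frontier traversal
flood_oracle <- function(tissue, seed_rcz, connectivity) {
  d <- dim(tissue)
  shift_arr <- function(a, dy, dx, dz) {
    out <- array(FALSE, d)
    ys <- seq_len(d[1]); xs <- seq_len(d[2]); zs <- seq_len(d[3])
    sy <- ys - dy; sx <- xs - dx; sz <- zs - dz
    oky <- sy >= 1 & sy <= d[1]; okx <- sx >= 1 & sx <= d[2]
    okz <- sz >= 1 & sz <= d[3]
    out[ys[oky], xs[okx], zs[okz]] <- a[sy[oky], sx[okx], sz[okz]]
    out
  }
  offs <- if (connectivity == 6) {
    list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    g <- expand.grid(-1:1, -1:1, -1:1)
    g <- g[rowSums(abs(g)) > 0, ]
    lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
  }
  vis <- array(FALSE, d)
  vis[seed_rcz[1], seed_rcz[2], seed_rcz[3]] <- TRUE
  repeat {
    grown <- vis
    for (o in offs) grown <- grown | shift_arr(vis, o[1], o[2], o[3])
    grown <- grown & tissue
    if (identical(grown, vis)) return(vis)
    vis <- grown
  }
}

# RMS residual of the best rigid fit found by exhaustive theta grid
# search with the per-theta optimal translation
grid_search_rms <- function(moving, fixed, step = 1e-3) {
  mc <- colMeans(moving); fc <- colMeans(fixed)
  best <- Inf
  for (theta in seq(-pi, pi - step, by = step)) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    t <- fc - as.numeric(R %*% mc)
    res <- sweep(moving %*% t(R), 2, t, "+") - fixed
    rms <- sqrt(mean(rowSums(res^2)))
    if (rms < best) best <- rms
  }
  best
}
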