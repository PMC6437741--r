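# shared constructors for level-set fields and small fixtures

# signed Euclidean distance field of a disc, positive inside
sdf_disc <- function(dim, cx, cy, r) {
  x <- matrix(rep(0:(dim[2] - 1), each = dim[1]), dim[1], dim[2])
  y <- matrix(rep(0:(dim[1] - 1), times = dim[2]), dim[1], dim[2])
  r - sqrt((x - cx)^2 + (y - cy)^2)
}

# {0,1} rasterisation of an ellipse interior
ellipse_mask <- function(params, dim) {
  (ellipse_levelset(params, dim) > 0) + 0
}

# brute-force k x k windowed sum with edge replication (loop oracle)
loop_box_sum <- function(m, k) {
  p <- k %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (di in -p:p) for (dj in -p:p) {
      ii <- min(max(i + di, 1), nr)
      jj <- min(max(j + dj, 1), nc)
      s <- s + m[ii, jj]
    }
    out[i, j] <- s
  }
  out
}
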