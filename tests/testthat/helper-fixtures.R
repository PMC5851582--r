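# small in-code fixtures and independent oracles shared across test files

mat_grid <- function(values, cell_size = 10, origin = c(0, 0), units = "m") {
  raster_grid(values, cell_size, origin, units = units)
}

# analytic 1-D water-table profile: fixed head h0 at the first cell center,
# no-flow at the far face; exact for the cell-centered 5-point scheme
strip_head_profile <- function(n, a, w, Tm, h0 = 0) {
  x <- (seq_len(n) - 0.5) * a          # cell centers
  L <- n * a                           # no-flow outer face
  xt <- x - x[1]
  h0 + w * (2 * (L - x[1]) * xt - xt^2) / (2 * Tm)
}

# min-plus (tropical) transitive closure over the 8-neighbor grid graph:
# an exhaustive all-path-lengths shortest-distance oracle, independent of
# the Dijkstra implementation
brute_cost_distance <- function(cost, source) {
  cm <- cost$values
  a <- cost$cell_size
  nr <- nrow(cm); nc <- ncol(cm)
  n <- nr * nc
  W <- matrix(Inf, n, n)
  diag(W) <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(cm[i, j])) next
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i2 <- i + di; j2 <- j + dj
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc || is.na(cm[i2, j2])) next
      u <- (j - 1) * nr + i; v <- (j2 - 1) * nr + i2
      W[u, v] <- (cm[i, j] + cm[i2, j2]) / 2 * sqrt(di^2 + dj^2) * a
    }
  }
  for (rep in seq_len(n)) {            # relax until closure
    W2 <- W
    for (k in seq_len(n)) W2 <- pmin(W2, outer(W[, k], W[k, ], `+`))
    if (identical(W2, W)) break
    W <- W2
  }
  s <- (source[2] - 1) * nr + source[1]
  out <- matrix(W[s, ], nr, nc)
  out[is.infinite(out) | is.na(cm)] <- NA_real_
  out
}

# direct textbook bilinear interpolation at a point (unit weights formula)
brute_bilinear <- function(m, grid, p) {
  a <- grid$cell_size
  fx <- (p[1] - grid$origin[1]) / a - 0.5
  fy <- (p[2] - grid$origin[2]) / a - 0.5
  j0 <- floor(fx) + 1; i0 <- floor(fy) + 1
  tx <- fx - floor(fx); ty <- fy - floor(fy)
  m[i0, j0] * (1 - tx) * (1 - ty) + m[i0, j0 + 1] * tx * (1 - ty) +
    m[i0 + 1, j0] * (1 - tx) * ty + m[i0 + 1, j0 + 1] * tx * ty
}

# explicit redundancy-analysis oracle: project standardized Y on the column
# space of standardized X, eigen-decompose the fitted cross-product
brute_rda <- function(Y, X) {
  Ys <- scale(as.matrix(Y)); Xs <- scale(as.matrix(X))
  H <- Xs %*% solve(crossprod(Xs)) %*% t(Xs)
  Yfit <- H %*% Ys
  n <- nrow(Ys)
  eig <- eigen(crossprod(Yfit) / (n - 1), symmetric = TRUE)$values
  eig <- eig[eig > max(eig) * 1e-12]
  list(eig = eig, total = sum(diag(crossprod(Ys) / (n - 1))))
}

# tiny constant-geometry driver stack for prediction-map tests
toy_stack <- function(nr = 6, nc = 6, cell = 60) {
  g <- function(v) raster_grid(matrix(v, nr, nc), cell, c(0, 0))
  structure(list(
    a = g(seq_len(nr * nc) / (nr * nc)),
    b = g(rev(seq_len(nr * nc)) / (nr * nc)),
    c = g(1)), class = "driver_stack")
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), .Machine$double.eps), tol)
}
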