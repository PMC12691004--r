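# Shared in-code fixtures: all test data is generated programmatically.

# digital sphere mask of radius r_mm centred in a cube, spacing in mm
make_sphere <- function(r_mm = 10, spacing = c(1, 1, 1), pad = 3) {
  nd <- ceiling(2 * r_mm / spacing) + 2 * pad + 1
  ctr <- (nd + 1) / 2
  ax <- lapply(1:3, function(a) ((seq_len(nd[a]) - ctr[a]) * spacing[a])^2)
  q <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  q <= r_mm^2
}

# CT grid with a soft-tissue ellipse in air
make_ellipse_ct <- function(dims = c(30, 30, 8), spacing = c(2, 2, 2.5),
                            semi = c(22, 16, 8), hu = 40) {
  ctr <- (dims + 1) / 2
  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - ctr[a]) * spacing[a] /
                                   semi[a])^2)
  q <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  v <- array(-1000, dims)
  v[q <= 1] <- hu
  list(grid = image_grid(v, spacing), mask = q <= 1)
}

# small stacked-model training setup: linearly separable two-feature data
make_separable <- function(n = 120, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, "a"] + 0.5 * X[, "b"] > 0
  list(X = X, y = y)
}

make_inner <- function(n, k = 4) {
  lapply(seq_len(k), function(f) {
    v <- seq(f, n, by = k)
    list(train = setdiff(seq_len(n), v), val = v)
  })
}

# brute-force point-in-polygon by angle summation (independent of the
# crossing-number implementation under test)
pip_winding <- function(px, py, poly) {
  n <- nrow(poly)
  ang <- rep(0, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    a1 <- atan2(poly[i, 2] - py, poly[i, 1] - px)
    a2 <- atan2(poly[j, 2] - py, poly[j, 1] - px)
    da <- a2 - a1
    da <- ifelse(da > pi, da - 2 * pi, ifelse(da < -pi, da + 2 * pi, da))
    ang <- ang + da
  }
  abs(ang) > pi
}
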