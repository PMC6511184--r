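# Independent brute-force oracles. These deliberately avoid the package's own
# code paths: densities are counted with explicit loops, exact test p-values
# are obtained by full enumeration, and point-in-polygon uses the winding
# number rather than the package's even-odd ray cast.

make_gray <- function(mat, extent_mm = 3) {
  angiogram(mat, scan_geometry(extent_mm, n_px = nrow(mat)))
}

# pixel counting with explicit loops
oracle_density <- function(fg, excl) {
  num <- 0L; den <- 0L
  for (i in seq_len(nrow(fg))) {
    for (j in seq_len(ncol(fg))) {
      if (!excl[i, j]) {
        den <- den + 1L
        if (fg[i, j]) num <- num + 1L
      }
    }
  }
  num / den
}

# Wilcoxon signed rank: enumerate all 2^n sign assignments of the nonzero
# differences (mid-ranks for tied magnitudes), two-sided doubled tail
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1.0)
  ranks <- rank(abs(d))
  W <- sum(ranks[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_null <- as.vector(signs %*% ranks)
  p_le <- mean(W_null <= W)
  p_ge <- mean(W_null >= W)
  min(1, 2 * min(p_le, p_ge))
}

# Mann-Whitney: enumerate all C(N, na) assignments of ranks to sample a
oracle_mann_whitney <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(length(r), na)
  U_null <- apply(splits, 2, function(idx) sum(r[idx])) - na * (na + 1) / 2
  min(1, 2 * min(mean(U_null <= U), mean(U_null >= U)))
}

# Spearman: enumerate all n! permutations of y
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  perms <- all_perms(length(y))
  rho_null <- apply(perms, 1, function(p) cor(rx, ry[p]))
  mean(abs(rho_null) >= abs(rho) - 1e-12)
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# winding-number point-in-polygon
oracle_inside <- function(px, py, v) {
  n <- nrow(v)
  ang <- 0
  for (e in seq_len(n)) {
    j <- if (e == n) 1L else e + 1L
    a1 <- atan2(v[e, 2] - py, v[e, 1] - px)
    a2 <- atan2(v[j, 2] - py, v[j, 1] - px)
    da <- a2 - a1
    if (da > pi) da <- da - 2 * pi
    if (da < -pi) da <- da + 2 * pi
    ang <- ang + da
  }
  abs(ang) > pi
}

# regular polygon vertices, circumradius R
regular_polygon <- function(n, R, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + R * cos(th), center[2] + R * sin(th))
}

flat_surfaces <- function(ilm, rpe, n_px = 4, extent_mm = 6) {
  g <- scan_geometry(extent_mm, n_px = n_px)
  surface_set(matrix(ilm, n_px, n_px), matrix(rpe, n_px, n_px), g)
}
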