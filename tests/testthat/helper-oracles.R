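# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity from first principles and
# share no code with the package internals.

# Per-pixel membership-triple lookup: the definition of the region
# partition applied pixel by pixel.
oracle_classify_pixels <- function(prev, curr, nxt) {
  labels <- matrix(0L, nrow(curr), ncol(curr))
  for (i in seq_len(nrow(curr))) {
    for (j in seq_len(ncol(curr))) {
      if (!curr[i, j]) next
      p <- prev[i, j]; q <- nxt[i, j]
      labels[i, j] <- if (p && q) 1L else if (!p && q) 2L else if (p && !q) 3L else 4L
    }
  }
  labels
}

# Centroid by explicit pixel averaging.
oracle_centroid <- function(mask) {
  s <- c(0, 0); n <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j]) { s <- s + c(i, j); n <- n + 1 }
  }
  s / n
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(m+n, m) group assignments (tie-free samples only).
oracle_wilcoxon_exact <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)])
  ew <- m * (m + n + 1) / 2
  combos <- utils::combn(m + n, m)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-9)
}

# Kruskal-Wallis H by the definitional rank formula (tie-free).
oracle_kw_H <- function(groups) {
  x <- unlist(groups)
  stopifnot(!anyDuplicated(x))
  r <- rank(x)
  N <- length(x)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 0
  for (g in seq_along(groups)) {
    Rg <- sum(r[idx == g])
    ng <- lengths(groups)[g]
    H <- H + Rg^2 / ng
  }
  unname(12 / (N * (N + 1)) * H - 3 * (N + 1))
}

# Type-7 quartiles by direct linear interpolation of order statistics.
oracle_quartiles_type7 <- function(x) {
  x <- sort(x); n <- length(x)
  vapply(c(0.25, 0.5, 0.75), function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
  }, numeric(1))
}

# Random small binary mask with a given foreground density.
random_mask <- function(nr = 8, nc = 8, p = 0.5) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# Shift a logical mask by (dr, dc) pixels inside a fixed frame.
shift_mask <- function(mask, dr, dc) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  idx <- which(mask, arr.ind = TRUE)
  idx[, 1] <- idx[, 1] + dr
  idx[, 2] <- idx[, 2] + dc
  keep <- idx[, 1] >= 1 & idx[, 1] <= nrow(mask) &
    idx[, 2] >= 1 & idx[, 2] <= ncol(mask)
  out[idx[keep, , drop = FALSE]] <- TRUE
  out
}

# Digital disk mask.
disk_mask <- function(size, center, radius) {
  m <- matrix(FALSE, size, size)
  for (i in seq_len(size)) for (j in seq_len(size)) {
    if ((i - center[1])^2 + (j - center[2])^2 <= radius^2) m[i, j] <- TRUE
  }
  m
}
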