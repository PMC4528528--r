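# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no C++, no vectorised shortcuts) so that agreement is a real
# cross-check and not a tautology.

# per-point homogeneous computation, scalar loop
oracle_apply_homography <- function(points, H) {
  out <- matrix(NA_real_, nrow(points), 2)
  for (i in seq_len(nrow(points))) {
    v <- c(points[i, 1], points[i, 2], 1)
    w <- sum(H[3, ] * v)
    out[i, ] <- c(sum(H[1, ] * v), sum(H[2, ] * v)) / w
  }
  out
}

# two-sided Pratt signed-rank p by enumeration of every sign assignment
oracle_signed_rank_pratt <- function(d) {
  r <- rank(abs(d)) # midranks, zeros included
  nz <- d != 0
  if (!any(nz)) return(NA_real_)
  rs <- r[nz]
  m <- length(rs)
  tobs <- sum(rs[d[nz] > 0])
  total <- sum(rs)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  tvals <- as.numeric(signs %*% rs)
  mean(abs(tvals - total / 2) >= abs(tobs - total / 2) - 1e-9)
}

# two-sided rank-sum p by enumeration of every group assignment (midranks)
oracle_rank_sum <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  m <- length(a)
  N <- length(pooled)
  wobs <- sum(r[seq_len(m)])
  mu <- m * mean(r)
  sets <- utils::combn(N, m)
  ws <- apply(sets, 2, function(idx) sum(r[idx]))
  mean(abs(ws - mu) >= abs(wobs - mu) - 1e-9)
}

# histogram-by-flooring density oracle
oracle_density <- function(x, y, cell, n_x, n_y) {
  M <- matrix(0, n_y, n_x)
  n <- 0
  for (i in seq_along(x)) {
    ix <- floor(x[i] / cell)
    iy <- floor(y[i] / cell)
    if (ix >= 0 && ix < n_x && iy >= 0 && iy < n_y) {
      M[iy + 1, ix + 1] <- M[iy + 1, ix + 1] + 1
      n <- n + 1
    }
  }
  M / n
}

# random well-conditioned homography with bottom-right coefficient 1
random_homography <- function() {
  repeat {
    H <- diag(3) + matrix(rnorm(9, 0, 0.1), 3, 3)
    H[3, 1:2] <- rnorm(2, 0, 0.003)
    H <- H / H[3, 3]
    if (abs(det(H)) > 0.1) return(H)
  }
}

# long density-map table on an arbitrary grid from a trials x cells matrix
fake_maps <- function(V, grid) {
  cells <- shoalwatch:::grid_cells(grid)
  stopifnot(ncol(V) == nrow(cells))
  out <- dplyr::bind_rows(lapply(seq_len(nrow(V)), function(i) {
    cells$density <- V[i, ]
    cells$trial <- paste0("t", i)
    cells
  }))
  attr(out, "grid") <- grid
  out
}

# minimal one-cell rank-sum significance map (for Stouffer closed forms)
tiny_sig_map <- function(p, direction, n = 8L) {
  s <- tibble::tibble(ix = 0L, iy = 0L, x = 0.25, y = 0.25,
                      p = p, direction = as.integer(direction), n = n)
  attr(s, "grid") <- grid_spec()
  attr(s, "test_kind") <- "group_rank_sum"
  class(s) <- c("significance_map", class(s))
  s
}

# short, cheap trial for unit tests (full-length trials are exercised in the
# acceptance suite)
quick_trial <- function(seed, shoal_size = 2, duration_s = 60, fps = 10, ...) {
  simulate_trial(behaviour_params(...), shoal_size = shoal_size,
                 duration_s = duration_s, fps = fps, seed = seed)
}
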