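# Independent brute-force oracle for the polynomial recruitment problem:
# eliminate the equality constraints through an invertible column block,
# then grid-search the remaining free forces with iterative refinement.
# Only used on tiny instances (<= 3 muscles, 1-2 constraints).

recruitment_oracle <- function(R, M_ext, N, p = 2, rounds = 8, grid_n = 41) {
  m <- nrow(R); n <- ncol(R)
  b <- -as.numeric(M_ext)
  stopifnot(n <= 3, m <= 2, m < n)

  # pick a well-conditioned dependent block
  combos <- utils::combn(n, m)
  best_det <- 0; dep <- NULL
  for (j in seq_len(ncol(combos))) {
    B <- R[, combos[, j], drop = FALSE]
    dt <- abs(det(B))
    if (dt > best_det) { best_det <- dt; dep <- combos[, j] }
  }
  stopifnot(best_det > 1e-12)
  free <- setdiff(seq_len(n), dep)
  Binv <- solve(R[, dep, drop = FALSE])

  obj_of <- function(f_free) {
    f_dep <- drop(Binv %*% (b - R[, free, drop = FALSE] %*% f_free))
    f <- numeric(n); f[free] <- f_free; f[dep] <- f_dep
    if (any(f < -1e-9) || any(f > N + 1e-9)) return(Inf)
    sum((f / N)^p)
  }

  lo <- setNames(rep(0, length(free)), NULL)
  hi <- N[free]
  best <- Inf; best_f <- (lo + hi) / 2
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_along(free), function(k)
      seq(lo[k], hi[k], length.out = grid_n))
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1, obj_of)
    i <- which.min(vals)
    if (vals[i] < best) { best <- vals[i]; best_f <- pts[i, ] }
    # shrink the window around the incumbent
    span <- (hi - lo) / (grid_n - 1) * 4
    lo <- pmax(best_f - span, 0)
    hi <- pmin(best_f + span, N[free])
  }
  best
}

# Deterministic random recruitment instance that is feasible by
# construction (the moment is generated by a strictly interior force).
random_recruitment_instance <- function(n, m) {
  N <- stats::runif(n, 100, 1000)
  R <- matrix(stats::runif(m * n, -0.04, 0.04), m, n)
  f_star <- stats::runif(n, 0.05, 0.8) * N
  list(system = equilibrium_system(R, -drop(R %*% f_star), N),
       R = R, N = N)
}
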