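# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the 2TC oracle integrates the closed-form impulse
# response by fine-grid quadrature instead of an ODE solver, the Patlak oracle
# is a zooming grid search, the rank-sum oracle enumerates labelings, and the
# ROC oracle scans every threshold with a double loop.

# C1(t) = K1 * int_0^t Cp(s) exp(-(k2+k3)(t-s)) ds ; C2 = k3 * int_0^t C1
# computed by trapezoid on a uniform fine grid, then interpolated to t_out
oracle_2tc <- function(K1, k2, k3, vb, cp_fun, t_out, dt = 5e-4) {
  t_hi <- max(t_out)
  g <- seq(0, t_hi, by = dt)
  cp <- cp_fun(g)
  a <- k2 + k3
  # exact recursion for the convolution with trapezoidal Cp panels
  c1 <- numeric(length(g))
  decay <- exp(-a * dt)
  for (i in seq_along(g)[-1])
    c1[i] <- c1[i - 1] * decay + K1 * dt * (cp[i] + cp[i - 1] * decay) / 2
  c2 <- k3 * c(0, cumsum(dt * (c1[-1] + c1[-length(c1)]) / 2))
  ct <- c1 + c2 + vb * cp
  stats::approx(g, ct, xout = t_out)$y
}

# zooming grid search for the weighted Patlak least squares
oracle_patlak_grid <- function(tissue, design, span = c(-0.1, 0.2),
                               span_vd = c(-2, 4), final_step = 1e-6) {
  wss <- function(ki, vd)
    sum(design$w * (tissue - ki * design$icp - vd * design$cp)^2)
  lo <- c(span[1], span_vd[1]); hi <- c(span[2], span_vd[2])
  best <- c(mean(lo[1], hi[1]), mean(lo[2], hi[2]))
  repeat {
    ki_grid <- seq(lo[1], hi[1], length.out = 21)
    vd_grid <- seq(lo[2], hi[2], length.out = 21)
    vals <- outer(ki_grid, vd_grid, Vectorize(wss))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    best <- c(ki_grid[ix[1]], vd_grid[ix[2]])
    step <- c(diff(ki_grid[1:2]), diff(vd_grid[1:2]))
    if (all(step <= final_step)) break
    lo <- best - 2 * step; hi <- best + 2 * step
  }
  c(Ki = best[1], Vd = best[2])
}

# exact two-sided rank-sum p by full enumeration of group labelings
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  combos <- utils::combn(length(pooled), na)
  w_all <- apply(combos, 2, function(ix) sum(r[ix])) - na * (na + 1) / 2
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# exhaustive Youden search over the same candidate threshold set
oracle_roc_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best_j <- -Inf; best_thr <- NA
  for (c0 in thr) {
    sens <- mean(scores[labels] >= c0)
    spec <- mean(scores[!labels] < c0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_thr <- c0 }
  }
  list(cutoff = best_thr, j = best_j)
}

default_cp_fun <- function(params = input_function_params()) {
  function(t) plasma_curve(params, t)
}

small_phantom <- function(shape = c(24, 24, 24), noise_scale = 0, seed = 1,
                          ...) {
  build_phantom(shape = shape, noise_scale = noise_scale, seed = seed, ...)
}
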