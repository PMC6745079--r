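# Independent oracles used across the suite. These deliberately avoid the
# package's fitting code paths: plain formula evaluation and exhaustive
# grid search only.

# Bi-exponential forward model, written out directly.
oracle_biexp <- function(te, s0, f_bw, t2s, t2l) {
  s0 * (f_bw * exp(-te / t2s) + (1 - f_bw) * exp(-te / t2l))
}

# Brute-force least-squares fit of the baseline-corrected mono-exponential
# model over a dense (f_app, t2s_app) lattice, followed by one local
# refinement pass around the coarse minimum (the RSS valley is a narrow
# curved trench, so a single-resolution lattice localizes the minimum
# poorly). Vectorized over t2s; amplitude = baseline/(1 - f_app).
oracle_abbrev_gridsearch <- function(te1, y1, baseline,
                                     f_range = c(0.01, 0.99),
                                     t2s_range = c(0.1, 5),
                                     step = 1e-3) {
  scan <- function(fs, ts) {
    E <- exp(outer(-te1, 1 / ts))  # |te1| x |ts|
    best <- list(rss = Inf, f = NA, t2s = NA)
    for (f in fs) {
      A <- baseline / (1 - f)
      rss <- colSums((A * E + baseline - y1)^2)
      i <- which.min(rss)
      if (rss[i] < best$rss) best <- list(rss = rss[i], f = f, t2s = ts[i])
    }
    best
  }
  b1 <- scan(seq(f_range[1], f_range[2], by = step),
             seq(t2s_range[1], t2s_range[2], by = step))
  fine <- step / 50
  b2 <- scan(seq(max(f_range[1], b1$f - 2 * step),
                 min(f_range[2], b1$f + 2 * step), by = fine),
             seq(max(t2s_range[1], b1$t2s - 50 * step),
                 min(t2s_range[2], b1$t2s + 50 * step), by = fine))
  list(f_bw_app = b2$f, t2s_app = b2$t2s, rss = b2$rss)
}

# Coarse 4-D grid search for the bi-exponential model. For each (s0, f)
# the residual over the (t2s, t2l) lattice decomposes as
# ||a_i - y||^2 + 2 (a_i - y) . b_j + ||b_j||^2 with a_i the fast and b_j
# the slow component, evaluated with one matrix product.
oracle_biexp_gridsearch <- function(te, y,
                                    s0s = seq(0.9, 1.1, by = 0.01),
                                    fs = seq(0.05, 0.95, by = 0.01),
                                    ts = seq(0.2, 3, by = 0.02),
                                    tl = seq(10, 30, by = 0.5)) {
  Es <- exp(outer(-te, 1 / ts))
  El <- exp(outer(-te, 1 / tl))
  best <- list(rss = Inf)
  for (s0 in s0s) for (f in fs) {
    fast <- s0 * f * Es
    slow <- s0 * (1 - f) * El
    D <- fast - y
    rss <- outer(colSums(D^2), colSums(slow^2), `+`) + 2 * crossprod(D, slow)
    i <- arrayInd(which.min(rss), dim(rss))
    if (rss[i] < best$rss) {
      best <- list(rss = rss[i[1], i[2]], s0 = s0, f_bw = f,
                   t2s = ts[i[1]], t2l = tl[i[2]])
    }
  }
  best
}

# Closed-form log-linear regression estimate of a mono-exponential decay.
oracle_loglinear_t2l <- function(te, y) {
  co <- stats::coef(stats::lm(log(y) ~ te))
  -1 / co[[2]]
}

# Principal-axis direction of a point cloud via an explicit eigen
# decomposition of the covariance matrix (independent of prcomp).
oracle_principal_angle <- function(points, b0 = c(0, 0, 1)) {
  ev <- eigen(stats::cov(points))
  dir <- ev$vectors[, which.max(ev$values)]
  acos(abs(sum(dir * b0)) / sqrt(sum(dir^2))) * 180 / pi
}

# Exhaustive enumeration of lattice offsets within a Euclidean ball.
oracle_ball_count <- function(radius, voxel = c(1, 1, 1)) {
  r <- floor(radius / min(voxel))
  n <- 0L
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    d2 <- (dx * voxel[1])^2 + (dy * voxel[2])^2 + (dz * voxel[3])^2
    if (d2 > 0 && d2 <= radius^2 + 1e-9) n <- n + 1L
  }
  n
}

# Noiseless abbreviated-schedule curve for given truth.
make_abbrev_curve <- function(f_bw, t2s, t2l = 20, s0 = 1) {
  sch <- standard_schedules()$abbreviated
  decay_curve(sch$all_tes,
              oracle_biexp(sch$all_tes, s0, f_bw, t2s, t2l), sch)
}
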