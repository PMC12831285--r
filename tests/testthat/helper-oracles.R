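# Independent brute-force oracles.  These deliberately avoid the code
# paths they validate: superposition by zooming grid search over Euler
# angles (not SVD), embedding by gauge-fixed grid search over polar
# coordinates (not gradient optimization).

# Minimum RMSD of x onto y over all proper rotations + translations,
# by 3-level zooming grid over Euler angles.
oracle_superpose_rmsd <- function(x, y, n_grid = 13L, n_levels = 5L) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  rmsd_at <- function(a, b, c) {
    R <- foldsteer:::rotation_from_euler(a, b, c)
    sqrt(mean(rowSums((xc %*% R - yc)^2)))
  }
  centers <- c(0, 0, 0)
  width <- 360
  best <- Inf
  for (lvl in seq_len(n_levels)) {
    ga <- centers[1] + seq(-width / 2, width / 2, length.out = n_grid)
    gb <- centers[2] + seq(-width / 2, width / 2, length.out = n_grid)
    gc <- centers[3] + seq(-width / 2, width / 2, length.out = n_grid)
    for (a in ga) for (b in gb) for (c in gc) {
      r <- rmsd_at(a, b, c)
      if (r < best) {
        best <- r
        centers <- c(a, b, c)
      }
    }
    width <- 2 * width / (n_grid - 1)   # zoom around the best cell
  }
  # generic local polish of the same Euler-angle objective (the grid
  # basin is already correct; this removes the residual grid spacing)
  fit <- stats::optim(centers, function(p) rmsd_at(p[1], p[2], p[3]),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-15))
  min(best, fit$value)
}

# Optimal dot-product embedding residual for a 3x3 correlation matrix
# over unit-disk 2-vectors, by gauge-fixed zooming grid search:
# x1 = (r1, 0), x2 = r2 (cos t2, sin t2) with t2 in [0, pi],
# x3 = r3 (cos t3, sin t3).
oracle_embed_residual_3 <- function(cc, n_r = 9L, n_t = 17L,
                                    n_levels = 3L) {
  c12 <- cc[1, 2]; c13 <- cc[1, 3]; c23 <- cc[2, 3]
  lo <- c(0, 0, 0, 0, -pi)        # r1, r2, r3, t2, t3
  hi <- c(1, 1, 1, pi, pi)
  center <- (lo + hi) / 2
  span <- hi - lo
  best <- Inf
  best_par <- center
  for (lvl in seq_len(n_levels)) {
    g <- expand.grid(
      r1 = pmin(1, pmax(0, center[1] + seq(-span[1] / 2, span[1] / 2,
                                           length.out = n_r))),
      r2 = pmin(1, pmax(0, center[2] + seq(-span[2] / 2, span[2] / 2,
                                           length.out = n_r))),
      r3 = pmin(1, pmax(0, center[3] + seq(-span[3] / 2, span[3] / 2,
                                           length.out = n_r))),
      t2 = center[4] + seq(-span[4] / 2, span[4] / 2,
                           length.out = n_t),
      t3 = center[5] + seq(-span[5] / 2, span[5] / 2,
                           length.out = n_t))
    res <- (c12 - g$r1 * g$r2 * cos(g$t2))^2 +
      (c13 - g$r1 * g$r3 * cos(g$t3))^2 +
      (c23 - g$r2 * g$r3 * cos(g$t3 - g$t2))^2
    i <- which.min(res)
    if (res[i] < best) {
      best <- res[i]
      best_par <- as.numeric(g[i, ])
    }
    center <- best_par
    span <- span / 6
  }
  best
}

# Exhaustive best strictly-monotone alignment of a short template onto
# a query under unit match scoring (brute force over all monotone
# injections), returning the best mapping(s) score and pair sets.
oracle_best_monotone_mapping <- function(query, template) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(template, "")[[1]]
  nq <- length(q)
  nt <- length(t)
  best <- list(score = -Inf, maps = list())
  recurse <- function(qi, ti, pairs, score) {
    if (ti > nt) {
      if (score > best$score) {
        best$score <<- score
        best$maps <<- list(pairs)
      } else if (score == best$score) {
        best$maps <<- c(best$maps, list(pairs))
      }
      return()
    }
    remaining <- nt - ti
    for (qpos in qi:(nq - remaining)) {
      s <- if (q[qpos] == t[ti]) 1L else -1L
      recurse(qpos + 1L, ti + 1L, rbind(pairs, c(qpos - 1L, ti - 1L)),
              score + s)
    }
  }
  recurse(1L, 1L, matrix(integer(0), 0, 2), 0L)
  best
}
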