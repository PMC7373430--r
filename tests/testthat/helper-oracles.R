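# Independent oracles used to check the implementation. Each one takes a
# deliberately different computational path from the code it validates.

# Monte-Carlo integral of the anisotropic Gaussian over a ball of diameter d
oracle_mc_cf <- function(psf, d, n = 2e6, seed = 42) {
  withr::with_seed(seed, {
    x <- stats::rnorm(n, sd = psf$sigma_x)
    y <- stats::rnorm(n, sd = psf$sigma_y)
    z <- stats::rnorm(n, sd = psf$sigma_z)
  })
  mean(x^2 + y^2 + z^2 <= (d / 2)^2)
}

# exhaustive search over all candidate thresholds of the Kapur entropy
# objective, computed directly from the raw histogram split
oracle_kapur <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- counts / sum(counts)
  best <- -Inf
  best_t <- NA_real_
  for (t in 1:(n_bins - 1L)) {
    p1 <- p[1:t]; p2 <- p[(t + 1L):n_bins]
    w1 <- sum(p1); w2 <- sum(p2)
    if (w1 <= 0 || w2 <= 0) next
    q1 <- p1[p1 > 0] / w1
    q2 <- p2[p2 > 0] / w2
    obj <- -sum(q1 * log(q1)) - sum(q2 * log(q2))
    if (obj > best) {
      best <- obj
      best_t <- edges[t + 1L]
    }
  }
  best_t
}

# exhaustive search of the Otsu between-class variance
oracle_otsu <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  best <- -Inf
  best_t <- NA_real_
  for (t in 1:(n_bins - 1L)) {
    w1 <- sum(counts[1:t]); w2 <- sum(counts[(t + 1L):n_bins])
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(counts[1:t] * mids[1:t]) / w1
    m2 <- sum(counts[(t + 1L):n_bins] * mids[(t + 1L):n_bins]) / w2
    obj <- w1 * w2 * (m1 - m2)^2
    if (obj > best) {
      best <- obj
      best_t <- edges[t + 1L]
    }
  }
  best_t
}

# exact two-sided rank-sum p value by enumerating which observations are
# assigned to group a, scoring each assignment by pairwise comparisons
# (valid with ties; independent of midrank arithmetic)
oracle_wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  u_of <- function(ia) {
    av <- pooled[ia]; bv <- pooled[-ia]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, u_of)
  u_obs <- u_of(seq_len(na))
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Fligner-Killeen statistic computed from scratch (formula path independent
# of stats::fligner.test)
oracle_fligner_stat <- function(groups) {
  a <- unlist(lapply(groups, function(v) abs(v - stats::median(v))))
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(a)
  sc <- stats::qnorm((1 + rank(a) / (n + 1)) / 2)
  abar <- mean(sc)
  v <- sum((sc - abar)^2) / (n - 1)
  ni <- lengths(groups)
  mi <- tapply(sc, g, mean)
  sum(ni * (mi - abar)^2) / v
}

# permutation-null p value for the Fligner-Killeen statistic
oracle_fligner_perm_p <- function(groups, B = 5000, seed = 99) {
  obs <- oracle_fligner_stat(groups)
  x <- unlist(groups)
  ni <- lengths(groups)
  withr::with_seed(seed, {
    perm <- replicate(B, {
      xp <- sample(x)
      splits <- split(xp, rep(seq_along(ni), ni))
      oracle_fligner_stat(splits)
    })
  })
  mean(perm >= obs - 1e-12)
}

# dense eigensolver oracle for eigenvector centrality
oracle_eigen_centrality <- function(adj) {
  e <- eigen(adj, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- abs(v) / sqrt(sum(v^2))
  v
}

# 3-D Riemann-sum profile of a ball convolved with the Gaussian PSF,
# evaluated at lateral offsets (independent of the quadrature code)
oracle_ball_profile <- function(psf, d, offsets, h = 0.005) {
  R <- d / 2
  g <- seq(-R + h / 2, R - h / 2, by = h)
  pts <- expand.grid(x = g, y = g, z = g)
  pts <- pts[pts$x^2 + pts$y^2 + pts$z^2 <= R^2, ]
  vapply(offsets, function(x0) {
    sum(stats::dnorm(pts$x - x0, sd = psf$sigma_x) *
        stats::dnorm(pts$y, sd = psf$sigma_y) *
        stats::dnorm(pts$z, sd = psf$sigma_z)) * h^3
  }, numeric(1))
}
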