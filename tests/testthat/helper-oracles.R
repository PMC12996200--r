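# Independent brute-force oracles used to check the package's estimators.
# These deliberately avoid the implementation paths they verify.

# AUC by exhaustive concordant-pair counting (ties get half credit).
brute_auc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Two-sample KS statistic by evaluating both ECDFs at every jump point.
brute_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# Sample entropy by direct template counting (Chebyshev, no self-matches).
brute_sampen <- function(x, m, r) {
  n <- length(x)
  N <- n - m
  A <- 0; B <- 0
  for (i in 1:(N - 1)) {
    for (j in (i + 1):N) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  -log(A / B)
}

# Time-averaged log-derivative of the logistic map: the exact Lyapunov
# exponent of the orbit.
logistic_lyap_oracle <- function(r, x0, n) {
  x <- x0
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + log(abs(r * (1 - 2 * x)))
    x <- r * x * (1 - x)
  }
  acc / n
}

# Benettin's variational method for the Lorenz top exponent: integrate the
# flow with RK4 together with a tangent vector, renormalizing each step.
benettin_lorenz <- function(sigma = 10, rho = 28, beta = 8 / 3,
                            dt = 0.005, n_steps = 40000, transient = 4000) {
  f <- function(s) {
    c(sigma * (s[2] - s[1]), s[1] * (rho - s[3]) - s[2],
      s[1] * s[2] - beta * s[3])
  }
  jac_v <- function(s, v) {
    c(sigma * (v[2] - v[1]),
      (rho - s[3]) * v[1] - v[2] - s[1] * v[3],
      s[2] * v[1] + s[1] * v[2] - beta * v[3])
  }
  rk4 <- function(s, v) {
    k1 <- f(s);              l1 <- jac_v(s, v)
    k2 <- f(s + dt / 2 * k1); l2 <- jac_v(s + dt / 2 * k1, v + dt / 2 * l1)
    k3 <- f(s + dt / 2 * k2); l3 <- jac_v(s + dt / 2 * k2, v + dt / 2 * l2)
    k4 <- f(s + dt * k3);     l4 <- jac_v(s + dt * k3, v + dt * l3)
    list(s = s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4),
         v = v + dt / 6 * (l1 + 2 * l2 + 2 * l3 + l4))
  }
  s <- c(-8, 8, 27)
  v <- c(1, 0, 0)
  acc <- 0
  for (i in seq_len(n_steps)) {
    st <- rk4(s, v)
    s <- st$s
    nv <- sqrt(sum(st$v^2))
    v <- st$v / nv
    if (i > transient) acc <- acc + log(nv)
  }
  acc / ((n_steps - transient) * dt)
}

# Correlation sums by direct pairwise Chebyshev distances (small n only).
brute_corr_sums <- function(pts, r_grid, theiler) {
  n <- nrow(pts)
  d <- abs(outer(pts[, 1], pts[, 1], "-"))
  if (ncol(pts) > 1) {
    for (k in 2:ncol(pts)) {
      d <- pmax(d, abs(outer(pts[, k], pts[, k], "-")))
    }
  }
  keep <- abs(outer(seq_len(n), seq_len(n), "-")) > theiler &
    upper.tri(matrix(0, n, n))
  dv <- d[keep]
  vapply(r_grid, function(r) mean(dv <= r), numeric(1))
}

# Histogram AMI (base-table implementation, independent of the package's).
brute_ami <- function(x, lag, bins = 16) {
  n <- length(x)
  br <- seq(min(x), max(x), length.out = bins + 1)
  cx <- cut(x, br, include.lowest = TRUE)
  tab <- table(cx[1:(n - lag)], cx[(1 + lag):n])
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(pa, pb)[idx]))
}

# Exhaustive minimum-entropy search over single-feature predictor triples.
exhaustive_predictor_objective <- function(X, y, bins = 4) {
  Z <- scale(as.matrix(X))
  nf <- ncol(Z)
  combos <- expand.grid(a = 1:nf, b = 1:nf, c = 1:nf)
  combos <- combos[combos$a <= combos$b & combos$b <= combos$c, ]
  min(apply(combos, 1, function(cb) {
    conditional_entropy_objective(Z[, as.integer(cb), drop = FALSE], y, bins)
  }))
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

make_rec <- function(x, rate = 4000, site = "aortic", source = "personnel",
                     id = "S001") {
  cardiodyn:::new_recording(x, rate, site, source, id)
}
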