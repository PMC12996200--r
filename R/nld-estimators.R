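#' Maximal Lyapunov exponent (Rosenstein method)
#'
#' Embeds the series, finds each point's nearest neighbour outside a Theiler
#' window, and tracks the mean log-divergence of the neighbour pairs forward
#' in time; the exponent is the least-squares slope of that curve over
#' `fit_range`, in nats per sample. A positive value indicates exponential
#' trajectory divergence (chaos); periodic orbits give values near zero.
#'
#' @param x numeric series, or an already-embedded point matrix.
#' @param dim,tau embedding parameters; selected automatically (AMI delay,
#'   FNN dimension) when `NULL` and `x` is a series.
#' @param theiler temporal exclusion window in samples (default `dim * tau`).
#' @param fit_range integer vector of divergence-curve steps (0-based, in
#'   units of the possibly strided step) to fit; chosen automatically from
#'   the curve's rise toward saturation when `NULL`.
#' @param kmax number of forward steps tracked.
#' @param rate_hz optional sampling rate; when given, the result carries a
#'   `nats_per_sec` attribute.
#' @param max_points cap on embedded points; longer sets are strided, and
#'   the slope is rescaled to per-sample units.
#' @return Numeric scalar, nats per sample, with attributes `curve`,
#'   `fit_range`, `stride` and (optionally) `nats_per_sec`.
#' @export
max_lyapunov <- function(x, dim = NULL, tau = NULL, theiler = NULL,
                         fit_range = NULL, kmax = NULL, rate_hz = NULL,
                         max_points = 3000) {
  if (is.matrix(x)) {
    pts <- x
    tau <- tau %||% 1L
  } else {
    x <- as.numeric(x)
    tau <- tau %||% select_delay(x)
    dim <- dim %||% select_embedding_dim(x, tau)
    pts <- delay_embedding(x, dim, tau)
  }
  N <- nrow(pts)
  if (N < 500) stop("need at least 500 embedded points")
  theiler <- theiler %||% (ncol(pts) * tau)
  stride <- if (is.finite(max_points) && N > max_points) {
    ceiling(N / max_points)
  } else 1L
  if (stride > 1L) pts <- pts[seq(1L, N, by = stride), , drop = FALSE]
  theiler_s <- max(1L, ceiling(theiler / stride))
  kmax <- kmax %||% max(20L, min(300L, floor(nrow(pts) / 10)))
  curve <- cpp_divergence_curve(pts, as.integer(theiler_s), as.integer(kmax))
  if (is.null(fit_range)) {
    y <- curve
    y1 <- y[2]  # k = 1; k = 0 can sit on near-duplicate neighbour pairs
    rise <- max(y, na.rm = TRUE) - y1
    if (!is.finite(rise) || rise < 0.5) {
      # no exponential expansion beyond noise: fit the whole curve, whose
      # oscillations average out to the (near-zero) exponent
      fit_range <- 1:kmax
    } else {
      k2 <- which(y >= y1 + 0.75 * rise)[1] - 1L
      fit_range <- 1:max(k2, 5L)
    }
  }
  ks <- fit_range[fit_range >= 0 & fit_range <= kmax]
  yy <- curve[ks + 1L]
  ok <- is.finite(yy)
  if (sum(ok) < 3) stop("divergence curve too short for the fit range")
  slope <- coef(lm(yy[ok] ~ ks[ok]))[2]
  out <- unname(slope) / stride
  attr(out, "curve") <- curve
  attr(out, "fit_range") <- ks
  attr(out, "stride") <- stride
  if (!is.null(rate_hz)) attr(out, "nats_per_sec") <- out * rate_hz
  out
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Computes the correlation sum C(r) over a log-spaced radius grid
#' (Chebyshev norm, Theiler exclusion) and fits the slope of
#' `log C(r)` vs `log r` over an automatically selected scaling region: the
#' longest consecutive radius window whose local slopes are stable. The
#' chosen radius range is attached for audit.
#'
#' @param x numeric series, or an already-embedded point matrix.
#' @param dim,tau embedding parameters (as in [max_lyapunov()]).
#' @param theiler temporal exclusion window in samples.
#' @param r_grid optional increasing radius grid; derived from the pairwise
#'   distance distribution when `NULL`.
#' @param max_points cap on embedded points (strided subsample).
#' @param min_region_len minimum number of grid intervals in the scaling
#'   region.
#' @param c_max largest correlation-sum value admitted to the scaling
#'   region (radii where C(r) saturates toward 1 are excluded).
#' @return Numeric scalar slope with attributes `r_range`, `r_grid`,
#'   `corr_sum`.
#' @export
correlation_dimension <- function(x, dim = NULL, tau = NULL, theiler = NULL,
                                  r_grid = NULL, max_points = 3000,
                                  min_region_len = 5, c_max = 0.25) {
  if (is.matrix(x)) {
    pts <- x
    tau <- tau %||% 1L
  } else {
    x <- as.numeric(x)
    tau <- tau %||% select_delay(x)
    dim <- dim %||% select_embedding_dim(x, tau)
    pts <- delay_embedding(x, dim, tau)
  }
  N <- nrow(pts)
  if (N < 100) stop("need at least 100 embedded points")
  theiler <- theiler %||% (ncol(pts) * tau)
  stride <- if (is.finite(max_points) && N > max_points) ceiling(N / max_points) else 1L
  if (stride > 1L) pts <- pts[seq(1L, N, by = stride), , drop = FALSE]
  theiler_s <- max(1L, ceiling(theiler / stride))
  ns <- nrow(pts)
  if (is.null(r_grid)) {
    d <- sample_pair_distances(pts, 4000L)
    d <- d[d > 0]
    if (!length(d)) stop("degenerate distances: all points identical")
    r_grid <- exp(seq(log(quantile(d, 0.005)), log(quantile(d, 0.95)),
                      length.out = 30))
  }
  r_grid <- sort(unique(r_grid))
  C <- cpp_corr_sums(pts, r_grid, as.integer(theiler_s))
  npairs <- ns * (ns - 1) / 2  # upper bound; enough for a support cutoff
  # restrict the fit to the genuine scaling range: enough pairs for a stable
  # estimate, but below the saturation radii where C(r) flattens toward 1
  keep <- C * npairs >= 20 & C > 0 & C <= c_max
  if (sum(keep) < min_region_len + 1) stop("too few populated radii for a fit")
  lr <- log(r_grid[keep]); lc <- log(C[keep])
  slopes <- diff(lc) / diff(lr)
  win <- best_stable_window(slopes, min_region_len)
  idx <- win[1]:(win[2] + 1L)  # slope window -> C indices
  fit <- lm(lc[idx] ~ lr[idx])
  out <- unname(coef(fit)[2])
  attr(out, "r_range") <- exp(range(lr[idx]))
  attr(out, "r_grid") <- r_grid
  attr(out, "corr_sum") <- C
  out
}

# longest window of local slopes with sd below a stability tolerance;
# ties go to the smaller sd.
best_stable_window <- function(slopes, min_len) {
  m <- length(slopes)
  best <- NULL
  for (i in 1:(m - min_len + 1)) {
    for (j in (i + min_len - 1):m) {
      w <- slopes[i:j]
      tol <- 0.15 * max(abs(median(w)), 0.5)
      s <- sd(w)
      if (s <= tol) {
        len <- j - i + 1
        if (is.null(best) || len > best$len ||
            (len == best$len && s < best$sd)) {
          best <- list(i = i, j = j, len = len, sd = s)
        }
      }
    }
  }
  if (is.null(best)) {
    # fall back to the most stable minimal window
    sds <- vapply(1:(m - min_len + 1), function(i) {
      sd(slopes[i:(i + min_len - 1)])
    }, numeric(1))
    i <- which.min(sds)
    best <- list(i = i, j = i + min_len - 1)
  }
  c(best$i, best$j)
}

sample_pair_distances <- function(pts, npairs) {
  n <- nrow(pts)
  idx <- withr::with_seed(7L, {
    cbind(sample.int(n, npairs, replace = TRUE),
          sample.int(n, npairs, replace = TRUE))
  })
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  d <- abs(pts[idx[, 1], 1] - pts[idx[, 2], 1])
  if (ncol(pts) > 1) {
    for (k in 2:ncol(pts)) {
      d <- pmax(d, abs(pts[idx[, 1], k] - pts[idx[, 2], k]))
    }
  }
  d
}

#' Sample entropy
#'
#' `-ln(A/B)` where `B` counts pairs of length-`m` templates within Chebyshev
#' distance `r_frac * sd(x)` and `A` the corresponding length-`m+1`
#' matches; self-matches are excluded. A constant series returns 0 (all
#' templates match). If no length-`m+1` match exists the value is capped at
#' `ln(B)` with a warning.
#'
#' @param x numeric series (length >= 200).
#' @param m template length.
#' @param r_frac tolerance as a fraction of the series standard deviation.
#' @param max_n cap on series length; longer series are strided.
#' @return Nonnegative numeric scalar (nats).
#' @export
sample_entropy <- function(x, m = 2, r_frac = 0.2, max_n = 4000) {
  x <- as.numeric(x)
  if (length(x) < 200) stop("need at least 200 samples")
  s <- sd(x)
  if (s == 0) return(0)
  if (length(x) > max_n) {
    x <- x[seq(1, length(x), by = ceiling(length(x) / max_n))]
  }
  cnt <- cpp_sampen_counts(x, as.integer(m), r_frac * s)
  A <- cnt[1]; B <- cnt[2]
  if (B == 0) {
    warning("no template matches at length m; returning NA")
    return(NA_real_)
  }
  if (A == 0) {
    warning("no template matches at length m+1; capping at ln(B)")
    return(log(B))
  }
  -log(A / B)
}

#' Renyi entropy of order q
#'
#' `(1/(1-q)) * ln(sum p_i^q)` in nats. Continuous input is discretized into
#' `bins` equal-width bins over its observed range; alternatively a
#' probability vector can be passed with `pmf = TRUE`. `q = 1` returns the
#' Shannon limit.
#'
#' @param x numeric series, or probabilities when `pmf = TRUE`.
#' @param q entropy order (> 0).
#' @param bins number of equal-width bins for continuous input.
#' @param pmf treat `x` as a probability mass function.
#' @return Numeric scalar (nats).
#' @export
renyi_entropy <- function(x, q = 2, bins = 32, pmf = FALSE) {
  if (!length(x)) stop("empty input")
  if (q <= 0) stop("q must be > 0")
  if (pmf) {
    p <- x
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) stop("pmf must be nonnegative and sum to 1")
  } else {
    x <- as.numeric(x)
    rng <- range(x)
    if (rng[1] == rng[2]) return(0)
    br <- seq(rng[1], rng[2], length.out = bins + 1)
    ix <- pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L), bins)
    p <- tabulate(ix, bins) / length(x)
  }
  p <- p[p > 0]
  if (q == 1) return(-sum(p * log(p)))
  log(sum(p^q)) / (1 - q)
}

#' Hurst exponent
#'
#' `"rescaled_range"` (default): slope of mean `log(R/S)` over dyadic-ish
#' window sizes, with the Anis-Lloyd finite-sample expectation subtracted so
#' that white noise is centred on 0.5. `"dfa"`: detrended fluctuation
#' analysis (order-1) on the integrated series.
#'
#' @param x numeric series (length >= 512).
#' @param method `"rescaled_range"` or `"dfa"`.
#' @return Numeric scalar.
#' @export
hurst_exponent <- function(x, method = c("rescaled_range", "dfa")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 512) stop("need at least 512 samples")
  if (sd(x) == 0) stop("degenerate input: constant series")
  w <- unique(round(2^seq(4, floor(log2(n / 4) * 2) / 2, by = 0.5)))
  w <- w[w >= 16 & w <= n / 4]
  if (method == "rescaled_range") {
    rs <- vapply(w, function(wi) rs_statistic(x, wi), numeric(1))
    keep <- is.finite(rs) & rs > 0
    emp <- coef(lm(log(rs[keep]) ~ log(w[keep])))[2]
    al <- vapply(w[keep], rs_expected, numeric(1))
    ref <- coef(lm(log(al) ~ log(w[keep])))[2]
    unname(0.5 + emp - ref)
  } else {
    prof <- cumsum(x - mean(x))
    fl <- vapply(w, function(wi) dfa_fluct(prof, wi), numeric(1))
    keep <- is.finite(fl) & fl > 0
    unname(coef(lm(log(fl[keep]) ~ log(w[keep])))[2])
  }
}

rs_statistic <- function(x, w) {
  nb <- floor(length(x) / w)
  vals <- vapply(seq_len(nb), function(b) {
    seg <- x[((b - 1) * w + 1):(b * w)]
    s <- sd(seg)
    if (s == 0) return(NA_real_)
    z <- cumsum(seg - mean(seg))
    (max(z) - min(z)) / s
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# Anis-Lloyd expected R/S of an i.i.d. series for a window of size w.
rs_expected <- function(w) {
  i <- seq_len(w - 1)
  s <- sum(sqrt((w - i) / i))
  if (w <= 340) {
    g <- exp(lgamma((w - 1) / 2) - lgamma(w / 2))
    (w - 0.5) / w * g / sqrt(pi) * s
  } else {
    (w - 0.5) / w * s / sqrt(w * pi / 2)
  }
}

dfa_fluct <- function(prof, w) {
  nb <- floor(length(prof) / w)
  t <- seq_len(w)
  res2 <- vapply(seq_len(nb), function(b) {
    seg <- prof[((b - 1) * w + 1):(b * w)]
    fit <- lm.fit(cbind(1, t), seg)
    mean(fit$residuals^2)
  }, numeric(1))
  sqrt(mean(res2))
}

#' Fractal dimension of a waveform
#'
#' `"higuchi"`: slope of mean curve length `L(k)` against `1/k` on log axes,
#' for stride `k = 1..k_max`. `"katz"`: `log10(n) / (log10(d/L) + log10(n))`
#' with `n` the number of steps, `L` the total absolute first-difference
#' length and `d` the maximum excursion from the first sample. Constant
#' series return 1 with a warning; so does a degenerate Katz denominator
#' (e.g. a two-point series, whose excursion equals its length).
#'
#' @param x numeric series (length >= 128 for Higuchi).
#' @param method `"higuchi"` or `"katz"`.
#' @param k_max largest Higuchi stride.
#' @return Numeric scalar (1 for a smooth line, up to 2 for noise).
#' @export
fractal_dimension <- function(x, method = c("higuchi", "katz"), k_max = 16) {
  method <- match.arg(method)
  x <- as.numeric(x)
  n <- length(x)
  if (sd(x) == 0) {
    warning("constant series; fractal dimension defined as 1")
    return(1.0)
  }
  if (method == "higuchi") {
    if (n < 128) stop("need at least 128 samples")
    L <- vapply(seq_len(k_max), function(k) {
      mean(vapply(seq_len(k), function(m) {
        idx <- seq(m, n, by = k)
        if (length(idx) < 2) return(NA_real_)
        norm <- (n - 1) / (floor((n - m) / k) * k)
        sum(abs(diff(x[idx]))) * norm / k
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    unname(coef(lm(log(L) ~ log(1 / seq_len(k_max))))[2])
  } else {
    steps <- n - 1
    L <- sum(abs(diff(x)))
    d <- max(abs(x - x[1]))
    denom <- log10(d / L) + log10(steps)
    if (!is.finite(denom) || denom <= 0) {
      warning("degenerate Katz denominator; returning 1")
      return(1.0)
    }
    log10(steps) / denom
  }
}

#' Chaos screen
#'
#' A recording qualifies for low-dimensional chaotic modelling when its
#' maximal Lyapunov exponent is positive and its correlation dimension is
#' below `dcorr_max`.
#'
#' @param nld list (or one-row data.frame) with elements `mle` and `dcorr`.
#' @param dcorr_max upper dimension bound (default 3).
#' @return List with logical `pass` and a character vector `reasons` naming
#'   any failed criteria.
#' @export
chaos_screen <- function(nld, dcorr_max = 3) {
  mle <- nld$mle
  dcorr <- nld$dcorr
  if (!is.finite(mle) || !is.finite(dcorr)) stop("features must be finite")
  reasons <- character(0)
  if (mle <= 0) reasons <- c(reasons, "MLE <= 0")
  if (dcorr >= dcorr_max) reasons <- c(reasons, sprintf("DCorr >= %g", dcorr_max))
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Nonlinear-dynamics feature bank for one series
#'
#' Computes the seven NLD features used by the modelling stage: maximal
#' Lyapunov exponent (nats/sample), correlation dimension, sample entropy,
#' order-2 Renyi entropy, Hurst exponent, and Higuchi and Katz fractal
#' dimensions. The embedding delay is selected by AMI; the dimension is
#' either fixed (`dim`) or FNN-selected (`dim = NULL`).
#'
#' @param x numeric series (a preprocessed recording).
#' @param rate_hz sampling rate of `x`.
#' @param dim fixed embedding dimension, or `NULL` for FNN selection.
#' @param max_points cap on embedded points for neighbour searches.
#' @return Named list of the seven features plus `tau` and `emb_dim`.
#' @export
nld_features <- function(x, rate_hz, dim = 5, max_points = 3000) {
  x <- as.numeric(x)
  tau <- select_delay(x, max_lag = max(10L, min(floor(length(x) / 4), 100L)))
  d <- dim %||% select_embedding_dim(x, tau, max_dim = 6)
  pts <- delay_embedding(x, d, tau)
  theiler <- d * tau
  mle <- max_lyapunov(pts, tau = tau, theiler = theiler, rate_hz = rate_hz,
                      max_points = max_points)
  dcorr <- correlation_dimension(pts, tau = tau, theiler = theiler,
                                 max_points = max_points)
  list(mle = as.numeric(mle),
       dcorr = as.numeric(dcorr),
       sampen = sample_entropy(x),
       renyi_q2 = renyi_entropy(x, q = 2),
       hurst = hurst_exponent(x),
       higuchi_fd = fractal_dimension(x, "higuchi"),
       katz_fd = fractal_dimension(x, "katz"),
       tau = tau, emb_dim = d)
}
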