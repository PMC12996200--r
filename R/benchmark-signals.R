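#' Generate a benchmark signal with known dynamical invariants
#'
#' Produces standard test-bed series for nonlinear-dynamics estimators:
#' chaotic flows and maps with known Lyapunov exponents and attractor
#' dimensions, fractional Gaussian noise with a prescribed Hurst exponent,
#' plus sine and white-noise controls. Identical `(kind, params, n, seed)`
#' reproduce bitwise-identical values.
#'
#' @param kind one of `"lorenz"`, `"henon"`, `"logistic_map"`, `"fgn"`,
#'   `"sine"`, `"white_noise"`.
#' @param params named list of parameters; missing entries take the defaults
#'   listed below.
#' @param n number of samples to return (>= 16).
#' @param seed integer seed for stochastic kinds (ignored by deterministic
#'   systems).
#'
#' @details Defaults: Lorenz `sigma = 10`, `rho = 28`, `beta = 8/3`,
#'   `dt = 0.01`, initial state `(-8, 8, 27)`, `transient_frac = 0.1`
#'   (integrated with a fixed-step RK4 and the leading fraction discarded);
#'   Henon `a = 1.4`, `b = 0.3`, 100 discarded transient iterates; logistic
#'   map `r=4`, `x0 = 0.2` (the returned orbit starts at `x0` exactly);
#'   fGn requires `H` in (0, 1) and uses exact circulant-embedding
#'   (Davies-Harte) synthesis with unit variance; sine takes `freq`, `rate`,
#'   `amplitude`, `phase`; white noise takes `sd`.
#'
#' @return An object of class `benchmark_signal`: a list with `kind`,
#'   `params`, `n`, `seed` and the numeric `values`.
#' @export
#' @examples
#' s <- generate_benchmark_signal("logistic_map", list(r = 4, x0 = 0.2), 100, 0)
#' head(s$values)
generate_benchmark_signal <- function(kind, params = list(), n, seed = 0L) {
  if (!is.numeric(n) || n < 16) stop("`n` must be >= 16")
  n <- as.integer(n)
  kinds <- c("lorenz", "henon", "logistic_map", "fgn", "sine", "white_noise")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds) {
    stop("unknown benchmark signal kind: ", paste(kind, collapse = ","))
  }
  values <- switch(kind,
    sine = {
      p <- merge_params(params, list(freq = 1, rate = 100, amplitude = 1, phase = 0))
      if (p$freq <= 0 || p$rate <= 0) stop("sine requires positive freq and rate")
      p$amplitude * sin(2 * pi * p$freq * (0:(n - 1)) / p$rate + p$phase)
    },
    white_noise = {
      p <- merge_params(params, list(sd = 1))
      withr::with_seed(seed, rnorm(n, sd = p$sd))
    },
    logistic_map = {
      p <- merge_params(params, list(r = 4, x0 = 0.2, transient = 0))
      if (p$r <= 0 || p$r > 4) stop("logistic map requires r in (0, 4]")
      iterate_map(function(x) p$r * x * (1 - x), p$x0, n, p$transient)
    },
    henon = {
      p <- merge_params(params, list(a = 1.4, b = 0.3, x0 = 0.1, y0 = 0.3,
                                     transient = 100))
      henon_orbit(p$a, p$b, p$x0, p$y0, n, p$transient)
    },
    lorenz = {
      p <- merge_params(params, list(sigma = 10, rho = 28, beta = 8 / 3,
                                     dt = 0.01, x0 = c(-8, 8, 27),
                                     transient_frac = 0.1, coord = "x"))
      lorenz_orbit(p, n)
    },
    fgn = {
      p <- merge_params(params, list(H = NULL, sd = 1))
      if (is.null(p$H) || !is.numeric(p$H) || p$H <= 0 || p$H >= 1) {
        stop("fGn requires Hurst parameter H in (0, 1)")
      }
      p$sd * fgn_davies_harte(n, p$H, seed)
    }
  )
  structure(list(kind = kind, params = params, n = n, seed = seed,
                 values = values),
            class = "benchmark_signal")
}

merge_params <- function(params, defaults) {
  if (length(params)) {
    bad <- setdiff(names(params), names(defaults))
    if (length(bad)) stop("invalid parameter(s): ", paste(bad, collapse = ", "))
    defaults[names(params)] <- params
  }
  defaults
}

iterate_map <- function(f, x0, n, transient) {
  x <- x0
  for (i in seq_len(transient)) x <- f(x)
  out <- numeric(n)
  out[1] <- x
  for (i in seq_len(n - 1)) out[i + 1] <- f(out[i])
  out
}

henon_orbit <- function(a, b, x, y, n, transient) {
  out <- numeric(n)
  total <- n + transient
  for (i in seq_len(total)) {
    xn <- 1 - a * x^2 + y
    y <- b * x
    x <- xn
    if (!is.finite(x)) stop("Henon orbit diverged; check parameters")
    if (i > transient) out[i - transient] <- x
  }
  out
}

lorenz_orbit <- function(p, n) {
  n_trans <- ceiling(p$transient_frac * n)
  times <- seq(0, by = p$dt, length.out = n + n_trans)
  deriv <- function(t, state, parms) {
    x <- state[1]; y <- state[2]; z <- state[3]
    list(c(p$sigma * (y - x), x * (p$rho - z) - y, x * y - p$beta * z))
  }
  sol <- deSolve::ode(y = p$x0, times = times, func = deriv, parms = NULL,
                      method = "rk4")
  col <- match(p$coord, c("x", "y", "z"))
  if (is.na(col)) stop("lorenz coord must be one of x, y, z")
  as.numeric(sol[(n_trans + 1):(n_trans + n), col + 1])
}

# Exact fGn synthesis by circulant embedding of the autocovariance
# (Davies-Harte). Unit-variance increments of fractional Brownian motion.
fgn_davies_harte <- function(n, H, seed) {
  k <- 0:n
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  c_row <- c(g[1:n], g[n + 1], rev(g[2:n]))
  lambda <- Re(fft(c_row))
  lambda[lambda < 0] <- 0  # tiny negative eigenvalues from roundoff
  m <- 2 * n
  z <- withr::with_seed(seed, rnorm(2 * n))
  w <- complex(length.out = m)
  w[1] <- sqrt(lambda[1] / m) * z[1]
  w[n + 1] <- sqrt(lambda[n + 1] / m) * z[2]
  re <- z[seq(3, by = 2, length.out = n - 1)]
  im <- z[seq(4, by = 2, length.out = n - 1)]
  w[2:n] <- sqrt(lambda[2:n] / (2 * m)) * complex(real = re, imaginary = im)
  w[(n + 2):m] <- Conj(w[n:2])
  Re(fft(w))[1:n]
}
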